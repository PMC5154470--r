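---
title: "Discovering dynamic connectivity states with variational Bayes HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering dynamic connectivity states with variational Bayes HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbhmm)
```

## The problem

Static functional-connectivity analysis summarizes a whole multi-region
recording with a single covariance or correlation matrix. Many systems —
resting-state fMRI prominently among them — are better described as
switching between a small number of *connectivity states*: periods during
which the covariance between regions is stable, separated by rapid
transitions. `vbhmm` identifies such states from multi-subject,
multi-region time series, quantifies their temporal dynamics (occupancy
rates, mean lifetimes, transition probabilities), and characterizes each
state as a partial-correlation network with a community structure.

## The model

Observations $y_t^s \in \mathbb{R}^M$ (time $t = 1,\dots,T_s$, subject
$s = 1,\dots,S$, $M$ regions) follow a hidden Markov model shared across
subjects. A discrete chain $z_t^s \in \{1,\dots,K\}$ with initial
distribution $\pi$ and transition matrix $A$ selects, at every time point,
a multivariate Gaussian emission:

$$y_t^s \mid z_t^s = k \;\sim\; \mathcal{N}(\mu_k, \Sigma_k).$$

Inference is fully Bayesian with conjugate priors: Dirichlet on $\pi$ and
on each row of $A$, Normal–Wishart on each $(\mu_k, \Sigma_k^{-1})$. The
joint posterior over states and parameters is approximated by a mean-field
factorization $q(Z)\,q(\pi)\,q(A)\,q(\Theta)$, optimized by coordinate
ascent on the negative free energy (evidence lower bound)

$$F(q) = \mathbb{E}_q\!\left[\log \frac{p(Y, Z, \Phi)}{q(Z, \Phi)}\right]
  \;\le\; \log p(Y).$$

Each iteration alternates a conjugate M-step (closed-form hyperparameter
updates from the expected sufficient statistics) and an E-step
(forward–backward recursions over the *sub-normalized* quantities
$\exp \mathbb{E}[\log \pi]$, $\exp \mathbb{E}[\log A]$ and the expected
Gaussian log-densities). With that choice of E-step quantities the lower
bound has the convenient exact form

$$F(q) = \sum_s \log \tilde Z_s
  - \mathrm{KL}(q(\pi)\,\|\,p(\pi))
  - \sum_j \mathrm{KL}(q(A_{j\cdot})\,\|\,p(A_{j\cdot}))
  - \sum_k \mathrm{KL}(q(\mathrm{NW}_k)\,\|\,p(\mathrm{NW}_k)),$$

where $\tilde Z_s$ is the forward-recursion normalizer of subject $s$.
`free_energy()` computes exactly this; the test suite asserts it is
non-decreasing over iterations (to $10^{-6}$), which is the defining
property of mean-field coordinate ascent and the package's main internal
correctness check for the update equations.

### Automatic state pruning

$K$ is initialized *above* the number of states the data support (default
25). The Dirichlet concentrations default to $1/K$: this sparse prior makes
the expected log-transition weights into unsupported states strongly
negative, so their responsibilities collapse toward zero, their posteriors
stay at the prior, and they never appear in the decoded paths. The
effective number of states is then simply the number of states with
non-zero Viterbi occupancy — no model-selection sweep over $K$ is needed.

### Fixing the means

In resting-state applications the signal mean carries no information and
states should differ only in covariance. The Normal scale hyperparameter
$\lambda_k$ controls this: `fix_means = TRUE` (default) sets
$\lambda_k = 1000$, pinning each posterior mean at the prior mean (zero) so
that states are discovered purely through covariance changes. For task-like
data with genuine level shifts, `fix_means = FALSE` uses a non-informative
$\lambda_k = 0.001$ and lets the data move the means.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `K` | 25 | initial state count; surplus states are pruned |
| `dirichlet_concentration` | `1/K` | sparsity of $\pi$ and $A$ priors; smaller prunes harder |
| `fix_means` | `TRUE` | $\lambda_k = 1000$, states differ by covariance only |
| `nw_dof` | `M + 2` | Wishart dof; smallest integer value giving a finite prior mean covariance |
| `nw_scale` | `(M+2) diag(var)` | prior expected covariance matches the pooled per-node variance |
| `n_restarts` | 100 | K-means initializations; the max-$F$ restart is kept |
| `tol` | `1e-3` | free-energy improvement (nats/iteration) at convergence |
| `tr_seconds` | — | sampling interval; converts lifetimes to seconds |

The prior scale choices deserve a note: published applications of this
model class report the hyperparameters only in an appendix we treat as
unavailable, so the package picks data-scaled defaults (prior expected
covariance equal to the empirical diagonal) and exposes every value through
`vbhmm_priors()`. Exact numerical equivalence with any particular published
fit is therefore not claimed; the validation suite instead checks that the
*behavior* (pruning, recovery of planted covariance structure, dynamics
metrics) matches.

### Why restarts matter

K-means initialization is the only stochastic ingredient, and coordinate
ascent only finds local optima. Restarts differ substantially in their
final $F$, and low-$F$ solutions typically split one true state across two
fitted states (inflating the state count and deflating the dominant-state
occupancy). Selecting the maximum-$F$ restart across 100 initializations
reliably returns the maximally pruned solution, while small restart
counts noticeably degrade recovery on the validation simulations.
Restart $r$ uses seed `seed + r - 1`, making every fit exactly
reproducible; the winning restart index is stored in the result.

## Dynamics metrics

All dynamics are computed from the Viterbi paths (ties broken toward the
lower state index, decoded in log space):

* **Occupancy rate**: $100 \cdot$ (time points in state $k$) / (total time
  points), pooled over subjects; also per subject. Sums to exactly 100.
* **Mean lifetime**: mean length of maximal runs of a state, times the
  sampling interval. Runs truncated by the scan boundaries count as
  complete runs (the conservation law *lifetime × run count = total time in
  state* then holds exactly); unvisited states report 0.
* **Subject transition matrices**: the default `mle` estimator is
  $C(i,j)/\sum_j C(i,j)$ from consecutive-pair counts, whose rows over
  visited source states sum to 1. A second mode, `as_printed`, implements
  the joint/marginal construction $A(i,j) = p(i,j)/p(i)$ with
  $p(i,j) = C(i,j)/(C(i)C(j))$ and $p(i) = C(i)/T$ exactly as it is
  sometimes printed; note that form reduces to $T\,C(i,j)/(C(i)^2 C(j))$
  and is not row-stochastic in general. Both are provided so users can
  reproduce either convention; summaries default to `mle`.

Group metrics pool counts and runs across subjects rather than averaging
per-subject ratios; per-subject values are returned alongside so that
mean ± SEM summaries across subjects can be formed.

## From states to networks

Each active state's expected covariance is `scale_matrix / dof` of its
Normal–Wishart posterior — regularized by the prior, hence always full
rank — and is converted to partial correlations by inverting and rescaling:
$\rho_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}$.

Communities are found on the *unthresholded, signed* partial-correlation
matrix with a Louvain optimization of signed modularity in the asymmetric
convention: the positive part of the weight matrix is normalized by the
total positive strength $v^+$ and the negative part by $v^+ + v^-$, so
negative edges discourage co-assignment more weakly than positive edges
encourage it. The diagonal is zeroed before clustering. Because Louvain's
greedy node-moving depends on the visiting order, `detect_communities()`
runs 100 randomized restarts under a fixed seed stream and keeps the
max-modularity partition (the test suite verifies it attains the global
optimum found by exhaustive partition search on 6-node problems). The
resolution parameter defaults to $\gamma = 1$ and is configurable.

States whose partitions induce the same grouping of nodes (checked
label-permutation-invariantly) are merged into **dynamic functional
networks (DFNs)**: the Viterbi paths are relabeled, runs of sibling states
fuse, and all dynamics are recomputed on the merged labels. DFNs are
ordered by occupancy, and DFNs at or below a configurable cutoff (default
15%) can be pooled into a residual "mixed" DFN. With a node-to-network
label map, link strengths are additionally summarized as within- versus
cross-network means.

## The validation simulators

Three generators reproduce the structure of the validation designs used
for this model class. All draw zero-mean Gaussians; none convolves a
hemodynamic response or adds scanner noise, so they probe the inference
machinery, not fMRI realism. Defaults use 5 subjects.

1. **Block design** (`simulate_block_design`): 2 nodes, alternating
   30-sample OFF/ON blocks over 240 samples; OFF has correlation −0.8, ON
   is uncorrelated. The series length, block length and OFF correlation are
   package choices (configurable), honoring the stated structure of the
   design.
2. **HMM generative** (`simulate_hmm`): 6 nodes, 232 samples, two states
   from a sticky chain ($A_{ii} = 0.98$, uniform start); state 1 correlates
   nodes 1–3 at $r = 0.8$, state 2 nodes 4–6.
3. **Split half** (`simulate_split_half`): 6 nodes, 116 + 116 samples;
   nodes 1–3 correlated in the first half, nodes 4–6 in the second.

What passing on these simulations shows: the fitter prunes to a small
state set, recovers planted covariance structure, and the decoded paths
track the true regimes. What it does not show: robustness to temporal
autocorrelation, non-Gaussian noise, inter-subject parameter heterogeneity,
or hemodynamic blurring — all present in real fMRI and outside these
generators.

Decoded states are matched to true labels by maximizing the label-overlap
matrix over injective assignments (exact search over the small number of
active states, greedy only as a fallback); agreement is the fraction of
time points mapped onto the true state.

## Numerical choices

* All chain computations (forward–backward, Viterbi) run in log space with
  log-sum-exp; underflow cannot occur. The forward–backward recursion is
  compiled (C++); an equivalent pure-R reference implementation is kept and
  cross-checked in the tests.
* Convergence stops a restart when the bound improves by less than `tol`
  nats in an iteration ($|F_t - F_{t-1}| < 10^{-3}$ by default), the
  convention of the standard variational-inference libraries. A *relative*
  criterion ($|\Delta F| / |F|$) was rejected on evidence: with
  $|F| \sim 10^4$ it halts while the bound is still climbing by several
  nats per iteration, freezing the slow late-stage merging of redundant
  states and — worse — making the across-restart max-$F$ model selection
  compare under-converged bounds, which on the validation designs can leave
  a true state split across two fitted states.
* The first M-step consumes the K-means one-hot responsibilities, with
  pairwise marginals taken as outer products of consecutive one-hot rows
  (consistent counting); iteration then alternates M- and E-steps.
* Posterior scale matrices are symmetrized every update; eigenvalues are
  floored at $10^{-8}$ (with a warning) should a degenerate responsibility
  pattern ever drive one near singularity.
* Viterbi and Louvain tie-breaks are deterministic (lower index / first
  appearance), so identical seeds give bit-identical results on the same
  platform. Equality of free energies across platforms is not promised.

## Problem sizes used by the tests

The packaged validation runs fit 5 subjects × 232–240 samples × 25 states
with 100 restarts per simulation (a few minutes each on one CPU); unit
tests use smaller fits (2 subjects, 80–200 samples, `K` ≤ 10, ≤ 10
restarts) and exhaustive oracles at $T \le 8$, $K \le 3$ where exactness is
asserted at $10^{-10}$.

## Known limitations

* Emissions are Gaussian only; no autoregressive or non-Gaussian families.
* Inference is batch variational Bayes; no streaming updates and no
  sampling-based alternative for posterior-approximation diagnostics.
* The transition structure is shared across subjects (subject-specific
  matrices are derived descriptively from decoded paths, not modeled).
* Chance-level significance testing of occupancy/lifetime (permutation
  nulls) is not implemented.
* Mean-field VB is known to underestimate posterior uncertainty; point
  summaries (expected covariances, decoded paths) are the intended output.
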