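RESULTS_SCHEMA_VERSION <- "1.0"

#' Run the full state-discovery pipeline
#'
#' Orchestrates the complete analysis: fit the VB-HMM, Viterbi-decode every
#' subject, summarize state dynamics, extract per-state partial-correlation
#' networks with signed-Louvain communities, and merge states sharing a
#' community structure into dynamic functional networks (DFNs). If
#' `out_dir` is given the bundle is also written to disk with
#' [write_results()].
#'
#' @param data a [roi_ts_set], or `NULL` if `manifest` is given.
#' @param manifest optional path to a manifest file (see
#'   [read_roi_manifest()]); requires `tr_seconds`.
#' @param tr_seconds sampling interval in seconds (defaults to the value
#'   stored in `data`).
#' @param K initial number of states.
#' @param n_restarts,tol,max_iterations,seed passed to [fit_vbhmm()].
#' @param priors optional [vbhmm_priors].
#' @param node_map optional named character vector (or path to a two-column
#'   file) mapping node names to static-network labels, enabling link-type
#'   summaries per DFN.
#' @param dfn_cutoff_pct occupancy cutoff for pooling low-occupancy DFNs
#'   into the mixed DFN (default 15).
#' @param pool_mixed pool low-occupancy DFNs (default TRUE)?
#' @param transition_mode `"mle"` or `"as_printed"`.
#' @param community_runs Louvain restarts per state (default 100).
#' @param out_dir optional output directory.
#' @param verbose print progress.
#' @return An object of class `vbhmm_results`: list with `fit`, `paths`,
#'   `dynamics`, `networks` (per-state), `pruned`, `merged` (DFNs, merged
#'   paths/dynamics, DFN transition matrix), `link_summary` (if `node_map`
#'   given), and `config`.
#' @export
run_pipeline <- function(data = NULL, manifest = NULL, tr_seconds = NULL,
                         K = 25, n_restarts = 100, tol = 1e-3,
                         max_iterations = 200, seed = 1, priors = NULL,
                         node_map = NULL, dfn_cutoff_pct = 15,
                         pool_mixed = TRUE,
                         transition_mode = c("mle", "as_printed"),
                         community_runs = 100, out_dir = NULL,
                         verbose = FALSE) {
  transition_mode <- match.arg(transition_mode)
  if (is.null(data)) {
    if (is.null(manifest)) stop("supply `data` or `manifest`", call. = FALSE)
    if (is.null(tr_seconds)) {
      stop("`tr_seconds` is required with a manifest", call. = FALSE)
    }
    data <- read_roi_manifest(manifest, tr_seconds)
  }
  stopifnot(inherits(data, "roi_ts_set"))
  if (is.null(tr_seconds)) tr_seconds <- data$tr_seconds
  if (is.character(node_map) && length(node_map) == 1) {
    node_map <- read_node_map(node_map)
  }
  if (verbose) message("fitting VB-HMM (K = ", K, ", ", n_restarts,
                       " restarts) ...")
  fit <- fit_vbhmm(data, priors = priors, K = K, n_restarts = n_restarts,
                   tol = tol, max_iterations = max_iterations, seed = seed,
                   verbose = verbose)
  paths <- decode_states(fit, data)
  dyn <- state_dynamics(paths, K = fit$K, tr_seconds = tr_seconds,
                        transition_mode = transition_mode)
  if (verbose) message(length(dyn$zero_states), " of ", fit$K,
                       " states pruned (zero occupancy)")
  sn <- state_networks(fit, paths, seed = seed, n_runs = community_runs)
  merged <- merge_states(sn$networks, paths, tr_seconds = tr_seconds,
                         cutoff_pct = dfn_cutoff_pct,
                         pool_mixed = pool_mixed,
                         transition_mode = transition_mode)
  link_summary <- NULL
  if (!is.null(node_map)) {
    link_summary <- lapply(merged$dfns, function(d) {
      rep_state <- d$member_states[1]
      net <- sn$networks[[which(vapply(sn$networks, function(x) x$state_id,
                                       numeric(1)) == rep_state)]]
      c(dfn_id = d$dfn_id,
        suppressWarnings(classify_links(net$pcorr, node_map)))
    })
  }
  bundle <- structure(
    list(fit = fit, paths = paths, dynamics = dyn,
         networks = sn$networks, pruned = sn$pruned, merged = merged,
         link_summary = link_summary,
         config = list(K = K, n_restarts = n_restarts, tol = tol,
                       max_iterations = max_iterations, seed = seed,
                       tr_seconds = tr_seconds,
                       dfn_cutoff_pct = dfn_cutoff_pct,
                       pool_mixed = pool_mixed,
                       transition_mode = transition_mode,
                       community_runs = community_runs,
                       winning_restart = fit$winning_restart,
                       schema_version = RESULTS_SCHEMA_VERSION)),
    class = "vbhmm_results")
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' @export
print.vbhmm_results <- function(x, ...) {
  cat("VB-HMM results: ", length(x$paths), " subject(s), K = ", x$fit$K,
      ", ", length(x$networks), " active state(s), ",
      length(x$merged$dfns), " DFN(s)\n", sep = "")
  for (d in x$merged$dfns) {
    cat(sprintf("  DFN-%s: states {%s}, occupancy %.1f%%, lifetime %.2f s%s\n",
                d$dfn_id, paste(d$member_states, collapse = ","),
                d$occupancy_pct, d$mean_lifetime_seconds,
                if (isTRUE(d$is_mixed)) " [mixed]" else ""))
  }
  invisible(x)
}

#' Write a results bundle to a directory
#'
#' Numeric artifacts (posterior hyperparameters, free-energy trace, decoded
#' paths, dynamics tables, DFN structure) are serialized as JSON at full
#' double precision, plus human-readable CSV tables for paths, occupancy and
#' lifetimes. A schema version is embedded for compatibility checks on read.
#'
#' @param bundle a `vbhmm_results` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "vbhmm_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fit <- bundle$fit
  posterior <- list(
    schema_version = RESULTS_SCHEMA_VERSION,
    K = fit$K, M = fit$M,
    pi = fit$pi, A = fit$A,
    nw = lapply(fit$nw, function(x) list(m = x$m, lambda = x$lambda,
                                         a = x$a, B = x$B)),
    free_energy_trace = fit$free_energy_trace,
    converged = fit$converged,
    n_iterations = fit$n_iterations,
    winning_restart = fit$winning_restart,
    logZ = as.list(fit$logZ),
    seed = fit$seed
  )
  jsonlite::write_json(posterior, file.path(dir, "posterior.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  paths_df <- do.call(rbind, lapply(bundle$paths, function(p) {
    data.frame(subject = p$subject_id, time = seq_along(p$path),
               state = p$path)
  }))
  utils::write.csv(paths_df, file.path(dir, "state_paths.csv"),
                   row.names = FALSE)
  dyn <- bundle$dynamics
  dynamics <- list(
    schema_version = RESULTS_SCHEMA_VERSION,
    K = dyn$K, tr_seconds = dyn$tr_seconds,
    transition_mode = dyn$transition_mode,
    occupancy_pct = dyn$occupancy_pct,
    mean_lifetime_seconds = dyn$mean_lifetime_seconds,
    occupancy_by_subject = dyn$occupancy_by_subject,
    lifetime_by_subject = dyn$lifetime_by_subject,
    subject_transition = dyn$subject_transition,
    zero_states = as.integer(dyn$zero_states)
  )
  jsonlite::write_json(dynamics, file.path(dir, "dynamics.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  occ_df <- data.frame(state = seq_len(dyn$K),
                       occupancy_pct = dyn$occupancy_pct,
                       mean_lifetime_seconds = dyn$mean_lifetime_seconds)
  utils::write.csv(occ_df, file.path(dir, "dynamics.csv"), row.names = FALSE)
  networks <- list(
    schema_version = RESULTS_SCHEMA_VERSION,
    states = lapply(bundle$networks, function(x) {
      list(state_id = x$state_id, pcorr = x$pcorr, partition = x$partition,
           modularity = x$modularity, occupancy_pct = x$occupancy_pct)
    }),
    pruned = as.integer(bundle$pruned),
    dfns = lapply(bundle$merged$dfns, unclass),
    dfn_transition = bundle$merged$transition,
    merged_paths = lapply(bundle$merged$paths, function(p) {
      list(subject_id = p$subject_id, path = p$path)
    }),
    link_summary = bundle$link_summary
  )
  jsonlite::write_json(networks, file.path(dir, "networks.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(c(bundle$config,
                         list(schema_version = RESULTS_SCHEMA_VERSION)),
                       file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @noRd
read_results_json <- function(dir, name) {
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop("results file missing: ", path, call. = FALSE)
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  sv <- x$schema_version
  if (is.null(sv) || !identical(as.character(sv), RESULTS_SCHEMA_VERSION)) {
    stop("schema version mismatch in ", name, ": found ",
         if (is.null(sv)) "<none>" else sv, ", expected ",
         RESULTS_SCHEMA_VERSION, call. = FALSE)
  }
  x
}

#' Read a results bundle back from a directory
#'
#' Reconstructs the numeric content written by [write_results()] (posterior
#' hyperparameters, decoded paths, dynamics, networks and DFNs) exactly, up
#' to double-precision round-trip.
#'
#' @param dir directory written by [write_results()].
#' @return list with `posterior`, `paths`, `dynamics`, `networks` and
#'   `config` fields mirroring the written artifacts.
#' @export
read_results <- function(dir) {
  post <- read_results_json(dir, "posterior.json")
  if (!is.matrix(post$A)) post$A <- matrix(unlist(post$A), post$K, post$K)
  post$nw <- lapply(post$nw, function(x) {
    B <- x$B
    if (!is.matrix(B)) B <- matrix(unlist(B), length(x$m), length(x$m))
    list(m = as.numeric(x$m), lambda = x$lambda, a = x$a, B = B)
  })
  dynamics <- read_results_json(dir, "dynamics.json")
  networks <- read_results_json(dir, "networks.json")
  config <- read_results_json(dir, "config.json")
  paths_df <- utils::read.csv(file.path(dir, "state_paths.csv"))
  paths <- lapply(split(paths_df, paths_df$subject), function(d) {
    d <- d[order(d$time), ]
    structure(list(subject_id = as.character(d$subject[1]),
                   path = as.integer(d$state)),
              class = "state_sequence")
  })
  list(posterior = post, paths = paths, dynamics = dynamics,
       networks = networks, config = config)
}
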