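#' Multi-subject region-of-interest time series
#'
#' Container for the observations fed to [fit_vbhmm()]: one numeric matrix
#' per subject with time points in rows and regions (nodes) in columns, plus
#' the sampling interval (TR) in seconds. All subjects must share the same
#' node count; series lengths may differ.
#'
#' @param series a numeric matrix or a list of numeric matrices, each
#'   `T_s x M` (rows = time points, columns = nodes).
#' @param tr_seconds positive sampling interval in seconds (the fMRI TR).
#' @param ids optional character vector of subject identifiers; defaults to
#'   names of `series` or `"subject_1"`, `"subject_2"`, ...
#'
#' @return An object of class `roi_ts_set`: a list with elements `subjects`
#'   (named list of matrices), `tr_seconds`, `M` (node count) and
#'   `node_names`.
#' @export
roi_ts_set <- function(series, tr_seconds, ids = NULL) {
  if (is.matrix(series)) series <- list(series)
  if (!is.list(series) || length(series) == 0) {
    stop("`series` must be a matrix or a non-empty list of matrices",
         call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- names(series)
    if (is.null(ids) || any(ids == "")) {
      ids <- paste0("subject_", seq_along(series))
    }
  }
  if (length(ids) != length(series) || anyDuplicated(ids)) {
    stop("`ids` must be unique and match the number of series", call. = FALSE)
  }
  series <- lapply(series, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  M <- ncol(series[[1]])
  if (M < 2) stop("at least 2 nodes are required", call. = FALSE)
  for (i in seq_along(series)) {
    x <- series[[i]]
    if (ncol(x) != M) {
      stop("subject '", ids[i], "' has ", ncol(x),
           " nodes; expected ", M, call. = FALSE)
    }
    if (nrow(x) < 2) {
      stop("subject '", ids[i], "' has fewer than 2 time points",
           call. = FALSE)
    }
    if (any(!is.finite(x))) {
      stop("subject '", ids[i], "' contains non-finite values (NaN/Inf/NA)",
           call. = FALSE)
    }
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    stop("`tr_seconds` must be a single positive number", call. = FALSE)
  }
  node_names <- colnames(series[[1]])
  if (is.null(node_names)) node_names <- paste0("node_", seq_len(M))
  series <- lapply(series, function(x) {
    colnames(x) <- node_names
    x
  })
  names(series) <- ids
  structure(
    list(subjects = series, tr_seconds = as.numeric(tr_seconds),
         M = M, node_names = node_names),
    class = "roi_ts_set"
  )
}

#' @export
print.roi_ts_set <- function(x, ...) {
  Ts <- vapply(x$subjects, nrow, integer(1))
  cat("ROI time-series set: ", length(x$subjects), " subject(s), ",
      x$M, " nodes, TR = ", x$tr_seconds, " s\n", sep = "")
  cat("  series lengths: ", paste(Ts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Stack all subjects' samples into one (sum T_s) x M matrix.
#' @noRd
stack_series <- function(data) do.call(rbind, unname(data$subjects))

#' Read one subject's time series from a delimited text file
#'
#' Rows are time points, columns are nodes. The delimiter is inferred from
#' the file extension (`.tsv`/`.txt` = tab, otherwise comma) and a header
#' row of node names is auto-detected.
#'
#' @param path path to a CSV/TSV file.
#' @return numeric matrix `T_s x M`.
#' @export
read_roi_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(cells))))
  df <- utils::read.table(path, sep = sep, header = header,
                          check.names = FALSE)
  as.matrix(df)
}

#' Assemble a [roi_ts_set] from a manifest file
#'
#' The manifest is a two-column delimited text file (comma or whitespace):
#' subject id, then the path (absolute, or relative to the manifest) of that
#' subject's series file.
#'
#' @param manifest_path path to the manifest file.
#' @param tr_seconds sampling interval in seconds.
#' @return A [roi_ts_set].
#' @export
read_roi_manifest <- function(manifest_path, tr_seconds) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  lines <- readLines(manifest_path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("manifest is empty: ", manifest_path,
                               call. = FALSE)
  base <- dirname(manifest_path)
  ids <- character(length(lines))
  series <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[,\t ]+")[[1]]
    if (length(parts) < 2) {
      stop("manifest line ", i, " needs 'id path': ", lines[i], call. = FALSE)
    }
    ids[i] <- parts[1]
    p <- parts[2]
    if (!file.exists(p)) p <- file.path(base, parts[2])
    series[[i]] <- read_roi_series(p)
  }
  roi_ts_set(series, tr_seconds, ids = ids)
}

#' Read a node-to-static-network label map
#'
#' Two-column text file: node name, static network label (e.g. SN, CEN,
#' DMN). Used by [classify_links()] to split links into within- and
#' cross-network types.
#'
#' @param path path to the map file.
#' @return named character vector: names are node names, values are labels.
#' @export
read_node_map <- function(path) {
  if (!file.exists(path)) stop("node map not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, col.names = c("node", "network"),
                          colClasses = "character")
  stats::setNames(df$network, df$node)
}
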