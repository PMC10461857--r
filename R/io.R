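#' Write / read a spike raster as plain text
#'
#' Three 0-based columns `time_ms neuron trial` after a header line carrying
#' the raster dimensions, e.g. `# N=100 t_run=2000 dt=1 n_trials=2`.
#'
#' @param raster a `spike_raster`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d t_run=%g dt=%g n_trials=%d",
                     attr(raster, "N"), attr(raster, "t_run"),
                     attr(raster, "dt"), attr(raster, "n_trials")), con)
  writeLines("time_ms neuron trial", con)
  if (nrow(raster) > 0)
    utils::write.table(
      data.frame(time_ms = raster$time, neuron = raster$neuron - 1L,
                 trial = raster$trial - 1L),
      con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[A-Za-z_]+=[0-9.eE+-]+", hdr))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  df <- utils::read.table(path, skip = 2,
                          col.names = c("time", "neuron", "trial"))
  if (nrow(df)) { df$neuron <- df$neuron + 1L; df$trial <- df$trial + 1L }
  structure(df, N = as.integer(meta[["N"]]), t_run = meta[["t_run"]],
            dt = meta[["dt"]], n_trials = as.integer(meta[["n_trials"]]),
            class = c("spike_raster", "data.frame"))
}

#' Write a time x neuron trajectory to CSV
#'
#' First column `time_ms`, one column per neuron.
#' @param X a `rate_matrix`, `rate_trajectory` or plain matrix.
#' @param path output file.
#' @param times sample times (taken from the object when available).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(X, path, times = NULL) {
  if (inherits(X, "rate_trajectory")) { times <- X$times; X <- X$r }
  if (is.null(times)) times <- attr(X, "times")
  X <- as.matrix(X)
  df <- data.frame(time_ms = times, X)
  names(df) <- c("time_ms", paste0("n", seq_len(ncol(X))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a bifurcation diagram as JSON
#'
#' Schema: `{sweep, kappa_thr, values: [...], branches: [{value, overlap,
#' branch, kappa, rate, stable}, ...]}`.
#' @param diagram a `bifurcation_diagram` (see [scan_bifurcation()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bifurcation_json <- function(diagram, path) {
  stopifnot(inherits(diagram, "bifurcation_diagram"))
  obj <- list(sweep = attr(diagram, "sweep"),
              kappa_thr = attr(diagram, "kappa_thr"),
              n_realizations = attr(diagram, "n_realizations"),
              values = unique(diagram$value),
              branches = as.data.frame(diagram))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export PCA and alignment summaries as CSV
#'
#' One row per principal component: eigenvalue, explained fraction, and the
#' cosine with each named direction.
#' @param pca a `pca_result`.
#' @param alignment an `alignment_table` from [pc_alignment()] (optional).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pca_csv <- function(pca, path, alignment = NULL) {
  k <- if (!is.null(alignment)) nrow(alignment)
       else min(8, length(pca$explained))
  df <- data.frame(pc = seq_len(k),
                   eigenvalue = pca$eigenvalues[seq_len(k)],
                   explained = pca$explained[seq_len(k)])
  if (!is.null(alignment))
    df <- cbind(df, alignment[seq_len(k), -1, drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a sparse matrix as 0-based coordinate-list text
#' @param mat a sparse matrix.
#' @param path output file (columns: row, col, value_mV).
#' @return `path`, invisibly.
#' @export
write_sparse_coo <- function(mat, path) {
  trip <- Matrix::mat2triplet(mat)
  utils::write.table(
    data.frame(row = trip$i - 1L, col = trip$j - 1L, value_mV = trip$x),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
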