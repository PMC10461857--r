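#' Project trajectories onto a direction in state space
#'
#' `mean` mode computes `(1/N) sum_i w_i r_i(t)` (so the all-ones direction
#' yields the population-averaged rate); `unit_norm` mode computes
#' `X w / ||w||^2`, the latent-coordinate convention.
#'
#' @param X trajectory matrix, time x neuron (a `rate_matrix`, the `r` field
#'   of a `rate_trajectory`, or any numeric matrix).
#' @param w direction vector (length N).
#' @param normalization `"mean"` or `"unit_norm"`.
#' @return numeric time series.
#' @export
project <- function(X, w, normalization = c("mean", "unit_norm")) {
  normalization <- match.arg(normalization)
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(w))
  if (normalization == "mean") as.numeric(X %*% w) / ncol(X)
  else {
    nw <- sum(w^2)
    if (nw == 0) stop("zero direction vector in unit_norm mode")
    as.numeric(X %*% w) / nw
  }
}

#' Principal component analysis of a trajectory matrix
#'
#' Column-centers the time x neuron matrix `X` and eigendecomposes the
#' correlation matrix `C = Xc^T Xc`, returning the orthonormal components
#' sorted by decreasing eigenvalue together with the explained-variance
#' fractions (diagonal of the rotated correlation matrix over its trace).
#' When there are fewer time samples than neurons the spectrum is obtained
#' through the dual (Gram) matrix `Xc Xc^T`, which has the same nonzero
#' eigenvalues; the components returned are identical.
#'
#' @param X trajectory matrix (time x neuron).
#' @param n_pc number of components to return (default: all nonzero).
#' @return an object of class `pca_result`: `components` (neuron x n_pc,
#'   orthonormal), `eigenvalues` (all, sorted), `explained` (fractions),
#'   `total_var` (trace of C), `degenerate` flag.
#' @export
run_pca <- function(X, n_pc = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 time points")
  Xc <- sweep(X, 2, colMeans(X))
  Tn <- nrow(Xc); N <- ncol(Xc)
  kmax <- min(Tn - 1, N)
  if (is.null(n_pc)) n_pc <- kmax
  n_pc <- min(n_pc, kmax)
  total <- sum(Xc^2)
  if (total < .Machine$double.eps * Tn * N) {
    return(structure(list(components = matrix(0, N, 0),
                          eigenvalues = numeric(0), explained = numeric(0),
                          total_var = 0, degenerate = TRUE),
                     class = "pca_result"))
  }
  if (N <= Tn) {
    e <- eigen(crossprod(Xc), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    comp <- e$vectors[, seq_len(n_pc), drop = FALSE]
  } else {
    g <- eigen(tcrossprod(Xc), symmetric = TRUE)
    lam <- pmax(g$values[seq_len(kmax)], 0)
    keep <- seq_len(n_pc)
    comp <- crossprod(Xc, g$vectors[, keep, drop = FALSE])
    comp <- sweep(comp, 2, sqrt(pmax(lam[keep], .Machine$double.eps)), "/")
  }
  structure(list(components = comp, eigenvalues = lam,
                 explained = lam / sum(lam), total_var = total,
                 degenerate = FALSE),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  if (x$degenerate) { cat("pca_result: degenerate (constant) input\n") }
  else {
    k <- min(8, length(x$explained))
    cat("pca_result:", ncol(x$components), "components;",
        "explained fractions:", paste(signif(x$explained[seq_len(k)], 3),
                                      collapse = " "), "\n")
  }
  invisible(x)
}

#' Alignment of principal components with named directions
#'
#' Signed cosine of each component with each unit-normalized direction.
#' Directions are used raw (not orthogonalized), matching the convention of
#' reporting projections of PCs onto the global axis and the input and
#' connectivity vectors directly.
#'
#' @param pca a `pca_result`.
#' @param directions named list of vectors (e.g. `list(global = rep(1, N),
#'   I = ens$I[, 1], m = ens$m[, 1])`).
#' @param n_pc number of components to report.
#' @return an `alignment_table`: data frame with `pc` and one cosine column
#'   per direction.
#' @export
pc_alignment <- function(pca, directions, n_pc = ncol(pca$components)) {
  stopifnot(inherits(pca, "pca_result"), length(directions) > 0,
            !is.null(names(directions)))
  n_pc <- min(n_pc, ncol(pca$components))
  out <- data.frame(pc = seq_len(n_pc))
  for (nm in names(directions)) {
    d <- directions[[nm]]
    if (sqrt(sum(d^2)) == 0) stop("zero-norm direction '", nm, "'")
    out[[nm]] <- vapply(seq_len(n_pc), function(k)
      cosine(pca$components[, k], d), numeric(1))
  }
  structure(out, class = c("alignment_table", "data.frame"))
}

#' PC1 geometry as a function of the spike-filter timescale
#'
#' For each filter time constant, converts the raster to instantaneous rates,
#' averages over trials, runs PCA, and records the alignment (absolute
#' cosine) of the first principal component with each named direction, plus
#' its alignment with the plane spanned by all non-global directions. Used to
#' show how fast filtering emphasizes synchronous population fluctuations
#' along the global axis while slow filtering reveals the low-rank plane.
#'
#' @param raster a `spike_raster`.
#' @param tau_f_values filter time constants (ms).
#' @param directions named list of direction vectors; include `global` for
#'   the all-ones axis if wanted.
#' @param dt_out rate sampling step (ms).
#' @param t_min discard samples before this time (filter burn-in; ms).
#' @return data frame with one row per `tau_f`: `|cos(PC1, direction)|` per
#'   direction, `plane` (alignment of PC1 with span of the non-global
#'   directions), and `explained1`. Degenerate (zero-variance) rate matrices
#'   yield `NA` rows.
#' @export
filter_timescale_sweep <- function(raster, tau_f_values, directions,
                                   dt_out = NULL, t_min = 0) {
  stopifnot(all(tau_f_values > 0))
  nong <- setdiff(names(directions), "global")
  rows <- lapply(tau_f_values, function(tf) {
    dt_use <- if (is.null(dt_out)) max(min(tf / 2, 10), attr(raster, "dt"))
              else dt_out
    rates <- average_trials(filter_spikes(raster, tau_f = tf,
                                          dt_out = dt_use))
    keep <- attr(rates, "times") >= t_min
    p <- run_pca(rates[keep, , drop = FALSE], n_pc = 3)
    row <- list(tau_f = tf)
    if (p$degenerate) {
      for (nm in names(directions)) row[[nm]] <- NA_real_
      row$plane <- NA_real_; row$explained1 <- NA_real_
    } else {
      al <- pc_alignment(p, directions, n_pc = 1)
      for (nm in names(directions)) row[[nm]] <- abs(al[[nm]][1])
      row$plane <- if (length(nong))
        subspace_alignment(p$components[, 1],
                           do.call(cbind, directions[nong]))
      else NA_real_
      row$explained1 <- p$explained[1]
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}
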