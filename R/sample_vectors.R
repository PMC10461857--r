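#' Sample a correlated ensemble of connectivity/input/readout vectors
#'
#' Draws, for each of `N` neurons, one i.i.d. realization of the joint Gaussian
#' described by `stats`, and returns the vectors as columns of matrices. The
#' sampler factorizes the joint covariance with a (pivoted) triangular
#' factorization over independent standard-normal factors, which generalizes
#' the usual explicit three-vector construction to arbitrary rank and input
#' count, and handles degenerate (rank-deficient) covariances such as a vector
#' exactly aligned with another.
#'
#' Identical `(stats, N, seed)` reproduce the ensemble bit-for-bit.
#'
#' @param stats a [vector_stats()] object.
#' @param N number of neurons.
#' @param seed integer seed.
#' @param I_norm optional target Euclidean norm(s) for the input vector(s):
#'   after sampling, each input column is rescaled so its norm is exactly
#'   `I_norm[s]`. `NA` entries leave the column untouched. This implements the
#'   amplitude convention in which a preset quotes the overall norm `|I|` of a
#'   unit-standard-deviation input pattern.
#' @return an object of class `vector_ensemble`: list with matrices `m`, `n`
#'   (`N x rank`), `I` (`N x n_in`), vector `w` (length `N`), plus `stats`,
#'   `N` and `seed`.
#' @export
#' @examples
#' ens <- sample_vectors(rank1_stats(cov_nI = 1), N = 1000, seed = 1)
#' crossprod(ens$n, ens$I)[1] / 1000  # close to 1
sample_vectors <- function(stats, N, seed, I_norm = NULL) {
  stopifnot(inherits(stats, "vector_stats"), N >= 1)
  Sigma <- stats$Sigma
  d <- ncol(Sigma)
  ch <- suppressWarnings(chol(Sigma, pivot = TRUE))
  r <- attr(ch, "rank")
  piv <- attr(ch, "pivot")
  Rfac <- ch[seq_len(r), order(piv), drop = FALSE]  # t(Rfac) %*% Rfac == Sigma

  X <- with_seed(seed, matrix(stats::rnorm(N * r), N, r)) %*% Rfac
  X <- sweep(X, 2, stats$mu, "+")
  colnames(X) <- colnames(Sigma)

  rank <- stats$rank; n_in <- stats$n_in
  m <- X[, paste0("m", seq_len(rank)), drop = FALSE]
  n <- X[, paste0("n", seq_len(rank)), drop = FALSE]
  I <- if (n_in > 0) X[, paste0("I", seq_len(n_in)), drop = FALSE]
       else matrix(0, N, 0)
  w <- X[, "w"]

  if (!is.null(I_norm) && n_in > 0) {
    I_norm <- rep_len(I_norm, n_in)
    for (s in seq_len(n_in)) {
      if (is.na(I_norm[s])) next
      nrm <- sqrt(sum(I[, s]^2))
      if (nrm == 0) stop("cannot rescale all-zero input vector ", s)
      I[, s] <- I[, s] * (I_norm[s] / nrm)
    }
  }

  structure(list(m = m, n = n, I = I, w = w, stats = stats,
                 N = N, seed = as.integer(seed)),
            class = "vector_ensemble")
}

#' @export
print.vector_ensemble <- function(x, ...) {
  cat("vector_ensemble: N =", x$N, ", rank =", x$stats$rank,
      ", inputs =", x$stats$n_in, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Factored low-rank connectivity matrix
#'
#' Represents `P = (1/N) sum_r m^(r) n^(r)T` in factored form, supporting
#' O(N R) matrix-vector products. Dense materialization is refused above a
#' size threshold because entries scale as 1/N and the dense form is only
#' useful for small-N checks.
#'
#' @param ensemble a `vector_ensemble`, or a list with matrices `m` and `n`.
#' @return an object of class `lowrank_matrix` (fields `m`, `n`, `N`).
#' @export
lowrank_matrix <- function(ensemble) {
  m <- as.matrix(ensemble$m); n <- as.matrix(ensemble$n)
  stopifnot(nrow(m) == nrow(n), ncol(m) == ncol(n), all(is.finite(m)),
            all(is.finite(n)))
  structure(list(m = m, n = n, N = nrow(m)), class = "lowrank_matrix")
}

#' Dense form of a factored low-rank matrix
#' @param lr a `lowrank_matrix`.
#' @param max_n refuse materialization above this N (guards memory).
#' @return dense `N x N` matrix with entries `sum_r m_i^(r) n_j^(r) / N`.
#' @export
as_dense <- function(lr, max_n = 5000) {
  stopifnot(inherits(lr, "lowrank_matrix"))
  if (lr$N > max_n)
    stop("refusing to materialize a dense ", lr$N, "x", lr$N,
         " matrix (max_n = ", max_n, ")")
  tcrossprod(lr$m, lr$n) / lr$N
}

#' Matrix-vector product through the factored form
#' @param lr a `lowrank_matrix`.
#' @param x vector of length N (or `N x k` matrix).
#' @return `P %*% x` computed in O(N R k).
#' @export
lr_matvec <- function(lr, x) {
  lr$m %*% (crossprod(lr$n, x) / lr$N)
}

#' Empirical overlaps of a sampled ensemble
#'
#' Computes the raw scalar products between all sampled vectors divided by N.
#' The R x R block `P_ov[r, s] = n^(r)T m^(s) / N` is the empirical overlap
#' matrix whose large-N limit (for zero-mean statistics) is the covariance
#' `cov(n_r, m_s)`; input overlaps `n^(r)T I^(s) / N` are reported alongside.
#'
#' @param ensemble a `vector_ensemble`.
#' @return an object of class `overlap_summary`: `P_ov` (R x R), `nI`
#'   (R x n_in), `gram` (all pairwise overlaps, named), `means`, `sds`.
#' @export
empirical_overlaps <- function(ensemble) {
  stopifnot(inherits(ensemble, "vector_ensemble"))
  rank <- ensemble$stats$rank; n_in <- ensemble$stats$n_in
  A <- cbind(ensemble$m, ensemble$n, ensemble$I, ensemble$w)
  colnames(A) <- c(paste0("m", seq_len(rank)), paste0("n", seq_len(rank)),
                   if (n_in > 0) paste0("I", seq_len(n_in)), "w")
  gram <- crossprod(A) / ensemble$N
  P_ov <- gram[paste0("n", seq_len(rank)), paste0("m", seq_len(rank)),
               drop = FALSE]
  nI <- if (n_in > 0)
    gram[paste0("n", seq_len(rank)), paste0("I", seq_len(n_in)), drop = FALSE]
  else matrix(0, rank, 0)
  structure(list(P_ov = P_ov, nI = nI, gram = gram,
                 means = colMeans(A), sds = apply(A, 2, stats::sd)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("overlap matrix n^T m / N:\n"); print(x$P_ov)
  if (ncol(x$nI)) { cat("input overlaps n^T I / N:\n"); print(x$nI) }
  invisible(x)
}

#' Moments of the entries of a rank-one outer-product matrix
#'
#' For `P_ij = m_i n_j / N`, returns the empirical mean and standard deviation
#' over all `N^2` entries, computed exactly from the sampled vectors without
#' materializing the matrix (the entry moments factorize over i and j).
#'
#' @param ensemble a `vector_ensemble` with rank 1.
#' @return list with `mean` and `sd` of the entries (units of `n`).
#' @export
lowrank_entry_stats <- function(ensemble) {
  stopifnot(inherits(ensemble, "vector_ensemble"), ensemble$stats$rank == 1)
  m <- ensemble$m[, 1]; n <- ensemble$n[, 1]; N <- ensemble$N
  e_m <- mean(m); e_n <- mean(n)
  e_m2 <- mean(m^2); e_n2 <- mean(n^2)
  mu <- e_m * e_n / N
  v <- (e_m2 * e_n2 - (e_m * e_n)^2) / N^2
  list(mean = mu, sd = sqrt(max(v, 0)))
}
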