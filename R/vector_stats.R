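#' Joint Gaussian statistics of connectivity, input and readout vectors
#'
#' Describes the per-coordinate joint Gaussian distribution from which the
#' right/left connectivity vectors `m^(r)`, `n^(r)` (r = 1..rank), the input
#' vectors `I^(s)` (s = 1..n_in) and the readout vector `w` are sampled.
#' Coordinates are i.i.d. across neurons; within a neuron the variables can be
#' arbitrarily correlated through `cov`.
#'
#' Units follow the spiking-model bookkeeping: `m` and `w` are dimensionless,
#' `n` and `I` carry mV (covariances carry the product of member units). Rate
#' -model presets use the same machinery with all quantities dimensionless.
#'
#' @param rank number of rank-one terms R (>= 1).
#' @param n_in number of input vectors (>= 0).
#' @param mean_m,mean_n means of the m- and n-vector entries; scalars are
#'   recycled to length `rank`.
#' @param mean_I,mean_w means of the input-vector and readout entries
#'   (`mean_I` recycled to length `n_in`).
#' @param sd_m,sd_n,sd_I,sd_w standard deviations, recycled likewise.
#' @param cov named numeric vector of pairwise covariances. Names are
#'   dot-separated variable pairs using the labels `m1..mR`, `n1..nR`,
#'   `I1..In_in`, `w`; for rank-1/single-input configurations the indices may
#'   be dropped (`"m.n"`, `"n.I"`, `"m.w"`, ...). Unlisted pairs are
#'   uncorrelated.
#' @return an object of class `vector_stats` with elements `mu` (named mean
#'   vector) and `Sigma` (named covariance matrix), plus the constructor
#'   arguments.
#' @export
#' @examples
#' # the classic rank-1 configuration: n and I overlap, m independent
#' vector_stats(cov = c("n.I" = 1))
vector_stats <- function(rank = 1, n_in = 1,
                         mean_m = 0, mean_n = 0, mean_I = 0, mean_w = 0,
                         sd_m = 1, sd_n = 1, sd_I = 1, sd_w = 1,
                         cov = NULL) {
  stopifnot(rank >= 1, n_in >= 0)
  mean_m <- rep_len(mean_m, rank);  sd_m <- rep_len(sd_m, rank)
  mean_n <- rep_len(mean_n, rank);  sd_n <- rep_len(sd_n, rank)
  mean_I <- rep_len(mean_I, max(n_in, 1))[seq_len(n_in)]
  sd_I   <- rep_len(sd_I,   max(n_in, 1))[seq_len(n_in)]
  if (any(c(sd_m, sd_n, sd_I, sd_w) < 0))
    stop("standard deviations must be non-negative")

  vars <- c(paste0("m", seq_len(rank)), paste0("n", seq_len(rank)),
            if (n_in > 0) paste0("I", seq_len(n_in)), "w")
  mu <- c(mean_m, mean_n, mean_I, mean_w)
  sd <- c(sd_m, sd_n, sd_I, sd_w)
  names(mu) <- names(sd) <- vars
  d <- length(vars)
  Sigma <- diag(sd^2, d)
  dimnames(Sigma) <- list(vars, vars)

  if (length(cov)) {
    if (is.null(names(cov)) || any(!nzchar(names(cov))))
      stop("`cov` must be a named vector, e.g. c(\"n1.m1\" = 2)")
    for (nm in names(cov)) {
      pair <- .resolve_pair(nm, vars)
      Sigma[pair[1], pair[2]] <- Sigma[pair[2], pair[1]] <- cov[[nm]]
    }
  }
  .check_psd(Sigma, sd)

  structure(list(rank = rank, n_in = n_in, mu = mu, Sigma = Sigma, sd = sd),
            class = "vector_stats")
}

# map a user-supplied pair name like "n.I" or "m1.n2" onto canonical labels
.resolve_pair <- function(nm, vars) {
  parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("covariance name '", nm, "' is not of the form 'x.y'")
  expand <- function(p) {
    if (p %in% vars) return(p)
    p1 <- paste0(p, "1")
    if (p %in% c("m", "n", "I") && p1 %in% vars) return(p1)
    stop("unknown variable '", p, "' in covariance name '", nm, "'")
  }
  c(expand(parts[1]), expand(parts[2]))
}

# positive semi-definiteness check; on failure name the offending pair if one
# 2x2 principal minor is responsible
.check_psd <- function(Sigma, sd, tol = 1e-8) {
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) >= -tol * scale) return(invisible(TRUE))
  vars <- colnames(Sigma)
  for (a in seq_along(vars)) for (b in seq_len(a - 1)) {
    if (abs(Sigma[a, b]) > sd[a] * sd[b] + tol * scale)
      stop("covariance between '", vars[b], "' and '", vars[a],
           "' (", Sigma[a, b], ") exceeds the product of their standard ",
           "deviations (", sd[a] * sd[b], "): covariance matrix is not ",
           "positive semi-definite")
  }
  stop("the implied covariance matrix over (",
       paste(vars, collapse = ", "),
       ") is not positive semi-definite (min eigenvalue ", signif(min(ev), 4), ")")
}

#' Convenience constructor for rank-1, single-input statistics
#'
#' @inheritParams vector_stats
#' @param cov_mn,cov_nI,cov_mI,cov_mw,cov_nw,cov_Iw pairwise covariances.
#' @return a `vector_stats` object.
#' @export
rank1_stats <- function(mean_m = 0, mean_n = 0, mean_I = 0, mean_w = 0,
                        sd_m = 1, sd_n = 1, sd_I = 1, sd_w = 1,
                        cov_mn = 0, cov_nI = 0, cov_mI = 0,
                        cov_mw = 0, cov_nw = 0, cov_Iw = 0) {
  vector_stats(rank = 1, n_in = 1,
               mean_m = mean_m, mean_n = mean_n, mean_I = mean_I,
               mean_w = mean_w,
               sd_m = sd_m, sd_n = sd_n, sd_I = sd_I, sd_w = sd_w,
               cov = c("m.n" = cov_mn, "n.I" = cov_nI, "m.I" = cov_mI,
                       "m.w" = cov_mw, "n.w" = cov_nw, "I.w" = cov_Iw))
}

#' Convenience constructor for zero-mean rank-2 statistics
#'
#' The four covariances are the entries that populate the overlap matrix
#' `P^ov[r, s] = cov(n_r, m_s)` in the large-N limit.
#'
#' @param sd_m,sd_n length-2 standard deviations of (m1, m2) and (n1, n2).
#' @param cov_n1m1,cov_n1m2,cov_n2m1,cov_n2m2 covariances between the left
#'   and right connectivity vectors.
#' @param n_in,sd_I,mean_I input-vector statistics (default: one independent
#'   unit-variance input).
#' @return a `vector_stats` object.
#' @export
rank2_stats <- function(sd_m = c(1, 1), sd_n = c(1, 1),
                        cov_n1m1 = 0, cov_n1m2 = 0,
                        cov_n2m1 = 0, cov_n2m2 = 0,
                        n_in = 0, sd_I = 1, mean_I = 0) {
  vector_stats(rank = 2, n_in = n_in,
               sd_m = sd_m, sd_n = sd_n, sd_I = sd_I, mean_I = mean_I,
               cov = c("n1.m1" = cov_n1m1, "n1.m2" = cov_n1m2,
                       "n2.m1" = cov_n2m1, "n2.m2" = cov_n2m2))
}

#' Look up a covariance entry by pair name
#' @param stats a `vector_stats` object.
#' @param a,b variable labels (index-free forms allowed for rank-1).
#' @return scalar covariance.
#' @export
stats_cov <- function(stats, a, b) {
  pair <- .resolve_pair(paste(a, b, sep = "."), colnames(stats$Sigma))
  stats$Sigma[pair[1], pair[2]]
}

#' @export
print.vector_stats <- function(x, ...) {
  cat("vector_stats: rank", x$rank, "with", x$n_in, "input(s)\n")
  cat("means:\n"); print(x$mu)
  cat("covariance:\n"); print(x$Sigma)
  invisible(x)
}
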