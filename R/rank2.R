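#' Mean-field flow of the rank-2 collective variables
#'
#' For zero-mean rank-2 statistics, the latent dynamics reduce to
#' `dk1/dt = -k1 + (cov(n1,m1) k1 + cov(n1,m2) k2) <phi'(0, Delta)>` (and
#' symmetrically for k2), with `Delta = sd_m1^2 k1^2 + sd_m2^2 k2^2`. Time is
#' in units of the network time constant.
#'
#' @param kappa1,kappa2 coordinates along `m^(1)` and `m^(2)`.
#' @param stats a rank-2 [vector_stats()] with zero means.
#' @param x_off transfer-function offset.
#' @param order Gauss-Hermite order.
#' @return numeric length-2 vector `(dk1/dt, dk2/dt)`.
#' @export
rank2_rhs <- function(kappa1, kappa2, stats, x_off = 0, order = 512) {
  stopifnot(inherits(stats, "vector_stats"), stats$rank == 2)
  if (any(abs(stats$mu[c("m1", "m2", "n1", "n2")]) > 1e-12))
    stop("rank-2 mean-field flow assumes zero-mean connectivity vectors")
  S <- stats$Sigma
  Delta <- S["m1", "m1"] * kappa1^2 + S["m2", "m2"] * kappa2^2
  g <- gaussian_expectation("dphi", 0, Delta, x_off, order = order)
  c(-kappa1 + (S["n1", "m1"] * kappa1 + S["n1", "m2"] * kappa2) * g,
    -kappa2 + (S["n2", "m1"] * kappa1 + S["n2", "m2"] * kappa2) * g)
}

#' Integrate the rank-2 mean-field flow
#'
#' Euler integration of [rank2_rhs()], useful for predicting limit cycles and
#' ring-attractor relaxation in the `(kappa1, kappa2)` plane.
#'
#' @param stats a rank-2 zero-mean [vector_stats()].
#' @param kappa0 length-2 initial condition.
#' @param x_off transfer-function offset.
#' @param tau time constant (ms).
#' @param dt Euler step (ms).
#' @param t_run duration (ms).
#' @return a `latent_trajectory` with `kappa` a `T x 2` matrix and
#'   `provenance = "mean-field"`.
#' @export
simulate_rank2_flow <- function(stats, kappa0 = c(0.1, 0), x_off = 0,
                                tau = 100, dt = 1, t_run = 10000) {
  n_steps <- round(t_run / dt)
  K <- matrix(NA_real_, n_steps, 2)
  k <- kappa0
  a <- dt / tau
  for (t in seq_len(n_steps)) {
    k <- k + a * rank2_rhs(k[1], k[2], stats, x_off)
    K[t, ] <- k
  }
  structure(list(times = seq_len(n_steps) * dt, kappa = K,
                 v = matrix(0, n_steps, 0), provenance = "mean-field"),
            class = "latent_trajectory")
}

#' Classify the dynamical regime implied by a rank-2 overlap matrix
#'
#' Builds the overlap matrix `P_ov[r, s] = cov(n_r, m_s)` from zero-mean
#' statistics, computes its eigenvalues, multiplies by the gain at the origin
#' `phi'(0) = 1 - tanh(x_off)^2`, and labels the regime:
#' \itemize{
#'   \item `"stable-origin"`: all `Re(phi'(0) lambda) < 1`;
#'   \item `"complex-oscillatory"`: a supercritical complex pair (spiral out
#'     of the origin into a limit cycle);
#'   \item `"degenerate-ring"`: supercritical degenerate real pair (a ring of
#'     marginal fixed points in the large-N limit);
#'   \item `"real-bistable"`: supercritical distinct real eigenvalue(s).
#' }
#'
#' @param stats a rank-2 (or rank-R) zero-mean [vector_stats()].
#' @param x_off transfer-function offset.
#' @param tol relative tolerance for eigenvalue degeneracy.
#' @return an object of class `overlap_matrix_analysis`: list with `P_ov`,
#'   `eigenvalues`, `gain`, `regime`.
#' @export
analyze_overlap_matrix <- function(stats, x_off = 0, tol = 1e-8) {
  stopifnot(inherits(stats, "vector_stats"))
  R <- stats$rank
  P <- matrix(NA_real_, R, R)
  for (r in seq_len(R)) for (s in seq_len(R))
    P[r, s] <- stats$Sigma[paste0("n", r), paste0("m", s)]
  ev <- eigen(P, only.values = TRUE)$values
  gain <- transfer_deriv(0, x_off)
  scaled <- gain * ev
  supercritical <- any(Re(scaled) >= 1)
  regime <- if (!supercritical) "stable-origin"
  else if (any(abs(Im(scaled)) > tol * max(abs(scaled)))) "complex-oscillatory"
  else if (R == 2 && abs(ev[1] - ev[2]) <= tol * max(abs(ev), 1))
    "degenerate-ring"
  else "real-bistable"
  structure(list(P_ov = P, eigenvalues = ev, gain = gain, regime = regime),
            class = "overlap_matrix_analysis")
}

#' @export
print.overlap_matrix_analysis <- function(x, ...) {
  cat("overlap matrix:\n"); print(x$P_ov)
  cat("eigenvalues:", format(x$eigenvalues, digits = 4),
      "| gain phi'(0) =", signif(x$gain, 4), "\n")
  cat("regime:", x$regime, "\n")
  invisible(x)
}
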