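#' Firing-rate transfer function and its derivative
#'
#' The rate model maps activation to firing rate through the positive sigmoid
#' `phi(x) = 1 + tanh(x - x_off)`, bounded in (0, 2); `x_off` shifts the
#' inflection point so that the resting state sits on the low branch of the
#' sigmoid. The derivative `phi'(x) = 1 - tanh(x - x_off)^2` is the gain.
#'
#' @param x activation (any numeric array).
#' @param x_off transfer-function offset (dimensionless).
#' @return elementwise `phi(x)` resp. `phi'(x)`.
#' @export
transfer <- function(x, x_off = 0) 1 + tanh(x - x_off)

#' @rdname transfer
#' @export
transfer_deriv <- function(x, x_off = 0) {
  t <- tanh(x - x_off)
  1 - t * t
}

#' Integration parameters for the rate network
#'
#' @param tau time constant (ms).
#' @param dt Euler step (ms), must be `< tau`.
#' @param t_run total simulated time (ms).
#' @param x_off transfer-function offset.
#' @return an object of class `rate_params`.
#' @export
rate_params <- function(tau = 100, dt = 1, t_run = 5000, x_off = 2.9) {
  stopifnot(tau > 0, dt > 0, t_run > 0, dt < tau)
  structure(list(tau = tau, dt = dt, t_run = t_run, x_off = x_off),
            class = "rate_params")
}

#' Step-input time course
#'
#' Amplitude `u(t)` multiplying the input vector(s): zero before `onset`,
#' `amplitude` from `onset` to `offset`.
#'
#' @param params a [rate_params()] (or any list with `dt`, `t_run`).
#' @param onset,offset step on/off times (ms); `offset = Inf` keeps it on.
#' @param amplitude step height (dimensionless); can be a vector for several
#'   input channels.
#' @return a `T x n_in` matrix sampled on the integration grid (class
#'   `stimulus_series`, attribute `times`).
#' @export
stimulus_step <- function(params, onset = 1000, offset = Inf, amplitude = 1) {
  times <- seq(params$dt, params$t_run, by = params$dt)
  u <- outer(as.numeric(times >= onset & times < offset), amplitude)
  structure(u, times = times, class = c("stimulus_series", class(u)))
}

#' Constant-zero stimulus
#' @inheritParams stimulus_step
#' @param n_in number of input channels.
#' @return a `T x n_in` zero matrix on the integration grid.
#' @export
stimulus_zero <- function(params, n_in = 1) {
  times <- seq(params$dt, params$t_run, by = params$dt)
  structure(matrix(0, length(times), n_in), times = times,
            class = c("stimulus_series", "matrix", "array"))
}

# coerce u to a T x n_in matrix on the grid
.as_stimulus <- function(u, n_steps, n_in) {
  if (is.null(u)) return(matrix(0, n_steps, max(n_in, 1)))
  u <- as.matrix(u)
  if (nrow(u) != n_steps)
    stop("stimulus has ", nrow(u), " samples but the grid has ", n_steps)
  u
}

#' Simulate the full N-dimensional rate network
#'
#' Forward-Euler integration of
#' `tau * dx/dt = -x + P phi(x) + sum_s I^(s) u_s(t)`,
#' with the recurrent term applied in factored O(N R) form when `conn` is a
#' [lowrank_matrix()] (a dense matrix or a `connectivity_bundle` are also
#' accepted; `NULL` means no recurrence).
#'
#' @param conn recurrent connectivity: `lowrank_matrix`, dense matrix,
#'   `connectivity_bundle`, or `NULL`.
#' @param I `N x n_in` matrix of input vectors (or `NULL` for no input).
#' @param u stimulus amplitudes, `T x n_in` (see [stimulus_step()]), or `NULL`.
#' @param x0 initial activations (length N; scalar recycled).
#' @param params a [rate_params()].
#' @param record_every record every k-th step (1 = every step).
#' @param diverge_bound abort with a diagnostic if `max(abs(x))` exceeds this.
#' @return an object of class `rate_trajectory`: `times` (ms), `x` and
#'   `r = phi(x)` as `T x N` matrices, and the parameters used.
#' @export
simulate_rate <- function(conn, I = NULL, u = NULL, x0 = 0, params,
                          record_every = 1, diverge_bound = 1e6) {
  stopifnot(inherits(params, "rate_params"))
  N <- if (inherits(conn, "lowrank_matrix")) conn$N
       else if (inherits(conn, "connectivity_bundle")) conn$N
       else if (is.matrix(conn)) nrow(conn)
       else if (!is.null(I)) nrow(as.matrix(I))
       else length(x0)
  if (N < 1) stop("cannot infer network size")
  x <- rep_len(x0, N)
  n_steps <- round(params$t_run / params$dt)
  I <- if (is.null(I)) NULL else as.matrix(I)
  if (!is.null(I) && nrow(I) != N) stop("input vectors I have wrong length")
  u <- .as_stimulus(u, n_steps, if (is.null(I)) 1 else ncol(I))

  rec <- function(r_of_x) {
    if (is.null(conn)) return(0)
    if (inherits(conn, "lowrank_matrix")) as.numeric(lr_matvec(conn, r_of_x))
    else if (inherits(conn, "connectivity_bundle")) conn_matvec(conn, r_of_x)
    else as.numeric(conn %*% r_of_x)
  }

  keep <- seq(record_every, n_steps, by = record_every)
  X <- matrix(NA_real_, length(keep), N)
  k <- 1L
  a <- params$dt / params$tau
  for (t in seq_len(n_steps)) {
    drive <- rec(transfer(x, params$x_off))
    if (!is.null(I)) drive <- drive + as.numeric(I %*% u[t, ])
    x <- x + a * (-x + drive)
    if (max(abs(x)) > diverge_bound)
      stop("rate simulation diverged at t = ", t * params$dt,
           " ms (max |x| > ", diverge_bound, ")")
    if (k <= length(keep) && t == keep[k]) { X[k, ] <- x; k <- k + 1L }
  }
  structure(list(times = keep * params$dt, x = X,
                 r = transfer(X, params$x_off), params = params),
            class = "rate_trajectory")
}

#' Simulate the reduced latent dynamics with empirical finite-N sums
#'
#' Integrates the (R + n_in)-dimensional system
#' `tau dv_s/dt = -v_s + u_s(t)` and
#' `tau dkappa_r/dt = -kappa_r + (1/N) sum_i n_i^(r) phi(sum_l kappa_l m_i^(l)
#'  + sum_s v_s I_i^(s))`,
#' evaluating the recurrent term as an empirical sum over the sampled ensemble
#' rather than the N -> infinity Gaussian integral. The reduction assumes the
#' m- and I-columns form an (approximately) orthogonal set; a warning is
#' emitted if pairwise overlaps are large for the sampled N.
#'
#' @param ensemble a `vector_ensemble`.
#' @param u stimulus amplitudes `T x n_in` or `NULL`.
#' @param kappa0,v0 initial latent coordinates (recycled).
#' @param params a [rate_params()].
#' @return an object of class `latent_trajectory`: `times`, `kappa`
#'   (`T x R`), `v` (`T x n_in`), `provenance = "reduced-ODE"`.
#' @export
simulate_latent_empirical <- function(ensemble, u = NULL, kappa0 = 0, v0 = 0,
                                      params) {
  stopifnot(inherits(ensemble, "vector_ensemble"),
            inherits(params, "rate_params"))
  N <- ensemble$N
  R <- ensemble$stats$rank; n_in <- ensemble$stats$n_in
  B <- cbind(ensemble$m, ensemble$I)
  if (ncol(B) > 1) {
    G <- crossprod(B) / N
    nrm <- sqrt(diag(G))
    off <- abs(G / outer(nrm, nrm))
    diag(off) <- 0
    if (max(off) > 3 / sqrt(N))
      warning("m/I columns are not near-orthogonal (max normalized overlap ",
              signif(max(off), 3), "); the reduced dynamics assume they are")
  }
  kappa <- rep_len(kappa0, R); v <- rep_len(v0, max(n_in, 1))[seq_len(n_in)]
  n_steps <- round(params$t_run / params$dt)
  u <- .as_stimulus(u, n_steps, n_in)
  K <- matrix(NA_real_, n_steps, R); V <- matrix(NA_real_, n_steps, n_in)
  a <- params$dt / params$tau
  for (t in seq_len(n_steps)) {
    xfield <- as.numeric(ensemble$m %*% kappa)
    if (n_in > 0) xfield <- xfield + as.numeric(ensemble$I %*% v)
    krec <- as.numeric(crossprod(ensemble$n, transfer(xfield, params$x_off))) / N
    kappa <- kappa + a * (-kappa + krec)
    if (n_in > 0) v <- v + a * (-v + u[t, ])
    if (max(abs(kappa)) > 1e6)
      stop("latent simulation diverged at t = ", t * params$dt, " ms")
    K[t, ] <- kappa; if (n_in > 0) V[t, ] <- v
  }
  structure(list(times = seq_len(n_steps) * params$dt, kappa = K, v = V,
                 provenance = "reduced-ODE", params = params),
            class = "latent_trajectory")
}

#' Simulate the rank-1 latent dynamics in the mean-field limit
#'
#' Integrates `tau dkappa/dt = -kappa + F(kappa, v)` with the recurrent term
#' given by the N -> infinity Gaussian-integral form (see [F_rank1()]) rather
#' than the empirical finite-N sum. The deviation between this trajectory and
#' the latent coordinates of a sampled finite network shrinks as 1/sqrt(N).
#'
#' @param stats a rank-1 [vector_stats()].
#' @param u stimulus amplitudes `T x 1` or `NULL`.
#' @param kappa0,v0 initial latent coordinates.
#' @param params a [rate_params()].
#' @param order Gauss-Hermite order for the Gaussian integrals.
#' @return a `latent_trajectory` with `provenance = "mean-field"`.
#' @export
simulate_latent_meanfield <- function(stats, u = NULL, kappa0 = 0, v0 = 0,
                                      params, order = 512) {
  stopifnot(inherits(stats, "vector_stats"), stats$rank == 1,
            inherits(params, "rate_params"))
  n_steps <- round(params$t_run / params$dt)
  u <- .as_stimulus(u, n_steps, 1)
  K <- matrix(NA_real_, n_steps, 1); V <- matrix(NA_real_, n_steps, 1)
  kappa <- kappa0; v <- v0
  a <- params$dt / params$tau
  for (t in seq_len(n_steps)) {
    kappa <- kappa + a * (-kappa + F_rank1(kappa, v, stats, params$x_off,
                                           order = order))
    v <- v + a * (-v + u[t, 1])
    K[t, 1] <- kappa; V[t, 1] <- v
  }
  structure(list(times = seq_len(n_steps) * params$dt, kappa = K, v = V,
                 provenance = "mean-field", params = params),
            class = "latent_trajectory")
}

#' Extract latent coordinates from a full trajectory
#'
#' Recovers `kappa_r(t)` and `v_s(t)` as the coordinates, in the (m, I) basis,
#' of the orthogonal projection of the activation `x(t)` onto
#' `span{m-columns, I-columns}` (least squares through a QR factorization).
#' When the basis vectors are exactly orthogonal this reduces to
#' `kappa_r = x^T m^(r) / ||m^(r)||^2` and `v_s = x^T I^(s) / ||I^(s)||^2`;
#' for sampled Gaussian vectors the correction removes the O(1/sqrt(N))
#' cross-talk between the directions.
#'
#' @param traj a `rate_trajectory` (its `x` field is projected).
#' @param ensemble the `vector_ensemble` supplying the basis.
#' @return a `latent_trajectory` with `provenance = "projected"`.
#' @export
latent_from_trajectory <- function(traj, ensemble) {
  stopifnot(inherits(traj, "rate_trajectory"),
            inherits(ensemble, "vector_ensemble"))
  if (ncol(traj$x) != ensemble$N)
    stop("trajectory and ensemble disagree on N")
  R <- ensemble$stats$rank; n_in <- ensemble$stats$n_in
  B <- cbind(ensemble$m, ensemble$I)
  nrm <- sqrt(colSums(B^2))
  if (any(nrm == 0)) stop("zero-norm basis vector in (m, I)")
  qrB <- qr(B)
  coefs <- t(qr.coef(qrB, t(traj$x)))  # T x (R + n_in)
  structure(list(times = traj$times,
                 kappa = coefs[, seq_len(R), drop = FALSE],
                 v = if (n_in > 0) coefs[, R + seq_len(n_in), drop = FALSE]
                     else matrix(0, nrow(coefs), 0),
                 provenance = "projected", params = traj$params),
            class = "latent_trajectory")
}
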