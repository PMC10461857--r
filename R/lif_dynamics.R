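#' Parameters of the leaky integrate-and-fire network
#'
#' Membrane dynamics `tau_m dV/dt = -V + mu0 + I u(t) + noise + synapses`;
#' a spike is emitted when V crosses `v_thr`, V is reset to `v_r` and clamped
#' there for `tau_ref`; each presynaptic spike produces an instantaneous
#' postsynaptic jump of `J_ij` mV delivered after the synaptic delay
#' `tau_del`.
#'
#' The white-noise term supports two discretization conventions via
#' `noise_convention`: `"sqrt_dt_over_tau"` (default) adds a V-jump of
#' `sigma0 * sqrt(dt / tau_m) * eta` per step, giving stationary membrane
#' variance `sigma0^2 / 2` for an uncoupled neuron; `"sqrt_dt"` adds
#' `sigma0 * sqrt(dt) * eta`.
#'
#' @param tau_m membrane time constant (ms).
#' @param v_thr,v_r threshold and reset potentials (mV), `v_r < v_thr`.
#' @param tau_ref refractory period (ms).
#' @param tau_del synaptic delay (ms); must be a multiple of `dt` (or 0,
#'   treated as a one-step delay).
#' @param mu0 constant baseline input (mV).
#' @param sigma0 noise amplitude (mV).
#' @param dt Euler step (ms).
#' @param t_run simulated duration (ms).
#' @param noise_convention `"sqrt_dt_over_tau"` or `"sqrt_dt"`.
#' @param rate_cap abort threshold on the instantaneous population rate
#'   (spk/s); guards against runaway excitation.
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 20, v_thr = 20, v_r = 10, tau_ref = 0.5,
                       tau_del = 1.5, mu0 = 40, sigma0 = 0.71,
                       dt = 0.1, t_run = 2000,
                       noise_convention = c("sqrt_dt_over_tau", "sqrt_dt"),
                       rate_cap = 1e5) {
  noise_convention <- match.arg(noise_convention)
  stopifnot(tau_m > 0, v_r < v_thr, tau_ref >= 0, tau_del >= 0,
            dt > 0, t_run > 0)
  # delay and refractoriness are realized in whole steps: round(tau/dt),
  # with at least a one-step delay (common presets pair dt = 1 ms with
  # tau_del = 1.5 ms, so exact divisibility is not required)
  structure(list(tau_m = tau_m, v_thr = v_thr, v_r = v_r, tau_ref = tau_ref,
                 tau_del = tau_del, mu0 = mu0, sigma0 = sigma0,
                 dt = dt, t_run = t_run, noise_convention = noise_convention,
                 rate_cap = rate_cap),
            class = "lif_params")
}

#' Simulate a network of leaky integrate-and-fire neurons
#'
#' Runs `n_trials` independent trials of the LIF network defined by `conn`
#' (sparse E-I plus factored low-rank, see [compose_connectivity()]), an
#' optional external input `I u(t)`, and the membrane parameters in `params`.
#' The integration loop is compiled; noise and initial conditions use R's RNG
#' so that `seed` makes the raster reproducible.
#'
#' @param conn a `connectivity_bundle`, a `lowrank_matrix`, a sparse matrix,
#'   or `NULL` (uncoupled neurons).
#' @param I `N x n_in` input vectors or `NULL`.
#' @param u stimulus amplitudes `T x n_in` on the dt grid, or `NULL`.
#' @param params a [lif_params()].
#' @param N network size (required only when `conn` and `I` are both `NULL`).
#' @param V0 initial potentials: `"uniform"` (default, U[v_r, v_thr)),
#'   `"gaussian"` (N((v_thr + v_r)/2, (v_thr - v_r)/4), the protocol used when
#'   probing bistability), or a numeric vector of length N reused on every
#'   trial.
#' @param seed integer seed.
#' @param n_trials number of trials; each trial redraws V0 and the noise.
#' @return an object of class `spike_raster`: data frame with columns `time`
#'   (ms), `neuron` (1-based), `trial`, plus attributes `N`, `t_run`, `dt`,
#'   `n_trials`, `params`.
#' @export
simulate_lif <- function(conn = NULL, I = NULL, u = NULL, params,
                         N = NULL, V0 = "uniform", seed = 1, n_trials = 1) {
  stopifnot(inherits(params, "lif_params"))
  if (inherits(conn, "lowrank_matrix"))
    conn <- compose_connectivity(NULL, conn)
  if (inherits(conn, "Matrix") || is.matrix(conn))
    conn <- compose_connectivity(methods::as(conn, "CsparseMatrix"), NULL)
  if (!is.null(conn) && !inherits(conn, "connectivity_bundle"))
    stop("unsupported connectivity object")
  if (is.null(N))
    N <- if (!is.null(conn)) conn$N
         else if (!is.null(I)) nrow(as.matrix(I))
         else stop("N must be given when conn and I are NULL")

  ei <- NULL
  if (!is.null(conn)) ei <- if (!is.null(conn$full_sparse)) conn$full_sparse
                            else conn$ei
  has_ei <- !is.null(ei) && length(ei@x) > 0
  if (has_ei) ei <- methods::as(ei, "CsparseMatrix")
  lr <- if (!is.null(conn)) conn$lowrank else NULL
  has_lr <- !is.null(lr)

  n_steps <- round(params$t_run / params$dt)
  has_input <- !is.null(I)
  Imat <- if (has_input) as.matrix(I) else matrix(0, 1, 1)
  umat <- if (has_input) .as_stimulus(u, n_steps, ncol(Imat))
          else matrix(0, 1, 1)
  if (has_input && nrow(Imat) != N) stop("input vectors I have wrong length")

  nc <- if (params$noise_convention == "sqrt_dt") 2L else 1L
  out <- with_seed(seed, {
    pieces <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      v0 <- if (is.numeric(V0)) rep_len(V0, N)
      else if (identical(V0, "uniform"))
        stats::runif(N, params$v_r, params$v_thr)
      else if (identical(V0, "gaussian"))
        stats::rnorm(N, (params$v_thr + params$v_r) / 2,
                     (params$v_thr - params$v_r) / 4)
      else stop("V0 must be 'uniform', 'gaussian', or a numeric vector")
      res <- lif_core_cpp(
        N,
        if (has_ei) ei@p else integer(1),
        if (has_ei) ei@i else integer(0),
        if (has_ei) ei@x else numeric(0),
        has_ei,
        if (has_lr) lr$m else matrix(0, 1, 1),
        if (has_lr) lr$n else matrix(0, 1, 1),
        has_lr,
        Imat, umat, has_input,
        params$mu0, params$sigma0, params$tau_m,
        params$v_thr, params$v_r, params$tau_ref, params$tau_del,
        params$dt, n_steps, v0, nc, params$rate_cap)
      pieces[[tr]] <- data.frame(time = res$time, neuron = res$neuron,
                                 trial = rep(tr, length(res$time)))
    }
    do.call(rbind, pieces)
  })
  structure(out, N = N, t_run = params$t_run, dt = params$dt,
            n_trials = n_trials, params = params,
            class = c("spike_raster", "data.frame"))
}

#' Convert spikes to instantaneous firing rates by exponential filtering
#'
#' Event-driven solution of `tau_f dr/dt = -r + sum_k delta(t - t_k)`: between
#' spikes the rate decays as `exp(-dt / tau_f)`, each spike adds `1 / tau_f`
#' (so a single spike contributes unit time-integral). The filter is evaluated
#' exactly at the spike times and sampled on a `dt_out` grid.
#'
#' @param raster a `spike_raster` (see [simulate_lif()]).
#' @param tau_f filter time constant (ms).
#' @param dt_out output sampling step (ms).
#' @param trials which trials to filter (default: all present).
#' @return a list of `rate_matrix` objects, one per trial: `T x N` matrices
#'   (spk/s) with attributes `times` (ms), `tau_f`. A single-trial raster
#'   returns a one-element list.
#' @export
filter_spikes <- function(raster, tau_f, dt_out = 1, trials = NULL) {
  stopifnot(inherits(raster, "spike_raster"), tau_f > 0)
  N <- attr(raster, "N"); t_run <- attr(raster, "t_run")
  if (is.null(trials)) trials <- seq_len(attr(raster, "n_trials"))
  times <- seq(dt_out, t_run, by = dt_out)
  n_out <- length(times)
  decay <- exp(-dt_out / tau_f)
  lapply(trials, function(tr) {
    sp <- raster[raster$trial == tr, , drop = FALSE]
    # each spike contributes exp(-(t_bin - t_spk)/tau_f)/tau_f to the sample
    # closing its bin, then decays with the grid
    bin <- pmin(pmax(ceiling(sp$time / dt_out - 1e-9), 1L), n_out)
    wgt <- exp(-(times[bin] - sp$time) / tau_f) / tau_f
    # neurons x bins in CSC so each time bin is a contiguous slice
    K <- Matrix::sparseMatrix(i = sp$neuron, j = bin, x = wgt,
                              dims = c(N, n_out))
    kp <- K@p; knr <- K@i + 1L; kx <- K@x
    R <- matrix(0, n_out, N)
    r <- numeric(N)
    for (t in seq_len(n_out)) {
      r <- r * decay
      if (kp[t + 1L] > kp[t]) {
        idx <- (kp[t] + 1L):kp[t + 1L]
        r[knr[idx]] <- r[knr[idx]] + kx[idx]
      }
      R[t, ] <- r
    }
    structure(R * 1000, times = times, tau_f = tau_f, dt = dt_out,
              class = c("rate_matrix", "matrix", "array"))  # spk/s
  })
}

#' Average filtered rates over trials
#'
#' @param rates list of `rate_matrix` objects on identical grids with equal
#'   `tau_f` (as returned by [filter_spikes()]).
#' @return a single `rate_matrix`, the pointwise mean.
#' @export
average_trials <- function(rates) {
  if (inherits(rates, "rate_matrix")) return(rates)
  stopifnot(length(rates) >= 1)
  ref_t <- attr(rates[[1]], "times"); ref_f <- attr(rates[[1]], "tau_f")
  for (r in rates) {
    if (!isTRUE(all.equal(attr(r, "times"), ref_t)) ||
        !identical(attr(r, "tau_f"), ref_f))
      stop("rate matrices have mismatched grids or filter constants")
  }
  out <- Reduce(`+`, rates) / length(rates)
  structure(out, times = ref_t, tau_f = ref_f, dt = attr(rates[[1]], "dt"),
            class = c("rate_matrix", "matrix", "array"))
}

#' Firing-regime presets for the E-I background
#'
#' Returns the E-I and membrane parameters that place the balanced random
#' network in the asynchronous irregular (`"AI"`), synchronous irregular
#' (`"SI"`), or no-background (`"no_EI"`, purely low-rank coupling) regime.
#'
#' @param name one of `"AI"`, `"SI"`, `"no_EI"`.
#' @param N,C network size and in-degree (defaults: full scale).
#' @param t_run,dt simulation length and step (ms).
#' @return list with elements `ei` ([ei_spec()]) and `lif` ([lif_params()]).
#' @export
regime_preset <- function(name = c("AI", "SI", "no_EI"),
                          N = 12500, C = 1250, t_run = 2000, dt = 1) {
  name <- match.arg(name)
  par <- switch(name,
    AI    = list(J = 0.1, g = 5, mu0 = 40),
    SI    = list(J = 0.1, g = 6, mu0 = 80),
    no_EI = list(J = 0,   g = 5, mu0 = 30))
  list(ei = ei_spec(N = N, C = C, f_exc = 0.8, J = par$J, g = par$g),
       lif = lif_params(mu0 = par$mu0, dt = dt, t_run = t_run))
}

#' Population firing rate from a raster
#'
#' Mean spike count per neuron per second over a time window.
#' @param raster a `spike_raster`.
#' @param from,to window bounds (ms; default whole run).
#' @return population-averaged rate in spk/s (averaged over trials).
#' @export
population_rate <- function(raster, from = 0, to = attr(raster, "t_run")) {
  N <- attr(raster, "N"); n_tr <- attr(raster, "n_trials")
  k <- sum(raster$time > from & raster$time <= to)
  k / (N * n_tr * (to - from) * 1e-3)
}
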