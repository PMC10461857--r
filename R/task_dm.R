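#' Configuration of the perceptual decision-making task
#'
#' A trial consists of a fixation epoch, a stimulation epoch during which a
#' noisy scalar stimulus `u(t) = u_mean + psi(t)` drives the network along
#' the input vector `I`, a delay epoch, and a decision epoch during which the
#' readout `z(t) = (1/N) sum_i w_i r_i(t)` is averaged and thresholded at
#' zero (ties labelled 0). The stimulus noise `psi` is drawn i.i.d. per
#' integration step with standard deviation `u_sd` (no `1/sqrt(dt)` scaling:
#' the quoted noise amplitude is the per-step standard deviation).
#'
#' Each trial is preceded by a settling period of `t_settle` ms (discarded
#' from analysis) during which the network reaches its stationary state and
#' the rate filter converges; the decision statistic is the decision-epoch
#' readout minus the fixation-epoch readout (`baseline_correct = TRUE`),
#' which removes the network-realization-specific readout offset produced by
#' finite-size correlations between the readout vector and the baseline
#' firing pattern.
#'
#' @param t_fix,t_stim,t_del,t_dec epoch durations (ms).
#' @param t_settle discarded settling period before the fixation epoch (ms).
#' @param u_mean stimulus mean (dimensionless; sign encodes the category).
#' @param u_sd stimulus noise standard deviation.
#' @param tau_f readout filter time constant (ms).
#' @param dt integration step (ms).
#' @param dt_out rate sampling step for the readout (ms).
#' @param baseline_correct subtract the fixation-epoch readout mean.
#' @return an object of class `dm_config`.
#' @export
dm_config <- function(t_fix = 100, t_stim = 800, t_del = 100, t_dec = 20,
                      t_settle = 400, u_mean = 0.512, u_sd = 1, tau_f = 100,
                      dt = 1, dt_out = 5, baseline_correct = TRUE) {
  stopifnot(t_fix >= 0, t_stim > 0, t_del >= 0, t_dec > 0, t_settle >= 0)
  structure(list(t_fix = t_fix, t_stim = t_stim, t_del = t_del, t_dec = t_dec,
                 t_settle = t_settle,
                 t_run = t_fix + t_stim + t_del + t_dec,
                 u_mean = u_mean, u_sd = u_sd, tau_f = tau_f,
                 dt = dt, dt_out = dt_out, baseline_correct = baseline_correct),
            class = "dm_config")
}

#' Generate the noisy stimulus time course of one trial
#'
#' @param config a [dm_config()].
#' @param seed trial seed.
#' @return a `T x 1` `stimulus_series` on the dt grid: zero outside the
#'   stimulation epoch, `u_mean + N(0, u_sd^2)` per step inside it.
#' @export
generate_stimulus <- function(config, seed) {
  stopifnot(inherits(config, "dm_config"))
  times <- seq(config$dt, config$t_settle + config$t_run, by = config$dt)
  on_at <- config$t_settle + config$t_fix
  stim <- times > on_at & times <= on_at + config$t_stim
  u <- numeric(length(times))
  u[stim] <- config$u_mean +
    with_seed(seed, stats::rnorm(sum(stim), 0, config$u_sd))
  structure(matrix(u, ncol = 1), times = times,
            class = c("stimulus_series", "matrix", "array"))
}

#' Connectivity statistics of the decision-making network
#'
#' Zero-mean unit-rank statistics supporting evidence integration: the
#' input-integration overlap `cov(n, I)`, the positive-feedback overlap
#' `cov(m, n)`, and the readout overlap `cov(m, w)`. The readout vector is
#' constructed explicitly as `w = (cov_mw / var_m) m + sd_w_extra * Z` with
#' `Z` independent standard normal, so the printed `cov(m, w)` is honored for
#' any residual readout variance.
#'
#' @param var_m variance of the m entries.
#' @param cov_mn,cov_nI,cov_mw overlaps (see above).
#' @param sd_n,sd_I standard deviations of n (mV) and I (mV).
#' @param sd_w_extra standard deviation of the readout component independent
#'   of `m` (default 0: the readout is a pure rescaling of `m`, the
#'   minimum-variance construction).
#' @return list of class `dm_stats` with the sampling statistics and the
#'   readout construction constants.
#' @export
dm_stats <- function(var_m = 0.02, cov_mn = 0.016, cov_nI = 0.26,
                     cov_mw = 2.1, sd_n = 1, sd_I = 1, sd_w_extra = 0) {
  stopifnot(var_m > 0, sd_n > 0, sd_I > 0, sd_w_extra >= 0)
  base <- vector_stats(rank = 1, n_in = 1,
                       sd_m = sqrt(var_m), sd_n = sd_n, sd_I = sd_I,
                       cov = c("m.n" = cov_mn, "n.I" = cov_nI))
  structure(list(base = base, var_m = var_m, cov_mw = cov_mw,
                 sd_w_extra = sd_w_extra),
            class = "dm_stats")
}

#' Build the decision-making spiking network
#'
#' Samples the unit-rank vectors `(m, n, I)` from `stats`, constructs the
#' readout `w` from `m` plus independent residual, and superposes the rank-1
#' structure on an asynchronous-irregular E-I background.
#'
#' @param stats a [dm_stats()].
#' @param N network size.
#' @param ei an [ei_spec()] for the background (default: AI regime at size
#'   `N` with in-degree `N/10` and `C J` matched to the full-scale network).
#' @param lif a [lif_params()] (default: AI preset timing).
#' @param seed integer seed (spawns substreams for vectors and topology).
#' @return list of class `dm_network`: `ensemble`, `w`, `conn`, `lif`, `N`.
#' @export
build_dm_network <- function(stats, N = 12500, ei = NULL, lif = NULL,
                             seed = 1) {
  stopifnot(inherits(stats, "dm_stats"))
  seeds <- spawn_seeds(seed, c("vectors", "topology", "readout"))
  ens <- sample_vectors(stats$base, N, seeds[["vectors"]])
  a <- stats$cov_mw / stats$var_m
  w <- a * ens$m[, 1]
  if (stats$sd_w_extra > 0)
    w <- w + stats$sd_w_extra *
      with_seed(seeds[["readout"]], stats::rnorm(N))
  if (is.null(ei)) {
    C <- round(N / 10)
    ei <- ei_spec(N = N, C = C, f_exc = 0.8, J = 0.1 * 1250 / C, g = 5)
  }
  if (is.null(lif)) lif <- lif_params(mu0 = 40, dt = 1, t_run = 1020)
  ei_mat <- if (ei$J > 0) sample_ei_matrix(ei, seeds[["topology"]]) else NULL
  conn <- compose_connectivity(ei_mat, lowrank_matrix(ens))
  structure(list(ensemble = ens, w = w, conn = conn, lif = lif, N = N,
                 ei = ei, seed = seed),
            class = "dm_network")
}

#' Run one decision-making trial
#'
#' Simulates the spiking network for the full trial, filters spikes at
#' `config$tau_f`, computes the readout trace `z(t)` and the decision-epoch
#' mean `z_bar`, and thresholds at zero.
#'
#' @param network a [build_dm_network()] result.
#' @param config a [dm_config()].
#' @param seed trial seed (spawns stimulus and membrane-noise substreams).
#' @param u_sign +1 or -1: sign applied to `config$u_mean` for this trial.
#' @return list of class `dm_trial`: `z` (readout trace), `times`, `z_bar`,
#'   `label` (1 if `z_bar > 0`, else 0), `seed`.
#' @export
run_trial <- function(network, config, seed, u_sign = 1) {
  stopifnot(inherits(network, "dm_network"), inherits(config, "dm_config"))
  seeds <- spawn_seeds(seed, c("stimulus", "noise"))
  cfg <- config
  cfg$u_mean <- u_sign * config$u_mean
  u <- generate_stimulus(cfg, seeds[["stimulus"]])
  lif <- network$lif
  lif$dt <- config$dt; lif$t_run <- config$t_settle + config$t_run
  raster <- simulate_lif(network$conn, I = network$ensemble$I, u = u,
                         params = lif, seed = seeds[["noise"]], n_trials = 1)
  rates <- filter_spikes(raster, tau_f = config$tau_f,
                         dt_out = config$dt_out)[[1]]
  z <- project(rates, network$w, "mean")
  times <- attr(rates, "times")
  fix <- times > config$t_settle &
         times <= config$t_settle + config$t_fix
  dec <- times > config$t_settle + config$t_fix + config$t_stim + config$t_del
  z_fix <- mean(z[fix])
  z_bar <- mean(z[dec]) - if (config$baseline_correct) z_fix else 0
  structure(list(z = z, times = times, z_bar = z_bar, z_fix = z_fix,
                 label = as.integer(z_bar > 0), seed = seed),
            class = "dm_trial")
}

#' Psychometric curve over connectivity overlaps
#'
#' For each feedback overlap `cov(m, n)` in `overlaps` and each stimulus sign,
#' builds a network realization and runs `n_trials` independent trials,
#' recording the fraction labelled 1.
#'
#' @param overlaps values of `cov(m, n)` to scan.
#' @param config a [dm_config()].
#' @param stats_fn function(overlap) returning the [dm_stats()] to use
#'   (default: [dm_stats()] with `cov_mn = overlap`).
#' @param N network size.
#' @param ei,lif optional overrides passed to [build_dm_network()].
#' @param n_trials trials per (overlap, sign).
#' @param seed master seed.
#' @return an object of class `psychometric_curve`: data frame with columns
#'   `overlap`, `u_sign`, `frac_label1`, `n_trials`.
#' @export
psychometric <- function(overlaps, config = dm_config(),
                         stats_fn = function(ov) dm_stats(cov_mn = ov),
                         N = 12500, ei = NULL, lif = NULL,
                         n_trials = 30, seed = 1) {
  net_seeds <- spawn_seeds(seed, length(overlaps))
  rows <- list()
  for (k in seq_along(overlaps)) {
    net <- build_dm_network(stats_fn(overlaps[k]), N = N, ei = ei, lif = lif,
                            seed = net_seeds[k])
    trial_seeds <- spawn_seeds(net_seeds[k] + 1L, 2 * n_trials)
    for (sgn in c(1, -1)) {
      offs <- if (sgn > 0) 0 else n_trials
      labs <- vapply(seq_len(n_trials), function(tr)
        run_trial(net, config, trial_seeds[offs + tr], u_sign = sgn)$label,
        integer(1))
      rows[[length(rows) + 1]] <-
        data.frame(overlap = overlaps[k], u_sign = sgn,
                   frac_label1 = mean(labs), n_trials = n_trials)
    }
  }
  structure(do.call(rbind, rows),
            class = c("psychometric_curve", "data.frame"))
}
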