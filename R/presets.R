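#' Parameter presets for the studied network configurations
#'
#' Returns fully populated parameter sets for the rate-network, spiking and
#' task experiments analyzed in the package. Rate-model presets are
#' dimensionless; spiking presets carry mV units and inherit the common
#' membrane constants (`tau_m` = 20 ms, `v_thr` = 20 mV, `v_r` = 10 mV,
#' `sigma0` = 0.71 mV, `tau_del` = 1.5 ms unless stated).
#'
#' Input-vector amplitudes are specified as overall Euclidean norms `|I|` of
#' a unit-standard-deviation pattern (rescaled after sampling); an input
#' "along the global axis" has constant entries `|I| / sqrt(N)`.
#'
#' @param id preset identifier; see [preset_ids()].
#' @param N optional network-size override. Spiking presets rescale the
#'   in-degree as `C propto N` and the synaptic strength as `J propto 1/C`
#'   (preserving `C J`), and input norms as `sqrt(N)` (preserving per-entry
#'   amplitude), so reduced-scale networks stay in the same regime.
#' @return a list describing the preset; fields depend on `kind`
#'   (`"rate"`, `"lif"`, `"rate_scan"`, `"lif_rank2"`, `"dm"`).
#' @export
preset <- function(id, N = NULL) {
  build <- .preset_registry[[id]]
  if (is.null(build))
    stop("unknown preset '", id, "'; see preset_ids()")
  p <- build()
  if (!is.null(N)) p <- .rescale_preset(p, N)
  p$id <- id
  p
}

#' @rdname preset
#' @export
preset_ids <- function() names(.preset_registry)

# spiking presets keep C J fixed (same mean recurrent drive) and keep the
# input vector's Euclidean norm |I| fixed (the input-driven variance along I
# scales as |I|^2, so this preserves the state-space geometry) when resized
.rescale_preset <- function(p, N) {
  if (!is.null(p$ei)) {
    scale <- N / p$N
    C_new <- round(p$ei$C * scale)
    p$ei <- ei_spec(N = N, C = C_new, f_exc = p$ei$f_exc,
                    J = p$ei$J * p$ei$C / C_new, g = p$ei$g)
  }
  if (!is.null(p$stats) && inherits(p$stats, "vector_stats") &&
      p$stats$n_in > 0 && p$stats$mu[["I1"]] != 0) {
    # global-axis input: constant entries |I|/sqrt(N)
    p$stats$mu[["I1"]] <- p$stats$mu[["I1"]] * sqrt(p$N / N)
  }
  p$N <- N
  p
}

.rate_common <- function() rate_params(tau = 100, dt = 1, t_run = 5000,
                                       x_off = 2.9)

.lif_common <- function(mu0, J, g, t_run = 2000, dt = 1, tau_ref = 0.5,
                        tau_del = 1.5, C = 1250, N = 12500) {
  list(ei = ei_spec(N = N, C = C, f_exc = 0.8, J = J, g = g),
       lif = lif_params(tau_m = 20, v_thr = 20, v_r = 10, tau_ref = tau_ref,
                        tau_del = tau_del, mu0 = mu0, sigma0 = 0.71,
                        dt = dt, t_run = t_run))
}

.preset_registry <- list(

  # --- rate networks, input-driven geometry -------------------------------
  # three arrangements of the input vector: along the global axis (purple),
  # orthogonal to n (gray), aligned with n (blue)
  table1_gray = function() list(
    kind = "rate", N = 1000,
    stats = rank1_stats(sd_m = 1, sd_n = 1, sd_I = 1),
    params = .rate_common(), input = list(onset = 1000, amplitude = 1)),
  table1_blue = function() list(
    kind = "rate", N = 1000,
    stats = rank1_stats(sd_m = 1, sd_n = 1, sd_I = 1, cov_nI = 1),
    params = .rate_common(), input = list(onset = 1000, amplitude = 1)),
  table1_purple = function() list(
    kind = "rate", N = 1000,
    stats = rank1_stats(sd_m = 1, sd_n = 1, sd_I = 0, mean_I = 1),
    params = .rate_common(), input = list(onset = 1000, amplitude = 1)),

  # --- spiking networks, input-driven geometry (AI background) ------------
  table2_fig3_left = function() c(
    list(kind = "lif", N = 12500,
         stats = rank1_stats(sd_m = 2, sd_n = 20, sd_I = 0,
                             mean_I = 22.5 / sqrt(12500)),
         I_norm = NA, tau_f = 100,
         input = list(onset = 1000, amplitude = 1)),
    .lif_common(mu0 = 40, J = 0.1, g = 5)),
  table2_fig3_middle = function() c(
    list(kind = "lif", N = 12500,
         stats = rank1_stats(sd_m = 2, sd_n = 20, sd_I = 1),
         I_norm = 125, tau_f = 100,
         input = list(onset = 1000, amplitude = 1)),
    .lif_common(mu0 = 40, J = 0.1, g = 5)),
  table2_fig3_right = function() c(
    list(kind = "lif", N = 12500,
         stats = rank1_stats(sd_m = 2, sd_n = 20, sd_I = 1, cov_nI = 0.4),
         I_norm = 125, tau_f = 100,
         input = list(onset = 1000, amplitude = 1)),
    .lif_common(mu0 = 40, J = 0.1, g = 5)),

  # --- firing-regime presets (vectors as fig3 right, varying background) --
  table2_fig5_si = function() c(
    list(kind = "lif", N = 12500,
         stats = rank1_stats(sd_m = 2, sd_n = 20, sd_I = 1, cov_nI = 0.4),
         I_norm = 50, tau_f = c(1, 100),
         input = list(onset = 1000, amplitude = 1)),
    .lif_common(mu0 = 80, J = 0.1, g = 6)),
  table2_fig5_ai = function() c(
    list(kind = "lif", N = 12500,
         stats = rank1_stats(sd_m = 2, sd_n = 20, sd_I = 1, cov_nI = 0.4),
         I_norm = 50, tau_f = c(1, 100),
         input = list(onset = 1000, amplitude = 1)),
    .lif_common(mu0 = 40, J = 0.1, g = 5)),
  table2_fig5_noei = function() c(
    list(kind = "lif", N = 12500,
         stats = rank1_stats(sd_m = 2, sd_n = 20, sd_I = 1, cov_nI = 0.4),
         I_norm = 50, tau_f = c(1, 100),
         input = list(onset = 1000, amplitude = 1)),
    .lif_common(mu0 = 30, J = 0, g = 5)),

  # --- rank-1 autonomous bifurcations, rate model -------------------------
  # mean-driven feedback: overlap swept through <n> at fixed <m>
  table3_AC = function() list(
    kind = "rate_scan", N = 2000, sweep = "mean_n",
    values = seq(0.1, 6, length.out = 25),
    stats = rank1_stats(mean_m = 2, sd_m = 2, sd_n = 6),
    params = rate_params(tau = 100, dt = 10, t_run = 20000, x_off = 2.9),
    n_trials = 4),
  # covariance-driven feedback: zero means, overlap = cov(m, n)
  table3_DF = function() list(
    kind = "rate_scan", N = 2000, sweep = "cov_mn",
    values = seq(0.1, 12, length.out = 25),
    stats = rank1_stats(sd_m = 2, sd_n = 6),
    params = rate_params(tau = 100, dt = 10, t_run = 20000, x_off = 2.9),
    n_trials = 8),

  # --- rank-1 autonomous bifurcations, spiking model ----------------------
  table4_GI = function() c(
    list(kind = "lif_scan", N = 12500, sweep = "mean_n",
         values = seq(0, 150, length.out = 16),
         stats = rank1_stats(mean_m = 0.01, sd_m = 2, sd_n = 20),
         tau_f = 100, n_nets = 5, n_trials = 3),
    .lif_common(mu0 = 17.7, J = 0.2, g = 4.8, t_run = 1200,
                tau_ref = 2, tau_del = 2.5, C = 4000)),
  table4_JL = function() c(
    list(kind = "lif_scan", N = 12500, sweep = "cov_mn",
         values = seq(0, 40, length.out = 16),
         stats = rank1_stats(sd_m = 2, sd_n = 20),
         tau_f = 100, n_nets = 7, n_trials = 2),
    .lif_common(mu0 = 40, J = 0.1, g = 5, t_run = 1200)),

  # --- rank-2 autonomous dynamics, rate model -----------------------------
  # complex-conjugate overlap eigenvalues 2 +/- 0.8i: limit cycle
  table5_AC = function() list(
    kind = "rate", N = 1000,
    stats = rank2_stats(sd_m = c(1, 1), sd_n = c(7.24, 3.63),
                        cov_n1m1 = 2, cov_n1m2 = -0.8,
                        cov_n2m1 = 0.8, cov_n2m2 = 2),
    params = rate_params(tau = 100, dt = 1, t_run = 10000, x_off = 0),
    n_nets = 3, n_trials = 5),
  # degenerate real pair {2, 2}: ring attractor / slow manifold
  table5_GI = function() list(
    kind = "rate", N = 1000,
    stats = rank2_stats(sd_m = c(1, 1), sd_n = c(7.24, 3.63),
                        cov_n1m1 = 2, cov_n2m2 = 2),
    params = rate_params(tau = 100, dt = 1, t_run = 10000, x_off = 0),
    n_nets = 15, n_trials = 3),

  # --- rank-2 autonomous dynamics, spiking model --------------------------
  table6_DF = function() c(
    list(kind = "lif_rank2", N = 12500,
         stats = rank2_stats(sd_m = c(1, 1), sd_n = c(82.4, 46),
                             cov_n1m1 = 30, cov_n1m2 = -8,
                             cov_n2m1 = 8, cov_n2m2 = 26),
         tau_f = 20, n_nets = 3, n_trials = 1),
    .lif_common(mu0 = 40, J = 0.1, g = 5, t_run = 1200)),
  table6_JL = function() c(
    list(kind = "lif_rank2", N = 12500,
         stats = rank2_stats(sd_m = c(1, 1), sd_n = c(26, 26),
                             cov_n1m1 = 25, cov_n2m2 = 25),
         tau_f = 20, n_nets = 35, n_trials = 1),
    .lif_common(mu0 = 40, J = 0.1, g = 5, t_run = 3000)),

  # --- perceptual decision-making task ------------------------------------
  # task vectors on the mV scale of the other spiking presets (sd_m = 2,
  # sd_n = 20 mV); the n-I integration overlap is the quoted 0.26 as a
  # correlation (cov = 0.26 * sd_n * sd_I) and the feedback overlap cov(m, n)
  # is swept in mV toward the critical value, where integration is slowest
  fig9_dm = function() list(
    kind = "dm", N = 12500,
    stats = dm_stats(var_m = 4, cov_mn = 10, cov_nI = 5.2, cov_mw = 4,
                     sd_n = 20, sd_I = 1),
    config = dm_config(),
    overlaps = c(0, 5, 10, 15))
)
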