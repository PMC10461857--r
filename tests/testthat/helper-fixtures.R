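# shared fixtures built in code at test time

# a hand-constructed raster: explicit spike list with raster metadata
make_raster <- function(time, neuron, trial = rep(1L, length(time)),
                        N, t_run, dt = 1) {
  structure(data.frame(time = time, neuron = as.integer(neuron),
                       trial = as.integer(trial)),
            N = as.integer(N), t_run = t_run, dt = dt,
            n_trials = max(c(trial, 1L)),
            class = c("spike_raster", "data.frame"))
}

# random rank-1 statistics with a PSD-safe correlation structure
random_rank1_stats <- function(seed) {
  with_seed(seed, {
    sd_m <- runif(1, 0.5, 3); sd_n <- runif(1, 0.5, 8)
    rho <- runif(1, -0.9, 0.9)
    rank1_stats(mean_m = runif(1, -1, 2), mean_n = runif(1, -2, 2),
                sd_m = sd_m, sd_n = sd_n, cov_mn = rho * sd_m * sd_n)
  })
}

# a reduced-scale AI-regime spiking network with the fig3-right vector layout
build_ai_network <- function(N = 2500, preset_id = "table2_fig3_right",
                             seed = 11) {
  p <- preset(preset_id, N = N)
  seeds <- spawn_seeds(seed, c("vectors", "topology", "noise"))
  ens <- sample_vectors(p$stats, p$N, seeds[["vectors"]], I_norm = p$I_norm)
  ei <- if (p$ei$J > 0) sample_ei_matrix(p$ei, seeds[["topology"]]) else NULL
  conn <- compose_connectivity(ei, lowrank_matrix(ens))
  list(preset = p, ens = ens, conn = conn, noise_seed = seeds[["noise"]])
}
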