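#' Load an experiment configuration from JSON
#'
#' A configuration names a preset and optionally overrides top-level scalar
#' fields (`N`, `seed`, `n_trials`, ...). Unknown keys are rejected by name.
#'
#' @param path JSON file with keys among `preset`, `seed`, `N`, `n_trials`,
#'   `out_dir`, `overrides` (a flat list applied to the preset).
#' @return list of class `experiment_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("preset", "seed", "N", "n_trials", "out_dir", "overrides")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(raw$preset)) stop("configuration must name a `preset`")
  if (!raw$preset %in% preset_ids())
    stop("unknown preset '", raw$preset, "'")
  cfg <- list(preset = raw$preset,
              seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
              N = raw$N, n_trials = raw$n_trials,
              out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
              overrides = raw$overrides)
  structure(cfg, class = "experiment_config")
}

#' @rdname load_config
#' @param preset preset id.
#' @param seed master seed.
#' @param N optional size override.
#' @param n_trials optional trial-count override.
#' @param out_dir output directory.
#' @param overrides named list applied over the preset's top-level fields.
#' @export
experiment_config <- function(preset, seed = 1, N = NULL, n_trials = NULL,
                              out_dir = ".", overrides = NULL) {
  stopifnot(preset %in% preset_ids())
  structure(list(preset = preset, seed = as.integer(seed), N = N,
                 n_trials = n_trials, out_dir = out_dir,
                 overrides = overrides),
            class = "experiment_config")
}

#' Run a preset experiment end to end
#'
#' Orchestrates sampling, simulation, filtering and analysis according to the
#' preset's kind, writes the artifacts into `out_dir`, and returns a manifest
#' listing every file with the seeds used. Re-running with an identical
#' configuration reproduces the outputs.
#'
#' Artifact sets by kind: rate presets produce a latent-trajectory CSV and a
#' PCA/alignment CSV; spiking presets a raster, a PCA/alignment CSV and a
#' filter-sweep CSV; scan presets a bifurcation JSON; the task preset a
#' psychometric CSV.
#'
#' @param config an [experiment_config()] (or [load_config()] result).
#' @return the manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  p <- preset(config$preset, N = config$N)
  for (nm in names(config$overrides)) {
    if (!nm %in% names(p))
      stop("override '", nm, "' does not match a preset field")
    p[[nm]] <- config$overrides[[nm]]
  }
  if (!is.null(config$n_trials)) p$n_trials <- config$n_trials
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(config$seed, c("vectors", "topology", "noise"))
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  if (p$kind == "rate") {
    ens <- sample_vectors(p$stats, p$N, seeds[["vectors"]])
    u <- if (!is.null(p$input))
      stimulus_step(p$params, onset = p$input$onset,
                    amplitude = p$input$amplitude) else NULL
    traj <- simulate_rate(lowrank_matrix(ens),
                          I = if (ens$stats$n_in) ens$I else NULL,
                          u = u, x0 = 0, params = p$params)
    lat <- latent_from_trajectory(traj, ens)
    utils::write.csv(data.frame(time_ms = lat$times, kappa = lat$kappa,
                                v = lat$v),
                     out("latent.csv"), row.names = FALSE)
    pca <- run_pca(traj$r, n_pc = 8)
    dirs <- list(global = rep(1, p$N), m = ens$m[, 1])
    if (ens$stats$n_in) dirs$I <- ens$I[, 1]
    write_pca_csv(pca, out("pca.csv"), pc_alignment(pca, dirs, n_pc = 8))
    files <- c("latent.csv", "pca.csv")

  } else if (p$kind == "lif") {
    ens <- sample_vectors(p$stats, p$N, seeds[["vectors"]],
                          I_norm = p$I_norm)
    ei <- if (p$ei$J > 0) sample_ei_matrix(p$ei, seeds[["topology"]])
          else NULL
    conn <- compose_connectivity(ei, lowrank_matrix(ens))
    u <- if (!is.null(p$input))
      stimulus_step(p$lif, onset = p$input$onset,
                    amplitude = p$input$amplitude) else NULL
    n_tr <- if (is.null(p$n_trials)) 2 else p$n_trials
    raster <- simulate_lif(conn, I = ens$I, u = u, params = p$lif,
                           seed = seeds[["noise"]], n_trials = n_tr)
    write_raster(raster, out("raster.txt"))
    tau_f <- p$tau_f[length(p$tau_f)]
    rates <- average_trials(filter_spikes(raster, tau_f = tau_f, dt_out = 2))
    pca <- run_pca(rates, n_pc = 8)
    dirs <- list(global = rep(1, p$N), I = ens$I[, 1], m = ens$m[, 1])
    write_pca_csv(pca, out("pca.csv"), pc_alignment(pca, dirs, n_pc = 8))
    sweep <- filter_timescale_sweep(raster, c(1, 3, 10, 30, 100), dirs)
    utils::write.csv(sweep, out("filter_sweep.csv"), row.names = FALSE)
    files <- c("raster.txt", "pca.csv", "filter_sweep.csv")

  } else if (p$kind == "rate_scan") {
    diagram <- scan_bifurcation(p$stats, sweep = p$sweep, values = p$values,
                                n_realizations = 50, N = p$N,
                                x_off = p$params$x_off, seed = config$seed)
    write_bifurcation_json(diagram, out("bifurcation.json"))
    files <- "bifurcation.json"

  } else if (p$kind == "dm") {
    n_tr <- if (is.null(p$n_trials)) 30 else p$n_trials
    psy <- psychometric(p$overlaps, config = p$config,
                        stats_fn = function(ov) {
                          s <- p$stats
                          dm_stats(var_m = s$var_m, cov_mn = ov,
                                   cov_nI = s$base$Sigma["n1", "I1"],
                                   cov_mw = s$cov_mw)
                        },
                        N = p$N, n_trials = n_tr, seed = config$seed)
    utils::write.csv(psy, out("psychometric.csv"), row.names = FALSE)
    files <- "psychometric.csv"

  } else stop("preset kind '", p$kind, "' has no pipeline recipe")

  manifest <- list(preset = config$preset, kind = p$kind, N = p$N,
                   seed = config$seed, sub_seeds = as.list(seeds),
                   files = as.list(files),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
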