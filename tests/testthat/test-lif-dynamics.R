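test_that("subthreshold drift without noise never spikes", {
  p <- lif_params(mu0 = 15, sigma0 = 0, dt = 0.1, t_run = 500)
  ras <- simulate_lif(NULL, params = p, N = 20, V0 = rep(10, 20), seed = 1)
  expect_equal(nrow(ras), 0L)
})

test_that("noiseless firing matches the closed-form inter-spike interval", {
  # ISI = tau_ref + tau_m log((mu0 - v_r)/(mu0 - v_thr))
  isi_theory <- 0.5 + 20 * log((40 - 10) / (40 - 20))  # 8.61 ms -> 116.1 spk/s
  for (dt in c(0.1, 1)) {
    p <- lif_params(mu0 = 40, sigma0 = 0, tau_ref = 0.5, dt = dt,
                    t_run = 2000)
    ras <- simulate_lif(NULL, params = p, N = 5, V0 = rep(10, 5), seed = 1)
    isi <- diff(sort(ras$time[ras$neuron == 1]))
    expect_lt(abs(mean(isi) - isi_theory), dt + 1e-9)
  }
})

test_that("no inter-spike interval is shorter than the refractory period", {
  p <- lif_params(mu0 = 30, sigma0 = 3, tau_ref = 2, dt = 0.5, t_run = 1000)
  ras <- simulate_lif(NULL, params = p, N = 50, seed = 2)
  isis <- unlist(lapply(split(ras$time, ras$neuron), function(t) diff(sort(t))))
  expect_gte(min(isis), 2)
})

test_that("a synaptic kick arrives exactly one delay after the spike", {
  # neuron 1 fires deterministically; neuron 2 sits just below threshold and
  # is pushed over only by the arriving kick
  J <- Matrix::sparseMatrix(i = 2, j = 1, x = 2, dims = c(2, 2))
  Ivec <- matrix(c(25, 0), 2, 1)  # only neuron 1 is driven over threshold
  for (tau_del in c(1.5, 4)) {
    p <- lif_params(mu0 = 19.75, sigma0 = 0, tau_del = tau_del,
                    tau_ref = 0.5, dt = 0.5, t_run = 100)
    u <- matrix(1, round(p$t_run / p$dt), 1)
    ras <- simulate_lif(J, I = Ivec, u = u, params = p, N = 2,
                        V0 = c(10, 19.5), seed = 1)
    t1 <- min(ras$time[ras$neuron == 1])
    t2 <- min(ras$time[ras$neuron == 2])
    expect_equal(t2 - t1, max(tau_del, p$dt))
  }
})

test_that("membrane fluctuations match the Ornstein-Uhlenbeck closed form", {
  # uncoupled, subthreshold: stationary Var(V - mu0) = sigma0^2 / 2 under the
  # sqrt(dt/tau_m) convention
  p <- lif_params(mu0 = 10, sigma0 = 2, v_thr = 1e3, dt = 0.1, t_run = 200)
  N <- 2e4
  ras <- simulate_lif(NULL, params = p, N = N, V0 = rep(10, N), seed = 3)
  # no spikes: read stationary V through a fresh run's returned potentials
  res <- attr(ras, "params")
  expect_equal(nrow(ras), 0L)
  # draw the stationary sample directly from the core by rerunning and
  # capturing final V via the exposed simulator state
  Vfin <- lowrankSNN:::lif_core_cpp(
    N, integer(1), integer(0), numeric(0), FALSE,
    matrix(0, 1, 1), matrix(0, 1, 1), FALSE,
    matrix(0, 1, 1), matrix(0, 1, 1), FALSE,
    10, 2, 20, 1e3, 0, 0, 1.5, 0.1, 2000, rep(10, N), 1L, Inf)$V
  v_emp <- var(Vfin - 10)
  expect_lt(abs(v_emp - 2^2 / 2) / (2^2 / 2), 0.05)
})

test_that("exponential filter conserves the unit integral per spike", {
  ras <- make_raster(time = 100, neuron = 1, N = 1, t_run = 600)
  r <- filter_spikes(ras, tau_f = 20, dt_out = 0.25)[[1]]
  # rates are in spk/s; integral over time (s) of one spike is 1
  integral <- sum(r) * 0.25 / 1000
  expect_equal(integral, 1, tolerance = 0.01)
  expect_equal(max(r) / 1000, 1 / 20)  # peak 1/tau_f
})

test_that("periodic spikes filter to their rate and match spike counts", {
  times <- seq(10, 2000, by = 10)  # 100 spk/s
  ras <- make_raster(times, rep(1, length(times)), N = 1, t_run = 2000)
  r <- filter_spikes(ras, tau_f = 50, dt_out = 1)[[1]]
  late <- attr(r, "times") > 500
  # right-edge sampling biases the mean upward by ~dt_out / (2 tau_f) = 1%
  expect_equal(mean(r[late, 1]), 100, tolerance = 0.02)
  # time-averaged filtered rate equals count / t_run up to boundary terms
  expect_equal(mean(r[, 1]), length(times) / 2, tolerance = 0.05)
})

test_that("trial averaging is the pointwise mean with variance ~ 1/N_tr", {
  p <- lif_params(mu0 = 30, sigma0 = 2, dt = 0.5, t_run = 1000)
  ras <- simulate_lif(NULL, params = p, N = 30, seed = 5, n_trials = 8)
  rl <- filter_spikes(ras, tau_f = 50, dt_out = 5)
  expect_equal(average_trials(rl[1]), rl[[1]], ignore_attr = TRUE)
  m2 <- average_trials(rl[1:2])
  expect_equal(as.numeric(m2), as.numeric((rl[[1]] + rl[[2]]) / 2))
  # pointwise scatter around the trial mean shrinks roughly as 1/sqrt(N_tr)
  late <- attr(rl[[1]], "times") > 300
  sd1 <- sd(rl[[1]][late, 1] - average_trials(rl)[late, 1])
  sd8 <- sd(average_trials(rl)[late, 1] -
              mean(average_trials(rl)[late, 1]))
  expect_lt(sd8, sd1)  # averaged trace is smoother than single trials
  expect_error(average_trials(list(rl[[1]],
    filter_spikes(ras, tau_f = 20, dt_out = 5)[[1]])), "mismatch")
})

test_that("regime presets carry the published background parameters", {
  ai <- regime_preset("AI")
  expect_equal(c(ai$ei$J, ai$ei$g, ai$lif$mu0), c(0.1, 5, 40))
  si <- regime_preset("SI")
  expect_equal(c(si$ei$J, si$ei$g, si$lif$mu0), c(0.1, 6, 80))
  no <- regime_preset("no_EI")
  expect_equal(c(no$ei$J, no$lif$mu0), c(0, 30))
  expect_error(regime_preset("bogus"))
})

test_that("raster determinism and the population-rate runaway guard", {
  p <- lif_params(mu0 = 30, sigma0 = 2, dt = 0.5, t_run = 300)
  a <- simulate_lif(NULL, params = p, N = 20, seed = 9)
  b <- simulate_lif(NULL, params = p, N = 20, seed = 9)
  expect_identical(a$time, b$time)
  expect_identical(a$neuron, b$neuron)
  pc <- lif_params(mu0 = 40, sigma0 = 0, tau_ref = 0, dt = 0.5, t_run = 100,
                   rate_cap = 10)
  expect_error(simulate_lif(NULL, params = pc, N = 50, V0 = rep(19.9, 50),
                            seed = 1),
               "runaway")
})
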