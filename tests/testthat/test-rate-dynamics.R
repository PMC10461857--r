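test_that("transfer function pins its inflection, saturation and offset", {
  expect_equal(transfer(2.9, x_off = 2.9), 1)
  expect_equal(transfer_deriv(2.9, x_off = 2.9), 1)
  expect_equal(transfer(c(-1e3, 1e3), x_off = 0), c(0, 2))
  # high-precision reference for phi(0) and phi'(0) at the standard offset
  expect_equal(transfer(0, x_off = 2.9), 0.006036832649416848, tolerance = 1e-12)
  expect_equal(transfer_deriv(0, x_off = 2.9), 0.012037221950396630,
               tolerance = 1e-12)
})

test_that("uncoupled activations decay with the membrane time constant", {
  params <- rate_params(tau = 100, dt = 0.5, t_run = 300, x_off = 0)
  traj <- simulate_rate(NULL, x0 = 2, params = params)
  at_tau <- which.min(abs(traj$times - 100))
  expect_equal(traj$x[at_tau, 1] / 2, exp(-1), tolerance = 5e-3)
  expect_true(all(traj$r > 0 & traj$r < 2))
})

test_that("input latent follows the low-pass-filtered step exactly", {
  params <- rate_params(tau = 100, dt = 0.1, t_run = 500, x_off = 0)
  ens <- sample_vectors(rank1_stats(), 200, seed = 1)
  ens$n[, 1] <- 0  # no recurrence: kappa decays, v follows the step
  u <- stimulus_step(params, onset = 0, amplitude = 1.5)
  lat <- simulate_latent_empirical(ens, u = u, kappa0 = 0.7, params = params)
  expect_equal(lat$v[, 1], 1.5 * (1 - exp(-lat$times / 100)),
               tolerance = 2e-3)
  expect_equal(lat$kappa[, 1], 0.7 * exp(-lat$times / 100), tolerance = 2e-3)
})

test_that("latent extraction inverts exact linear combinations", {
  ens <- sample_vectors(rank1_stats(), 500, seed = 2)
  x <- 3 * ens$m[, 1] + 2 * ens$I[, 1]
  traj <- structure(list(times = c(1, 2), x = rbind(x, x),
                         r = transfer(rbind(x, x)),
                         params = rate_params(t_run = 2)),
                    class = "rate_trajectory")
  lat <- latent_from_trajectory(traj, ens)
  expect_equal(unname(lat$kappa[1, 1]), 3, tolerance = 1e-10)
  expect_equal(unname(lat$v[1, 1]), 2, tolerance = 1e-10)
  # reconstruction is the orthogonal projection: residual orthogonal to basis
  y <- rnorm(500)
  traj$x <- rbind(y, y)
  laty <- latent_from_trajectory(traj, ens)
  resid <- y - laty$kappa[1, 1] * ens$m[, 1] - laty$v[1, 1] * ens$I[, 1]
  expect_lt(abs(sum(resid * ens$m[, 1])), 1e-9)
  expect_lt(abs(sum(resid * ens$I[, 1])), 1e-9)
})

test_that("empirical latent reduction reproduces the full network exactly", {
  # with x(0) in span{m, I} the finite-N latent ODE is an exact reduction
  p <- preset("table1_blue")
  u <- stimulus_step(p$params, onset = 1000, amplitude = 1)
  ens <- sample_vectors(p$stats, 400, seed = 5)
  traj <- simulate_rate(lowrank_matrix(ens), I = ens$I, u = u, x0 = 0,
                        params = p$params)
  lat_full <- latent_from_trajectory(traj, ens)
  lat_red <- simulate_latent_empirical(ens, u = u, params = p$params)
  expect_lt(max(abs(lat_full$kappa - lat_red$kappa)), 1e-10)
  expect_lt(max(abs(lat_full$v - lat_red$v)), 1e-10)
})

test_that("finite networks approach the mean-field latent as 1/sqrt(N)", {
  p <- preset("table1_blue")
  params <- rate_params(tau = 100, dt = 2, t_run = 3000, x_off = 2.9)
  u <- stimulus_step(params, onset = 500, amplitude = 1)
  mf <- simulate_latent_meanfield(p$stats, u = u, params = params)
  dev <- sapply(c(250, 4000), function(N) {
    mean(sapply(1:5, function(s) {
      ens <- sample_vectors(p$stats, N, seed = 40 + s)
      lat <- simulate_latent_empirical(ens, u = u, params = params)
      max(abs(lat$kappa - mf$kappa))
    }))
  })
  expect_lt(dev[2], dev[1])          # shrinks with N
  expect_lt(dev[1], 0.8 / sqrt(250)) # and sits at the 1/sqrt(N) scale
  expect_lt(dev[2], 0.8 / sqrt(4000))
})

test_that("trajectories stay confined to the input-connectivity subspace", {
  p <- preset("table1_blue")
  params <- rate_params(tau = 100, dt = 2, t_run = 2000, x_off = 2.9)
  u <- stimulus_step(params, onset = 500, amplitude = 1)
  N <- 500
  ens <- sample_vectors(p$stats, N, seed = 3)
  traj <- simulate_rate(lowrank_matrix(ens), I = ens$I, u = u, x0 = 0,
                        params = params)
  W <- with_seed(1, matrix(rnorm(N * 20), N, 20))
  B <- cbind(ens$m, ens$I)
  W <- W - B %*% solve(crossprod(B), crossprod(B, W))
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  expect_lt(max(abs(traj$x %*% W)) / max(abs(traj$x)), 5 / sqrt(N))
})

test_that("halving the Euler step changes the endpoint at O(dt)", {
  p <- preset("table1_blue")
  ens <- sample_vectors(p$stats, 300, seed = 6)
  run <- function(dt) {
    params <- rate_params(tau = 100, dt = dt, t_run = 2000, x_off = 2.9)
    u <- stimulus_step(params, onset = 500, amplitude = 1)
    lat <- simulate_latent_empirical(ens, u = u, params = params)
    lat$kappa[nrow(lat$kappa), 1]
  }
  d1 <- abs(run(4) - run(2))
  d2 <- abs(run(2) - run(1))
  expect_lt(d2, 0.75 * d1)  # first-order convergence
})

test_that("divergent simulations abort with a diagnostic", {
  params <- rate_params(tau = 10, dt = 5, t_run = 5000, x_off = 0)
  expect_error(
    simulate_rate(matrix(5, 100, 100), x0 = 1, params = params,
                  diverge_bound = 100),
    "diverged")
})
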