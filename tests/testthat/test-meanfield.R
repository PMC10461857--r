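test_that("Gaussian expectations pin the delta-measure and symmetry limits", {
  x_off <- 2.9
  expect_equal(gaussian_expectation("phi", x_off, 0, x_off), 1)
  expect_equal(gaussian_expectation("dphi", x_off, 0, x_off), 1)
  # odd symmetry of tanh: <phi> -> 1 for wide inputs centered on the offset
  expect_equal(gaussian_expectation("phi", x_off, 1e4, x_off), 1,
               tolerance = 1e-6)
  # frozen high-precision reference at (mu = x_off, Delta = 1)
  expect_equal(gaussian_expectation("phi", x_off, 1, x_off), 1,
               tolerance = 1e-10)
  expect_equal(gaussian_expectation("dphi", x_off, 1, x_off),
               0.60570550960215883, tolerance = 1e-10)
})

test_that("quadrature and Monte-Carlo expectations agree to sampling error", {
  grid <- expand.grid(mu = c(-2, 0, 1, 3), Delta = c(0.1, 1, 9))
  for (k in seq_len(nrow(grid))) {
    q <- gaussian_expectation("phi", grid$mu[k], grid$Delta[k], 2.9)
    n_mc <- 1e6
    mc <- gaussian_expectation("phi", grid$mu[k], grid$Delta[k], 2.9,
                               method = "monte_carlo", n_samples = n_mc,
                               seed = k)
    expect_lt(abs(q - mc), 3 * 1 / sqrt(n_mc) * 2)  # |phi| <= 2
  }
})

test_that("the self-consistency function is odd for zero-mean statistics", {
  st <- rank1_stats(sd_m = 2, sd_n = 6, cov_mn = 4)
  k <- c(0.2, 1, 3.7)
  expect_equal(F_rank1(-k, 0, st, 2.9), -F_rank1(k, 0, st, 2.9))
  # no mean, no covariance: F vanishes identically, kappa = 0 unique root
  st0 <- rank1_stats(sd_m = 2, sd_n = 6)
  expect_equal(F_rank1(c(-1, 0, 2), 0, st0, 2.9), c(0, 0, 0))
  fp <- solve_fixed_points_rank1(st0, x_off = 2.9)
  expect_equal(fp$kappa, 0)
  expect_true(fp$stable)
})

test_that("Stein's identity: finite-N sums converge to the Gaussian form", {
  N <- 1e5
  for (s in 1:10) {
    st <- random_rank1_stats(s)
    ens <- sample_vectors(st, N, seed = 100 + s)
    kappas <- c(-1.2, 0.4, 2.5)
    Fq <- F_rank1(kappas, 0, st, 2.9)
    Fe <- F_rank1_empirical(kappas, 0, ens, 2.9)
    for (j in seq_along(kappas)) {
      # sample std of the summand n_i phi(kappa m_i)
      sdv <- sd(ens$n[, 1] * transfer(kappas[j] * ens$m[, 1], 2.9))
      expect_lt(abs(Fq[j] - Fe[j]), 4 * sdv / sqrt(N))
    }
  }
})

test_that("mean-driven feedback bifurcates to low and high states", {
  # mean sweep: at overlap n^T m / N = 10 the positive sigmoid yields one
  # low and one high stable state separated by an unstable root
  st <- rank1_stats(mean_m = 2, mean_n = 5, sd_m = 2, sd_n = 6)
  fp <- solve_fixed_points_rank1(st, x_off = 2.9)
  expect_equal(sum(fp$stable), 2)
  expect_equal(sum(!fp$stable), 1)
  stable_k <- sort(fp$kappa[fp$stable])
  rates <- predicted_population_rate(stable_k, st, x_off = 2.9)
  expect_gt(rates[2] / rates[1], 10)   # high state ~ saturated, low ~ silent
  # below the critical overlap only the low state survives
  st_sub <- rank1_stats(mean_m = 2, mean_n = 0.5, sd_m = 2, sd_n = 6)
  expect_equal(sum(solve_fixed_points_rank1(st_sub, x_off = 2.9)$stable), 1)
})

test_that("covariance-driven feedback bifurcates to symmetric states", {
  st <- rank1_stats(sd_m = 2, sd_n = 6, cov_mn = 11.2)
  fp <- solve_fixed_points_rank1(st, x_off = 2.9)
  # roots come in +/- pairs around a fixed point at zero
  expect_true(any(fp$kappa == 0))
  nz <- fp$kappa[fp$kappa != 0]
  expect_equal(sort(nz), sort(-nz))
  stable_nz <- sort(abs(fp$kappa[fp$stable & fp$kappa != 0]))
  expect_gt(length(stable_nz), 0)
  # symmetric states share the population-averaged rate exactly
  r <- predicted_population_rate(c(-stable_nz[1], stable_nz[1]), st,
                                 x_off = 2.9)
  expect_equal(r[1], r[2])
})

test_that("zero-branch destabilization matches the closed-form condition", {
  # - 1 + dF/dkappa|_0 = 0 at cov_mn * phi'(0) = 1
  x_off <- 0.5
  crit_theory <- 1 / transfer_deriv(0, x_off)
  slope0 <- function(cov) {
    st <- rank1_stats(sd_m = 2, sd_n = 6, cov_mn = cov)
    h <- 1e-5
    -1 + (F_rank1(h, 0, st, x_off) - F_rank1(-h, 0, st, x_off)) / (2 * h)
  }
  covs <- seq(0.8, 1.2, by = 0.01) * crit_theory
  sgn <- sapply(covs, slope0)
  crit_num <- covs[which(diff(sign(sgn)) != 0)[1]]
  expect_equal(crit_num, crit_theory, tolerance = 0.02)
})

test_that("Monte-Carlo bifurcation scans classify symmetric branches", {
  d <- scan_bifurcation(rank1_stats(sd_m = 2, sd_n = 6), sweep = "cov_mn",
                        values = c(2, 11.2), n_realizations = 10, N = 3000,
                        x_off = 2.9, seed = 2)
  sub <- d[d$value == 2, ]
  expect_true(all(sub$branch == "zero"))
  top <- d[d$value == 11.2 & d$stable & d$branch != "zero", ]
  expect_gte(nrow(top), 2)
  kp <- top$kappa[top$branch == "pos"]; kn <- top$kappa[top$branch == "neg"]
  expect_equal(sort(kp), sort(-kn), tolerance = 0.1)
  # identical population rates on the two symmetric branches
  rp <- top$rate[top$branch == "pos"]; rn <- top$rate[top$branch == "neg"]
  expect_equal(sort(rp), sort(rn), tolerance = 0.05)
})

test_that("mean-sweep scans give distinct low/high population rates", {
  d <- scan_bifurcation(rank1_stats(mean_m = 2, sd_m = 2, sd_n = 6),
                        sweep = "mean_n", values = c(5), n_realizations = 10,
                        N = 3000, x_off = 2.9, seed = 4)
  st <- d[d$stable, ]
  expect_equal(nrow(st), 2)
  expect_gt(max(st$rate) / min(st$rate), 10)
  expect_equal(d$overlap, rep(10, nrow(d)))  # overlap = <n> <m>
})

test_that("rank-2 flow: origin, rotation rate, and regime labels", {
  s_osc <- rank2_stats(sd_m = c(1, 1), sd_n = c(7.24, 3.63),
                       cov_n1m1 = 2, cov_n1m2 = -0.8,
                       cov_n2m1 = 0.8, cov_n2m2 = 2)
  expect_equal(rank2_rhs(0, 0, s_osc, x_off = 0), c(0, 0))
  an <- analyze_overlap_matrix(s_osc, x_off = 0)
  expect_equal(sort(Im(an$eigenvalues)), c(-0.8, 0.8))
  expect_equal(Re(an$eigenvalues), c(2, 2))
  expect_equal(an$regime, "complex-oscillatory")

  # small-radius angular speed ~ phi'(0) sigma_w (in units of 1/tau)
  fl <- simulate_rank2_flow(s_osc, kappa0 = c(1e-3, 0), x_off = 0,
                            tau = 100, dt = 0.5, t_run = 200)
  ang <- atan2(fl$kappa[, 2], fl$kappa[, 1])
  dw <- diff(ang); dw <- ifelse(dw > pi, dw - 2 * pi,
                                ifelse(dw < -pi, dw + 2 * pi, dw))
  # angular speed per tau
  expect_equal(abs(sum(dw)) / (200 / 100), 0.8, tolerance = 0.05)

  s_ring <- rank2_stats(sd_m = c(1, 1), sd_n = c(7.24, 3.63),
                        cov_n1m1 = 2, cov_n2m2 = 2)
  expect_equal(analyze_overlap_matrix(s_ring, x_off = 0)$regime,
               "degenerate-ring")
  s_zero <- rank2_stats(sd_m = c(1, 1), sd_n = c(1, 1))
  expect_equal(analyze_overlap_matrix(s_zero, x_off = 0)$regime,
               "stable-origin")
  # subcritical gain: the same matrices are stable at high offset
  expect_equal(analyze_overlap_matrix(s_osc, x_off = 2.9)$regime,
               "stable-origin")
})

test_that("supercritical complex pair settles on a seed-independent orbit", {
  s_osc <- rank2_stats(sd_m = c(1, 1), sd_n = c(7.24, 3.63),
                       cov_n1m1 = 2, cov_n1m2 = -0.8,
                       cov_n2m1 = 0.8, cov_n2m2 = 2)
  radii <- sapply(list(c(0.05, 0), c(2, 1), c(-1, 3)), function(k0) {
    fl <- simulate_rank2_flow(s_osc, kappa0 = k0, x_off = 0,
                              tau = 100, dt = 1, t_run = 15000)
    tail_k <- fl$kappa[10000:15000, ]
    r <- sqrt(rowSums(tail_k^2))
    expect_lt(sd(r) / mean(r), 0.05)  # closed orbit: stationary radius
    mean(r)
  })
  expect_lt(diff(range(radii)) / mean(radii), 0.02)
})

test_that("predicted population rate is even in kappa for zero-mean m", {
  st <- rank1_stats(sd_m = 2, sd_n = 6)
  expect_equal(predicted_population_rate(0, st, x_off = 2.9),
               transfer(0, 2.9))
  expect_equal(predicted_population_rate(c(-1.3, 1.3), st, x_off = 2.9)[1],
               predicted_population_rate(c(-1.3, 1.3), st, x_off = 2.9)[2])
  # ensemble and statistics forms agree within 4/sqrt(N)
  ens <- sample_vectors(st, 1e5, seed = 11)
  expect_lt(abs(predicted_population_rate(1.5, ens, x_off = 2.9) -
                predicted_population_rate(1.5, st, x_off = 2.9)),
            4 / sqrt(1e5) * sd(transfer(1.5 * ens$m[, 1], 2.9)) * 10)
})
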