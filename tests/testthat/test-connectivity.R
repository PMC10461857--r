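test_that("vector statistics reject impossible covariances by name", {
  expect_error(rank1_stats(sd_m = 1, sd_n = 1, cov_mn = 2),
               "m1.*n1|n1.*m1")
  expect_error(vector_stats(rank = 2, cov = c("n2.m2" = 5),
                            sd_m = 1, sd_n = 1),
               "positive semi-definite")
  # boundary (perfectly correlated) covariances are allowed
  expect_s3_class(rank1_stats(cov_nI = 1), "vector_stats")
})

test_that("sampling is bit-reproducible and leaves the caller's RNG alone", {
  st <- rank1_stats(cov_mn = 0.5, cov_nI = 0.3)
  set.seed(99); before <- rnorm(1)
  a <- sample_vectors(st, 500, seed = 7)
  b <- sample_vectors(st, 500, seed = 7)
  expect_identical(a$m, b$m)
  expect_identical(a$n, b$n)
  expect_identical(a$I, b$I)
  set.seed(99); expect_identical(rnorm(1), before)
  c <- sample_vectors(st, 500, seed = 8)
  expect_false(identical(a$m, c$m))
})

test_that("sampled coordinates recover every configured moment", {
  N <- 1e5
  st <- vector_stats(rank = 2, n_in = 1,
                     mean_m = c(0.5, -1), mean_n = c(2, 0),
                     sd_m = c(1, 2), sd_n = c(3, 1.5), sd_I = 2, sd_w = 1,
                     cov = c("n1.m1" = 2, "n2.m2" = -1.2, "n1.I1" = 1.5,
                             "m1.w" = 0.4))
  ens <- sample_vectors(st, N, seed = 3)
  A <- cbind(ens$m, ens$n, ens$I, ens$w)
  colnames(A) <- colnames(st$Sigma)
  emp <- stats::cov(A)
  for (a in colnames(A)) for (b in colnames(A)) {
    se <- sqrt((st$Sigma[a, a] * st$Sigma[b, b] + st$Sigma[a, b]^2) / N)
    expect_lt(abs(emp[a, b] - st$Sigma[a, b]), 4 * se + 1e-12)
  }
  expect_lt(max(abs(colMeans(A) - st$mu) / (st$sd + 1e-12)), 4 / sqrt(N))
})

test_that("independent vectors have vanishing empirical overlap", {
  ens <- sample_vectors(rank1_stats(), 1e5, seed = 1)
  ov <- empirical_overlaps(ens)
  expect_lt(abs(ov$nI[1, 1]), 3 / sqrt(1e5))
  expect_lt(abs(ov$P_ov[1, 1]), 3 / sqrt(1e5))
})

test_that("overlap matrix reduces to exact arithmetic on given vectors", {
  ens <- sample_vectors(rank1_stats(), 2, seed = 1)
  ens$m[, 1] <- c(1, 1); ens$n[, 1] <- c(2, 0)
  expect_equal(empirical_overlaps(ens)$P_ov[1, 1], 1)
})

test_that("rank-2 overlaps converge to the configured covariances", {
  st <- rank2_stats(sd_m = c(1, 1), sd_n = c(7.24, 3.63),
                    cov_n1m1 = 2, cov_n1m2 = -0.8,
                    cov_n2m1 = 0.8, cov_n2m2 = 2)
  ens <- sample_vectors(st, 1e5, seed = 5)
  expect_equal(empirical_overlaps(ens)$P_ov,
               matrix(c(2, 0.8, -0.8, 2), 2,
                      dimnames = list(c("n1", "n2"), c("m1", "m2"))),
               tolerance = 0.06)
})

test_that("factored low-rank matrix matches its dense form", {
  st <- rank2_stats(sd_m = c(1, 1), sd_n = c(2, 2),
                    cov_n1m1 = 1, cov_n2m2 = 1)
  ens <- sample_vectors(st, 50, seed = 2)
  lr <- lowrank_matrix(ens)
  P <- as_dense(lr)
  expect_equal(P, tcrossprod(ens$m, ens$n) / 50)
  x <- rnorm(50)
  expect_equal(as.numeric(lr_matvec(lr, x)), as.numeric(P %*% x),
               tolerance = 1e-12)
  # numerical rank is at most 2
  sv <- svd(P)$d
  expect_lt(sv[3], 1e-10 * sv[1])
  expect_error(as_dense(lr, max_n = 10), "refusing")
})

test_that("rank-one of all-ones gives constant entries 1/N", {
  ens <- sample_vectors(rank1_stats(), 4, seed = 1)
  ens$m[, 1] <- 1; ens$n[, 1] <- 1
  expect_equal(as_dense(lowrank_matrix(ens)),
               matrix(0.25, 4, 4))
})

test_that("entry moments of the outer product match direct materialization", {
  ens <- sample_vectors(rank1_stats(sd_m = 2, sd_n = 20), 300, seed = 9)
  es <- lowrank_entry_stats(ens)
  P <- as_dense(lowrank_matrix(ens))
  expect_equal(es$mean, mean(P))
  # population (not n-1) standard deviation over all N^2 entries
  expect_equal(es$sd, sqrt(mean((P - mean(P))^2)), tolerance = 1e-12)
})

test_that("E-I matrix has exact row structure and density", {
  spec <- ei_spec(N = 1000, C = 100, f_exc = 0.8, J = 0.2, g = 5)
  M <- sample_ei_matrix(spec, seed = 4)
  expect_equal(length(M@x) / 1000^2, 0.1)           # density C/N
  expect_true(all(Matrix::rowSums(M != 0) == 100))  # in-degree
  expect_true(all(Matrix::rowSums(M > 0) == 80))    # excitatory in-degree
  expect_true(all(M@x %in% c(0.2, -1)))             # J and -g J
  expect_equal(unname(Matrix::diag(M)), rep(0, 1000))  # no self-connections
  # excitatory columns are the first f_exc * N indices
  trip <- Matrix::mat2triplet(M)
  expect_true(all(trip$x[trip$j <= 800] > 0))
  expect_true(all(trip$x[trip$j > 800] < 0))
  # J = 0 gives an empty matrix
  expect_equal(length(sample_ei_matrix(ei_spec(100, 10, J = 0), 1)@x), 0)
})

test_that("composition is additive and Dale sparsification masks onto E-I", {
  spec <- ei_spec(N = 400, C = 40, J = 0.5, g = 5)
  ei <- sample_ei_matrix(spec, seed = 6)
  # |P| ~ sd_m sd_n / N = 0.01 mV << J: the composed matrix keeps Dale signs
  ens <- sample_vectors(rank1_stats(sd_m = 2, sd_n = 2), 400, seed = 6)
  lr <- lowrank_matrix(ens)

  zero_lr <- lowrank_matrix(list(m = matrix(0, 400, 1),
                                 n = matrix(0, 400, 1)))
  bz <- compose_connectivity(ei, zero_lr, dale_sparsify = TRUE,
                             ei_spec = spec)
  expect_equal(bz$full_sparse, ei)

  b <- compose_connectivity(ei, lr, dale_sparsify = TRUE, ei_spec = spec)
  expect_true(all((b$full_sparse != 0) == (ei != 0)))
  expect_equal(b$dale_violations, 0L)
  # factored and masked paths agree with the dense sum where unmasked
  x <- rnorm(400)
  bf <- compose_connectivity(ei, lr)
  expect_equal(conn_matvec(bf, x),
               as.numeric(ei %*% x + as_dense(lr) %*% x), tolerance = 1e-10)
})

test_that("Dale violations are warned about, not fatal", {
  spec <- ei_spec(N = 50, C = 10, J = 0.01, g = 1)  # weak E-I, strong P
  ei <- sample_ei_matrix(spec, seed = 2)
  ens <- sample_vectors(rank1_stats(sd_m = 5, sd_n = 5), 50, seed = 2)
  expect_warning(
    b <- compose_connectivity(ei, lowrank_matrix(ens), dale_sparsify = TRUE,
                              ei_spec = spec),
    "Dale")
  expect_gt(b$dale_violations, 0)
})
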