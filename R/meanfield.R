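#' Gaussian expectation of the transfer function or its derivative
#'
#' Evaluates `<f(mu, Delta)> = int Dz f(mu + sqrt(Delta) z)` with `Dz` the
#' standard Gaussian measure and `f` either the transfer function `phi` or its
#' derivative. Quadrature uses Gauss-Hermite nodes (deterministic, default);
#' the Monte-Carlo path averages standard-normal draws, mirroring the
#' stochastic evaluation used for bifurcation scans.
#'
#' @param which `"phi"` or `"dphi"`.
#' @param mu mean input (vectorized).
#' @param Delta input variance (>= 0, vectorized with `mu`).
#' @param x_off transfer-function offset.
#' @param method `"quadrature"` or `"monte_carlo"`.
#' @param order Gauss-Hermite order (quadrature).
#' @param n_samples number of draws (Monte Carlo).
#' @param seed seed for the Monte-Carlo path.
#' @return numeric vector of expectations.
#' @export
gaussian_expectation <- function(which = c("phi", "dphi"), mu, Delta,
                                 x_off = 0,
                                 method = c("quadrature", "monte_carlo"),
                                 order = 512, n_samples = 1e5, seed = 1) {
  which <- match.arg(which); method <- match.arg(method)
  if (any(Delta < -1e-12)) stop("Delta must be non-negative")
  Delta <- pmax(Delta, 0)
  f <- if (which == "phi") transfer else transfer_deriv
  if (method == "quadrature") {
    gh <- .gh_nodes(order)
    # int Dz f(mu + sqrt(Delta) z) = (1/sqrt(pi)) sum w_k f(mu + sqrt(2 Delta) x_k)
    z <- outer(sqrt(2 * Delta), gh$x)       # n x order
    vals <- f(mu + z, x_off)
    as.numeric(vals %*% gh$w) / sqrt(pi)
  } else {
    z <- with_seed(seed, stats::rnorm(n_samples))
    vapply(seq_along(mu), function(k)
      mean(f(mu[k] + sqrt(Delta[k]) * z, x_off)), numeric(1))
  }
}

# symmetric root-bracketing grid: uniform coverage of [-span, span] plus a
# logarithmic refinement near zero, where low-activity roots of the positive
# transfer function accumulate
.root_grid <- function(span, n_uniform = 401, n_log = 120) {
  lg <- span * 10^seq(-5, 0, length.out = n_log)
  sort(unique(c(0, seq(-span, span, length.out = n_uniform), lg, -lg)))
}

# cache Gauss-Hermite nodes per order
.gh_cache <- new.env(parent = emptyenv())
.gh_nodes <- function(order) {
  key <- as.character(order)
  if (is.null(.gh_cache[[key]]))
    .gh_cache[[key]] <- pracma::gaussHermite(order)
  .gh_cache[[key]]
}

#' Mean-field right-hand side for the rank-1 collective variable
#'
#' Evaluates `F(kappa) = <n><phi(mu, Delta)> + (sigma_nm kappa + sigma_nI v)
#' <phi'(mu, Delta)>` with `mu = <I> v + <m> kappa` and
#' `Delta = (kappa sigma_m)^2 + (v sigma_I)^2`. At the fixed point
#' `kappa = F(kappa)`; with `v = 0` this is the autonomous self-consistency
#' function.
#'
#' @param kappa collective variable (vectorized).
#' @param v input latent variable (scalar).
#' @param stats a rank-1 [vector_stats()].
#' @param x_off transfer-function offset.
#' @param method,order,n_samples,seed passed to [gaussian_expectation()].
#' @return `F(kappa)`, vectorized over `kappa`.
#' @export
F_rank1 <- function(kappa, v = 0, stats, x_off = 0,
                    method = "quadrature", order = 512,
                    n_samples = 1e5, seed = 1) {
  stopifnot(inherits(stats, "vector_stats"), stats$rank == 1)
  mean_m <- stats$mu[["m1"]]; mean_n <- stats$mu[["n1"]]
  mean_I <- if (stats$n_in > 0) stats$mu[["I1"]] else 0
  sd_m <- stats$sd[["m1"]]
  sd_I <- if (stats$n_in > 0) stats$sd[["I1"]] else 0
  cov_mn <- stats$Sigma["m1", "n1"]
  cov_nI <- if (stats$n_in > 0) stats$Sigma["n1", "I1"] else 0
  mu <- mean_I * v + mean_m * kappa
  Delta <- (kappa * sd_m)^2 + (v * sd_I)^2
  ephi <- gaussian_expectation("phi", mu, Delta, x_off, method, order,
                               n_samples, seed)
  edphi <- gaussian_expectation("dphi", mu, Delta, x_off, method, order,
                                n_samples, seed)
  mean_n * ephi + (cov_mn * kappa + cov_nI * v) * edphi
}

#' Empirical finite-N evaluation of the rank-1 self-consistency function
#'
#' `F_emp(kappa) = (1/N) sum_i n_i phi(kappa m_i + v I_i)` on a sampled
#' ensemble; the Stein-lemma identity makes this converge to [F_rank1()] as
#' N grows.
#'
#' @param kappa collective variable (vectorized).
#' @param v input latent variable.
#' @param ensemble a rank-1 `vector_ensemble`.
#' @param x_off transfer-function offset.
#' @return empirical `F(kappa)`.
#' @export
F_rank1_empirical <- function(kappa, v = 0, ensemble, x_off = 0) {
  stopifnot(inherits(ensemble, "vector_ensemble"), ensemble$stats$rank == 1)
  m <- ensemble$m[, 1]; n <- ensemble$n[, 1]
  N <- ensemble$N
  base <- if (ensemble$stats$n_in > 0) v * ensemble$I[, 1] else numeric(N)
  out <- numeric(length(kappa))
  step <- max(1L, floor(5e7 / N))  # bound the dense N x K working block
  for (s in seq(1, length(kappa), by = step)) {
    cols <- s:min(s + step - 1L, length(kappa))
    X <- outer(m, kappa[cols]) + base
    out[cols] <- as.numeric(crossprod(n, transfer(X, x_off))) / N
  }
  out
}

#' Solve the rank-1 fixed-point equation
#'
#' Finds all solutions of `kappa = F(kappa)` by bracketing sign changes of
#' `kappa - F(kappa)` on a grid and bisecting each bracket, then classifies
#' stability from the slope `s = -1 + F'(kappa*)` (numerical derivative):
#' stable iff `s < 0`. `F` is bounded, so all roots lie inside a computable
#' interval; the default grid spans it.
#'
#' @param stats a rank-1 [vector_stats()] (or a function `F(kappa)`).
#' @param v input latent variable held fixed.
#' @param x_off transfer-function offset.
#' @param kappa_grid optional grid bracketing the roots; default: 400 points
#'   over a span derived from the statistics.
#' @param tol root tolerance (also used to deduplicate).
#' @param ... passed to [F_rank1()] when `stats` is a `vector_stats`.
#' @return an object of class `fixed_point_set`: data frame with columns
#'   `kappa`, `slope`, `stable`.
#' @export
solve_fixed_points_rank1 <- function(stats, v = 0, x_off = 0,
                                     kappa_grid = NULL, tol = 1e-9, ...) {
  Ffun <- if (is.function(stats)) stats
          else function(k) F_rank1(k, v = v, stats = stats, x_off = x_off, ...)
  if (is.null(kappa_grid)) {
    if (is.function(stats))
      stop("kappa_grid must be supplied when `stats` is a function")
    span <- 5 * max(stats$sd[["n1"]], 2 * abs(stats$mu[["n1"]]),
                    abs(stats$Sigma["m1", "n1"]) / max(stats$sd[["m1"]], 1e-12),
                    1)
    kappa_grid <- .root_grid(span)
  }
  g <- kappa_grid - Ffun(kappa_grid)
  roots <- kappa_grid[g == 0]
  sw <- which(g[-1] * g[-length(g)] < 0)
  for (k in sw) {
    r <- stats::uniroot(function(x) x - Ffun(x),
                        c(kappa_grid[k], kappa_grid[k + 1]), tol = tol)
    roots <- c(roots, r$root)
  }
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > max(tol * 100, 1e-7))]
  h <- max(diff(range(kappa_grid)) * 1e-5, 1e-6)
  slope <- vapply(roots, function(r)
    -1 + (Ffun(r + h) - Ffun(r - h)) / (2 * h), numeric(1))
  structure(data.frame(kappa = roots, slope = slope, stable = slope < 0),
            class = c("fixed_point_set", "data.frame"),
            incomplete = length(roots) == 0)
}

#' Predicted population-averaged firing rate at a rank-1 fixed point
#'
#' On a sampled ensemble, `(1/N) sum_i phi(kappa m_i)`; from statistics, the
#' N -> infinity Gaussian form `<phi(<m> kappa, sigma_m^2 kappa^2)>`.
#'
#' @param kappa collective variable (vectorized).
#' @param x a `vector_ensemble` or a rank-1 `vector_stats`.
#' @param x_off transfer-function offset.
#' @return predicted population rate (rate-model units).
#' @export
predicted_population_rate <- function(kappa, x, x_off = 0) {
  if (inherits(x, "vector_ensemble")) {
    m <- x$m[, 1]
    vapply(kappa, function(k) mean(transfer(k * m, x_off)), numeric(1))
  } else if (inherits(x, "vector_stats")) {
    gaussian_expectation("phi", x$mu[["m1"]] * kappa,
                         (x$sd[["m1"]] * kappa)^2, x_off)
  } else stop("x must be a vector_ensemble or vector_stats")
}

#' Bifurcation scan of the rank-1 fixed points
#'
#' Sweeps the overlap `n^T m / N` either through the mean `<n>` (with
#' `sigma_mn = 0`) or through the covariance `sigma_mn` (zero means). At each
#' sweep value the self-consistency function is evaluated by Monte-Carlo
#' integration: `F(kappa)` is averaged over `n_realizations` sampled vector
#' pairs `(m, n)` at size `N`, the equation `kappa = F(kappa)` is solved, and
#' branches are classified against the threshold `kappa_thr`: `|kappa| <=
#' kappa_thr` is the zero/low branch, larger roots are labelled by sign.
#' Predicted population rates are computed per branch as
#' `(1/N) sum_i phi(kappa m_i)` averaged over the same realizations.
#'
#' @param stats_template a rank-1 [vector_stats()] providing the fixed
#'   statistics (sd_m, sd_n, mean_m, ...).
#' @param sweep `"mean_n"` or `"cov_mn"`.
#' @param values sweep values (sorted increasing).
#' @param n_realizations vector-pair realizations per value.
#' @param N ensemble size per realization.
#' @param x_off transfer-function offset.
#' @param kappa_thr branch-classification threshold; default: half the
#'   smallest nonzero-root magnitude found at the largest sweep value.
#' @param seed master seed.
#' @return an object of class `bifurcation_diagram`: data frame with columns
#'   `value`, `overlap`, `branch` (`"zero"`, `"pos"`, `"neg"`), `kappa`,
#'   `rate`, `stable`; attributes `sweep`, `kappa_thr`, `n_realizations`.
#' @export
scan_bifurcation <- function(stats_template, sweep = c("mean_n", "cov_mn"),
                             values, n_realizations = 50, N = 5000,
                             x_off = 0, kappa_thr = NULL, seed = 1) {
  sweep <- match.arg(sweep)
  stopifnot(inherits(stats_template, "vector_stats"),
            stats_template$rank == 1, !is.unsorted(values))
  seeds <- spawn_seeds(seed, length(values))

  solve_at <- function(value, sub_seed) {
    st <- stats_template
    stats <- if (sweep == "mean_n")
      vector_stats(rank = 1, n_in = st$n_in,
                   mean_m = st$mu[["m1"]], mean_n = value,
                   sd_m = st$sd[["m1"]], sd_n = st$sd[["n1"]],
                   cov = c("m.n" = 0))
    else
      vector_stats(rank = 1, n_in = st$n_in,
                   mean_m = 0, mean_n = 0,
                   sd_m = st$sd[["m1"]], sd_n = st$sd[["n1"]],
                   cov = c("m.n" = value))
    rseeds <- spawn_seeds(sub_seed, n_realizations)
    enss <- lapply(rseeds, function(s) sample_vectors(stats, N, s))
    Femp <- function(k)
      rowMeans(matrix(vapply(enss, function(e)
        F_rank1_empirical(k, 0, e, x_off), numeric(length(k))),
        nrow = length(k)))
    span <- 5 * max(stats$sd[["n1"]], 2 * abs(stats$mu[["n1"]]),
                    abs(stats$Sigma["m1", "n1"]) / max(stats$sd[["m1"]], 1e-12),
                    1)
    fps <- solve_fixed_points_rank1(Femp, kappa_grid = .root_grid(span))
    rate <- vapply(fps$kappa, function(k)
      mean(vapply(enss, function(e) mean(transfer(k * e$m[, 1], x_off)),
                  numeric(1))), numeric(1))
    overlap <- if (sweep == "mean_n") value * stats_template$mu[["m1"]]
               else value
    data.frame(value = value, overlap = overlap, kappa = fps$kappa,
               rate = rate, stable = fps$stable)
  }

  rows <- do.call(rbind, Map(solve_at, values, seeds))
  if (is.null(kappa_thr)) {
    # half the smallest clearly-nonzero root at the strongest feedback;
    # roots below 1% of the largest magnitude are the zero root under
    # Monte-Carlo jitter, not a separate branch
    last <- rows[rows$value == max(values), ]
    floor_ <- 0.01 * max(abs(last$kappa), 1e-12)
    nz <- abs(last$kappa)[abs(last$kappa) > floor_]
    kappa_thr <- if (length(nz)) min(nz) / 2 else 0.5
  }
  rows$branch <- ifelse(abs(rows$kappa) <= kappa_thr, "zero",
                        ifelse(rows$kappa > 0, "pos", "neg"))
  structure(rows, sweep = sweep, kappa_thr = kappa_thr,
            n_realizations = n_realizations, N = N,
            class = c("bifurcation_diagram", "data.frame"))
}
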