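#' Sparse excitatory-inhibitory connectivity specification
#'
#' Fixed in-degree random E-I connectivity: every neuron receives exactly `C`
#' synapses, of which a fraction `f_exc` are excitatory with strength `J` (mV)
#' and the rest inhibitory with strength `-g J`. Excitatory presynaptic
#' partners are drawn from the excitatory subpopulation, which occupies the
#' first `f_exc * N` indices; inhibitory partners from the remainder.
#'
#' @param N number of neurons.
#' @param C in-degree (connections received per neuron), `C <= N`.
#' @param f_exc fraction of incoming connections that are excitatory.
#' @param J excitatory synaptic strength (mV).
#' @param g relative inhibition strength (inhibitory strength is `-g J`).
#' @return an object of class `ei_spec`.
#' @export
#' @examples
#' ei_spec(N = 12500, C = 1250)  # density C/N = 0.1, 1000 E + 250 I inputs
ei_spec <- function(N, C, f_exc = 0.8, J = 0.1, g = 5) {
  stopifnot(N >= 1, C >= 0, C <= N, f_exc >= 0, f_exc <= 1)
  CE <- f_exc * C
  if (abs(CE - round(CE)) > 1e-9)
    stop("f_exc * C = ", CE, " is not an integer; choose a compatible split")
  NE <- round(f_exc * N)
  structure(list(N = N, C = C, CE = as.integer(round(CE)),
                 CI = as.integer(C - round(CE)), NE = NE, NI = N - NE,
                 f_exc = f_exc, J = J, g = g),
            class = "ei_spec")
}

#' Sample a sparse E-I connectivity matrix
#'
#' Row i of the result holds the incoming synapses of neuron i: exactly
#' `f_exc * C` entries equal to `+J` at excitatory columns and `(1-f_exc) * C`
#' entries equal to `-g J` at inhibitory columns, partners drawn without
#' replacement and excluding self-connections. The nonzero density is exactly
#' `C / N` (up to the excluded diagonal).
#'
#' @param spec an [ei_spec()].
#' @param seed integer seed.
#' @return a sparse `dgCMatrix` (entries in mV).
#' @export
sample_ei_matrix <- function(spec, seed) {
  stopifnot(inherits(spec, "ei_spec"))
  N <- spec$N; CE <- spec$CE; CI <- spec$CI; NE <- spec$NE
  if (spec$J == 0 || spec$C == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(N, N)))
  if (CE > max(NE - 1, 0) || CI > max(spec$NI - 1, 0))
    stop("in-degree exceeds available presynaptic pool ",
         "(CE = ", CE, ", NE = ", NE, "; CI = ", CI, ", NI = ", spec$NI, ")")

  cols <- with_seed(seed, {
    out <- integer(N * (CE + CI))
    pos <- 0L
    for (i in seq_len(N)) {
      # sample from pool minus self: draw from pool size - 1, shift past i
      if (CE > 0) {
        if (i <= NE) {
          e <- sample.int(NE - 1L, CE)
          e <- e + (e >= i)
        } else e <- sample.int(NE, CE)
        out[pos + seq_len(CE)] <- e
        pos <- pos + CE
      }
      if (CI > 0) {
        if (i > NE) {
          h <- sample.int(spec$NI - 1L, CI)
          h <- h + (h >= (i - NE))
        } else h <- sample.int(spec$NI, CI)
        out[pos + seq_len(CI)] <- h + NE
        pos <- pos + CI
      }
    }
    out
  })
  rows <- rep(seq_len(N), each = CE + CI)
  vals <- rep(c(rep(spec$J, CE), rep(-spec$g * spec$J, CI)), N)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N))
}

#' Compose sparse E-I and low-rank connectivity
#'
#' The effective connectivity is `J = J_EI + P`. With `dale_sparsify = FALSE`
#' the low-rank part is kept factored and applied in O(N R) form during
#' simulation. With `dale_sparsify = TRUE`, entries of `P` at zero positions
#' of `J_EI` are set to zero, the masked sum is stored sparsely, and the
#' column-sign (Dale) property of the sum is verified: violations (possible
#' when `|P_ij| > |J_EI_ij|`) produce a warning with a count, not an error.
#'
#' @param ei sparse E-I matrix (`dgCMatrix`) or `NULL` for none.
#' @param lowrank a [lowrank_matrix()] or `NULL` for none.
#' @param dale_sparsify logical; mask `P` onto the sparsity pattern of `ei`.
#' @param ei_spec optional [ei_spec()] used to determine the E/I column split
#'   for the Dale check (defaults to sign of the dominant entry per column).
#' @return an object of class `connectivity_bundle` with fields `ei`,
#'   `lowrank`, `full_sparse` (masked sum, or `NULL`), `dale_enforced`,
#'   `dale_violations`, `N`.
#' @export
compose_connectivity <- function(ei, lowrank, dale_sparsify = FALSE,
                                 ei_spec = NULL) {
  if (is.null(ei) && is.null(lowrank))
    stop("at least one of `ei`, `lowrank` must be given")
  N <- if (!is.null(ei)) nrow(ei) else lowrank$N
  if (!is.null(ei) && !is.null(lowrank) && lowrank$N != N)
    stop("shape mismatch: ei is ", nrow(ei), "x", ncol(ei),
         " but lowrank has N = ", lowrank$N)

  full_sparse <- NULL
  violations <- NA_integer_
  if (dale_sparsify) {
    if (is.null(ei) || is.null(lowrank))
      stop("dale_sparsify requires both `ei` and `lowrank`")
    trip <- Matrix::mat2triplet(ei)
    pvals <- rowSums(lowrank$m[trip$i, , drop = FALSE] *
                     lowrank$n[trip$j, , drop = FALSE]) / N
    full_sparse <- Matrix::sparseMatrix(i = trip$i, j = trip$j,
                                        x = trip$x + pvals, dims = c(N, N))
    if (!is.null(ei_spec)) {
      col_sign <- rep(c(1, -1), c(ei_spec$NE, ei_spec$NI))
    } else {
      col_sign <- rep(NA_real_, N)
      first <- !duplicated(trip$j)
      col_sign[trip$j[first]] <- sign(trip$x[first])
    }
    ft <- Matrix::mat2triplet(full_sparse)
    violations <- sum(ft$x * col_sign[ft$j] < 0, na.rm = TRUE)
    if (violations > 0)
      warning("Dale's law violated at ", violations,
              " entries after sparsification")
  }
  structure(list(ei = ei,
                 lowrank = if (dale_sparsify) NULL else lowrank,
                 lowrank_raw = lowrank,
                 full_sparse = full_sparse,
                 dale_enforced = dale_sparsify,
                 dale_violations = violations, N = N),
            class = "connectivity_bundle")
}

#' Effective connectivity applied to a vector
#'
#' Computes `(J_EI + P) %*% x` through the bundle's preferred representation:
#' masked sparse matrix when Dale sparsification was requested, otherwise
#' sparse E-I product plus factored low-rank product.
#'
#' @param conn a `connectivity_bundle`.
#' @param x numeric vector of length N.
#' @return numeric vector `J %*% x`.
#' @export
conn_matvec <- function(conn, x) {
  stopifnot(inherits(conn, "connectivity_bundle"))
  if (!is.null(conn$full_sparse)) return(as.numeric(conn$full_sparse %*% x))
  out <- numeric(conn$N)
  if (!is.null(conn$ei)) out <- out + as.numeric(conn$ei %*% x)
  if (!is.null(conn$lowrank)) out <- out + as.numeric(lr_matvec(conn$lowrank, x))
  out
}

#' @export
print.connectivity_bundle <- function(x, ...) {
  cat("connectivity_bundle: N =", x$N,
      if (!is.null(x$ei)) "| sparse E-I" else "",
      if (!is.null(x$lowrank) || !is.null(x$full_sparse)) "| low-rank" else "",
      if (x$dale_enforced) paste0("| Dale-sparsified (", x$dale_violations,
                                  " sign violations)") else "", "\n")
  invisible(x)
}
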