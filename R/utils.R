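#' Run code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the previous RNG
#' state, so that seeded sampling never perturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive independent sub-seeds from a master seed
#'
#' One master seed spawns a fixed number of named substreams (vectors, E-I
#' topology, noise, stimulus, ...) so that changing the realization of one
#' component leaves the others untouched.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds, or a character vector of stream names.
#' @return integer vector of sub-seeds (named if `n` was named).
#' @export
#' @examples
#' spawn_seeds(1, c("vectors", "topology", "noise"))
spawn_seeds <- function(master, n) {
  nms <- NULL
  if (is.character(n)) { nms <- n; n <- length(n) }
  s <- with_seed(master, sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(nms)) names(s) <- nms
  s
}

# unit-normalized cosine between two vectors
cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Alignment of a vector with a linear subspace
#'
#' Returns the cosine of the angle between `v` and its orthogonal projection
#' onto the column span of `basis`, i.e. the fraction of the norm of `v` lying
#' in the subspace. Equals 1 when `v` is in the span, 0 when orthogonal.
#'
#' @param v numeric vector.
#' @param basis matrix whose columns span the subspace.
#' @return scalar in [0, 1].
#' @export
subspace_alignment <- function(v, basis) {
  basis <- as.matrix(basis)
  stopifnot(length(v) == nrow(basis))
  q <- qr.Q(qr(basis))
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(NA_real_)
  sqrt(sum((crossprod(q, v))^2)) / nv
}
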