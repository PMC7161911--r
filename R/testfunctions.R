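# Analytic test functions with known Sobol decompositions, used as oracles
# for the sensitivity estimators, plus a generator of synthetic parameter
# observations for the distribution-fitting recovery tests.

#' Ishigami test function
#'
#' `f(x) = sin(x1) + a sin^2(x2) + b x3^4 sin(x1)` on `[-pi, pi]^3`;
#' the standard benchmark with closed-form Sobol indices (see
#' [ishigami_indices()]).
#'
#' @param x Numeric matrix (rows = points, 3 columns) or length-3 vector,
#'   each coordinate in `[-pi, pi]`.
#' @param a,b Shape constants (default 7, 0.1).
#' @return Numeric vector of function values.
#' @export
ishigami <- function(x, a = 7, b = 0.1) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == 3)
  sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1])
}

#' Closed-form Sobol indices of the Ishigami function
#'
#' With x_i iid uniform on `[-pi, pi]`:
#' `V1 = (1 + b pi^4 / 5)^2 / 2`, `V2 = a^2 / 8`, `V3 = 0`,
#' `V13 = 8 b^2 pi^8 / 225`, and
#' `V = 1/2 + a^2/8 + b pi^4/5 + b^2 pi^8/18`.
#'
#' @inheritParams ishigami
#' @return List with `S` (first-order, length 3), `ST` (total-order) and the
#'   total variance `V`.
#' @export
ishigami_indices <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- 0.5 + a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18
  list(S = c(V1, V2, 0) / V,
       ST = c(V1 + V13, V2, V13) / V,
       V = V)
}

#' Additive linear test function and its exact indices
#'
#' `f(x) = sum(a_i x_i)` for x iid uniform on the unit cube; first-order
#' indices are `a_i^2 / sum(a^2)` and equal the total-order indices.
#'
#' @param x Matrix (rows = points) or vector in the unit cube.
#' @param a Coefficient vector.
#' @return Function values; `linear_additive_indices()` returns the exact
#'   first-order index vector.
#' @export
linear_additive <- function(x, a) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(a)) stop("dimension mismatch")
  drop(x %*% a)
}

#' @rdname linear_additive
#' @export
linear_additive_indices <- function(a) a^2 / sum(a^2)

#' Sobol g-function and its exact first-order indices
#'
#' `f(x) = prod((|4 x_i - 2| + a_i) / (1 + a_i))` on the unit cube; the
#' partial variance of factor i is `v_i = 1 / (3 (1 + a_i)^2)` and the total
#' variance `prod(1 + v_i) - 1`. Large `a_i` make a factor inert.
#'
#' @param x Matrix (rows = points) or vector in the unit cube.
#' @param a Non-negative coefficient vector.
#' @return Function values; `g_function_indices()` returns the exact
#'   first-order index vector.
#' @export
g_function <- function(x, a) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(a)) stop("dimension mismatch")
  apply(x, 1, function(r) prod((abs(4 * r - 2) + a) / (1 + a)))
}

#' @rdname g_function
#' @export
g_function_indices <- function(a) {
  v <- 1 / (3 * (1 + a)^2)
  V <- prod(1 + v) - 1
  v / V
}

#' Generate synthetic observations of a crop parameter
#'
#' Draws from the untruncated family of a [dist_spec()] — a stand-in for
#' literature observations — for distribution-fitting recovery tests.
#'
#' @param spec A [dist_spec()].
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_gsp_observations <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  spec2 <- spec
  spec2$truncation <- NULL
  d <- make_distribution(spec2)
  dist_sample(d, n, seed = seed)
}
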