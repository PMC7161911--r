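# Morris-type elementary-effects screening with enhanced sampling
# uniformity: oversampled trajectory pool, greedy max-min spread selection,
# effects statistics, cross-treatment normalization, importance selection.

#' Build an elementary-effects screening design
#'
#' Generates `pool_size` random Morris trajectories on a `levels`-point grid
#' in the unit hypercube with step `delta = levels / (2 * (levels - 1))`,
#' then greedily keeps the `r` trajectories that maximise the minimum
#' pairwise inter-trajectory distance (the uniformity enhancement). Each
#' trajectory perturbs every parameter exactly once, one coordinate per
#' step, so the design has `r * (k + 1)` rows.
#'
#' @param k Number of parameters (>= 1).
#' @param levels Number of grid levels (even).
#' @param r Number of trajectories kept.
#' @param pool_size Candidate pool size (default 500; >= r).
#' @param seed Integer seed.
#' @return Object of class `esu_design`: list with `points` (matrix
#'   `r*(k+1) x k`), `trajectory` and `changed` (0 for each trajectory's
#'   base row) per row, and `k`, `levels`, `r`, `delta`.
#' @export
build_esu_design <- function(k, levels = 8, r = 24, pool_size = 500,
                             seed = 1L) {
  k <- as.integer(unname(k))
  levels <- as.integer(unname(levels))
  r <- as.integer(unname(r))
  if (k < 1) stop("k must be >= 1")
  if (r > pool_size) stop("r must not exceed pool_size")
  if (levels %% 2 != 0) stop("levels must be even")
  if (r %% levels != 0)
    warning("number of trajectories is recommended to be a multiple of ",
            "the number of levels")
  delta <- levels / (2 * (levels - 1))
  grid <- (seq_len(levels) - 1) / (levels - 1)
  pool <- with_seed(seed, lapply(seq_len(pool_size), function(...)
    random_trajectory(k, grid, delta)))
  keep <- if (pool_size > r) select_spread(pool, r) else seq_len(r)
  pts <- do.call(rbind, lapply(pool[keep], `[[`, "points"))
  changed <- unlist(lapply(pool[keep], `[[`, "changed"))
  structure(list(points = pts,
                 trajectory = rep(seq_len(r), each = k + 1),
                 changed = changed, k = k, levels = levels, r = r,
                 delta = delta),
            class = "esu_design")
}

# one random Morris trajectory: base point on the sub-grid from which a
# +/- delta step stays inside [0, 1]; parameters perturbed in random order
random_trajectory <- function(k, grid, delta) {
  dir <- sample(c(-1, 1), k, replace = TRUE)
  x0 <- vapply(dir, function(d) {
    ok <- grid[grid + d * delta >= -1e-12 & grid + d * delta <= 1 + 1e-12]
    ok[sample.int(length(ok), 1)]
  }, numeric(1))
  ord <- sample.int(k)
  pts <- matrix(0, k + 1, k)
  pts[1, ] <- x0
  x <- x0
  for (j in seq_len(k)) {
    x[ord[j]] <- x[ord[j]] + dir[ord[j]] * delta
    pts[j + 1, ] <- x
  }
  pts <- pmin(pmax(pts, 0), 1)           # scrub float fuzz at the borders
  list(points = pts, changed = c(0L, ord))
}

# Campolongo-style spread: trajectory distance = sum of all pairwise
# point-to-point Euclidean distances; greedy farthest-point selection of r
# trajectories maximising the minimum distance to the chosen set. Distances
# from one trajectory to the whole pool are computed in a single matrix
# operation.
traj_distance <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * A %*% t(B)
  sum(sqrt(pmax(d2, 0)))
}

select_spread <- function(pool, r) {
  n <- length(pool)
  pts <- lapply(pool, `[[`, "points")
  m <- nrow(pts[[1]])                     # k + 1 points per trajectory
  P <- do.call(rbind, pts)                # all pool points, stacked
  p2 <- rowSums(P^2)
  grp <- rep(seq_len(n), each = m)
  dist_to_all <- function(i) {            # trajectory i vs whole pool
    A <- pts[[i]]
    d2 <- outer(rowSums(A^2), p2, `+`) - 2 * A %*% t(P)
    as.numeric(rowsum(colSums(sqrt(pmax(d2, 0))), grp))
  }
  # seed with the trajectory farthest from the pool centroid
  ctr <- Reduce(`+`, pts) / n
  d0 <- vapply(pts, function(p) sum((p - ctr)^2), numeric(1))
  sel <- which.max(d0)
  mind <- dist_to_all(sel)
  mind[sel] <- -Inf
  while (length(sel) < r) {
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, dist_to_all(nxt))
    mind[nxt] <- -Inf
  }
  sel
}

#' Map unit-hypercube design points to parameter values
#'
#' Column-wise inverse-cdf transform of the design coordinates through the
#' per-parameter truncated distributions; integer-flagged parameters
#' (branches per fork) are rounded to the nearest whole number.
#'
#' @param design An `esu_design` or `sobol_design` (or a bare matrix in
#'   \[0,1\]).
#' @param dists Named list of `trunc_dist`, one per column (e.g.
#'   [gsp_distributions()]).
#' @param integer Logical vector marking columns rounded to integers
#'   (default: the `integer` attribute of `dists`, else none).
#' @return Numeric matrix of parameter values, columns named after `dists`.
#' @export
map_to_parameters <- function(design, dists, integer = NULL) {
  pts <- if (is.matrix(design)) design else design$points
  if (ncol(pts) != length(dists))
    stop("design has ", ncol(pts), " columns but ", length(dists),
         " distributions were supplied")
  integer <- integer %||% attr(dists, "integer") %||%
    rep(FALSE, length(dists))
  out <- matrix(0, nrow(pts), length(dists),
                dimnames = list(NULL, names(dists)))
  for (j in seq_along(dists)) {
    v <- dists[[j]]$quantile(pts[, j])
    out[, j] <- if (integer[j]) pmin(pmax(round(v), 1), 4) else v
  }
  out
}

#' Elementary effects from a screening design
#'
#' For each trajectory and each parameter, the elementary effect is the
#' output change across the step that perturbed that parameter, divided by
#' the signed step (so a linear model `f = 3 x1 + x2` yields effects exactly
#' 3 and 1). Per parameter: `mu` is the signed mean over trajectories,
#' `mu_star` the mean absolute value, `sigma` the standard deviation.
#'
#' @param design An `esu_design`.
#' @param y Numeric outputs, one per design row (finite).
#' @param params Optional parameter names (length k).
#' @return Object of class `elementary_effects`: list with matrices `ee`
#'   (r x k) and per-parameter `mu`, `mu_star`, `sigma`.
#' @export
elementary_effects <- function(design, y, params = NULL) {
  stopifnot(inherits(design, "esu_design"))
  if (length(y) != nrow(design$points))
    stop("y must have one value per design row")
  if (any(!is.finite(y))) stop("non-finite outputs")
  k <- design$k; r <- design$r
  ee <- matrix(NA_real_, r, k)
  for (t in seq_len(r)) {
    rows <- which(design$trajectory == t)
    for (j in seq_len(k)) {
      at <- rows[which(design$changed[rows] == j)]
      step <- design$points[at, j] - design$points[at - 1, j]
      ee[t, j] <- (y[at] - y[at - 1]) / step
    }
  }
  if (!is.null(params)) colnames(ee) <- params
  mu <- colMeans(ee)
  structure(list(ee = ee, mu = mu,
                 mu_star = colMeans(abs(ee)),
                 sigma = apply(ee, 2, sd)),
            class = "elementary_effects")
}

#' Normalize elementary effects across treatments
#'
#' For each output variable, `mu_star` values are divided by the maximum
#' `mu_star` over all parameters and all treatments, and `sigma` likewise by
#' the maximum `sigma`, so the largest normalized value per output is 1.
#'
#' @param effects Nested list: `effects[[treatment]][[output]]` is an
#'   [elementary_effects()] object (all with the same parameter count).
#' @return Data frame with columns `treatment`, `output`, `parameter`,
#'   `mu`, `mu_star`, `sigma`, `mu_star_norm`, `sigma_norm`.
#' @export
normalize_effects <- function(effects) {
  stopifnot(length(effects) >= 1)
  treatments <- names(effects) %||% as.character(seq_along(effects))
  outputs <- names(effects[[1]]) %||%
    as.character(seq_along(effects[[1]]))
  rows <- list()
  for (o in outputs) {
    mu_max <- max(vapply(effects, function(tr) max(tr[[o]]$mu_star),
                         numeric(1)))
    sd_max <- max(vapply(effects, function(tr) max(tr[[o]]$sigma),
                         numeric(1)))
    if (mu_max == 0 && sd_max == 0)
      warning("all elementary effects are zero for output ", o)
    for (tt in treatments) {
      e <- effects[[tt]][[o]]
      par <- names(e$mu_star) %||% paste0("x", seq_along(e$mu_star))
      rows[[length(rows) + 1]] <- data.frame(
        treatment = tt, output = o, parameter = par,
        mu = unname(e$mu), mu_star = unname(e$mu_star),
        sigma = unname(e$sigma),
        mu_star_norm = if (mu_max > 0) unname(e$mu_star) / mu_max else 0,
        sigma_norm = if (sd_max > 0) unname(e$sigma) / sd_max else 0)
    }
  }
  do.call(rbind, rows)
}

#' Select important parameters from normalized effects
#'
#' A parameter is selected iff its normalized `mu_star` or normalized
#' `sigma` is strictly greater than the threshold for at least one output
#' variable in at least one group (location or treatment).
#'
#' @param normalized Data frame from [normalize_effects()].
#' @param threshold Selection threshold (default 0.5, strict `>`).
#' @return Character vector of selected parameter names.
#' @export
select_important <- function(normalized, threshold = 0.5) {
  hit <- normalized$mu_star_norm > threshold |
    normalized$sigma_norm > threshold
  pars <- unique(normalized$parameter)
  pars[pars %in% unique(normalized$parameter[hit])]
}
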