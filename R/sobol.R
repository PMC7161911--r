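# Sobol variance-based sensitivity analysis: Saltelli radial designs,
# first-order (Saltelli 2010) and total-order (Jansen) index estimators with
# bootstrap confidence intervals, and output uncertainty summaries.

#' Build a Sobol/Saltelli sampling design
#'
#' Two base matrices A and B (`n x k`) are drawn in the unit hypercube and
#' the hybrid matrices `A_B^(i)` (A with column i from B) and `B_A^(i)` are
#' formed for every parameter, giving `2 n (k + 1)` rows in the order
#' `A, B, A_B^(1..k), B_A^(1..k)`. The default sampler is a digitally
#' scrambled Sobol sequence in `2k` dimensions split into A | B (see
#' [sobol_points()]); `"lhs"` gives a randomized Latin hypercube per matrix
#' and `"random"` plain Monte Carlo.
#'
#' @param k Number of parameters (>= 1; at most 16 for the `"sobol"`
#'   sampler).
#' @param n Base sample size (>= 1).
#' @param seed Integer seed.
#' @param method `"sobol"` (default), `"lhs"` or `"random"`.
#' @return Object of class `sobol_design`: list with `points`
#'   (`2n(k+1) x k`), `block` (`"A"`, `"B"`, `"AB"`, `"BA"`), `column`
#'   (swapped column index, `NA` for A/B), `k`, `n`, `method`.
#' @export
build_sobol_design <- function(k, n, seed = 1L,
                               method = c("sobol", "lhs", "random")) {
  stopifnot(k >= 1, n >= 1)
  method <- match.arg(method)
  if (method == "sobol") {
    U <- sobol_points(n, 2 * k, seed = seed)
    A <- U[, seq_len(k), drop = FALSE]
    B <- U[, k + seq_len(k), drop = FALSE]
  } else {
    draw <- function() {
      if (method == "lhs") {
        vapply(seq_len(k), function(j)
          (sample.int(n) - runif(n)) / n, numeric(n))
      } else {
        matrix(runif(n * k), n, k)
      }
    }
    ab <- with_seed(seed, list(A = draw(), B = draw()))
    A <- matrix(ab$A, n, k); B <- matrix(ab$B, n, k)
  }
  AB <- lapply(seq_len(k), function(i) { M <- A; M[, i] <- B[, i]; M })
  BA <- lapply(seq_len(k), function(i) { M <- B; M[, i] <- A[, i]; M })
  pts <- rbind(A, B, do.call(rbind, AB), do.call(rbind, BA))
  structure(list(
    points = pts,
    block = c(rep("A", n), rep("B", n), rep("AB", n * k), rep("BA", n * k)),
    column = c(rep(NA_integer_, 2 * n), rep(seq_len(k), each = n),
               rep(seq_len(k), each = n)),
    k = k, n = n, method = method),
    class = "sobol_design")
}

#' Estimate first- and total-order Sobol indices
#'
#' First-order indices use the Saltelli (2010) estimator
#' `S_i = mean(f(B) * (f(A_B^i) - f(A))) / V`, averaged with its symmetric
#' counterpart on the `B_A` block; total-order indices use the Jansen
#' estimator `ST_i = mean((f(A) - f(A_B^i))^2) / (2 V)`, likewise
#' symmetrised. `V` is the variance of the pooled A and B evaluations.
#' Bootstrap percentile confidence intervals resample base-sample indices.
#'
#' @param design A [build_sobol_design()] object.
#' @param y Outputs for every design row, in design order (finite).
#' @param n_boot Bootstrap replicates (default 200; 0 disables).
#' @param conf Confidence level (default 0.95).
#' @param params Optional parameter names.
#' @return Object of class `sobol_indices`: data frame with `parameter`,
#'   `S_first`, `S_total` and bootstrap bounds, plus attribute `V`.
#' @export
estimate_indices <- function(design, y, n_boot = 200, conf = 0.95,
                             params = NULL) {
  stopifnot(inherits(design, "sobol_design"))
  N <- nrow(design$points)
  if (length(y) != N) stop("y must have one value per design row")
  if (any(!is.finite(y))) stop("non-finite outputs")
  k <- design$k; n <- design$n
  yA <- y[design$block == "A"]
  yB <- y[design$block == "B"]
  yAB <- matrix(y[design$block == "AB"], n, k)
  yBA <- matrix(y[design$block == "BA"], n, k)

  calc <- function(idx) {
    a <- yA[idx]; b <- yB[idx]
    V <- var(c(a, b))
    if (V <= 0) return(list(S = rep(0, k), ST = rep(0, k), V = 0))
    S <- ST <- numeric(k)
    for (i in seq_len(k)) {
      ab <- yAB[idx, i]; ba <- yBA[idx, i]
      S[i] <- (mean(b * (ab - a)) + mean(a * (ba - b))) / (2 * V)
      ST[i] <- (mean((a - ab)^2) + mean((b - ba)^2)) / (4 * V)
    }
    list(S = S, ST = ST, V = V)
  }
  est <- calc(seq_len(n))
  if (est$V == 0) warning("zero output variance; all indices set to 0")

  lo <- hi <- tlo <- thi <- rep(NA_real_, k)
  if (n_boot > 0 && est$V > 0) {
    bs <- with_seed(1L, replicate(n_boot, {
      r <- calc(sample.int(n, replace = TRUE))
      c(r$S, r$ST)
    }))
    q <- apply(bs, 1, quantile, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
    lo <- q[1, seq_len(k)];     hi <- q[2, seq_len(k)]
    tlo <- q[1, k + seq_len(k)]; thi <- q[2, k + seq_len(k)]
  }
  out <- data.frame(
    parameter = params %||% paste0("x", seq_len(k)),
    S_first = est$S, S_first_lo = lo, S_first_hi = hi,
    S_total = est$ST, S_total_lo = tlo, S_total_hi = thi)
  attr(out, "V") <- est$V
  class(out) <- c("sobol_indices", class(out))
  out
}

#' Uncertainty summary of simulated outputs
#'
#' Per parameter sample the across-year mean is formed first; the summary
#' reports mean, standard deviation and coefficient of variation (%) of
#' those means across samples, the empirical CDF over samples, and a
#' confidence band from the year-to-year variation (percentiles of the
#' pooled single-year values).
#'
#' @param outputs Numeric matrix, samples x years (a vector is treated as a
#'   single year).
#' @param conf Level of the year-variation band (default 0.95).
#' @return List with `mean`, `sd`, `cv` (percent, `NA` if the mean is 0),
#'   `cdf` (data frame `value`, `probability`), and `ci` (the
#'   year-variation percentile band).
#' @export
uncertainty_summary <- function(outputs, conf = 0.95) {
  m <- as.matrix(outputs)
  if (nrow(m) < 1) stop("no samples")
  means <- rowMeans(m)
  mu <- mean(means); s <- sd(means)
  if (length(means) == 1) s <- 0
  v <- sort(means)
  cdf <- data.frame(value = v,
                    probability = seq_along(v) / length(v))
  a <- (1 - conf) / 2
  list(mean = mu, sd = s,
       cv = if (mu != 0) 100 * s / mu else NA_real_,
       cdf = cdf,
       ci = quantile(as.numeric(m), probs = c(a, 1 - a), names = FALSE))
}

#' Compare screening and variance-based importance measures
#'
#' Ordinary least squares of the elementary-effects statistic on the total
#' Sobol index, reporting slope, intercept and R-squared.
#'
#' @param mu_star Elementary-effects means (per parameter).
#' @param s_total Total-order Sobol indices (same length, >= 3 points).
#' @return List `slope`, `intercept`, `r_squared`.
#' @export
compare_methods <- function(mu_star, s_total) {
  if (length(mu_star) != length(s_total)) stop("length mismatch")
  if (length(mu_star) < 3) stop("need at least 3 points")
  if (any(!is.finite(mu_star)) || any(!is.finite(s_total)))
    stop("non-finite inputs")
  fit <- lm(mu_star ~ s_total)
  # collinear inputs are legitimate here (R^2 = 1), silence lm's caution
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}
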