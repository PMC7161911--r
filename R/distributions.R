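# Parametric distributions for genotype-specific parameters (GSPs):
# specification, truncation, sampling, and maximum-likelihood fitting with
# Kolmogorov-Smirnov / AIC model selection.

DIST_FAMILIES <- c("uniform", "triangular", "normal", "lognormal",
                   "gamma", "weibull")

# family -> required parameter names
family_params <- function(family) {
  switch(family,
    uniform    = c("min", "max"),
    triangular = c("min", "max", "mode"),
    normal     = c("mean", "sd"),
    lognormal  = c("meanlog", "sdlog"),
    gamma      = c("shape", "scale"),
    weibull    = c("shape", "scale"),
    stop("unknown distribution family: ", family)
  )
}

#' Specify a parametric distribution for a crop parameter
#'
#' A `dist_spec` names one of six supported families together with its
#' parameters and an optional truncation rule. Parameter names by family:
#' uniform `min`,`max`; triangular `min`,`max`,`mode`; normal `mean`,`sd`;
#' lognormal `meanlog`,`sdlog`; gamma `shape`,`scale`; weibull
#' `shape`,`scale`.
#'
#' @param family One of `"uniform"`, `"triangular"`, `"normal"`,
#'   `"lognormal"`, `"gamma"`, `"weibull"`.
#' @param ... Named family parameters (see Details).
#' @param truncation Optional [truncation_rule()].
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("uniform", min = 0.7, max = 1.3)
#' dist_spec("weibull", shape = 4.183, scale = 1015.34,
#'           truncation = truncation_rule("value", 100, "probability", 0.9))
#' @export
dist_spec <- function(family, ..., truncation = NULL) {
  family <- match.arg(family, DIST_FAMILIES)
  params <- list(...)
  need <- family_params(family)
  if (!setequal(names(params), need)) {
    stop(sprintf("family '%s' requires parameters: %s", family,
                 paste(need, collapse = ", ")))
  }
  params <- lapply(params[need], as.numeric)
  with(params, switch(family,
    uniform = if (min >= max) stop("uniform requires min < max"),
    triangular = {
      if (min >= max) stop("triangular requires min < max")
      if (mode < min || mode > max)
        stop("triangular requires min <= mode <= max")
    },
    normal = if (sd <= 0) stop("normal requires sd > 0"),
    lognormal = if (sdlog <= 0) stop("lognormal requires sdlog > 0"),
    gamma = if (shape <= 0 || scale <= 0)
      stop("gamma requires shape, scale > 0"),
    weibull = if (shape <= 0 || scale <= 0)
      stop("weibull requires shape, scale > 0")
  ))
  if (!is.null(truncation) && !inherits(truncation, "truncation_rule"))
    stop("truncation must be a truncation_rule()")
  structure(list(family = family, params = params, truncation = truncation),
            class = "dist_spec")
}

#' Truncation rule for a distribution
#'
#' Each bound is given either as a `"value"` (a point on the parameter scale)
#' or a `"probability"` (a quantile level of the untruncated distribution);
#' the two kinds may be mixed, e.g. a left truncation at the value 100 with a
#' right truncation at the 0.9 probability level.
#'
#' @param left_kind,right_kind `"value"` or `"probability"`.
#' @param left,right The bound (value or probability level).
#' @return An object of class `truncation_rule`.
#' @export
truncation_rule <- function(left_kind = c("probability", "value"), left,
                            right_kind = c("probability", "value"), right) {
  left_kind <- match.arg(left_kind)
  right_kind <- match.arg(right_kind)
  if (left_kind == "probability" && (left <= 0 || left >= 1))
    stop("probability truncation bounds must lie in (0, 1)")
  if (right_kind == "probability" && (right <= 0 || right >= 1))
    stop("probability truncation bounds must lie in (0, 1)")
  structure(list(left_kind = left_kind, left = as.numeric(left),
                 right_kind = right_kind, right = as.numeric(right)),
            class = "truncation_rule")
}

# Untruncated d/p/q closures for a spec. Triangular has no stats:: analogue
# and is written out in closed form.
base_funs <- function(spec) {
  p <- spec$params
  switch(spec$family,
    uniform = list(
      d = function(x) dunif(x, p$min, p$max),
      p = function(q) punif(q, p$min, p$max),
      q = function(pr) qunif(pr, p$min, p$max),
      support = c(p$min, p$max), npar = 2L),
    triangular = list(
      d = function(x) dtri(x, p$min, p$max, p$mode),
      p = function(q) ptri(q, p$min, p$max, p$mode),
      q = function(pr) qtri(pr, p$min, p$max, p$mode),
      support = c(p$min, p$max), npar = 3L),
    normal = list(
      d = function(x) dnorm(x, p$mean, p$sd),
      p = function(q) pnorm(q, p$mean, p$sd),
      q = function(pr) qnorm(pr, p$mean, p$sd),
      support = c(-Inf, Inf), npar = 2L),
    lognormal = list(
      d = function(x) dlnorm(x, p$meanlog, p$sdlog),
      p = function(q) plnorm(q, p$meanlog, p$sdlog),
      q = function(pr) qlnorm(pr, p$meanlog, p$sdlog),
      support = c(0, Inf), npar = 2L),
    gamma = list(
      d = function(x) dgamma(x, shape = p$shape, scale = p$scale),
      p = function(q) pgamma(q, shape = p$shape, scale = p$scale),
      q = function(pr) qgamma(pr, shape = p$shape, scale = p$scale),
      support = c(0, Inf), npar = 2L),
    weibull = list(
      d = function(x) dweibull(x, shape = p$shape, scale = p$scale),
      p = function(q) pweibull(q, shape = p$shape, scale = p$scale),
      q = function(pr) qweibull(pr, shape = p$shape, scale = p$scale),
      support = c(0, Inf), npar = 2L)
  )
}

# Triangular distribution on [a, b] with mode c.
dtri <- function(x, a, b, c) {
  out <- numeric(length(x))
  i <- x >= a & x <= c & c > a
  out[i] <- 2 * (x[i] - a) / ((b - a) * (c - a))
  j <- x > c & x <= b
  out[j] <- 2 * (b - x[j]) / ((b - a) * (b - c))
  if (c == a) out[x == a] <- 2 / (b - a)
  out
}

ptri <- function(q, a, b, c) {
  out <- numeric(length(q))
  out[q >= b] <- 1
  i <- q > a & q <= c
  out[i] <- (q[i] - a)^2 / ((b - a) * (c - a))
  j <- q > c & q < b
  out[j] <- 1 - (b - q[j])^2 / ((b - a) * (b - c))
  out
}

qtri <- function(p, a, b, c) {
  pc <- (c - a) / (b - a)
  ifelse(p <= pc,
         a + sqrt(p * (b - a) * (c - a)),
         b - sqrt((1 - p) * (b - a) * (b - c)))
}

#' Build a (possibly truncated) distribution object
#'
#' Resolves the truncation rule of a [dist_spec()] to concrete support
#' endpoints and returns an object exposing the truncated cdf, pdf, quantile
#' function and sampler. Probability-kind truncation bounds are quantiles of
#' the untruncated distribution; value-kind bounds are used as-is. Without a
#' rule the distribution is untruncated.
#'
#' @param spec A [dist_spec()].
#' @return An object of class `trunc_dist` with elements `spec`, `support`
#'   (length-2 numeric) and internal cdf/pdf/quantile closures. Use
#'   [dist_cdf()], [dist_pdf()], [quantile()][quantile.trunc_dist] and
#'   [dist_sample()] on it.
#' @examples
#' d <- make_distribution(dist_spec("triangular", min = 189, max = 1447,
#'                                  mode = 764))
#' d$support
#' @export
make_distribution <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  bf <- base_funs(spec)
  tr <- spec$truncation
  if (is.null(tr)) {
    lo <- bf$support[1]; hi <- bf$support[2]
    Flo <- 0; Fhi <- 1
  } else {
    lo <- if (tr$left_kind == "probability") bf$q(tr$left) else tr$left
    hi <- if (tr$right_kind == "probability") bf$q(tr$right) else tr$right
    if (lo >= hi) stop("empty truncated support: left bound >= right bound")
    Flo <- bf$p(lo); Fhi <- bf$p(hi)
    if (Fhi - Flo <= 0) stop("empty truncated support: zero probability mass")
  }
  mass <- Fhi - Flo
  structure(list(
    spec = spec,
    support = c(lo, hi),
    cdf = function(x) pmin(1, pmax(0, (bf$p(pmin(pmax(x, lo), hi)) - Flo) / mass)),
    pdf = function(x) ifelse(x < lo | x > hi, 0, bf$d(x) / mass),
    quantile = function(p) {
      q <- bf$q(Flo + p * mass)
      # guard against floating-point overshoot at the endpoints
      pmin(pmax(q, lo), hi)
    }
  ), class = "trunc_dist")
}

#' @export
print.trunc_dist <- function(x, ...) {
  cat(sprintf("<trunc_dist> %s(%s), support [%g, %g]\n", x$spec$family,
              paste(sprintf("%s=%g", names(x$spec$params),
                            unlist(x$spec$params)), collapse = ", "),
              x$support[1], x$support[2]))
  invisible(x)
}

#' Cumulative distribution / density of a truncated distribution
#' @param dist A [make_distribution()] object.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector.
#' @export
dist_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "trunc_dist"))
  dist$cdf(x)
}

#' @rdname dist_cdf
#' @export
dist_pdf <- function(dist, x) {
  stopifnot(inherits(dist, "trunc_dist"))
  dist$pdf(x)
}

#' Quantile function of a truncated distribution
#'
#' Inverse of the truncated cdf over the resolved support, so
#' `quantile(d, 0)` and `quantile(d, 1)` return the support endpoints.
#'
#' @param x A `trunc_dist`.
#' @param probs Probabilities in \[0, 1\].
#' @param ... Ignored.
#' @return Numeric vector of quantiles.
#' @export
quantile.trunc_dist <- function(x, probs, ...) {
  if (any(probs < 0 | probs > 1, na.rm = TRUE))
    stop("probs must lie in [0, 1]")
  x$quantile(probs)
}

#' Draw samples from a truncated distribution
#'
#' Exact rejection-free sampling by inverse-cdf applied to a uniform
#' rescaled into the truncated probability band.
#'
#' @param dist A `trunc_dist`.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer; identical seeds give identical streams and
#'   the caller's RNG state is left untouched.
#' @return Numeric vector of length `n`, all within the support.
#' @export
dist_sample <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "trunc_dist"), n >= 1)
  with_seed(seed, dist$quantile(runif(n)))
}

# ---------------------------------------------------------------------------
# Kolmogorov-Smirnov statistic and asymptotic p-value

#' One-sample Kolmogorov-Smirnov statistic
#'
#' Computes `D = sup |ecdf(x) - F(x)|` by direct evaluation of both one-sided
#' differences at every jump of the empirical cdf, with the p-value from the
#' asymptotic Kolmogorov distribution (no correction for estimated
#' parameters, so p-values against a fitted cdf are approximate).
#'
#' @param obs Numeric observations (n >= 1, finite).
#' @param cdf A vectorised cumulative distribution function.
#' @return List with `statistic` (D), `pvalue` and `n`.
#' @export
ks_statistic <- function(obs, cdf) {
  obs <- as.numeric(obs)
  if (length(obs) == 0) stop("empty observation vector")
  if (any(!is.finite(obs))) stop("observations must be finite")
  n <- length(obs)
  Fx <- cdf(sort(obs))
  D <- max(pmax((seq_len(n)) / n - Fx, Fx - (seq_len(n) - 1) / n))
  list(statistic = D, pvalue = ks_pvalue_asymptotic(D, n), n = n)
}

# P(sqrt(n) D > lambda) under H0, asymptotic Kolmogorov series.
ks_pvalue_asymptotic <- function(D, n) {
  lambda <- sqrt(n) * D
  if (lambda < 1e-10) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

# ---------------------------------------------------------------------------
# Maximum-likelihood fitting with AIC ranking

neg_loglik <- function(obs, family, theta) {
  d <- switch(family,
    gamma   = dgamma(obs, shape = theta[1], scale = theta[2]),
    weibull = dweibull(obs, shape = theta[1], scale = theta[2])
  )
  if (any(d <= 0) || any(!is.finite(d))) return(1e300)
  -sum(log(d))
}

fit_one_family <- function(obs, family) {
  n <- length(obs)
  m <- mean(obs); s <- sd(obs)
  fit <- switch(family,
    uniform = {
      lo <- min(obs); hi <- max(obs)
      if (hi <= lo) return(NULL)
      list(params = list(min = lo, max = hi),
           loglik = -n * log(hi - lo), npar = 2L)
    },
    normal = {
      sd_mle <- sqrt(mean((obs - m)^2))
      if (sd_mle <= 0) return(NULL)
      list(params = list(mean = m, sd = sd_mle),
           loglik = sum(dnorm(obs, m, sd_mle, log = TRUE)), npar = 2L)
    },
    lognormal = {
      if (any(obs <= 0)) return(NULL)
      lm_ <- mean(log(obs)); ls <- sqrt(mean((log(obs) - lm_)^2))
      if (ls <= 0) return(NULL)
      list(params = list(meanlog = lm_, sdlog = ls),
           loglik = sum(dlnorm(obs, lm_, ls, log = TRUE)), npar = 2L)
    },
    gamma = {
      if (any(obs <= 0)) return(NULL)
      shape0 <- m^2 / s^2; scale0 <- s^2 / m      # method of moments
      opt <- try(optim(log(c(shape0, scale0)), function(lt)
        neg_loglik(obs, "gamma", exp(lt)), method = "Nelder-Mead"),
        silent = TRUE)
      if (inherits(opt, "try-error")) return(NULL)
      th <- exp(opt$par)
      list(params = list(shape = th[1], scale = th[2]),
           loglik = -opt$value, npar = 2L)
    },
    weibull = {
      if (any(obs <= 0)) return(NULL)
      shape0 <- max(0.5, 1.2 / (s / m))            # moment-based start
      scale0 <- m / gamma(1 + 1 / shape0)
      opt <- try(optim(log(c(shape0, scale0)), function(lt)
        neg_loglik(obs, "weibull", exp(lt)), method = "Nelder-Mead"),
        silent = TRUE)
      if (inherits(opt, "try-error")) return(NULL)
      th <- exp(opt$par)
      list(params = list(shape = th[1], scale = th[2]),
           loglik = -opt$value, npar = 2L)
    },
    triangular = {
      # a, b pinned just outside the data range (MLE lies on the boundary
      # where the likelihood is improper); profile likelihood over the mode.
      r <- max(obs) - min(obs)
      if (r <= 0) return(NULL)
      a <- min(obs) - 0.025 * r; b <- max(obs) + 0.025 * r
      prof <- function(cc) {
        d <- dtri(obs, a, b, cc)
        if (any(d <= 0)) return(1e300)
        -sum(log(d))
      }
      opt <- optimize(prof, c(a, b))
      list(params = list(min = a, max = b, mode = opt$minimum),
           loglik = -opt$objective, npar = 3L)
    }
  )
  if (is.null(fit) || !is.finite(fit$loglik)) return(NULL)
  spec <- do.call(dist_spec, c(list(family = family), fit$params))
  d <- make_distribution(spec)
  ks <- ks_statistic(obs, d$cdf)
  structure(list(spec = spec, loglik = fit$loglik,
                 aic = 2 * fit$npar - 2 * fit$loglik,
                 ks_stat = ks$statistic, ks_pvalue = ks$pvalue,
                 n_obs = n, fallback = FALSE),
            class = "fit_result")
}

#' Fit candidate distributions to observations and rank by AIC
#'
#' Maximum-likelihood fit of each requested family, ranked by ascending AIC
#' (`AIC = 2 k - 2 logLik`), with the Kolmogorov-Smirnov statistic and
#' asymptotic p-value of each fitted cdf. Following the convention used for
#' sparsely observed crop parameters, fewer than `min_obs` observations
#' trigger a uniform fallback over the observed (or supplied) range instead
#' of a parametric fit; the single returned result is flagged
#' `fallback = TRUE`.
#'
#' @param obs Numeric observations, finite, n >= 1.
#' @param families Character vector of families to try.
#' @param min_obs Minimum observations for parametric fitting (default 10).
#' @param fallback_range Optional length-2 numeric overriding the observed
#'   min/max used for the uniform fallback.
#' @return List of `fit_result` objects sorted by AIC (a single fallback
#'   result when n < `min_obs`). Each has `spec`, `loglik`, `aic`, `ks_stat`,
#'   `ks_pvalue`, `n_obs`, `fallback`.
#' @export
fit_distribution <- function(obs, families = DIST_FAMILIES, min_obs = 10,
                             fallback_range = NULL) {
  obs <- as.numeric(obs)
  if (length(obs) == 0) stop("no observations")
  if (any(!is.finite(obs))) stop("observations must be finite")
  if (length(unique(obs)) == 1) stop("all observations identical")
  if (length(families) == 0) stop("no candidate families")
  families <- match.arg(families, DIST_FAMILIES, several.ok = TRUE)

  if (length(obs) < min_obs) {
    rng <- fallback_range %||% range(obs)
    spec <- dist_spec("uniform", min = rng[1], max = rng[2])
    d <- make_distribution(spec)
    ks <- ks_statistic(obs, d$cdf)
    return(list(structure(list(
      spec = spec, loglik = -length(obs) * log(diff(rng)),
      aic = NA_real_, ks_stat = ks$statistic, ks_pvalue = ks$pvalue,
      n_obs = length(obs), fallback = TRUE), class = "fit_result")))
  }
  fits <- Filter(Negate(is.null), lapply(families, fit_one_family, obs = obs))
  if (length(fits) == 0) stop("no family could be fitted to these data")
  fits[order(vapply(fits, `[[`, numeric(1), "aic"))]
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s(%s)%s  logLik=%.3f AIC=%s K-S=%.4f (p=%.3f) n=%d\n",
              x$spec$family,
              paste(sprintf("%s=%.4g", names(x$spec$params),
                            unlist(x$spec$params)), collapse = ", "),
              if (x$fallback) " [uniform fallback]" else "",
              x$loglik, if (is.na(x$aic)) "NA" else sprintf("%.2f", x$aic),
              x$ks_stat, x$ks_pvalue, x$n_obs))
  invisible(x)
}

#' Write a table of fit results
#'
#' @param fits List of `fit_result` objects (from [fit_distribution()]).
#' @param path Optional file path; when `NULL` the data frame is returned
#'   invisibly without writing.
#' @param gsp Label recorded in the first column.
#' @return Data frame with one row per fit.
#' @export
fit_report <- function(fits, path = NULL, gsp = "") {
  df <- do.call(rbind, lapply(fits, function(f) data.frame(
    gsp = gsp, family = f$spec$family,
    params = paste(sprintf("%s=%.6g", names(f$spec$params),
                           unlist(f$spec$params)), collapse = ";"),
    ks = f$ks_stat, p = f$ks_pvalue, aic = f$aic, n = f$n_obs,
    fallback = f$fallback)))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  invisible(df)
}
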