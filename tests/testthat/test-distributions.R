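# distributions: specification, truncation, quantiles, sampling, fitting

test_that("dist_spec validates families and parameters", {
  expect_s3_class(dist_spec("uniform", min = 0.7, max = 1.3), "dist_spec")
  expect_error(dist_spec("uniform", min = 2, max = 1), "min < max")
  expect_error(dist_spec("triangular", min = 1, max = 2, mode = 5), "mode")
  expect_error(dist_spec("normal", mean = 0, sd = -1), "sd > 0")
  expect_error(dist_spec("normal", mean = 0), "requires parameters")
  expect_error(dist_spec("cauchy", location = 0, scale = 1))
  expect_error(truncation_rule("probability", 1.2, "probability", 0.9),
               "in \\(0, 1\\)")
})

test_that("truncation resolves to the documented supports", {
  # bare uniform and triangular bounds
  d <- make_distribution(dist_spec("uniform", min = 0.7, max = 1.3))
  expect_equal(d$support, c(0.7, 1.3))
  d <- make_distribution(dist_spec("triangular", min = 189, max = 1447,
                                   mode = 764))
  expect_equal(d$support, c(189, 1447))
  # probability truncation: endpoints are untruncated quantiles
  d <- make_distribution(dist_spec(
    "normal", mean = 242.613, sd = 59.975,
    truncation = truncation_rule("probability", 0.1, "probability", 0.9)))
  expect_equal(d$support, qnorm(c(0.1, 0.9), 242.613, 59.975))
  # mixed value/probability truncation
  d <- make_distribution(dist_spec(
    "weibull", shape = 4.183, scale = 1015.34,
    truncation = truncation_rule("value", 100, "probability", 0.9)))
  expect_equal(d$support,
               c(100, qweibull(0.9, 4.183, scale = 1015.34)))
  # degenerate truncation is rejected
  expect_error(make_distribution(dist_spec(
    "uniform", min = 0, max = 1,
    truncation = truncation_rule("value", 2, "value", 3))),
    "empty truncated support")
})

test_that("quantile is the inverse cdf over the support", {
  d <- make_distribution(dist_spec("uniform", min = 0.7, max = 1.3))
  expect_equal(quantile(d, 0.5), 1.0)
  d <- make_distribution(dist_spec("triangular", min = 189, max = 1447,
                                   mode = 764))
  expect_equal(quantile(d, 0), 189)
  expect_equal(quantile(d, 1), 1447)
  expect_error(quantile(d, 1.5), "\\[0, 1\\]")
  # lognormal median equals exp(meanlog); verified by root-finding the cdf
  d <- make_distribution(dist_spec("lognormal", meanlog = 5.748,
                                   sdlog = 0.314))
  expect_equal(quantile(d, 0.5), exp(5.748), tolerance = 1e-10)
  root <- uniroot(function(x) dist_cdf(d, x) - 0.5, c(1, 1e4),
                  tol = 1e-10)$root
  expect_equal(quantile(d, 0.5), root, tolerance = 1e-6)
})

test_that("cdf/quantile round-trip to 1e-8 on every packaged distribution", {
  p <- seq(0.01, 0.99, by = 0.01)
  for (nm in names(gsp_dists())) {
    d <- gsp_dists()[[nm]]
    expect_equal(dist_cdf(d, d$quantile(p)), p, tolerance = 1e-8,
                 label = nm)
    expect_equal(dist_cdf(d, d$support[1]), 0, tolerance = 1e-12)
    expect_equal(dist_cdf(d, d$support[2]), 1, tolerance = 1e-12)
  }
})

test_that("truncated pdf integrates to 1 over the support", {
  for (nm in names(gsp_dists())) {
    d <- gsp_dists()[[nm]]
    int <- integrate(function(x) dist_pdf(d, x), d$support[1],
                     d$support[2], rel.tol = 1e-9)$value
    expect_equal(int, 1, tolerance = 1e-6, label = nm)
  }
})

test_that("sampling is deterministic, in-support, and K-S-consistent", {
  d <- gsp_dists()[["LLIFA"]]
  x1 <- dist_sample(d, 100, seed = 7)
  x2 <- dist_sample(d, 100, seed = 7)
  expect_identical(x1, x2)
  x <- dist_sample(d, 1e4, seed = 1)
  expect_true(all(x >= d$support[1] & x <= d$support[2]))
  for (nm in names(gsp_dists())) {
    di <- gsp_dists()[[nm]]
    xi <- dist_sample(di, 1e4, seed = 3)
    expect_lt(ks_statistic(xi, di$cdf)$statistic, 0.02, label = nm)
  }
})

test_that("ks_statistic matches a brute-force oracle and stats::ks.test", {
  # single observation at the median of the hypothesised cdf
  expect_equal(ks_statistic(0, pnorm)$statistic, 0.5)
  rnorm_seeded <- function(s, n) {
    set.seed(s); rnorm(n)
  }
  for (s in 1:5) {
    x <- rnorm_seeded(s, 50)
    ours <- ks_statistic(x, pnorm)
    expect_equal(ours$statistic, ks_brute(x, pnorm), tolerance = 1e-12)
  }
  x <- rnorm_seeded(9, 500)
  ref <- suppressWarnings(stats::ks.test(x, pnorm, exact = FALSE))
  ours <- ks_statistic(x, pnorm)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$pvalue, ref$p.value, tolerance = 1e-6)
  expect_error(ks_statistic(numeric(0), pnorm), "empty")
})

test_that("ks p-values are calibrated under the null", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    ks_statistic(runif(1e4), punif)$pvalue > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("observations placed at (i-0.5)/n quantiles give D = 0.5/n", {
  n <- 40
  x <- qnorm((seq_len(n) - 0.5) / n)
  expect_equal(ks_statistic(x, pnorm)$statistic, 0.5 / n, tolerance = 1e-12)
})

test_that("fit_distribution recovers parameters and ranks by AIC", {
  obs <- generate_gsp_observations(
    dist_spec("gamma", shape = 8.984, scale = 0.0237), 500, seed = 21)
  fits <- fit_distribution(obs)
  expect_equal(fits[[1]]$spec$family, "gamma")
  expect_equal(fits[[1]]$spec$params$shape, 8.984, tolerance = 0.15)
  expect_equal(fits[[1]]$spec$params$scale, 0.0237, tolerance = 0.15)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  expect_true(!is.unsorted(aics))
  # fit invariants
  f <- fits[[1]]
  expect_equal(f$aic, 2 * 2 - 2 * f$loglik)
  expect_true(f$ks_stat >= 0 && f$ks_stat <= 1)
  expect_identical(f$n_obs, 500L)
})

test_that("fewer than 10 observations trigger the uniform fallback", {
  obs <- generate_gsp_observations(
    dist_spec("normal", mean = 10, sd = 2), 9, seed = 4)
  fits <- fit_distribution(obs)
  expect_length(fits, 1)
  expect_true(fits[[1]]$fallback)
  expect_equal(fits[[1]]$spec$family, "uniform")
  expect_equal(fits[[1]]$spec$params$min, min(obs))
  expect_equal(fits[[1]]$spec$params$max, max(obs))
  # configurable range override (e.g. TBLSZ is set to 11..17 by convention)
  fits <- fit_distribution(obs, fallback_range = c(11, 17))
  expect_equal(unlist(fits[[1]]$spec$params), c(min = 11, max = 17))
  expect_error(fit_distribution(rep(1, 20)), "identical")
  expect_error(fit_distribution(numeric(0)), "no observations")
})

test_that("AIC ranking is invariant to positive rescaling of the data", {
  set.seed(31)
  obs <- exp(rnorm(200, 1, 0.4))
  fam <- c("normal", "lognormal", "gamma", "weibull")
  rank1 <- vapply(fit_distribution(obs, fam), function(f) f$spec$family, "")
  rank2 <- vapply(fit_distribution(obs * 100, fam),
                  function(f) f$spec$family, "")
  expect_identical(rank1, rank2)
  expect_identical(rank1[1], "lognormal")
})

test_that("fit_report writes a delimited table", {
  obs <- generate_gsp_observations(
    dist_spec("normal", mean = 5, sd = 1), 60, seed = 2)
  fits <- fit_distribution(obs, c("normal", "uniform"))
  path <- tempfile(fileext = ".csv")
  df <- fit_report(fits, path, gsp = "DEMO")
  expect_true(file.exists(path))
  back <- read.csv(path)
  expect_equal(nrow(back), 2)
  expect_identical(back$gsp[1], "DEMO")
  expect_named(back, c("gsp", "family", "params", "ks", "p", "aic", "n",
                       "fallback"))
})
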