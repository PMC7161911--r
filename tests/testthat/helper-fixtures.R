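# Shared fixtures and independent oracles. Everything is generated in code;
# generated objects are cached for the duration of the test run.

.fx <- new.env()

cached <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

quick_weather <- function(site = "warm", years = 2, seed = 11) {
  cached(paste("w", site, years, seed),
         generate_weather(default_sites()[[site]], years, seed = seed))
}

# constant-forcing series (no weather noise; optional heavy daily rain)
constant_weather <- function(days = 400, tmax = 33, tmin = 23, srad = 17,
                             rain = 20, start = as.Date("2001-01-01")) {
  weather_series(data.frame(
    date = seq(start, by = "day", length.out = days),
    tmax = tmax, tmin = tmin, srad = srad, rain = rain))
}

# the packaged Table-style distribution set
gsp_dists <- function() cached("dists", gsp_distributions())

# --- independent oracles -------------------------------------------------

# brute-force K-S statistic: explicit sup over both one-sided differences
# at every jump of the empirical cdf
ks_brute <- function(obs, cdf) {
  x <- sort(obs)
  n <- length(x)
  d <- 0
  for (i in seq_len(n)) {
    d <- max(d, abs(i / n - cdf(x[i])), abs((i - 1) / n - cdf(x[i])))
  }
  d
}

# brute-force elementary effects: scan consecutive row pairs, find the
# changed coordinate by comparison, accumulate per-parameter effects
ee_brute <- function(design, y) {
  k <- design$k
  ee <- matrix(NA_real_, design$r, k)
  for (t in seq_len(design$r)) {
    rows <- which(design$trajectory == t)
    for (j in seq_along(rows)[-1]) {
      a <- rows[j - 1]; b <- rows[j]
      dif <- design$points[b, ] - design$points[a, ]
      ch <- which(abs(dif) > 1e-12)
      stopifnot(length(ch) == 1)
      ee[t, ch] <- (y[b] - y[a]) / dif[ch]
    }
  }
  list(mu = colMeans(ee), mu_star = colMeans(abs(ee)),
       sigma = apply(ee, 2, sd), ee = ee)
}

# double-loop Monte Carlo first-order Sobol index of f over iid U(lo, hi)
# coordinates: Var_i( E[f | x_i] ) / Var(f)
sobol_first_brute <- function(f, d, i, n_outer = 2048, n_inner = 512,
                              lo = 0, hi = 1, seed = 99) {
  with_seed(seed, {
    xi <- lo + (hi - lo) * runif(n_outer)
    cm <- vapply(xi, function(v) {
      x <- matrix(lo + (hi - lo) * runif(n_inner * d), n_inner, d)
      x[, i] <- v
      mean(f(x))
    }, numeric(1))
    x <- matrix(lo + (hi - lo) * runif(2^14 * d), 2^14, d)
    var(cm) / var(f(x))
  })
}
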