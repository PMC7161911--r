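# elementary-effects screening: design, effects, normalization, selection

test_that("design sizes and step follow the Morris construction", {
  d <- cached("esu_16_8_24", build_esu_design(16, 8, 24, pool_size = 100,
                                              seed = 1))
  expect_equal(nrow(d$points), 24 * 17)        # 408 combinations
  expect_equal(d$delta, 8 / 14)                # p / (2 (p - 1)) = 4/7
  d1 <- suppressWarnings(build_esu_design(1, 2, 1, pool_size = 1, seed = 2))
  expect_equal(nrow(d1$points), 2)
  expect_equal(abs(diff(d1$points[, 1])), d1$delta)
  expect_error(build_esu_design(0, 8, 4), "k must be")
  expect_error(build_esu_design(4, 8, 10, pool_size = 5), "pool_size")
  expect_warning(build_esu_design(3, 4, 6, pool_size = 10, seed = 1),
                 "multiple")
})

test_that("every trajectory changes one grid coordinate per step", {
  for (cfg in list(c(k = 5, p = 8, r = 4), c(k = 16, p = 8, r = 6),
                   c(k = 3, p = 4, r = 4))) {
    d <- suppressWarnings(build_esu_design(cfg["k"], cfg["p"], cfg["r"],
                                           pool_size = 50, seed = cfg["k"]))
    grid <- (seq_len(cfg["p"]) - 1) / (cfg["p"] - 1)
    expect_true(all(vapply(as.numeric(d$points), function(v)
      any(abs(v - grid) < 1e-9), logical(1))))
    for (t in seq_len(cfg["r"])) {
      rows <- which(d$trajectory == t)
      seen <- integer(0)
      for (j in seq_along(rows)[-1]) {
        dif <- d$points[rows[j], ] - d$points[rows[j] - 1, ]
        ch <- which(abs(dif) > 1e-12)
        expect_length(ch, 1)
        expect_equal(abs(dif[ch]), d$delta, tolerance = 1e-12)
        seen <- c(seen, ch)
      }
      expect_setequal(seen, seq_len(cfg["k"]))  # each parameter once
    }
  }
})

test_that("inverse-cdf mapping is monotone and respects integer flags", {
  dists <- gsp_dists()
  d <- cached("esu_16_8_24", build_esu_design(16, 8, 24, pool_size = 100,
                                              seed = 1))
  m <- map_to_parameters(d, dists)
  expect_equal(colnames(m), names(dists))
  # spec examples
  u <- map_to_parameters(matrix(0.5), dists["LNSLP"],
                         integer = FALSE)
  expect_equal(u[1], 1.0)
  tr <- map_to_parameters(matrix(0), dists["B01ND"], integer = FALSE)
  expect_equal(tr[1], 189)
  # monotonicity per column
  g <- seq(0, 1, by = 1 / 7)
  for (nm in c("LAXS", "LLIFA", "PARUE")) {
    v <- map_to_parameters(matrix(g), dists[nm], integer = FALSE)
    expect_true(all(diff(v) >= 0), label = nm)
  }
  br <- m[, c("BR1F", "BR2F", "BR3F", "BR4F")]
  expect_true(all(br == round(br) & br >= 1 & br <= 4))
  expect_error(map_to_parameters(d, dists[1:3]), "columns")
})

test_that("elementary effects are exact for a linear model", {
  d <- suppressWarnings(build_esu_design(2, 8, 12, pool_size = 60,
                                         seed = 3))
  y <- 3 * d$points[, 1] + d$points[, 2]
  ee <- elementary_effects(d, y)
  expect_equal(ee$mu_star, c(3, 1), tolerance = 1e-12)
  expect_equal(ee$mu, c(3, 1), tolerance = 1e-12)
  expect_lt(max(ee$sigma), 1e-12)
  # independent brute-force recomputation
  bf <- ee_brute(d, y)
  expect_equal(ee$mu_star, bf$mu_star, tolerance = 1e-12)
  expect_equal(ee$sigma, bf$sigma, tolerance = 1e-12)
})

test_that("effects flag constants and interactions correctly", {
  d <- suppressWarnings(build_esu_design(2, 8, 12, pool_size = 60,
                                         seed = 4))
  ee0 <- elementary_effects(d, rep(2.5, nrow(d$points)))
  expect_equal(ee0$mu, c(0, 0))
  expect_equal(ee0$mu_star, c(0, 0))
  expect_equal(ee0$sigma, c(0, 0))
  eei <- elementary_effects(d, d$points[, 1] * d$points[, 2])
  expect_gt(eei$sigma[1], 0)
  expect_true(all(eei$mu_star >= abs(eei$mu) - 1e-12))
  expect_error(elementary_effects(d, c(NA, rep(1, nrow(d$points) - 1))),
               "finite")
})

test_that("brute-force agreement holds on the crop-model scale design", {
  d <- cached("esu_16_8_24", build_esu_design(16, 8, 24, pool_size = 100,
                                              seed = 1))
  set.seed(8)
  y <- as.numeric(d$points %*% runif(16, -2, 2)) +
    d$points[, 1] * d$points[, 2]
  ee <- elementary_effects(d, y)
  bf <- ee_brute(d, y)
  expect_equal(ee$mu_star, bf$mu_star, tolerance = 1e-12)
  expect_equal(ee$mu, bf$mu, tolerance = 1e-12)
  expect_equal(ee$sigma, bf$sigma, tolerance = 1e-12)
})

make_effects <- function(mu_star, sigma = mu_star / 2) {
  structure(list(ee = NULL, mu = mu_star, mu_star = mu_star,
                 sigma = sigma), class = "elementary_effects")
}

test_that("normalization divides by the cross-treatment maximum", {
  eff <- list(
    t1 = list(out1 = make_effects(c(a = 2, b = 1))),
    t2 = list(out1 = make_effects(c(a = 4, b = 0.5))))
  nz <- normalize_effects(eff)
  expect_equal(max(nz$mu_star_norm), 1)
  expect_equal(nz$mu_star_norm[nz$treatment == "t1" & nz$parameter == "a"],
               0.5)
  # scale invariance
  eff10 <- list(
    t1 = list(out1 = make_effects(c(a = 20, b = 10))),
    t2 = list(out1 = make_effects(c(a = 40, b = 5))))
  expect_equal(normalize_effects(eff10)$mu_star_norm, nz$mu_star_norm)
  # single treatment: raw / max(raw)
  one <- normalize_effects(list(t1 = list(out1 = make_effects(c(3, 1)))))
  expect_equal(one$mu_star_norm, c(1, 1 / 3))
  expect_warning(
    normalize_effects(list(t1 = list(o = make_effects(c(0, 0), c(0, 0))))),
    "zero")
})

test_that("selection uses a strict threshold and is monotone", {
  eff <- list(
    t1 = list(o = make_effects(c(A = 0.6, B = 0.1, C = 0.5),
                               c(A = 0.1, B = 0.1, C = 0.1))))
  nz <- data.frame(treatment = "t1", output = "o",
                   parameter = c("A", "B", "C"),
                   mu_star_norm = c(0.6, 0.1, 0.5),
                   sigma_norm = c(0.1, 0.55, 0.5))
  sel <- select_important(nz)
  expect_setequal(sel, c("A", "B"))            # 0.5 exactly is excluded
  lower <- select_important(nz, threshold = 0.3)
  expect_true(all(sel %in% lower))
})
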