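# Sobol designs, index estimators, uncertainty summaries, method comparison

test_that("design sizes and hybrid structure follow 2n(k+1)", {
  d <- build_sobol_design(14, 512, seed = 1)
  expect_equal(nrow(d$points), 15360)
  d1 <- build_sobol_design(1, 1, seed = 1)
  expect_equal(nrow(d1$points), 4)
  d <- build_sobol_design(5, 16, seed = 2)
  A <- d$points[d$block == "A", ]
  B <- d$points[d$block == "B", ]
  for (i in 1:5) {
    ABi <- d$points[d$block == "AB" & d$column == i, ]
    expect_equal(ABi[, i], B[, i])
    expect_equal(ABi[, -i], A[, -i])
    BAi <- d$points[d$block == "BA" & d$column == i, ]
    expect_equal(BAi[, i], A[, i])
    expect_equal(BAi[, -i], B[, -i])
  }
})

test_that("all three samplers cover the unit hypercube", {
  for (m in c("sobol", "lhs", "random")) {
    d <- build_sobol_design(3, 256, seed = 4, method = m)
    expect_true(all(d$points > 0 & d$points < 1))
    expect_lt(max(abs(colMeans(d$points[d$block == "A", ]) - 0.5)), 0.08)
  }
})

test_that("Ishigami indices match the closed form", {
  d <- cached("sobol_ishigami",
              build_sobol_design(3, 4096, seed = 5))
  y <- ishigami(d$points * 2 * pi - pi)
  si <- cached("si_ishigami", estimate_indices(d, y, n_boot = 100))
  an <- ishigami_indices()
  expect_equal(si$S_first, an$S, tolerance = 0.05)
  expect_equal(si$S_total, an$ST, tolerance = 0.05)
  # x3 has no main effect but interacts with x1
  expect_lt(abs(si$S_first[3]), 0.05)
  expect_gt(si$S_total[3], 0.15)
  # bootstrap intervals bracket the point estimates
  expect_true(all(si$S_first_lo <= si$S_first + 1e-9 &
                    si$S_first <= si$S_first_hi + 1e-9))
})

test_that("estimates converge between n = 1024 and n = 4096", {
  an <- ishigami_indices()
  d1 <- build_sobol_design(3, 1024, seed = 6)
  s1 <- estimate_indices(d1, ishigami(d1$points * 2 * pi - pi), n_boot = 0)
  d2 <- cached("sobol_ishigami", build_sobol_design(3, 4096, seed = 5))
  s2 <- cached("si_ishigami",
               estimate_indices(d2, ishigami(d2$points * 2 * pi - pi),
                                n_boot = 100))
  expect_lt(max(abs(s1$S_first - s2$S_first)), 0.05)
  expect_lt(max(abs(s1$S_total - s2$S_total)), 0.05)
})

test_that("additive models decompose exactly", {
  a <- c(3, 1, 0.5, 2)
  d <- build_sobol_design(4, 2048, seed = 7)
  si <- estimate_indices(d, linear_additive(d$points, a), n_boot = 0,
                         params = letters[1:4])
  expect_equal(sum(si$S_first), 1, tolerance = 0.03)
  expect_equal(si$S_first, linear_additive_indices(a), tolerance = 0.03)
  expect_equal(si$S_total, si$S_first, tolerance = 0.03)
  expect_identical(si$parameter, letters[1:4])
})

test_that("degenerate outputs yield zero indices with a warning", {
  d <- build_sobol_design(2, 64, seed = 8)
  expect_warning(si <- estimate_indices(d, rep(3.3, nrow(d$points))),
                 "zero output variance")
  expect_equal(si$S_first, c(0, 0))
  expect_equal(si$S_total, c(0, 0))
  expect_error(estimate_indices(d, rep(NA_real_, nrow(d$points))),
               "finite")
  expect_error(estimate_indices(d, 1:5), "per design row")
})

test_that("total indices dominate first-order on the crop model", {
  # reduced-scale run: all 16 GSPs, one warm rainfed treatment, 2 years
  dists <- gsp_dists()
  d <- build_sobol_design(16, 64, seed = 9)
  params <- map_to_parameters(d, dists)
  w <- quick_weather("warm", years = 3, seed = 21)
  ev <- cassim:::evaluate_rows(params, w, load_soil("warm"), years = 2,
                               water_limited = TRUE)
  for (o in c("aboveground_biomass", "max_lai")) {
    si <- estimate_indices(d, ev$means[, o], n_boot = 0)
    expect_true(all(si$S_total >= si$S_first - 0.05), label = o)
  }
})

test_that("uncertainty summaries report mean, sd, cv, cdf and ci", {
  u <- uncertainty_summary(matrix(5, 10, 3))
  expect_equal(u$sd, 0)
  expect_equal(u$cv, 0)
  expect_equal(unique(u$cdf$value), 5)
  expect_equal(max(u$cdf$probability), 1)
  # lognormal cv closed form: 100 sqrt(exp(sigma^2) - 1)
  set.seed(10)
  x <- matrix(rlnorm(1e4, 0, 0.5), ncol = 1)
  u <- uncertainty_summary(x)
  expect_equal(u$cv, 100 * sqrt(exp(0.25) - 1), tolerance = 0.02 * 100)
  expect_equal(u$cdf$probability[which.max(u$cdf$value)], 1)
  expect_true(u$ci[1] <= u$mean && u$mean <= u$ci[2])
})

test_that("method comparison regression behaves like OLS", {
  st <- c(0.05, 0.1, 0.2, 0.4, 0.5)
  fit <- compare_methods(2 * st, st)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)               # mu* = 2 ST here
  fit <- compare_methods(0.5 * st, st)     # ST = 2 mu*: slope 0.5
  expect_equal(fit$slope, 0.5)
  set.seed(11)
  noise <- compare_methods(runif(100), runif(100))
  expect_lt(noise$r_squared, 0.1)
  perturbed <- c(2 * st[-5], 5)
  expect_lt(compare_methods(perturbed, st)$r_squared, 1)
  expect_error(compare_methods(1:2, 1:2), "3 points")
  expect_error(compare_methods(1:3, 1:4), "mismatch")
})
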