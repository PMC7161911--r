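# crop model components and season simulation

test_that("branching fires at B01ND + L*B12ND under constant forcing", {
  g <- gsp_set(B01ND = 764, B12ND = 456, BR1F = 2, BR2F = 3)
  st <- crop_state(g)
  st$germinated <- TRUE
  # constant tmean 28 C at branching base 13 C -> 15 Cd/day; stop before
  # the third threshold (764 + 2 * 456 = 1676 Cd) is reached
  for (d in 1:85) {
    st$day <- d
    update_branching(st, 15, g)
  }
  expect_equal(st$day_of_branch[1], ceiling(764 / 15))        # day 51
  expect_equal(st$day_of_branch[2], ceiling((764 + 456) / 15))
  expect_equal(st$branch_level, 2L)
  expect_equal(st$apex_count, 1 * 2 * 3)
})

test_that("branching never fires when B01ND exceeds season thermal time", {
  g <- gsp_set(B01ND = 1447)
  st <- crop_state(g)
  st$germinated <- TRUE
  for (d in 1:90) {
    st$day <- d
    update_branching(st, 15, g)                # 1350 Cd < 1447
  }
  expect_true(is.na(st$day_of_branch[1]))
  expect_equal(st$branch_level, 0L)
})

test_that("leaf appearance rate scales with LNSLP and decays with age", {
  ages <- seq(0, 4000, by = 100)
  ref <- leaf_appearance_rate(ages, 1)
  expect_equal(leaf_appearance_rate(ages, 1.3) /
                 leaf_appearance_rate(ages, 0.7), rep(1.3 / 0.7,
                                                      length(ages)))
  expect_true(all(diff(ref) < 0))
  expect_true(all(ref > 0))
  expect_error(leaf_appearance_rate(-1, 1), "negative")
})

test_that("potential leaf size peaks at 900 Cd and declines after", {
  sc <- species_constants()
  expect_equal(potential_leaf_size(900, 313), 313)
  expect_equal(potential_leaf_size(0, 313), sc$leaf_size_f0 * 313)
  expect_lt(potential_leaf_size(1200, 313), 313)
  # continuity at the peak
  expect_equal(potential_leaf_size(900 - 1e-9, 313),
               potential_leaf_size(900 + 1e-9, 313), tolerance = 1e-6)
  expect_error(potential_leaf_size(-5, 313), "negative")
})

test_that("node growth integrates to NODWT and scales with it", {
  for (leafno in c(0, 40)) {
    int <- integrate(node_growth_rate, 0, Inf,
                     leaf_no_at_creation = leafno, NODWT = 8)$value
    expect_equal(int, 8, tolerance = 0.01, label = paste("leafno", leafno))
  }
  ages <- seq(0, 3000, by = 50)
  expect_true(all(node_growth_rate(ages, 10, 8) >= 0))
  expect_equal(node_growth_rate(ages, 10, 16),
               2 * node_growth_rate(ages, 10, 8))
})

test_that("daily assimilation follows Beer's law interception", {
  expect_equal(daily_assimilation(17, 0, 1.4, 0.8), 0)
  expect_equal(daily_assimilation(17, 100, 1.4, 0.8),
               0.5 * 17 * 1.4, tolerance = 1e-10)
  kcan <- 0.8
  lai <- log(2) / kcan
  expect_equal(daily_assimilation(17, lai, 1.4, kcan),
               0.5 * 0.5 * 17 * 1.4)
})

test_that("demands split into lamina/petiole and 10% fibrous gross-up", {
  g <- gsp_set()
  st <- crop_state(g)
  dem0 <- compute_demand(st, g)
  expect_equal(unlist(dem0[c("leaf", "stem", "fibrous")]),
               c(leaf = 0, stem = 0, fibrous = 0))
  # one expanding cohort
  st$n_coh <- 1L
  st$co_n[1] <- 3
  st$co_target[1] <- 200
  st$co_area[1] <- 10
  st$dtt_leaf <- 12
  st$dtt_node <- 15
  st$stress <- 1
  dem <- compute_demand(st, g)
  expect_equal(dem$fibrous, 0.10 * (dem$leaf + dem$stem))
  petiole <- dem$leaf - dem$lamina
  expect_equal(petiole / dem$leaf, unname(g["LPEFR"]))
  expect_equal(dem$lamina,
               sum(dem$pot_inc * st$co_n[1]) / unname(g["SLAS"]))
})

test_that("spill-over allocation obeys the surplus and scaling rules", {
  d <- list(leaf = 4, stem = 5, fibrous = 0.9)
  al <- allocate_spillover(9.9, d)             # supply == demand
  expect_equal(al$storage, 0)
  expect_equal(al$ratio, 1)
  al <- allocate_spillover(1.5 * 9.9, d)       # surplus spills to storage
  expect_equal(al$storage, 0.5 * 9.9)
  expect_equal(al$leaf, 4)
  al <- allocate_spillover(0.6 * 9.9, d)       # shortfall scales organs
  expect_equal(al$ratio, 0.6)
  expect_equal(al$stem, 0.6 * 5)
  expect_equal(al$storage, 0)
  expect_error(allocate_spillover(-1, d), ">= 0")
})

test_that("senescence is a strict threshold on post-expansion age", {
  g <- gsp_set(LLIFA = 300)
  st <- crop_state(g)
  st$n_coh <- 1L
  st$co_n[1] <- 2
  st$co_area[1] <- st$co_target[1] <- 100
  st$co_expanded[1] <- TRUE
  st$lai <- 2 * 100 / 1e4
  st$mass_lamina <- 2 * 100 / unname(g["SLAS"])
  st$mass_petiole <- st$mass_lamina * unname(g["LPEFR"]) /
    (1 - unname(g["LPEFR"]))
  senesce(st, 300, 300)                        # exactly at LLIFA: alive
  expect_false(st$co_senesced[1])
  senesce(st, 1e-6, 300)                       # epsilon beyond: senesced
  expect_true(st$co_senesced[1])
  expect_equal(st$lai, 0)
  expect_equal(st$mass_lamina, 0, tolerance = 1e-12)
  expect_gt(st$mass_dead, 0)
  # LLIFA effectively infinite: nothing senesces
  st2 <- crop_state(g)
  st2$n_coh <- 1L
  st2$co_expanded[1] <- TRUE
  for (i in 1:400) senesce(st2, 15, 1e6)
  expect_false(st2$co_senesced[1])
})

test_that("LAI always equals the live-cohort ledger in a season run", {
  g <- gsp_set()
  w <- quick_weather("warm")
  out <- simulate_season(g, w, load_soil("warm"),
                         mgmt_options(year = 2001), engine = "reference")
  st <- out$final_state
  idx <- seq_len(st$n_coh)
  live <- idx[!st$co_senesced[idx]]
  expect_equal(st$lai,
               sum(st$co_area[live] * st$co_n[live]) / 1e4,
               tolerance = 1e-9)
})

test_that("fast and reference engines agree across random genotypes", {
  dists <- gsp_dists()
  w <- quick_weather("warm")
  soil <- load_soil("warm")
  set.seed(77)
  for (rep in 1:5) {
    u <- runif(16)
    p <- vapply(seq_along(dists), function(j) dists[[j]]$quantile(u[j]),
                numeric(1))
    names(p) <- names(dists)
    p[c("BR1F", "BR2F", "BR3F", "BR4F")] <-
      round(p[c("BR1F", "BR2F", "BR3F", "BR4F")])
    g <- gsp_set(p)
    for (wl in c(TRUE, FALSE)) {
      mg <- mgmt_options(year = 2001, water_limited = wl, trace = TRUE)
      a <- simulate_season(g, w, soil, mg)
      b <- simulate_season(g, w, soil, mg, engine = "reference")
      va <- season_output_vector(a); vb <- season_output_vector(b)
      expect_identical(is.na(va), is.na(vb))
      expect_equal(va, vb, tolerance = 1e-9)
      expect_equal(as.matrix(a$trace), as.matrix(b$trace),
                   tolerance = 1e-8)
    }
  }
})

test_that("season mass balance closes and spill-over is respected", {
  g <- gsp_set()
  w <- quick_weather("warm")
  out <- simulate_season(g, w, load_soil("warm"),
                         mgmt_options(year = 2001, trace = TRUE))
  expect_lt(abs(out$balance_residual),
            1e-6 * max(out$assimilation_total, 1))
  # storage-root growth is zero on every supply-limited day
  lim <- out$trace$ratio < 1
  expect_true(any(lim))
  expect_true(all(out$trace$storage_inc[lim] == 0))
  expect_true(all(out$trace$storage_inc >= 0))
})

test_that("doubling PARUE without stress strictly increases biomass", {
  w <- quick_weather("warm")
  soil <- load_soil("warm")
  mg <- mgmt_options(year = 2001, water_limited = FALSE)
  lo <- simulate_season(gsp_set(PARUE = 1.0), w, soil, mg)
  hi <- simulate_season(gsp_set(PARUE = 2.0), w, soil, mg)
  expect_gt(hi$aboveground_biomass, lo$aboveground_biomass)
})

test_that("forcing stress to 1 matches rainfed under ample rain", {
  w <- constant_weather(days = 500, rain = 20)
  soil <- load_soil("warm")
  g <- gsp_set()
  rf <- simulate_season(g, w, soil,
                        mgmt_options(year = 2001, water_limited = TRUE,
                                     trace = TRUE))
  un <- simulate_season(g, w, soil,
                        mgmt_options(year = 2001, water_limited = FALSE,
                                     trace = TRUE))
  expect_true(all(rf$trace$stress == 1))
  expect_equal(season_output_vector(rf), season_output_vector(un))
})

test_that("weather shorter than the season window is rejected", {
  w <- constant_weather(days = 100)
  expect_error(simulate_season(gsp_set(), w, load_soil("warm")),
               "too short")
})
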