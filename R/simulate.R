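# Season-level orchestration of the crop model: daily loop over the weather,
# soil water balance and stress, phenology, growth, allocation, senescence.
#
# Two engines compute identical results: "fast" inlines the daily update
# with pre-computed forcing vectors (used for the thousands of runs of a
# sensitivity design); "reference" composes the exported component
# operations step by step. The test suite asserts their agreement.

#' Management and run options for a season simulation
#'
#' @param planting_doy Planting day of year (default 115, late April).
#' @param year Calendar year to plant in; `NULL` picks the first year whose
#'   window (30 days pre-plant through harvest) the weather series covers.
#' @param density Plants per m2 (default 1).
#' @param season_days Planting-to-harvest duration, days (default 300).
#' @param water_limited Rainfed (`TRUE`) or water-unlimited (`FALSE`, the
#'   drought stress factor is forced to 1).
#' @param s,s_g Drought sensitivity thresholds (shared / germination).
#' @param trace Keep a daily trace table?
#' @param constants [species_constants()].
#' @return Named list of options.
#' @export
mgmt_options <- function(planting_doy = DEFAULT_PLANTING_DOY, year = NULL,
                         density = 1, season_days = SEASON_DAYS,
                         water_limited = TRUE, s = 1.0, s_g = 0.6,
                         trace = FALSE, constants = species_constants()) {
  stopifnot(season_days >= 1, density > 0)
  list(planting_doy = planting_doy, year = year, density = density,
       season_days = season_days, water_limited = water_limited,
       s = s, s_g = s_g, trace = trace, constants = constants)
}

# root extraction weights for a given rooting depth (cm)
root_weights <- function(thickness_cm, depth) {
  top <- cumsum(c(0, thickness_cm[-length(thickness_cm)]))
  overlap <- pmax(0, pmin(top + thickness_cm, depth) - top)
  if (sum(overlap) == 0) overlap[1] <- thickness_cm[1]
  overlap
}

# locate the simulation window (30 d pre-plant .. harvest) in the series
season_window <- function(weather, mgmt) {
  year <- mgmt$year %||% {
    years <- unique(as.integer(format(weather$date, "%Y")))
    ok <- vapply(years, function(y) {
      pd <- as.Date(sprintf("%d-01-01", y)) + (mgmt$planting_doy - 1)
      min(weather$date) <= pd - 30 &&
        max(weather$date) >= pd + mgmt$season_days - 1
    }, logical(1))
    if (!any(ok)) stop("weather series too short for a full season")
    years[which(ok)[1]]
  }
  planting <- as.Date(sprintf("%d-01-01", year)) + (mgmt$planting_doy - 1)
  i0 <- match(planting - 30, weather$date)
  i1 <- match(planting + mgmt$season_days - 1, weather$date)
  if (is.na(i0) || is.na(i1))
    stop("weather series too short for a full season")
  i0:i1
}

#' Simulate one cassava growing season
#'
#' Runs the daily loop: soil water balance and drought stress, thermal time
#' per process (leaf development at the genotype base TBLSZ; branching, node
#' growth and leaf aging at the species base), germination, branching, node
#' cohort creation, leaf expansion and node growth demand, canopy
#' assimilation, spill-over allocation, and senescence. The simulation
#' starts 30 days before planting with the soil at field capacity and is
#' fully deterministic for fixed inputs.
#'
#' @param gsps A [gsp_set()].
#' @param weather A `weather_series` covering 30 days pre-plant through
#'   harvest.
#' @param soil A [soil_profile()].
#' @param mgmt [mgmt_options()].
#' @param engine `"fast"` (inlined, default) or `"reference"` (composed
#'   from the exported component operations); results are identical.
#' @return Object of class `season_outputs`: list with the six outputs
#'   (`aboveground_biomass` and `yield` in kg/ha dry mass, `max_lai`,
#'   `leaves_at_harvest` per plant, `day_first_branch`, `day_second_branch`
#'   in days after planting, `NA` if never reached), the cumulative
#'   assimilation, the mass-balance residual, and (if requested) the daily
#'   `trace` data frame.
#' @export
simulate_season <- function(gsps, weather, soil, mgmt = mgmt_options(),
                            engine = c("fast", "reference")) {
  if (!inherits(gsps, "gsp_set")) gsps <- gsp_set(gsps)
  stopifnot(inherits(soil, "soil_profile"))
  engine <- match.arg(engine)
  win <- season_window(weather, mgmt)
  if (engine == "fast") {
    simulate_season_fast(gsps, weather, soil, mgmt, win)
  } else {
    simulate_season_reference(gsps, weather, soil, mgmt, win)
  }
}

# Parameter-independent per-day forcing for the compiled season loop:
# weather vectors, Priestley-Taylor reference ET, thermal-time clocks at the
# species bases, root-weight schedule, and the soil profile in mm.
season_forcing <- function(weather, soil, mgmt, win) {
  sc <- mgmt$constants
  nw <- length(win)
  tmax <- weather$tmax[win]; tmin <- weather$tmin[win]
  tmean <- (tmax + tmin) / 2
  dtt_node <- pmax(0, tmean - sc$base_temp_branching)
  dtt_age <- pmax(0, tmean - sc$base_temp_leaf_aging)
  th <- soil$layers$thickness_cm
  nl <- length(th)
  depth_v <- pmin(soil$depth_cm, 15 + 1.2 * pmax(0, seq_len(nw) - 30))
  top <- cumsum(c(0, th[-nl]))
  rw <- vapply(seq_len(nl), function(l)
    pmax(0, pmin(top[l] + th[l], depth_v) - top[l]), numeric(nw))
  rw <- rw / rowSums(rw)
  list(rain = weather$rain[win], srad = weather$srad[win], tmean = tmean,
       et0 = priestley_taylor_et(weather$srad[win], tmean),
       dtt_node = dtt_node, dtt_age = dtt_age,
       ctt_node = c(0, cumsum(dtt_node)), ctt_age = c(0, cumsum(dtt_age)),
       rw = rw,
       ll = th * 10 * soil$layers$ll, dul = th * 10 * soil$layers$dul,
       sat = th * 10 * soil$layers$sat,
       dulll = th * 10 * (soil$layers$dul - soil$layers$ll),
       Scn = 25400 / soil$runoff_curve - 254, dr = soil$drainage_rate,
       nw = nw, nl = nl)
}

simulate_season_fast <- function(gsps, weather, soil, mgmt, win,
                                 forcing = NULL) {
  sc <- mgmt$constants
  forcing <- forcing %||% season_forcing(weather, soil, mgmt, win)
  dtt_leaf <- pmax(0, forcing$tmean - gsps[["TBLSZ"]])
  par <- list(
    B01 = gsps[["B01ND"]], B12 = gsps[["B12ND"]], LAXS = gsps[["LAXS"]],
    SLAS = gsps[["SLAS"]], LLIFA = gsps[["LLIFA"]],
    LPEFR = gsps[["LPEFR"]], LNSLP = gsps[["LNSLP"]],
    NODWT = gsps[["NODWT"]], PARUE = gsps[["PARUE"]],
    KCAN = gsps[["KCAN"]],
    brf = pmax(1, round(c(gsps[["BR1F"]], gsps[["BR2F"]], gsps[["BR3F"]],
                          gsps[["BR4F"]]))),
    r0 = sc$leaf_app_r0, h_app = sc$leaf_app_h,
    klog = sc$node_logistic_k, mid0 = sc$node_logistic_mid,
    midpl = sc$node_mid_per_leaf, f0 = sc$leaf_size_f0,
    peak = sc$leaf_size_peak_age, decl = sc$leaf_size_decline,
    expdur = sc$leaf_expansion_dur, fib = sc$fibrous_root_fraction,
    parf = sc$par_fraction, germ_req = sc$germination_tt,
    init_area = sc$initial_leaf_area, stake_reserve = sc$stake_reserve,
    max_branch = sc$max_branch_level)
  res <- .season_loop(forcing, dtt_leaf, par,
                      list(density = mgmt$density, s = mgmt$s,
                           s_g = mgmt$s_g,
                           water_limited = mgmt$water_limited,
                           trace = mgmt$trace,
                           season_days = mgmt$season_days))
  out <- res[setdiff(names(res), "trace")]
  if (mgmt$trace) {
    tr <- res$trace
    colnames(tr) <- c("day", "lai", "stress", "supply", "demand",
                      "storage_inc", "ratio", "biomass")
    out$trace <- as.data.frame(tr[!is.na(tr[, 1]), , drop = FALSE])
  }
  structure(out, class = "season_outputs")
}

# Reference engine: the same season composed from the exported component
# operations on a crop_state environment.
simulate_season_reference <- function(gsps, weather, soil, mgmt, win) {
  sc <- mgmt$constants
  w <- weather[win, ]
  st <- crop_state(gsps, sc, mgmt$density,
                   max_days = mgmt$season_days + 10L)
  sw <- init_soil_water(soil)
  th <- soil$layers$thickness_cm
  tr <- if (mgmt$trace) vector("list", mgmt$season_days) else NULL
  supply_cum <- 0

  for (i in seq_len(nrow(w))) {
    day <- i - 30L
    tmean <- (w$tmax[i] + w$tmin[i]) / 2
    et0 <- priestley_taylor_et(w$srad[i], tmean)
    cover <- 1 - exp(-gsps[["KCAN"]] * st$lai)
    et <- et0 * (0.15 + 0.85 * cover)
    depth <- min(soil$depth_cm, 15 + 1.2 * max(0, day))
    rf <- root_weights(th, depth)
    sw <- step_water_balance(sw, soil, w$rain[i], et, root_frac = rf)
    if (day < 1) next

    st$day <- day
    stress <- if (mgmt$water_limited)
      drought_stress_factor(sw, soil, FALSE, mgmt$s, mgmt$s_g, rf) else 1
    dtt_leaf <- thermal_time(w$tmax[i], w$tmin[i], gsps[["TBLSZ"]])
    dtt_node <- thermal_time(w$tmax[i], w$tmin[i], sc$base_temp_branching)
    dtt_age <- thermal_time(w$tmax[i], w$tmin[i], sc$base_temp_leaf_aging)

    if (!st$germinated) {
      sg <- if (mgmt$water_limited)
        drought_stress_factor(sw, soil, TRUE, mgmt$s, mgmt$s_g, rf) else 1
      st$germ_tt <- st$germ_tt + dtt_node * sg
      if (st$germ_tt >= sc$germination_tt) {
        st$germinated <- TRUE
        k <- st$n_coh <- 1L
        st$co_n[k] <- st$apex_count
        st$co_area[k] <- sc$initial_leaf_area
        st$co_target[k] <- potential_leaf_size(0, gsps[["LAXS"]], sc)
        st$leaf_no_cum <- st$leaf_no_cum + st$apex_count
        lam <- st$co_n[k] * st$co_area[k] / gsps[["SLAS"]]
        st$mass_lamina <- lam
        st$mass_petiole <- lam * gsps[["LPEFR"]] / (1 - gsps[["LPEFR"]])
        st$mass_reserve <- sc$stake_reserve
        st$initial_biomass <- st$mass_lamina + st$mass_petiole +
          st$mass_reserve
        st$lai <- st$co_n[k] * st$co_area[k] / 1e4
        st$max_lai <- max(st$max_lai, st$lai)
      }
      if (mgmt$trace) tr[[day]] <- c(day, st$lai, stress, 0, 0, 0, 1,
                                     total_biomass(st))
      next
    }

    st$crop_age <- st$crop_age + dtt_leaf
    st$dtt_leaf <- dtt_leaf
    st$dtt_node <- dtt_node
    st$stress <- stress
    update_branching(st, dtt_node * stress, gsps)

    rate <- leaf_appearance_rate(st$crop_age, gsps[["LNSLP"]], sc)
    n_new <- st$apex_count * rate * dtt_leaf * stress
    if (n_new > 0) {
      k <- st$n_coh <- st$n_coh + 1L
      st$co_n[k] <- n_new
      st$co_created_age[k] <- st$crop_age
      st$co_leafno[k] <- st$leaf_no_cum / mgmt$density
      st$co_target[k] <- potential_leaf_size(st$crop_age, gsps[["LAXS"]], sc)
      st$leaf_no_cum <- st$leaf_no_cum + n_new
    }

    # leaves past their thermal expansion window stop growing and begin
    # aging toward senescence, regardless of realized area
    idx <- seq_len(st$n_coh)
    done <- idx[!st$co_expanded[idx] & !st$co_senesced[idx] &
                  st$co_leaf_age[idx] >= sc$leaf_expansion_dur]
    if (length(done)) st$co_expanded[done] <- TRUE

    dem <- compute_demand(st, gsps)
    supply <- daily_assimilation(w$srad[i], st$lai, gsps[["PARUE"]],
                                 gsps[["KCAN"]], sc$par_fraction) * stress
    # stake reserves cover early shortfall between demand and assimilation
    draw <- min(st$mass_reserve,
                max(0, dem$leaf + dem$stem + dem$fibrous - supply))
    st$mass_reserve <- st$mass_reserve - draw
    al <- allocate_spillover(supply + draw, dem)
    inc <- dem$pot_inc * al$ratio
    if (any(inc > 0)) {
      st$co_area[idx] <- st$co_area[idx] + inc
      st$lai <- st$lai + sum(inc * st$co_n[idx]) / 1e4
    }
    st$mass_lamina <- st$mass_lamina + al$leaf * (1 - gsps[["LPEFR"]])
    st$mass_petiole <- st$mass_petiole + al$leaf * gsps[["LPEFR"]]
    st$mass_stem <- st$mass_stem + al$stem
    st$mass_fibrous <- st$mass_fibrous + al$fibrous
    st$mass_storage <- st$mass_storage + al$storage
    supply_cum <- supply_cum + supply

    st$co_node_age[idx] <- st$co_node_age[idx] + dtt_node
    st$co_leaf_age[idx] <- st$co_leaf_age[idx] + dtt_leaf

    senesce(st, dtt_age, gsps[["LLIFA"]])
    st$max_lai <- max(st$max_lai, st$lai)

    if (!is.finite(total_biomass(st)) || !is.finite(st$lai))
      stop("non-finite crop state on day ", day)
    if (mgmt$trace) {
      tr[[day]] <- c(day, st$lai, stress, supply,
                     dem$leaf + dem$stem + dem$fibrous, al$storage,
                     al$ratio, total_biomass(st))
    }
  }

  out <- list(
    aboveground_biomass = 10 * (st$mass_lamina + st$mass_petiole +
                                  st$mass_stem + st$mass_dead),
    yield = 10 * st$mass_storage,
    max_lai = st$max_lai,
    leaves_at_harvest = st$leaf_no_cum / mgmt$density,
    day_first_branch = st$day_of_branch[1],
    day_second_branch = st$day_of_branch[2],
    assimilation_total = supply_cum,
    balance_residual = (total_biomass(st) - st$initial_biomass) -
      supply_cum,
    final_state = st)
  if (mgmt$trace) {
    m <- do.call(rbind, tr[!vapply(tr, is.null, logical(1))])
    colnames(m) <- c("day", "lai", "stress", "supply", "demand",
                     "storage_inc", "ratio", "biomass")
    out$trace <- as.data.frame(m)
  }
  structure(out, class = "season_outputs")
}

#' @export
print.season_outputs <- function(x, ...) {
  cat(sprintf(paste0(
    "<season_outputs>\n",
    "  aboveground biomass: %8.1f kg/ha\n",
    "  yield (storage root):%8.1f kg/ha\n",
    "  max LAI:             %8.2f\n",
    "  leaves at harvest:   %8.1f\n",
    "  day of 1st branch:   %8s\n",
    "  day of 2nd branch:   %8s\n"),
    x$aboveground_biomass, x$yield, x$max_lai, x$leaves_at_harvest,
    ifelse(is.na(x$day_first_branch), "-", x$day_first_branch),
    ifelse(is.na(x$day_second_branch), "-", x$day_second_branch)))
  invisible(x)
}

#' The six output variables as a numeric vector
#'
#' @param x A `season_outputs`.
#' @return Named numeric vector of the six analysis outputs; days to
#'   branching are `NA` when the level was never reached.
#' @export
season_output_vector <- function(x) {
  c(aboveground_biomass = x$aboveground_biomass, yield = x$yield,
    max_lai = x$max_lai, leaves_at_harvest = x$leaves_at_harvest,
    day_first_branch = x$day_first_branch,
    day_second_branch = x$day_second_branch)
}

OUTPUT_NAMES <- c("aboveground_biomass", "yield", "max_lai",
                  "leaves_at_harvest", "day_first_branch",
                  "day_second_branch")
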