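# Tipping-bucket soil water balance and the soil-water-content drought
# stress factor.

#' Layered soil profile
#'
#' @param layers Data frame with columns `thickness_cm`, `ll`, `dul`, `sat`
#'   (volumetric fractions, `0 < ll < dul < sat < 1` per layer).
#' @param runoff_curve SCS curve number (dimensionless, 30-100).
#' @param drainage_rate Fraction of water above the drained upper limit that
#'   drains per day.
#' @return Object of class `soil_profile`.
#' @export
soil_profile <- function(layers, runoff_curve = 75, drainage_rate = 0.4) {
  if (is.null(layers) || nrow(layers) == 0) stop("soil profile has no layers")
  need <- c("thickness_cm", "ll", "dul", "sat")
  if (!all(need %in% names(layers)))
    stop("layers need columns: ", paste(need, collapse = ", "))
  with(layers, {
    if (any(thickness_cm <= 0)) stop("layer thickness must be positive")
    if (any(!(0 < ll & ll < dul & dul < sat & sat < 1)))
      stop("each layer must satisfy 0 < ll < dul < sat < 1")
  })
  structure(list(layers = as.data.frame(layers)[, need],
                 runoff_curve = runoff_curve,
                 drainage_rate = drainage_rate,
                 depth_cm = sum(layers$thickness_cm)),
            class = "soil_profile")
}

#' Load a packaged synthetic soil profile
#'
#' Two plausible stand-in profiles are shipped (plain-text tables): a clayey
#' highland profile (`"cool"`) and a sandier lowland profile (`"warm"`).
#' They are synthetic constructions, not measured pedons.
#'
#' @param which `"cool"` or `"warm"`, or a path to a CSV in the same layout.
#' @return A [soil_profile()].
#' @export
load_soil <- function(which = c("cool", "warm")) {
  path <- if (file.exists(which[1])) which[1] else
    system.file("extdata", sprintf("soil_%s_synthetic.csv",
                                   match.arg(which)),
                package = "cassim", mustWork = TRUE)
  soil_profile(read.csv(path))
}

#' Initialise soil water at field capacity
#'
#' @param profile A [soil_profile()].
#' @return Object of class `soil_water_state`: per-layer volumetric water
#'   content (all at the drained upper limit) plus cumulative drainage,
#'   runoff and extraction in mm.
#' @export
init_soil_water <- function(profile) {
  stopifnot(inherits(profile, "soil_profile"))
  structure(list(water = profile$layers$dul,
                 cum_drainage = 0, cum_runoff = 0, cum_extraction = 0),
            class = "soil_water_state")
}

# mm of water held in each layer at volumetric content theta
layer_mm <- function(theta, thickness_cm) theta * thickness_cm * 10

#' Advance the soil water balance one day
#'
#' Rain is partitioned into SCS curve-number runoff and infiltration;
#' infiltration fills layers top-down to saturation (excess becomes runoff);
#' water above the drained upper limit percolates downward at
#' `drainage_rate` per day (bottom-layer percolation leaves the profile);
#' `et_demand` is then extracted, weighted by `root_frac`, never drawing a
#' layer below its lower limit. The daily mass balance
#' `rain = runoff + drainage + extraction + delta-storage` closes to
#' numerical precision.
#'
#' @param state A `soil_water_state`.
#' @param profile The matching [soil_profile()].
#' @param rain Daily rain, mm (>= 0).
#' @param et_demand Daily evapotranspiration demand, mm (>= 0).
#' @param root_frac Optional per-layer extraction weights (default: all
#'   layers, proportional to thickness).
#' @return Updated state, with attributes `runoff`, `drainage`,
#'   `extraction`, `infiltration` for the day (mm).
#' @export
step_water_balance <- function(state, profile, rain, et_demand,
                               root_frac = NULL) {
  stopifnot(inherits(state, "soil_water_state"),
            inherits(profile, "soil_profile"))
  if (rain < 0 || et_demand < 0) stop("rain and et_demand must be >= 0")
  ly <- profile$layers
  th <- ly$thickness_cm
  w <- layer_mm(state$water, th)          # mm per layer
  ll <- layer_mm(ly$ll, th)
  dul <- layer_mm(ly$dul, th)
  sat <- layer_mm(ly$sat, th)

  # curve-number runoff
  runoff <- 0
  if (rain > 0) {
    S <- 25400 / profile$runoff_curve - 254
    if (rain > 0.2 * S) runoff <- (rain - 0.2 * S)^2 / (rain + 0.8 * S)
  }
  inf <- rain - runoff

  # infiltration fills layers top-down to saturation
  for (i in seq_along(w)) {
    if (inf <= 0) break
    room <- sat[i] - w[i]
    add <- min(inf, room)
    w[i] <- w[i] + add
    inf <- inf - add
  }
  runoff <- runoff + inf                   # saturated-profile excess
  infiltration <- rain - runoff

  # drainage cascade: water above DUL moves down at drainage_rate/day
  drained_out <- 0
  for (i in seq_along(w)) {
    excess <- max(0, w[i] - dul[i])
    flux <- profile$drainage_rate * excess
    w[i] <- w[i] - flux
    if (i < length(w)) {
      take <- min(flux, sat[i + 1] - w[i + 1])
      w[i + 1] <- w[i + 1] + take
      w[i] <- w[i] + (flux - take)         # backed up: stays put
    } else {
      drained_out <- flux
    }
  }

  # root-weighted extraction, capped at the lower limit per layer
  if (is.null(root_frac)) root_frac <- th / sum(th)
  root_frac <- root_frac / max(sum(root_frac), 1e-12)
  extracted <- 0
  if (et_demand > 0) {
    want <- et_demand * root_frac
    avail <- pmax(0, w - ll)
    take <- pmin(want, avail)
    # one redistribution pass: unmet demand retried on remaining water
    unmet <- et_demand - sum(take)
    if (unmet > 1e-12) {
      avail2 <- avail - take
      if (sum(avail2) > 0) {
        take <- take + pmin(unmet * avail2 / sum(avail2), avail2)
      }
    }
    w <- w - take
    extracted <- sum(take)
  }

  out <- structure(list(water = w / (th * 10),
                        cum_drainage = state$cum_drainage + drained_out,
                        cum_runoff = state$cum_runoff + runoff,
                        cum_extraction = state$cum_extraction + extracted),
                   class = "soil_water_state")
  attr(out, "runoff") <- runoff
  attr(out, "drainage") <- drained_out
  attr(out, "extraction") <- extracted
  attr(out, "infiltration") <- infiltration
  out
}

#' Drought stress factor from soil water content
#'
#' A linear ramp on the root-zone plant-available-water fraction:
#' `clamp(paw / s, 0, 1)` where `paw = (theta - ll) / (dul - ll)` averaged
#' (thickness-weighted) over the root zone. Germination uses its own, more
#' tolerant sensitivity `s_g`; every other process (leaf appearance,
#' branching, leaf size, biomass increase) shares `s`. The factor is 1 at
#' field capacity and 0 at the lower limit.
#'
#' @param state A `soil_water_state`.
#' @param profile The matching [soil_profile()].
#' @param germination Use the germination sensitivity?
#' @param s Shared sensitivity threshold (default 1.0).
#' @param s_g Germination sensitivity threshold (default 0.6).
#' @param root_frac Optional per-layer weights (default thickness-weighted).
#' @return Factor in \[0, 1\].
#' @export
drought_stress_factor <- function(state, profile, germination = FALSE,
                                  s = 1.0, s_g = 0.6, root_frac = NULL) {
  ly <- profile$layers
  if (is.null(root_frac)) root_frac <- ly$thickness_cm
  root_frac <- root_frac / sum(root_frac)
  paw <- sum(root_frac * (state$water - ly$ll) / (ly$dul - ly$ll))
  sens <- if (germination) s_g else s
  min(1, max(0, paw / sens))
}

# Priestley-Taylor reference evapotranspiration (mm/day) from solar
# radiation (MJ m-2 day-1) and mean temperature (C); alpha = 1.26.
priestley_taylor_et <- function(srad, tmean, alpha = 1.26) {
  es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))
  delta <- 4098 * es / (tmean + 237.3)^2
  gam <- 0.0665
  rn <- pmax(0, 0.75 * srad - 1.2)         # crude net radiation
  pmax(0, alpha * delta / (delta + gam) * rn / 2.45)
}
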