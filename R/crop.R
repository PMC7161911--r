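# Cassava crop model: species-level constants and the component processes
# (branching, leaf appearance and size, node growth, light capture,
# assimilate demand, spill-over allocation, senescence). The daily
# orchestration lives in simulate.R.

#' Species-level constants of the crop model
#'
#' Functional forms the genotype parameters plug into. These are fixed for
#' the species and centralised here: the saturation leaf-appearance curve
#' `rate = r0 / (1 + age/h)`, the logistic node-mass curve (steepness,
#' midpoint, midpoint shift per leaf number at node creation), the potential
#' leaf-size ramp (fraction of maximum at planting, peak age, post-peak
#' exponential decline), the leaf expansion duration, the PAR fraction of
#' global radiation, the fibrous-root gross-up, and the base temperatures
#' for branching and leaf aging (leaf development uses the genotype's
#' TBLSZ).
#'
#' @param ... Named overrides of any default.
#' @return Named list of constants.
#' @export
species_constants <- function(...) {
  sc <- list(
    leaf_size_peak_age = 900,    # Cd: crop age of maximum potential leaf size
    leaf_size_f0 = 0.2,          # fraction of LAXS at planting
    leaf_size_decline = 5e-4,    # per Cd beyond the peak (5% per 100 Cd)
    leaf_app_r0 = 0.025,         # nodes per Cd per apex at age 0
    leaf_app_h = 900,            # Cd: half-decay age of the appearance curve
    leaf_expansion_dur = 100,    # Cd for a leaf to reach its target area
    node_logistic_k = 0.02,      # per Cd: steepness of node mass logistic
    node_logistic_mid = 250,     # Cd: midpoint at leaf number 0
    node_mid_per_leaf = 2,       # Cd midpoint shift per leaf at creation
    fibrous_root_fraction = 0.10,
    par_fraction = 0.5,          # PAR fraction of global solar radiation
    base_temp_branching = 13,    # C
    base_temp_leaf_aging = 13,   # C
    germination_tt = 10,         # Cd (branching base) planting -> emergence
    initial_leaf_area = 2,       # cm2: bootstrap leaf area from the stake
    stake_reserve = 15,          # g m-2: stake reserves fuelling early growth
    max_branch_level = 4L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(sc))
  if (length(bad)) stop("unknown species constant(s): ",
                        paste(bad, collapse = ", "))
  sc[names(over)] <- over
  sc
}

#' Create an empty crop state
#'
#' The state is an environment (reference semantics) so the daily update
#' operations can mutate it in place; cohort attributes are held in
#' pre-allocated parallel vectors.
#'
#' @param gsps A [gsp_set()].
#' @param constants [species_constants()].
#' @param density Plants per square metre.
#' @param max_days Pre-allocation size for cohort vectors.
#' @return Environment of class `crop_state`.
#' @export
crop_state <- function(gsps, constants = species_constants(), density = 1,
                       max_days = 400L) {
  st <- new.env(parent = emptyenv())
  st$gsps <- gsps
  st$constants <- constants
  st$density <- density
  st$day <- 0L                 # days after planting
  st$germinated <- FALSE
  st$germ_tt <- 0
  st$crop_age <- 0             # Cd, leaf-development base (TBLSZ)
  st$branch_tt <- 0            # Cd, branching base
  st$branch_level <- 0L
  st$apex_count <- density     # apices per m2
  st$day_of_branch <- rep(NA_real_, constants$max_branch_level)
  st$leaf_no_cum <- 0          # cumulative nodes per m2
  st$lai <- 0
  st$max_lai <- 0
  # cohort ledger (parallel vectors)
  st$n_coh <- 0L
  st$co_n <- numeric(max_days)          # nodes per m2
  st$co_created_age <- numeric(max_days)
  st$co_leafno <- numeric(max_days)     # leaves/plant when cohort appeared
  st$co_node_age <- numeric(max_days)   # Cd, branching base
  st$co_leaf_age <- numeric(max_days)   # Cd, leaf-development base (TBLSZ)
  st$co_area <- numeric(max_days)       # cm2 per leaf, current
  st$co_target <- numeric(max_days)     # cm2 per leaf, potential
  st$co_expanded <- logical(max_days)
  st$co_age_post <- numeric(max_days)   # Cd since full expansion
  st$co_senesced <- logical(max_days)
  # biomass pools, g per m2
  st$mass_lamina <- 0
  st$mass_petiole <- 0
  st$mass_stem <- 0
  st$mass_fibrous <- 0
  st$mass_storage <- 0
  st$mass_dead <- 0
  st$mass_reserve <- 0         # unspent stake reserve
  st$initial_biomass <- 0
  # per-day thermal increments and stress, set by the driver
  st$dtt_leaf <- 0
  st$dtt_node <- 0
  st$stress <- 1
  class(st) <- "crop_state"
  st
}

total_biomass <- function(st) {
  st$mass_lamina + st$mass_petiole + st$mass_stem + st$mass_fibrous +
    st$mass_storage + st$mass_dead + st$mass_reserve
}

#' Advance branching phenology
#'
#' The crop forks from level L to L+1 when cumulative branching thermal time
#' reaches `B01ND + L * B12ND` (first fork at B01ND, then a constant B12ND
#' interval), up to four levels. At each fork the apex count multiplies by
#' the (rounded) branches-per-fork parameter of that level and the day is
#' recorded.
#'
#' @param state A [crop_state()] (germinated).
#' @param daily_tt_branching Daily thermal time at the branching base, Cd.
#' @param gsps A [gsp_set()].
#' @return The state, invisibly (mutated in place).
#' @export
update_branching <- function(state, daily_tt_branching, gsps) {
  state$branch_tt <- state$branch_tt + daily_tt_branching
  brf <- c(gsps["BR1F"], gsps["BR2F"], gsps["BR3F"], gsps["BR4F"])
  while (state$branch_level < state$constants$max_branch_level &&
         state$branch_tt >=
           gsps["B01ND"] + state$branch_level * gsps["B12ND"]) {
    state$branch_level <- state$branch_level + 1L
    state$apex_count <- state$apex_count *
      max(1, round(brf[state$branch_level]))
    state$day_of_branch[state$branch_level] <- state$day
  }
  invisible(state)
}

#' Leaf (node) appearance rate per apex
#'
#' A saturation-decay curve scaled by the genotype's slope index:
#' `LNSLP * r0 / (1 + age/h)` nodes per degree-day per apex; strictly
#' positive and non-increasing in crop age.
#'
#' @param crop_thermal_age Crop age, Cd (leaf-development base), >= 0.
#' @param LNSLP Slope index relative to the reference curve.
#' @param constants [species_constants()].
#' @return Nodes per Cd per apex.
#' @export
leaf_appearance_rate <- function(crop_thermal_age, LNSLP,
                                 constants = species_constants()) {
  if (any(crop_thermal_age < 0)) stop("negative crop age")
  LNSLP * constants$leaf_app_r0 /
    (1 + crop_thermal_age / constants$leaf_app_h)
}

#' Potential size of a leaf initiated at a given crop age
#'
#' Ramps linearly from `f0 * LAXS` at planting to `LAXS` at the peak age
#' (900 Cd), then declines exponentially; continuous at the peak.
#'
#' @param crop_thermal_age Crop age, Cd, >= 0 (vectorised).
#' @param LAXS Maximum individual leaf area, cm2.
#' @param constants [species_constants()].
#' @return Potential leaf area, cm2.
#' @export
potential_leaf_size <- function(crop_thermal_age, LAXS,
                                constants = species_constants()) {
  if (any(crop_thermal_age < 0)) stop("negative crop age")
  peak <- constants$leaf_size_peak_age
  f0 <- constants$leaf_size_f0
  ifelse(crop_thermal_age <= peak,
         LAXS * (f0 + (1 - f0) * crop_thermal_age / peak),
         LAXS * exp(-constants$leaf_size_decline *
                      (crop_thermal_age - peak)))
}

#' Node (stem unit) growth rate
#'
#' Derivative of a logistic mass curve with asymptote `NODWT`; the midpoint
#' shifts later for nodes created when the plant already carries many
#' leaves. Integrated over node age the curve delivers `NODWT` (to < 1%).
#'
#' @param node_thermal_age Node age, Cd (vectorised).
#' @param leaf_no_at_creation Cumulative leaves per plant when the node
#'   appeared.
#' @param NODWT Individual node weight asymptote, g.
#' @param constants [species_constants()].
#' @return Growth rate, g per Cd.
#' @export
node_growth_rate <- function(node_thermal_age, leaf_no_at_creation, NODWT,
                             constants = species_constants()) {
  k <- constants$node_logistic_k
  t0 <- constants$node_logistic_mid +
    constants$node_mid_per_leaf * leaf_no_at_creation
  e <- exp(-k * (node_thermal_age - t0))
  k * NODWT * e / (1 + e)^2
}

#' Daily canopy assimilation
#'
#' Beer's-law light interception times radiation use efficiency:
#' `A = par_fraction * srad * (1 - exp(-KCAN * lai)) * PARUE`.
#'
#' @param srad Daily solar radiation, MJ m-2.
#' @param lai Leaf area index, m2 m-2.
#' @param PARUE Radiation use efficiency, g dry matter per MJ PAR.
#' @param KCAN PAR extinction coefficient.
#' @param par_fraction PAR fraction of global radiation (default 0.5).
#' @return Assimilation, g dry matter m-2 day-1.
#' @export
daily_assimilation <- function(srad, lai, PARUE, KCAN, par_fraction = 0.5) {
  stopifnot(srad >= 0, lai >= 0, PARUE >= 0, KCAN >= 0)
  par_fraction * srad * (1 - exp(-KCAN * lai)) * PARUE
}

#' Potential assimilate demand of the standing crop
#'
#' Stem demand sums the node logistic growth over all cohorts; leaf demand
#' converts the day's potential leaf-area increments to mass through the
#' specific leaf area (`mass = area / SLAS`) and grosses lamina up by the
#' petiole fraction (`petiole = LPEFR * (lamina + petiole)`); fibrous-root
#' demand is a fixed 10% of leaf plus stem. A leaf expands for a fixed
#' thermal window (`leaf_expansion_dur`) after its cohort appears; under
#' assimilate shortage it simply ends up smaller. Uses the day's thermal
#' increments and stress factor stored on the state by the season driver.
#'
#' @param state A [crop_state()].
#' @param gsps A [gsp_set()].
#' @return List with `leaf`, `stem`, `fibrous` demands (g m-2 day-1), the
#'   `lamina` share of leaf demand, and the per-cohort potential area
#'   increments (`pot_inc`, cm2 per leaf) used by the allocator.
#' @export
compute_demand <- function(state, gsps) {
  n <- state$n_coh
  if (n == 0L) {
    return(list(leaf = 0, stem = 0, fibrous = 0, lamina = 0,
                pot_inc = numeric(0)))
  }
  sc <- state$constants
  idx <- seq_len(n)
  live <- !state$co_senesced[idx]
  # leaf lamina: expanding live cohorts progress toward their target area
  pot_inc <- numeric(n)
  exp_idx <- idx[live & !state$co_expanded[idx]]
  if (length(exp_idx)) {
    step <- state$co_target[exp_idx] / sc$leaf_expansion_dur *
      state$dtt_leaf * state$stress
    pot_inc[exp_idx] <- pmin(step, state$co_target[exp_idx] -
                               state$co_area[exp_idx])
  }
  lamina <- sum(pot_inc[exp_idx] * state$co_n[exp_idx]) / gsps[["SLAS"]]
  leaf <- lamina / (1 - gsps[["LPEFR"]])
  rates <- node_growth_rate(state$co_node_age[idx], state$co_leafno[idx],
                            gsps[["NODWT"]], sc)
  stem <- sum(rates * state$co_n[idx]) * state$dtt_node
  fibrous <- sc$fibrous_root_fraction * (leaf + stem)
  list(leaf = leaf, stem = stem, fibrous = fibrous, lamina = lamina,
       pot_inc = pot_inc)
}

#' Spill-over allocation of daily assimilate
#'
#' Aboveground organs and fibrous roots are served first: when supply covers
#' total demand every organ receives its demand and the surplus goes to
#' storage roots; when it does not, every organ is scaled by the common
#' ratio `supply / total demand` and storage roots receive nothing.
#'
#' @param supply Daily assimilation, g m-2 (>= 0).
#' @param demands Named numeric/list with `leaf`, `stem`, `fibrous` (>= 0).
#' @return List `leaf`, `stem`, `fibrous`, `storage` increments plus the
#'   scaling `ratio` applied to demands.
#' @export
allocate_spillover <- function(supply, demands) {
  d <- c(leaf = demands[["leaf"]], stem = demands[["stem"]],
         fibrous = demands[["fibrous"]])
  if (supply < 0 || any(d < 0)) stop("supply and demands must be >= 0")
  total <- sum(d)
  if (supply >= total) {
    ratio <- 1
    storage <- supply - total
  } else {
    ratio <- if (total > 0) supply / total else 1
    storage <- 0
  }
  list(leaf = d[["leaf"]] * ratio, stem = d[["stem"]] * ratio,
       fibrous = d[["fibrous"]] * ratio, storage = storage, ratio = ratio)
}

#' Senesce leaves past their thermal lifetime
#'
#' Advances the post-expansion age of fully expanded cohorts and marks those
#' strictly beyond `LLIFA` as senesced: their area leaves the LAI and their
#' lamina and petiole mass move to the dead pool (still counted in
#' aboveground biomass).
#'
#' @param state A [crop_state()].
#' @param daily_tt_leaf_age Daily thermal time at the leaf-aging base, Cd.
#' @param LLIFA Leaf life after full expansion, Cd.
#' @return The state, invisibly (mutated in place).
#' @export
senesce <- function(state, daily_tt_leaf_age, LLIFA) {
  n <- state$n_coh
  if (n == 0L) return(invisible(state))
  idx <- seq_len(n)
  act <- idx[state$co_expanded[idx] & !state$co_senesced[idx]]
  if (length(act)) {
    state$co_age_post[act] <- state$co_age_post[act] + daily_tt_leaf_age
    dead <- act[state$co_age_post[act] > LLIFA]
    if (length(dead)) {
      gsps <- state$gsps
      area <- state$co_area[dead] * state$co_n[dead]       # cm2 m-2
      lam <- sum(area) / gsps[["SLAS"]]
      pet <- lam * gsps[["LPEFR"]] / (1 - gsps[["LPEFR"]])
      state$co_senesced[dead] <- TRUE
      state$lai <- max(0, state$lai - sum(area) / 1e4)
      state$mass_lamina <- state$mass_lamina - lam
      state$mass_petiole <- state$mass_petiole - pet
      state$mass_dead <- state$mass_dead + lam + pet
    }
  }
  invisible(state)
}
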