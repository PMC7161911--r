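# Experiment orchestration: the four-treatment (warm/cool x
# rainfed/unlimited) screening and Sobol analyses over multi-year synthetic
# weather, plus report table writers.

#' Configure a GSUA experiment
#'
#' The `"full"` preset mirrors the reference protocol (30 years, 24
#' screening trajectories over 16 parameters at 8 levels, Sobol base sample
#' 512); the `"desk"` preset is the scaled-down configuration used for
#' development and testing (5 years, 8 trajectories, base sample 64).
#'
#' @param scale `"desk"` or `"full"` preset, setting defaults below.
#' @param sites Named list of [site_profile()]s (default [default_sites()]).
#' @param regimes Water regimes to cross with sites.
#' @param years Simulation years per treatment.
#' @param esu List `k`, `levels`, `r`, `pool_size` for the screening design.
#' @param sobol List `n` (base sample size).
#' @param seeds List `weather`, `esu`, `sobol` integer seeds.
#' @param config GSP distribution table ([gsp_config()]).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(scale = c("desk", "full"),
                              sites = default_sites(),
                              regimes = c("rainfed", "unlimited"),
                              years = NULL, esu = list(), sobol = list(),
                              seeds = list(), config = gsp_config()) {
  scale <- match.arg(scale)
  full <- scale == "full"
  years <- years %||% if (full) 30L else 5L
  esu_def <- list(k = nrow(config), levels = 8L,
                  r = if (full) 24L else 8L, pool_size = 500L)
  esu_def[names(esu)] <- esu
  sobol_def <- list(n = if (full) 512L else 64L)
  sobol_def[names(sobol)] <- sobol
  seeds_def <- list(weather = 101L, esu = 202L, sobol = 303L)
  seeds_def[names(seeds)] <- seeds
  stopifnot(years >= 1)
  if (!full && (years > 5 || esu_def$r > 8 || sobol_def$n > 128))
    stop("desk preset requires years <= 5, r <= 8, n <= 128")
  structure(list(scale = scale, sites = sites, regimes = regimes,
                 years = as.integer(years), esu = esu_def,
                 sobol = sobol_def, seeds = seeds_def, gsp = config),
            class = "experiment_config")
}

# short deterministic hash of a configuration (djb2 over its deparse)
config_hash <- function(cfg) {
  s <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 5381
  for (c in s) h <- (h * 33 + c) %% 2^31
  sprintf("%08x", h)
}

treatment_grid <- function(cfg) {
  g <- expand.grid(site = names(cfg$sites), regime = cfg$regimes,
                   stringsAsFactors = FALSE)
  g$name <- paste(g$site, g$regime, sep = "_")
  g
}

# Evaluate a GSP parameter matrix for one treatment: simulate every row for
# every year and return the across-year means (rows x 6 outputs). Days to
# branching are censored at the season length when never reached. With
# per_year = TRUE the full rows x outputs x years array is also returned.
evaluate_rows <- function(params, weather, soil, years, water_limited,
                          season_days = SEASON_DAYS, per_year = FALSE) {
  wy <- unique(as.integer(format(weather$date, "%Y")))
  stopifnot(length(wy) >= years)
  arr <- array(NA_real_, c(nrow(params), length(OUTPUT_NAMES), years),
               dimnames = list(NULL, OUTPUT_NAMES, NULL))
  gs <- lapply(seq_len(nrow(params)), function(r) gsp_set(params[r, ]))
  for (y in seq_len(years)) {
    mg <- mgmt_options(year = wy[y], water_limited = water_limited,
                       season_days = season_days)
    win <- season_window(weather, mg)
    forcing <- season_forcing(weather, soil, mg, win)
    for (r in seq_len(nrow(params))) {
      out <- tryCatch(
        simulate_season_fast(gs[[r]], weather, soil, mg, win, forcing),
        error = function(e)
          stop("simulation failed at row ", r, ", year ", wy[y], ": ",
               conditionMessage(e)))
      v <- season_output_vector(out)
      v[is.na(v)] <- season_days          # censored: branch never appeared
      arr[r, , y] <- v
    }
  }
  res <- list(means = apply(arr, c(1, 2), mean))
  if (per_year) res$per_year <- arr
  res
}

treatment_weather <- function(cfg) {
  # one extra calendar year: a season planted at day 115 runs into the next
  lapply(names(cfg$sites), function(s) {
    generate_weather(cfg$sites[[s]], cfg$years + 1L,
                     seed = cfg$seeds$weather + match(s, names(cfg$sites)))
  }) |> setNames(names(cfg$sites))
}

#' Run the elementary-effects screening experiment
#'
#' Builds one screening design over all GSPs, maps it through the packaged
#' distributions, simulates every design row for every treatment and year,
#' averages outputs across years, computes elementary effects per treatment
#' and output, normalizes them jointly across the four treatments, and
#' applies the importance selection rule. Deterministic given the seeds.
#'
#' @param cfg An [experiment_config()].
#' @param threshold Selection threshold (default 0.5).
#' @return List (class `screening_results`): `design`, `params` (mapped
#'   values), `means` per treatment, `effects`, `normalized` (long table),
#'   `selected`, `provenance`.
#' @export
run_screening <- function(cfg, threshold = 0.5) {
  stopifnot(inherits(cfg, "experiment_config"))
  dists <- gsp_distributions(cfg$gsp)
  design <- build_esu_design(cfg$esu$k, cfg$esu$levels, cfg$esu$r,
                             cfg$esu$pool_size, seed = cfg$seeds$esu)
  params <- map_to_parameters(design, dists)
  wx <- treatment_weather(cfg)
  tg <- treatment_grid(cfg)
  means <- list()
  effects <- list()
  for (t in seq_len(nrow(tg))) {
    site <- tg$site[t]
    ev <- evaluate_rows(params, wx[[site]], load_soil(site), cfg$years,
                        water_limited = tg$regime[t] == "rainfed")
    means[[tg$name[t]]] <- ev$means
    effects[[tg$name[t]]] <- lapply(
      setNames(OUTPUT_NAMES, OUTPUT_NAMES),
      function(o) elementary_effects(design, ev$means[, o],
                                     params = colnames(params)))
  }
  normalized <- normalize_effects(effects)
  selected <- select_important(normalized, threshold)
  structure(list(design = design, params = params, means = means,
                 effects = effects, normalized = normalized,
                 selected = selected,
                 provenance = list(hash = config_hash(cfg),
                                   seeds = cfg$seeds, scale = cfg$scale,
                                   years = cfg$years)),
            class = "screening_results")
}

#' Run the Sobol uncertainty and sensitivity experiment
#'
#' Builds a Saltelli design over the selected GSPs (the others held at
#' their distribution medians), simulates all rows per treatment, and
#' estimates first/total-order indices plus uncertainty summaries per
#' output and treatment.
#'
#' @param cfg An [experiment_config()].
#' @param selected Character vector of GSP names (e.g. from
#'   [run_screening()]). Must be non-empty.
#' @return List (class `sobol_results`): `design`, `params`, `indices`
#'   (long data frame), `summaries` (nested list treatment -> output),
#'   `fixed` (medians used for unselected GSPs), `provenance`.
#' @export
run_sobol <- function(cfg, selected) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (length(selected) == 0) stop("empty parameter selection")
  dists <- gsp_distributions(cfg$gsp)
  if (!all(selected %in% names(dists)))
    stop("unknown GSP(s) in selection")
  med <- gsp_medians(cfg$gsp)
  design <- build_sobol_design(length(selected), cfg$sobol$n,
                               seed = cfg$seeds$sobol)
  sub <- dists[selected]
  attr(sub, "integer") <- attr(dists, "integer")[selected]
  mapped <- map_to_parameters(design, sub)
  # full parameter matrix: unselected columns fixed at medians
  params <- matrix(rep(med, each = nrow(mapped)), nrow(mapped),
                   length(med), dimnames = list(NULL, names(med)))
  params[, selected] <- mapped
  wx <- treatment_weather(cfg)
  tg <- treatment_grid(cfg)
  indices <- list()
  summaries <- list()
  for (t in seq_len(nrow(tg))) {
    site <- tg$site[t]
    ev <- evaluate_rows(params, wx[[site]], load_soil(site), cfg$years,
                        water_limited = tg$regime[t] == "rainfed",
                        per_year = TRUE)
    mc <- design$block %in% c("A", "B")   # plain Monte Carlo rows
    summaries[[tg$name[t]]] <- lapply(
      setNames(OUTPUT_NAMES, OUTPUT_NAMES), function(o)
        uncertainty_summary(ev$per_year[mc, o, , drop = TRUE]))
    for (o in OUTPUT_NAMES) {
      si <- estimate_indices(design, ev$means[, o], params = selected)
      si$output <- o
      si$treatment <- tg$name[t]
      indices[[paste(tg$name[t], o)]] <- as.data.frame(si)
    }
  }
  structure(list(design = design, params = params,
                 indices = do.call(rbind, indices),
                 summaries = summaries, fixed = med[setdiff(names(med),
                                                            selected)],
                 selected = selected,
                 provenance = list(hash = config_hash(cfg),
                                   seeds = cfg$seeds, scale = cfg$scale,
                                   years = cfg$years)),
            class = "sobol_results")
}

#' Write report tables for a GSUA experiment
#'
#' Emits delimited analogs of the study's figures and tables: the
#' normalized-effects table, the Sobol index table, a CV table (six outputs
#' by treatments), CDF curves, and the screening-vs-Sobol scatter with its
#' least-squares fit per output.
#'
#' @param screening A `screening_results` (or `NULL`).
#' @param sobol A `sobol_results` (or `NULL`).
#' @param dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
report_gsua <- function(screening = NULL, sobol = NULL, dir = ".") {
  if (is.null(screening) && is.null(sobol)) stop("nothing to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(screening)) {
    wr(screening$normalized, "effects_normalized.csv")
    wr(data.frame(parameter = screening$selected), "selected_gsps.csv")
  }
  if (!is.null(sobol)) {
    wr(sobol$indices, "sobol_indices.csv")
    cv <- do.call(rbind, lapply(names(sobol$summaries), function(tt)
      data.frame(treatment = tt, output = OUTPUT_NAMES,
                 mean = vapply(sobol$summaries[[tt]], `[[`, 1, "mean"),
                 sd = vapply(sobol$summaries[[tt]], `[[`, 1, "sd"),
                 cv = vapply(sobol$summaries[[tt]], `[[`, 1, "cv"))))
    wr(cv, "cv_table.csv")
    cdf <- do.call(rbind, lapply(names(sobol$summaries), function(tt)
      do.call(rbind, lapply(OUTPUT_NAMES, function(o)
        cbind(treatment = tt, output = o,
              sobol$summaries[[tt]][[o]]$cdf)))))
    wr(cdf, "cdf_curves.csv")
  }
  if (!is.null(screening) && !is.null(sobol)) {
    sel <- sobol$selected
    sc <- list()
    fits <- list()
    for (tt in names(screening$effects)) {
      for (o in OUTPUT_NAMES) {
        mu <- screening$effects[[tt]][[o]]$mu_star[sel]
        st <- sobol$indices[sobol$indices$treatment == tt &
                              sobol$indices$output == o, ]
        st <- st$S_total[match(sel, st$parameter)]
        sc[[paste(tt, o)]] <- data.frame(treatment = tt, output = o,
                                         parameter = sel, mu_star = mu,
                                         s_total = st)
        fit <- try(compare_methods(mu, st), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          fits[[paste(tt, o)]] <- data.frame(
            treatment = tt, output = o, slope = fit$slope,
            intercept = fit$intercept, r_squared = fit$r_squared)
        }
      }
    }
    wr(do.call(rbind, sc), "mu_star_vs_s_total.csv")
    if (length(fits)) wr(do.call(rbind, fits), "method_comparison_fits.csv")
  }
  prov <- (screening %||% sobol)$provenance
  writeLines(c(sprintf("config_hash: %s", prov$hash),
               sprintf("scale: %s", prov$scale),
               sprintf("years: %d", prov$years),
               sprintf("seeds: weather=%d esu=%d sobol=%d",
                       prov$seeds$weather, prov$seeds$esu,
                       prov$seeds$sobol)),
             file.path(dir, "provenance.txt"))
  invisible(c(files, file.path(dir, "provenance.txt")))
}
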