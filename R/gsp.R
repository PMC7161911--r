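# Genotype-specific parameters (GSPs): packaged distribution table, loaders,
# and the validated parameter set consumed by the simulator.

GSP_NAMES <- c("B01ND", "B12ND", "LAXS", "SLAS", "LLIFA", "LPEFR", "LNSLP",
               "NODWT", "NODL", "PARUE", "TBLSZ", "BR1F", "BR2F", "BR3F",
               "BR4F", "KCAN")

#' Load a GSP distribution configuration table
#'
#' Reads a delimited configuration describing one probability distribution
#' per genotype-specific parameter (family, family parameters, optional
#' truncation, integer flag). With no argument the packaged default table of
#' the 16 cassava GSPs is returned.
#'
#' @param path Optional path to a CSV in the packaged layout.
#' @return Data frame with one row per GSP (class `gsp_config`).
#' @export
gsp_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gsp_distributions.csv",
                                package = "cassim", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gsp", "family", "p1", "p2", "p3", "left_kind", "left",
            "right_kind", "right", "integer")
  if (!all(need %in% names(df)))
    stop("gsp config is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  class(df) <- c("gsp_config", class(df))
  df
}

# one config row -> dist_spec
row_to_spec <- function(row) {
  pn <- family_params(row$family)
  pv <- as.numeric(row[paste0("p", seq_along(pn))])
  params <- as.list(setNames(pv, pn))
  tr <- NULL
  if (!is.na(row$left_kind) && nzchar(row$left_kind)) {
    tr <- truncation_rule(row$left_kind, as.numeric(row$left),
                          row$right_kind, as.numeric(row$right))
  }
  do.call(dist_spec, c(list(family = row$family), params,
                       list(truncation = tr)))
}

#' Build truncated distributions for every GSP in a configuration
#'
#' @param config A [gsp_config()] data frame (default: packaged table).
#' @return Named list of `trunc_dist`, one per GSP, with an `integer`
#'   attribute (logical vector) marking parameters mapped to whole numbers.
#' @export
gsp_distributions <- function(config = gsp_config()) {
  dists <- lapply(seq_len(nrow(config)), function(i)
    make_distribution(row_to_spec(config[i, , drop = FALSE])))
  names(dists) <- config$gsp
  attr(dists, "integer") <- setNames(config$integer == 1, config$gsp)
  dists
}

#' Median parameter values of the packaged GSP distributions
#'
#' Used as the nominal parameter vector (e.g. to fix parameters excluded
#' from a Sobol design). Integer-flagged GSPs are rounded.
#'
#' @inheritParams gsp_distributions
#' @return Named numeric vector.
#' @export
gsp_medians <- function(config = NULL) {
  if (is.null(config)) {                  # memoized default table
    if (is.null(.cassim_cache$medians)) {
      .cassim_cache$medians <- gsp_medians(gsp_config())
    }
    return(.cassim_cache$medians)
  }
  dists <- gsp_distributions(config)
  med <- vapply(dists, function(d) quantile(d, 0.5), numeric(1))
  int <- attr(dists, "integer")
  med[int] <- round(med[int])
  med
}

.cassim_cache <- new.env(parent = emptyenv())

#' Construct a validated GSP set
#'
#' @param ... Named GSP values, or a single named vector/list. Missing
#'   entries default to the packaged distribution medians.
#' @return Named numeric vector of all 16 GSPs (class `gsp_set`).
#' @examples
#' gsp_set(PARUE = 1.6, B01ND = 764)
#' @export
gsp_set <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) &&
      (is.numeric(args[[1]]) || is.list(args[[1]]))) {
    args <- as.list(args[[1]])
  }
  vals <- gsp_medians()
  if (length(args)) {
    bad <- setdiff(names(args), GSP_NAMES)
    if (length(bad)) stop("unknown GSP(s): ", paste(bad, collapse = ", "))
    vals[names(args)] <- unlist(args)
  }
  if (any(vals <= 0)) stop("all GSPs must be positive")
  br <- vals[c("BR1F", "BR2F", "BR3F", "BR4F")]
  if (any(br < 1 | br > 4)) stop("BR1F-BR4F must lie in [1, 4]")
  if (vals["LPEFR"] <= 0 || vals["LPEFR"] >= 1)
    stop("LPEFR must lie in (0, 1)")
  structure(vals, class = c("gsp_set", "numeric"))
}
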