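#' Canopy area of a city assessment
#'
#' The canopy area attributed to a city assessment is its assessment area
#' multiplied by the canopy fraction of the RU it sits in, as estimated by
#' the national point-sampling survey. A city carrying a canopy-area
#' override (the external surrogate city, whose canopy came from its own
#' satellite estimate) returns the override unchanged.
#'
#' @param city one-row data frame (a row of [load_city_table()]).
#' @param ru matching RU row from [load_ru_table()], or `NULL` when the city
#'   carries an override.
#' @return canopy area in hectares.
#' @examples
#' ru <- load_ru_table(); cities <- load_city_table()
#' hfx <- cities[cities$name == "Halifax", ]
#' city_canopy_area(hfx, ru[ru$ru_id == hfx$ru_id, ])  # 69270 * 0.500
#' @export
city_canopy_area <- function(city, ru = NULL) {
  stopifnot(nrow(city) == 1L)
  ovr <- city$canopy_area_override_ha
  if (!is.null(ovr) && length(ovr) == 1L && !is.na(ovr)) return(ovr)
  if (is.null(ru) || nrow(ru) != 1L) {
    stop("city '", city$name, "' has neither an RU assignment nor a canopy ",
         "override", call. = FALSE)
  }
  city$assessment_area_ha * ru$canopy_fraction
}

city_canopy_areas <- function(cities, ru) {
  vapply(seq_len(nrow(cities)), function(i) {
    row <- cities[i, , drop = FALSE]
    city_canopy_area(row, ru[ru$ru_id == row$ru_id, , drop = FALSE])
  }, numeric(1))
}

#' Per-city carbon densities
#'
#' Storage density and gross sequestration rate of each city per hectare of
#' its attributed canopy, with standard errors scaled the same way. These are
#' the building blocks of both the pooled ecozone densities and the Monte
#' Carlo rate distributions.
#'
#' @param cities city table ([load_city_table()]).
#' @param ru RU table ([load_ru_table()]).
#' @return data frame with one row per city: `name`, `ru_id`, `ecozone`,
#'   `canopy_ha`, `storage_density`, `storage_density_se`, `seq_rate`,
#'   `seq_rate_se` (t C per ha canopy; SE `NA` where the source reported none).
#' @export
city_densities <- function(cities, ru) {
  at <- city_canopy_areas(cities, ru)
  if (any(at <= 0)) {
    stop("zero canopy area attributed to city '",
         cities$name[which(at <= 0)[1]], "'", call. = FALSE)
  }
  data.frame(
    name = cities$name,
    ru_id = cities$ru_id,
    ecozone = ru$ecozone[match(cities$ru_id, ru$ru_id)],
    canopy_ha = at,
    storage_density = cities$carbon_storage_t / at,
    storage_density_se = cities$carbon_storage_se_t / at,
    seq_rate = cities$seq_gross_t_yr / at,
    seq_rate_se = cities$seq_gross_se_t_yr / at,
    stringsAsFactors = FALSE
  )
}

#' Pool city assessments into one ecozone density pair
#'
#' Canopy-area-weighted pooling: total carbon over total attributed canopy,
#' `sum(storage) / sum(canopy)` and `sum(sequestration) / sum(canopy)`. For
#' an ecozone with a single city this equals the city's own ratio exactly.
#' The unweighted mean of city densities is also returned for comparison;
#' the weighted estimator is the default throughout because it reproduces
#' the published multi-city ecozone values.
#'
#' @param cities city table rows belonging to one ecozone.
#' @param ru RU table.
#' @return list with `storage_density`, `seq_rate`, their pooled standard
#'   errors (`storage_density_se`, `seq_rate_se`, from the city sampling SEs
#'   combined in quadrature over the pooled canopy), `n_cities`, `canopy_ha`,
#'   and the unweighted alternatives `storage_density_unweighted`,
#'   `seq_rate_unweighted`.
#' @examples
#' ru <- load_ru_table(); cities <- load_city_table()
#' pool_ecozone_density(cities[cities$name == "Halifax", ], ru)
#' @export
pool_ecozone_density <- function(cities, ru) {
  if (nrow(cities) == 0L) stop("no cities to pool", call. = FALSE)
  at <- city_canopy_areas(cities, ru)
  total_at <- sum(at)
  if (total_at <= 0) stop("zero pooled canopy area", call. = FALSE)
  se_pool <- function(se) {
    if (all(is.na(se))) return(NA_real_)
    sqrt(sum(se[!is.na(se)]^2)) / total_at
  }
  list(
    storage_density = sum(cities$carbon_storage_t) / total_at,
    seq_rate = sum(cities$seq_gross_t_yr) / total_at,
    storage_density_se = se_pool(cities$carbon_storage_se_t),
    seq_rate_se = se_pool(cities$seq_gross_se_t_yr),
    n_cities = nrow(cities),
    canopy_ha = total_at,
    storage_density_unweighted = mean(cities$carbon_storage_t / at),
    seq_rate_unweighted = mean(cities$seq_gross_t_yr / at)
  )
}

#' Derive the ecozone density map from city assessments
#'
#' Applies the derivation rules to produce a density pair for every urban
#' ecozone: pooled from the ecozone's cities, copied from a source ecozone,
#' or fixed managed-forest-model constants for the boreal ecozones. Values
#' are carried at full floating precision; rounding to the one-decimal
#' reporting convention happens only at report time.
#'
#' @param cities city table ([load_city_table()]).
#' @param ru RU table ([load_ru_table()]).
#' @param rules derivation rules ([load_ecozone_rules()]).
#' @return data frame of class `ecozone_densities` with one row per ecozone:
#'   `ecozone`, `storage_density_t_ha`, `seq_rate_t_ha_yr`, their pooled SEs,
#'   `source` (`POOLED`, `PROXY_CITY` or `FOREST_MODEL`) and `n_cities`.
#' @examples
#' d <- derive_ecozone_densities(load_city_table(), load_ru_table())
#' round(d$storage_density_t_ha, 1)
#' @export
derive_ecozone_densities <- function(cities, ru,
                                     rules = load_ecozone_rules()) {
  eco_of_city <- ru$ecozone[match(cities$ru_id, ru$ru_id)]
  pooled <- list()
  for (eco in rules$ecozone[rules$rule == "pool"]) {
    sub <- cities[eco_of_city == eco, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("ecozone '", eco, "' has rule 'pool' but no assigned city",
           call. = FALSE)
    }
    pooled[[eco]] <- pool_ecozone_density(sub, ru)
  }
  rows <- lapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    if (r$rule == "pool") {
      p <- pooled[[r$ecozone]]
      src <- if (any(cities$external[eco_of_city == r$ecozone])) "PROXY_CITY" else "POOLED"
      data.frame(ecozone = r$ecozone,
                 storage_density_t_ha = p$storage_density,
                 seq_rate_t_ha_yr = p$seq_rate,
                 storage_density_se = p$storage_density_se,
                 seq_rate_se = p$seq_rate_se,
                 source = src, n_cities = p$n_cities,
                 stringsAsFactors = FALSE)
    } else if (r$rule == "copy") {
      p <- pooled[[r$source_ecozone]]
      if (is.null(p)) {
        stop("ecozone '", r$ecozone, "' copies from '", r$source_ecozone,
             "' which has no pooled densities", call. = FALSE)
      }
      data.frame(ecozone = r$ecozone,
                 storage_density_t_ha = p$storage_density,
                 seq_rate_t_ha_yr = p$seq_rate,
                 storage_density_se = p$storage_density_se,
                 seq_rate_se = p$seq_rate_se,
                 source = "PROXY_CITY", n_cities = p$n_cities,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(ecozone = r$ecozone,
                 storage_density_t_ha = r$storage_const_t_ha,
                 seq_rate_t_ha_yr = r$seq_const_t_ha_yr,
                 storage_density_se = 0, seq_rate_se = 0,
                 source = "FOREST_MODEL", n_cities = 0L,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$storage_density_t_ha > 0), all(out$seq_rate_t_ha_yr > 0),
            all(out$seq_rate_t_ha_yr < out$storage_density_t_ha))
  class(out) <- c("ecozone_densities", "data.frame")
  out
}

#' Assign a density pair to every reconciliation unit
#'
#' Maps each RU to its ecozone's density pair. Every RU must be covered by
#' the density map; an uncovered RU is a configuration error that names the
#' gap, because a silent fallback would corrupt the national total.
#'
#' @param ru RU table ([load_ru_table()]).
#' @param densities ecozone density map ([derive_ecozone_densities()] or
#'   [load_printed_densities()]).
#' @return data frame with one row per RU: `ru_id`, `name`, `ecozone`,
#'   `storage_density_t_ha`, `seq_rate_t_ha_yr`, `source` and where
#'   available the pooled SEs.
#' @examples
#' assign_ru_densities(load_ru_table(), load_printed_densities())
#' @export
assign_ru_densities <- function(ru, densities) {
  idx <- match(ru$ecozone, densities$ecozone)
  if (anyNA(idx)) {
    gaps <- ru$ru_id[is.na(idx)]
    stop("no density rule covers RU(s) ", paste(gaps, collapse = ", "),
         " (ecozone(s) ", paste(unique(ru$ecozone[is.na(idx)]), collapse = ", "),
         ")", call. = FALSE)
  }
  out <- data.frame(
    ru_id = ru$ru_id, name = ru$name, ecozone = ru$ecozone,
    storage_density_t_ha = densities$storage_density_t_ha[idx],
    seq_rate_t_ha_yr = densities$seq_rate_t_ha_yr[idx],
    source = densities$source[idx],
    stringsAsFactors = FALSE
  )
  if ("storage_density_se" %in% names(densities)) {
    out$storage_density_se <- densities$storage_density_se[idx]
    out$seq_rate_se <- densities$seq_rate_se[idx]
  }
  out
}
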