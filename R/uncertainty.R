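#' Monte Carlo uncertainty configuration
#'
#' Settings for the three-class uncertainty propagation. Stated percentage
#' uncertainties (the 20% model uncertainty and the 0.2% canopy-cover
#' uncertainty) are interpreted by default as 95%-confidence half-widths,
#' the standard convention for greenhouse-gas inventory uncertainty
#' reporting, and converted to standard deviations by dividing by 1.96;
#' `percent_as_ci95 = FALSE` treats them as standard deviations directly.
#'
#' @param iterations Monte Carlo iterations; at least 1000 is recommended
#'   for reporting runs.
#' @param seed integer seed; identical configuration gives bit-identical
#'   bounds.
#' @param model_uncertainty multiplicative model uncertainty for the
#'   plot-based assessment model (default 0.20).
#' @param canopy_uncertainty canopy-cover uncertainty (default 0.002);
#'   `canopy_semantics` chooses whether it is absolute (percentage points of
#'   cover) or relative (fraction of the cover value).
#' @param canopy_semantics `"absolute"` or `"relative"`.
#' @param area_lower,area_mode,area_upper triangular distribution for urban
#'   area, as relative deviations from the recorded value: lower boundary
#'   -10% after inventory practice for urban areas; upper +33%, the share of
#'   national urban area in small centres outside the assessment.
#' @param percentiles reported probability levels.
#' @param percent_as_ci95 interpret percentage uncertainties as 95%
#'   half-widths (divide by 1.96) rather than standard deviations.
#' @param model_shared one model factor per iteration shared across RUs
#'   (a common model bias moves all RUs together; the default) or drawn
#'   independently per RU.
#' @param combine combine proxy SD components in `"quadrature"`
#'   (independence) or `"additive"` (conservative) fashion.
#' @param rate_uncertainty_scale multiplier on every rate SD component;
#'   0 collapses the rate distributions to point masses.
#' @return list of class `uncertainty_config`.
#' @export
uncertainty_config <- function(iterations = 10000, seed = 1L,
                               model_uncertainty = 0.20,
                               canopy_uncertainty = 0.002,
                               canopy_semantics = c("absolute", "relative"),
                               area_lower = -0.10, area_mode = 0,
                               area_upper = 0.33,
                               percentiles = c(0.025, 0.975),
                               percent_as_ci95 = TRUE,
                               model_shared = TRUE,
                               combine = c("quadrature", "additive"),
                               rate_uncertainty_scale = 1) {
  if (iterations < 2) stop("iterations must be at least 2", call. = FALSE)
  if (iterations < 1000) {
    warning("fewer than 1000 iterations: percentile bounds will be noisy",
            call. = FALSE)
  }
  stopifnot(area_lower <= 0, area_upper >= 0,
            area_lower <= area_mode, area_mode <= area_upper,
            model_uncertainty >= 0, canopy_uncertainty >= 0,
            rate_uncertainty_scale >= 0,
            length(percentiles) == 2L, percentiles[1] < percentiles[2])
  z <- if (percent_as_ci95) stats::qnorm(0.975) else 1
  structure(list(
    iterations = as.integer(iterations), seed = as.integer(seed),
    model_uncertainty = model_uncertainty, sd_model = model_uncertainty / z,
    canopy_uncertainty = canopy_uncertainty, sd_canopy = canopy_uncertainty / z,
    canopy_semantics = match.arg(canopy_semantics),
    area_lower = area_lower, area_mode = area_mode, area_upper = area_upper,
    percentiles = percentiles, percent_as_ci95 = percent_as_ci95,
    model_shared = model_shared, combine = match.arg(combine),
    rate_uncertainty_scale = rate_uncertainty_scale
  ), class = "uncertainty_config")
}

#' Triangular random draws
#'
#' Inverse-CDF sampling from a triangular(min, mode, max) distribution;
#' degenerates to a point mass when min equals max. Mean is
#' (min + mode + max) / 3.
#'
#' @param n number of draws.
#' @param min,mode,max distribution parameters.
#' @return numeric vector of draws.
#' @export
rtriangular <- function(n, min, mode, max) {
  stopifnot(min <= mode, mode <= max)
  if (max == min) return(rep(mode, n))
  u <- stats::runif(n)
  f <- (mode - min) / (max - min)
  ifelse(u < f,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Classify reconciliation units for uncertainty propagation
#'
#' Three classes of urban area with increasing uncertainty: the fraction of
#' an RU's urban area directly covered by city assessments (CITY_COVERED,
#' uncertainty from the assessments' own sampling errors), the remaining
#' urban area of such RUs (PARTIAL, rebuilt from the RU city mean plus
#' inter-city variability), and RUs containing no assessed city (PROXY,
#' built from a proxy mean plus inter-city and inter-RU variability). The
#' covered fraction is the summed city assessment area over the RU urban
#' area, capped at 1 with a warning (an assessment study area can extend
#' beyond the population-centre boundary).
#'
#' @param ru RU table ([load_ru_table()]).
#' @param cities city table ([load_city_table()]).
#' @return data frame: `ru_id`, `class` (for the dominant class:
#'   `CITY_COVERED` if fully covered, `PARTIAL` if partly, `PROXY` if no
#'   city), `w_city` covered weight in `[0, 1]`.
#' @export
classify_ru <- function(ru, cities) {
  urban_ha <- convert_units(ru$urban_area_km2, "km2", "ha")
  covered <- vapply(ru$ru_id, function(id) {
    sum(cities$assessment_area_ha[cities$ru_id == id])
  }, numeric(1))
  w <- covered / urban_ha
  if (any(w > 1)) {
    warning("city assessment area exceeds urban area in RU(s) ",
            paste(ru$ru_id[w > 1], collapse = ", "),
            "; covered weight capped at 1", call. = FALSE)
    w <- pmin(w, 1)
  }
  data.frame(
    ru_id = ru$ru_id,
    class = ifelse(w == 0, "PROXY", ifelse(w >= 1, "CITY_COVERED", "PARTIAL")),
    w_city = w,
    stringsAsFactors = FALSE
  )
}

combine_sds <- function(sds, combine) {
  sds <- sds[!is.na(sds)]
  if (combine == "quadrature") sqrt(sum(sds^2)) else sum(sds)
}

#' Build per-RU rate distributions for the Monte Carlo
#'
#' For each RU and each quantity (storage density; gross sequestration
#' rate) a mixture of normal components weighted by urban-area fraction:
#' covered RUs get one component per assessed city (mean and SD from the
#' assessment's own totals scaled to density units) plus a PARTIAL
#' component at the RU city mean with the inter-city SD; PROXY RUs get a
#' single component at the proxy mean whose SD combines the proxy's own SE,
#' the inter-city SD, and the inter-RU SD. The inter-city SD is the spread
#' of city densities in the reference ecozone (the one with the most
#' assessed cities, the Mixedwood Plains in the national data); the
#' inter-RU SD is the spread of the 18 assigned RU density values.
#'
#' @param ru RU table.
#' @param cities city table.
#' @param ru_densities per-RU assigned densities ([assign_ru_densities()]),
#'   carrying pooled SEs when derived in-pipeline.
#' @param config [uncertainty_config()].
#' @param reference_ecozone ecozone whose cities define inter-city
#'   variability; defaults to the ecozone with the most assessed cities.
#' @return list with one element per RU (`class`, `w_city`, and per-quantity
#'   component tables `label`, `mean`, `sd`, `weight`) plus the pooled
#'   variability estimates as attributes `sd_intercity`, `sd_interru`.
#' @export
build_rate_distributions <- function(ru, cities, ru_densities,
                                     config = uncertainty_config(),
                                     reference_ecozone = NULL) {
  cd <- city_densities(cities, ru)
  cls <- classify_ru(ru, cities)
  if (is.null(reference_ecozone)) {
    counts <- table(cd$ecozone)
    reference_ecozone <- names(counts)[which.max(counts)]
  }
  ref <- cd[cd$ecozone == reference_ecozone, , drop = FALSE]
  sd_ic <- c(
    storage = if (nrow(ref) > 1) stats::sd(ref$storage_density) else 0,
    seq = if (nrow(ref) > 1) stats::sd(ref$seq_rate) else 0
  )
  sd_ru <- c(storage = stats::sd(ru_densities$storage_density_t_ha),
             seq = stats::sd(ru_densities$seq_rate_t_ha_yr))
  s <- config$rate_uncertainty_scale
  has_se <- all(c("storage_density_se", "seq_rate_se") %in% names(ru_densities))

  dists <- lapply(seq_len(nrow(ru)), function(i) {
    id <- ru$ru_id[i]
    w <- cls$w_city[cls$ru_id == id]
    dens_i <- ru_densities[ru_densities$ru_id == id, ]
    if (nrow(dens_i) == 0L) {
      stop("no assigned density for RU ", id, " (proxy designation missing)",
           call. = FALSE)
    }
    comp <- function(quantity) {
      mcol <- if (quantity == "storage") "storage_density" else "seq_rate"
      dmean <- if (quantity == "storage") dens_i$storage_density_t_ha else dens_i$seq_rate_t_ha_yr
      dse <- if (!has_se) 0 else {
        v <- if (quantity == "storage") dens_i$storage_density_se else dens_i$seq_rate_se
        if (is.na(v)) 0 else v
      }
      if (w > 0) {
        own <- cd[cd$ru_id == id, , drop = FALSE]
        city_w <- w * own$canopy_ha / sum(own$canopy_ha)
        city_sd <- own[[paste0(mcol, "_se")]]
        city_sd[is.na(city_sd)] <- 0
        ru_mean <- sum(own$canopy_ha * own[[mcol]]) / sum(own$canopy_ha)
        parts <- data.frame(
          label = c(paste0("city:", own$name), "partial"),
          mean = c(own[[mcol]], ru_mean),
          sd = s * c(city_sd, sd_ic[[if (quantity == "storage") "storage" else "seq"]]),
          weight = c(city_w, 1 - w)
        )
        parts[parts$weight > 0, , drop = FALSE]
      } else {
        data.frame(
          label = "proxy",
          mean = dmean,
          sd = s * combine_sds(
            c(dse, sd_ic[[if (quantity == "storage") "storage" else "seq"]],
              sd_ru[[if (quantity == "storage") "storage" else "seq"]]),
            config$combine),
          weight = 1
        )
      }
    }
    list(ru_id = id, class = cls$class[cls$ru_id == id], w_city = w,
         storage = comp("storage"), seq = comp("seq"))
  })
  names(dists) <- as.character(ru$ru_id)
  attr(dists, "sd_intercity") <- sd_ic
  attr(dists, "sd_interru") <- sd_ru
  attr(dists, "reference_ecozone") <- reference_ecozone
  dists
}

draw_rate <- function(components, n) {
  total <- numeric(n)
  truncated <- 0L
  for (k in seq_len(nrow(components))) {
    x <- stats::rnorm(n, components$mean[k], components$sd[k])
    truncated <- truncated + sum(x < 0)
    total <- total + components$weight[k] * pmax(x, 0)
  }
  list(draws = total, truncated = truncated, n_draws = n * nrow(components))
}

percentile_bounds <- function(draws, percentiles) {
  m <- mean(draws)
  q <- stats::quantile(draws, percentiles, names = FALSE, type = 7)
  c(mean = m, sd = stats::sd(draws), p_low = q[1], p_high = q[2],
    rel_low = q[1] / m - 1, rel_high = q[2] / m - 1)
}

#' Run the three-class Monte Carlo uncertainty propagation
#'
#' Each iteration draws, per RU, an urban area from the triangular
#' activity-data distribution, a canopy fraction perturbed by the
#' canopy-cover uncertainty, a carbon rate from the RU's class mixture, and
#' a multiplicative model factor (shared across RUs by default), multiplies
#' them through the Tier-2 gain equation, and aggregates nationally.
#' Percentile bounds are taken from the empirical draws by linear
#' interpolation on order statistics. Negative draws are truncated at zero
#' and the truncation rate is reported. Fixed seed gives bit-identical
#' results.
#'
#' @param ru RU table ([load_ru_table()]).
#' @param cities city table ([load_city_table()]).
#' @param ru_densities per-RU assigned densities ([assign_ru_densities()]).
#' @param config [uncertainty_config()].
#' @return list of class `uncertainty_result`: `storage` and `seq_gross`
#'   data frames (per RU plus a `National` row: `mean`, `p_low`, `p_high`,
#'   `rel_low`, `rel_high`), `truncation_rate`, `distributions`, `config`.
#'   Net sequestration and CO2 removals are fixed multiples of gross, so
#'   their relative bounds equal the gross ones.
#' @export
run_monte_carlo <- function(ru, cities, ru_densities,
                            config = uncertainty_config()) {
  stopifnot(inherits(config, "uncertainty_config"))
  set.seed(config$seed)
  dists <- build_rate_distributions(ru, cities, ru_densities, config)
  n <- config$iterations
  n_ru <- nrow(ru)
  urban_ha <- convert_units(ru$urban_area_km2, "km2", "ha")

  model <- if (config$sd_model == 0) {
    matrix(1, n, n_ru)
  } else if (config$model_shared) {
    matrix(pmax(stats::rnorm(n, 1, config$sd_model), 0), n, n_ru)
  } else {
    matrix(pmax(stats::rnorm(n * n_ru, 1, config$sd_model), 0), n, n_ru)
  }

  storage_kt <- matrix(0, n, n_ru)
  seq_kt <- matrix(0, n, n_ru)
  canopy_rec_ha <- convert_units(ru$canopy_area_km2, "km2", "ha")
  truncated <- 0; total_draws <- 0
  for (i in seq_len(n_ru)) {
    area_factor <- rtriangular(n, 1 + config$area_lower,
                               1 + config$area_mode, 1 + config$area_upper)
    cf <- ru$canopy_fraction[i]
    cf_i <- if (config$sd_canopy == 0) rep(cf, n) else {
      noise <- stats::rnorm(n, 0, config$sd_canopy)
      if (config$canopy_semantics == "absolute") cf + noise else cf * (1 + noise)
    }
    cf_i <- pmin(pmax(cf_i, 0), 1)
    d <- dists[[i]]
    r_st <- draw_rate(d$storage, n)
    r_sq <- draw_rate(d$seq, n)
    truncated <- truncated + r_st$truncated + r_sq$truncated
    total_draws <- total_draws + r_st$n_draws + r_sq$n_draws
    # recorded canopy area perturbed multiplicatively by the urban-area
    # factor and the relative canopy-cover deviation; recorded canopy area
    # and printed cover fraction are independently rounded in the source
    # table, so scaling (rather than re-deriving urban x cover) keeps the
    # zero-uncertainty limit on the deterministic account
    canopy_ha <- canopy_rec_ha[i] * area_factor * (cf_i / cf)
    storage_kt[, i] <- canopy_ha * r_st$draws * model[, i] / 1000
    seq_kt[, i] <- canopy_ha * r_sq$draws * model[, i] / 1000
  }

  summarize <- function(mat) {
    per_ru <- t(apply(mat, 2, percentile_bounds, percentiles = config$percentiles))
    nat <- percentile_bounds(rowSums(mat), config$percentiles)
    out <- as.data.frame(rbind(per_ru, National = nat))
    out <- cbind(data.frame(ru = c(ru$name, "National"),
                            class = c(vapply(dists, `[[`, "", "class"), NA),
                            stringsAsFactors = FALSE), out)
    rownames(out) <- NULL
    out
  }
  structure(list(
    storage = summarize(storage_kt),
    seq_gross = summarize(seq_kt),
    truncation_rate = truncated / total_draws,
    distributions = dists,
    config = config
  ), class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat("Monte Carlo uncertainty (", x$config$iterations, " iterations, seed ",
      x$config$seed, ")\n", sep = "")
  nat <- function(df) df[df$ru == "National", ]
  s <- nat(x$storage); q <- nat(x$seq_gross)
  cat(sprintf("National storage: %.1f kt C (%+.0f%%, %+.0f%%)\n",
              s$mean, 100 * s$rel_low, 100 * s$rel_high))
  cat(sprintf("National gross sequestration: %.1f kt C/yr (%+.0f%%, %+.0f%%)\n",
              q$mean, 100 * q$rel_low, 100 * q$rel_high))
  cat(sprintf("Truncation rate: %.3f\n", x$truncation_rate))
  invisible(x)
}
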