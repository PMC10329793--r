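#' Accounting configuration
#'
#' @param f_net net-to-gross sequestration ratio. The assessment text states
#'   net sequestration (gross minus emissions from biomass decay) as 74% of
#'   gross; the published per-RU tables imply approximately 0.75. The default
#'   follows the text.
#' @param report_precision decimals used when rounding report columns.
#' @return list of class `accounting_config`.
#' @export
accounting_config <- function(f_net = 0.74, report_precision = 1) {
  stopifnot(is.numeric(f_net), length(f_net) == 1L, f_net > 0, f_net <= 1)
  structure(list(f_net = f_net, co2_ratio = CO2_RATIO,
                 report_precision = report_precision),
            class = "accounting_config")
}

#' Tier-2 gain: canopy area times carbon rate
#'
#' The gain term of the Tier-2 accounting equation: annual accumulation (or
#' standing stock) equals the canopy area multiplied by the carbon rate per
#' unit canopy. Applied identically for storage (density, t C ha-1) and
#' gross sequestration (rate, t C ha-1 yr-1).
#'
#' @param canopy_area_ha canopy area in hectares (>= 0).
#' @param crw carbon rate per hectare of canopy (> 0).
#' @return flux or stock in kilotonnes.
#' @examples
#' tier2_flux(13600, 22.6)  # kt C
#' @export
tier2_flux <- function(canopy_area_ha, crw) {
  if (any(canopy_area_ha < 0)) stop("negative canopy area", call. = FALSE)
  if (any(crw <= 0)) stop("carbon rate must be positive", call. = FALSE)
  convert_units(canopy_area_ha * crw, "t", "kt")
}

#' Net sequestration and CO2 removals from a gross flux
#'
#' Net is a fixed fraction of gross (decay emissions); CO2 is net times the
#' exact mass ratio 44/12.
#'
#' @param gross gross sequestration (any mass unit; >= 0).
#' @param config [accounting_config()].
#' @return list with `net` and `co2` in the units of `gross`.
#' @export
net_and_co2 <- function(gross, config = accounting_config()) {
  if (any(gross < 0)) stop("negative gross flux", call. = FALSE)
  net <- config$f_net * gross
  list(net = net, co2 = net * config$co2_ratio)
}

#' Build the per-RU and national carbon account
#'
#' Multiplies each RU's canopy area by its assigned storage density and
#' gross sequestration rate (the Tier-2 gain), derives net sequestration
#' and CO2 removals, and sums to the national account. The national row is
#' the exact column sum of the RU rows.
#'
#' @param ru RU table ([load_ru_table()]).
#' @param ru_densities per-RU density assignment ([assign_ru_densities()]).
#' @param config [accounting_config()].
#' @return list of class `carbon_account` with `ru` (data frame, one row per
#'   RU: `canopy_ha`, `storage_kt`, `seq_gross_kt`, `seq_net_kt`,
#'   `co2_net_kt`) and `national` (named numeric of the same quantities).
#' @examples
#' ru <- load_ru_table()
#' acct <- build_account(ru, assign_ru_densities(ru, load_printed_densities()))
#' acct$national
#' @export
build_account <- function(ru, ru_densities, config = accounting_config()) {
  idx <- match(ru$ru_id, ru_densities$ru_id)
  if (anyNA(idx)) {
    stop("missing density for RU(s) ",
         paste(ru$ru_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  d <- ru_densities[idx, ]
  canopy_ha <- convert_units(ru$canopy_area_km2, "km2", "ha")
  storage <- tier2_flux(canopy_ha, d$storage_density_t_ha)
  gross <- tier2_flux(canopy_ha, d$seq_rate_t_ha_yr)
  nc <- net_and_co2(gross, config)
  tab <- data.frame(
    ru_id = ru$ru_id, name = ru$name, ecozone = ru$ecozone,
    canopy_ha = canopy_ha,
    storage_kt = storage, seq_gross_kt = gross,
    seq_net_kt = nc$net, co2_net_kt = nc$co2,
    stringsAsFactors = FALSE
  )
  national <- c(canopy_ha = sum(canopy_ha), storage_kt = sum(storage),
                seq_gross_kt = sum(gross), seq_net_kt = sum(nc$net),
                co2_net_kt = sum(nc$co2))
  structure(list(ru = tab, national = national, config = config),
            class = "carbon_account")
}

#' @export
print.carbon_account <- function(x, ...) {
  p <- x$config$report_precision
  cat("Urban forest carbon account (", nrow(x$ru), " reconciliation units)\n",
      sep = "")
  tab <- x$ru
  num <- c("storage_kt", "seq_gross_kt", "seq_net_kt", "co2_net_kt")
  tab[num] <- lapply(tab[num], round, digits = p)
  print(tab[, c("ru_id", "name", num)], row.names = FALSE)
  cat("National: storage", round(x$national[["storage_kt"]], p),
      "kt C; gross", round(x$national[["seq_gross_kt"]], p),
      "kt C/yr; net", round(x$national[["seq_net_kt"]], p),
      "kt C/yr; CO2", round(x$national[["co2_net_kt"]], p), "kt/yr\n")
  invisible(x)
}

#' Difference against the fixed-rate baseline
#'
#' Recomputes the account under the single fixed storage density and
#' sequestration rate of the previous national assessment, applies the same
#' net and CO2 conversions, and reports this assessment minus the baseline
#' per RU and nationally. Negative values mean the updated assessment is
#' lower than the baseline.
#'
#' @param account a [build_account()] result.
#' @param baseline baseline rates ([load_baseline_rates()]).
#' @param config [accounting_config()]; defaults to the account's own.
#' @return list of class `baseline_comparison` with `ru` (per-RU differences
#'   in kt) and `national` (named numeric).
#' @examples
#' ru <- load_ru_table()
#' acct <- build_account(ru, assign_ru_densities(ru, load_printed_densities()))
#' baseline_comparison(acct, load_baseline_rates())$ru[1, ]
#' @export
baseline_comparison <- function(account, baseline = load_baseline_rates(),
                                config = account$config) {
  stopifnot(inherits(account, "carbon_account"))
  if (baseline$storage_density <= 0 || baseline$seq_rate <= 0) {
    stop("baseline rates must be positive", call. = FALSE)
  }
  canopy_ha <- account$ru$canopy_ha
  base_storage <- tier2_flux(canopy_ha, baseline$storage_density)
  base_gross <- tier2_flux(canopy_ha, baseline$seq_rate)
  base_nc <- net_and_co2(base_gross, config)
  tab <- data.frame(
    ru_id = account$ru$ru_id, name = account$ru$name,
    storage_diff_kt = account$ru$storage_kt - base_storage,
    seq_gross_diff_kt = account$ru$seq_gross_kt - base_gross,
    seq_net_diff_kt = account$ru$seq_net_kt - base_nc$net,
    co2_net_diff_kt = account$ru$co2_net_kt - base_nc$co2,
    stringsAsFactors = FALSE
  )
  national <- colSums(tab[, -(1:2)])
  structure(list(ru = tab, national = national, baseline = baseline),
            class = "baseline_comparison")
}
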