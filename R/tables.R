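#' Path to a packaged fixture table
#'
#' The package ships the published input tables of the national assessment as
#' plain CSV: the reconciliation-unit (RU) table with urban area and canopy
#' cover, the city assessment summaries, the ecozone density-derivation
#' rules, the published ecozone density table, and the fixed-rate baseline.
#'
#' @param file fixture file name, e.g. `"ru_table.csv"`.
#' @return absolute path to the installed fixture.
#' @export
uf_fixture <- function(file) {
  path <- system.file("extdata", file, package = "urbancarbon")
  if (!nzchar(path)) stop("no packaged fixture called ", file, call. = FALSE)
  path
}

parse_stop <- function(file, row, col, what) {
  stop(sprintf("%s: row %s, column '%s': %s", basename(file),
               paste(row, collapse = ","), col, what), call. = FALSE)
}

read_fixture_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop(basename(path), ": parse error: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L) stop(basename(path), ": empty table", call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(basename(path), ": missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

check_numeric <- function(df, cols, file, allow_na = character()) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v) & v != "")
      parse_stop(file, if (length(bad)) bad else "?", col, "non-numeric cell")
    }
    if (!(col %in% allow_na) && anyNA(v)) {
      parse_stop(file, which(is.na(v)), col, "missing value")
    }
  }
  df
}

#' Load the reconciliation-unit table
#'
#' Reads the RU table (18 province-by-ecozone strata with urban area): RU
#' identifier, name, total RU area, urban area, canopy area (all km2), canopy
#' cover (percent of urban area), and ecozone label. The canopy fraction used
#' downstream is the printed cover percentage divided by 100; because the
#' printed areas are rounded to whole km2, the ratio canopy/urban can deviate
#' slightly from the printed fraction and the loader reports inconsistencies
#' beyond rounding slack as warnings, not errors.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return a data frame of class `ru_table` with one row per RU and a
#'   `canopy_fraction` column.
#' @examples
#' ru <- load_ru_table()
#' sum(ru$urban_area_km2)
#' @export
load_ru_table <- function(path = uf_fixture("ru_table.csv")) {
  req <- c("ru_id", "name", "ru_area_km2", "urban_area_km2",
           "canopy_area_km2", "canopy_cover_pct", "ecozone")
  ru <- read_fixture_csv(path, req)
  num <- setdiff(req, c("name", "ecozone"))
  ru <- check_numeric(ru, num, path)
  if (anyDuplicated(ru$ru_id)) {
    parse_stop(path, which(duplicated(ru$ru_id)), "ru_id", "duplicate ru_id")
  }
  for (col in num) {
    if (any(ru[[col]] < 0)) parse_stop(path, which(ru[[col]] < 0), col, "negative value")
  }
  bad <- ru$canopy_area_km2 > ru$urban_area_km2 | ru$urban_area_km2 > ru$ru_area_km2
  if (any(bad)) {
    parse_stop(path, which(bad), "canopy_area_km2",
               "area ordering violated (canopy <= urban <= RU)")
  }
  ru$canopy_fraction <- ru$canopy_cover_pct / 100
  # printed values are independently rounded: flag gaps beyond rounding slack
  gap <- abs(ru$canopy_area_km2 / ru$urban_area_km2 - ru$canopy_fraction)
  if (any(gap > 0.005)) {
    warning("canopy_area/urban_area differs from printed canopy cover by >0.005 ",
            "for RU(s) ", paste(ru$ru_id[gap > 0.005], collapse = ", "),
            " (printed rounding)", call. = FALSE)
  }
  class(ru) <- c("ru_table", "data.frame")
  ru
}

#' Load the city assessment table
#'
#' Reads the plot-based city assessment summaries: assessment area (ha),
#' number of plots, total carbon storage and gross sequestration with their
#' sampling standard errors (tonnes C), the RU each city sits in, and an
#' optional canopy-area override used for the external surrogate city whose
#' canopy came from its own satellite estimate rather than the national
#' point-sampling survey. Missing standard errors stay `NA` (absent), never
#' zero.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return a data frame of class `city_table`, one row per city.
#' @examples
#' cities <- load_city_table()
#' cities[cities$name == "Halifax", ]
#' @export
load_city_table <- function(path = uf_fixture("city_table.csv")) {
  req <- c("name", "ru_id", "external", "assessment_area_ha", "n_plots",
           "carbon_storage_t", "carbon_storage_se_t",
           "seq_gross_t_yr", "seq_gross_se_t_yr", "canopy_area_override_ha")
  cities <- read_fixture_csv(path, req)
  num <- setdiff(req, c("name", "external", "note"))
  cities <- check_numeric(cities, num, path,
                          allow_na = c("carbon_storage_se_t", "seq_gross_se_t_yr",
                                       "canopy_area_override_ha"))
  cities$external <- as.logical(cities$external)
  for (col in num) {
    bad <- !is.na(cities[[col]]) & cities[[col]] < 0
    if (any(bad)) parse_stop(path, which(bad), col, "negative value")
  }
  if (any(cities$n_plots < 1)) {
    parse_stop(path, which(cities$n_plots < 1), "n_plots", "fewer than one plot")
  }
  ovr <- cities$canopy_area_override_ha
  bad <- !is.na(ovr) & ovr > cities$assessment_area_ha
  if (any(bad)) {
    parse_stop(path, which(bad), "canopy_area_override_ha",
               "override exceeds assessment area")
  }
  class(cities) <- c("city_table", "data.frame")
  cities
}

#' Load the ecozone density-derivation rules
#'
#' Each urban ecozone carries one rule: `pool` (canopy-area-weighted pooling
#' of the cities assigned to the ecozone), `copy` (adopt another ecozone's
#' pooled values, e.g. Semiarid Prairies from Subhumid Prairies), or
#' `constant` (fixed storage density and sequestration rate taken from
#' managed-forest modelling, used for the boreal ecozones).
#'
#' @param path CSV path; defaults to the packaged rules.
#' @return data frame with columns `ecozone`, `rule`, `source_ecozone`,
#'   `storage_const_t_ha`, `seq_const_t_ha_yr`.
#' @export
load_ecozone_rules <- function(path = uf_fixture("ecozone_rules.csv")) {
  rules <- read_fixture_csv(path, c("ecozone", "rule", "source_ecozone",
                                    "storage_const_t_ha", "seq_const_t_ha_yr"))
  ok <- rules$rule %in% c("pool", "copy", "constant")
  if (!all(ok)) parse_stop(path, which(!ok), "rule", "unknown rule")
  rules
}

#' Load the published ecozone density table
#'
#' The published carbon storage densities (t C per ha of canopy) and gross
#' sequestration rates (t C per ha per year) for the nine urban ecozones, at
#' printed precision (one decimal). Used for strict replication of the
#' published account; the pipeline can equally derive unrounded densities
#' from the city table via [derive_ecozone_densities()].
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data frame with columns `ecozone`, `storage_density_t_ha`,
#'   `seq_rate_t_ha_yr`, `source`, `comment`.
#' @export
load_printed_densities <- function(path = uf_fixture("ecozone_densities.csv")) {
  d <- read_fixture_csv(path, c("ecozone", "storage_density_t_ha",
                                "seq_rate_t_ha_yr", "source"))
  check_numeric(d, c("storage_density_t_ha", "seq_rate_t_ha_yr"), path)
  if (any(d$storage_density_t_ha <= 0) || any(d$seq_rate_t_ha_yr <= 0)) {
    stop(basename(path), ": densities must be positive", call. = FALSE)
  }
  d
}

#' Load the fixed-rate baseline
#'
#' The previous national assessment applied a single storage density
#' (76.9 t C ha-1) and gross sequestration rate (2.12 t C ha-1 yr-1) of
#' canopy to the whole country; these are the comparison baseline.
#'
#' @param path CSV path; defaults to the packaged values.
#' @return list with `storage_density` and `seq_rate`.
#' @export
load_baseline_rates <- function(path = uf_fixture("baseline.csv")) {
  b <- read_fixture_csv(path, c("storage_density_t_ha", "seq_rate_t_ha_yr"))
  if (b$storage_density_t_ha[1] <= 0 || b$seq_rate_t_ha_yr[1] <= 0) {
    stop("baseline rates must be positive", call. = FALSE)
  }
  list(storage_density = b$storage_density_t_ha[1],
       seq_rate = b$seq_rate_t_ha_yr[1])
}
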