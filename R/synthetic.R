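#' Define a synthetic world with known ground truth
#'
#' A synthetic world fixes the quantities the pipeline is supposed to
#' recover: a true density pair per ecozone, a true canopy fraction per RU,
#' and the coefficient of variation of city plot sampling. The default
#' world mirrors the national study conditions: the 18 published RUs with
#' their canopy fractions, the published ecozone densities as truth, and a
#' plot-noise CV of 0.05 (city totals are reported with standard errors of
#' a few percent, consistent with a few hundred plots at this CV).
#'
#' @param ru RU table; defaults to the packaged national table.
#' @param true_densities data frame `ecozone`, `storage_density_t_ha`,
#'   `seq_rate_t_ha_yr`; defaults to the published ecozone densities.
#' @param cv plot-sampling coefficient of variation of a single plot;
#'   city-level relative noise is `cv / sqrt(n_plots)`.
#' @param noise `"normal"` (truncated at zero, flagged) or `"lognormal"`
#'   (mean-one multiplicative, always positive).
#' @param seed integer seed stored with the world.
#' @return list of class `synthetic_world`.
#' @export
synthetic_world <- function(ru = load_ru_table(),
                            true_densities = load_printed_densities(),
                            cv = 0.05, noise = c("normal", "lognormal"),
                            seed = 1L) {
  stopifnot(cv >= 0,
            all(true_densities$storage_density_t_ha > 0),
            all(true_densities$seq_rate_t_ha_yr > 0))
  if (!all(ru$ecozone %in% true_densities$ecozone)) {
    stop("true_densities must cover every RU ecozone", call. = FALSE)
  }
  structure(list(ru = ru, true_densities = true_densities, cv = cv,
                 noise = match.arg(noise), seed = as.integer(seed)),
            class = "synthetic_world")
}

true_density_of <- function(world, ru_id) {
  eco <- world$ru$ecozone[world$ru$ru_id == ru_id]
  i <- match(eco, world$true_densities$ecozone)
  c(storage = world$true_densities$storage_density_t_ha[i],
    seq = world$true_densities$seq_rate_t_ha_yr[i])
}

#' Generate one synthetic city assessment
#'
#' Emulates the statistical structure of a plot-based city assessment
#' summary: the true total (area times RU canopy fraction times true
#' density) perturbed by sampling noise with relative SD `cv / sqrt(n_plots)`,
#' and a standard-error field set to the generating SD. Storage and
#' sequestration noise are independent. With `cv = 0` the totals are exact
#' and the SEs zero.
#'
#' @param world a [synthetic_world()].
#' @param ru_id RU the city sits in.
#' @param area_ha assessment area, hectares (> 0).
#' @param n_plots number of plots (>= 1).
#' @param name city name.
#' @param seed optional seed for this city alone.
#' @return one-row data frame in the city-table schema.
#' @export
generate_city <- function(world, ru_id, area_ha, n_plots, name = "synthcity",
                          seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"), area_ha > 0, n_plots >= 1)
  if (!is.null(seed)) set.seed(seed)
  cf <- world$ru$canopy_fraction[world$ru$ru_id == ru_id]
  if (length(cf) != 1L) stop("unknown ru_id ", ru_id, call. = FALSE)
  d <- true_density_of(world, ru_id)
  rel_sd <- world$cv / sqrt(n_plots)
  noisy <- function(truth) {
    if (rel_sd == 0) return(truth)
    if (world$noise == "lognormal") {
      sdlog <- sqrt(log(1 + rel_sd^2))
      truth * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    } else {
      x <- truth * (1 + stats::rnorm(1, 0, rel_sd))
      if (x < 0) {
        warning("negative synthetic total truncated to zero", call. = FALSE)
        x <- 0
      }
      x
    }
  }
  truth_st <- area_ha * cf * d[["storage"]]
  truth_sq <- area_ha * cf * d[["seq"]]
  data.frame(
    name = name, ru_id = ru_id, external = FALSE,
    assessment_area_ha = area_ha, n_plots = n_plots,
    carbon_storage_t = noisy(truth_st),
    carbon_storage_se_t = truth_st * rel_sd,
    seq_gross_t_yr = noisy(truth_sq),
    seq_gross_se_t_yr = truth_sq * rel_sd,
    canopy_area_override_ha = NA_real_,
    note = "",
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic city table
#'
#' Spreads `n_cities` across the given RUs (cycling), with assessment areas
#' and plot counts drawn uniformly from the given ranges. Every generated
#' table satisfies the city-table invariants.
#'
#' @param world a [synthetic_world()].
#' @param n_cities number of cities.
#' @param ru_ids RUs to host cities; default all RUs of the world.
#' @param area_range assessment area range, ha.
#' @param plots_range plot count range.
#' @param seed integer seed.
#' @return data frame of class `city_table`.
#' @export
generate_city_table <- function(world, n_cities, ru_ids = world$ru$ru_id,
                                area_range = c(2000, 60000),
                                plots_range = c(150, 400), seed = world$seed) {
  set.seed(seed)
  host <- rep_len(ru_ids, n_cities)
  areas <- stats::runif(n_cities, area_range[1], area_range[2])
  plots <- sample(seq(plots_range[1], plots_range[2]), n_cities, replace = TRUE)
  out <- do.call(rbind, lapply(seq_len(n_cities), function(i) {
    generate_city(world, host[i], areas[i], plots[i],
                  name = sprintf("synthcity_%02d", i))
  }))
  class(out) <- c("city_table", "data.frame")
  out
}

#' Pool-everything derivation rules for a synthetic world
#'
#' A rules table that pools every ecozone from its generated cities, for
#' end-to-end recovery experiments where every ecozone hosts cities.
#'
#' @param world a [synthetic_world()].
#' @return rules data frame in the [load_ecozone_rules()] schema.
#' @export
synthetic_rules <- function(world) {
  data.frame(ecozone = unique(world$ru$ecozone), rule = "pool",
             source_ecozone = NA_character_, storage_const_t_ha = NA_real_,
             seq_const_t_ha_yr = NA_real_, stringsAsFactors = FALSE)
}

#' True national totals of a synthetic world
#'
#' The quantity an exact pipeline must recover: each RU's canopy area times
#' its ecozone's true density, summed nationally, in kt.
#'
#' @param world a [synthetic_world()].
#' @param config [accounting_config()].
#' @return named numeric: `storage_kt`, `seq_gross_kt`, `seq_net_kt`,
#'   `co2_net_kt`.
#' @export
true_national_totals <- function(world, config = accounting_config()) {
  i <- match(world$ru$ecozone, world$true_densities$ecozone)
  canopy_ha <- convert_units(world$ru$canopy_area_km2, "km2", "ha")
  storage <- sum(canopy_ha * world$true_densities$storage_density_t_ha[i]) / 1000
  gross <- sum(canopy_ha * world$true_densities$seq_rate_t_ha_yr[i]) / 1000
  nc <- net_and_co2(gross, config)
  c(storage_kt = storage, seq_gross_kt = gross,
    seq_net_kt = nc$net, co2_net_kt = nc$co2)
}

#' Generate a synthetic categorical landcover raster
#'
#' Pixels are canopy with probability `true_fraction` and other-urban
#' otherwise, optionally under block-level clustering (block canopy
#' probabilities drawn from a Beta distribution with mean `true_fraction`,
#' giving the same marginal fraction but higher cell-level variance, a
#' blotchy texture closer to real imagery). Clouds overwrite pixels at
#' `cloud_fraction`, and a non-urban margin of `margin_px` pixels can frame
#' the scene to exercise the urban-content discard rule. The realized
#' canopy fraction among urban pixels is recorded as ground truth.
#'
#' @param true_fraction canopy probability in `[0, 1]`.
#' @param extent raster size, pixels (rows, cols).
#' @param res_m metres per pixel.
#' @param seed integer seed.
#' @param clustering logical; block-level clustering on.
#' @param block_px block edge for clustering, pixels.
#' @param concentration Beta concentration for block probabilities (smaller
#'   means blotchier).
#' @param cloud_fraction probability a pixel is obscured by cloud.
#' @param margin_px width of a non-urban frame around the scene.
#' @return a [landcover_grid()] with attribute `true_fraction_realized`.
#' @export
generate_raster <- function(true_fraction, extent = c(400, 400), res_m = 50,
                            seed = 1L, clustering = FALSE, block_px = 10,
                            concentration = 4, cloud_fraction = 0,
                            margin_px = 0) {
  stopifnot(true_fraction >= 0, true_fraction <= 1,
            cloud_fraction >= 0, cloud_fraction < 1)
  set.seed(seed)
  nr <- extent[1]; nc <- extent[2]
  if (clustering && true_fraction > 0 && true_fraction < 1) {
    br <- ceiling(nr / block_px); bc <- ceiling(nc / block_px)
    p_block <- matrix(stats::rbeta(br * bc, true_fraction * concentration,
                                   (1 - true_fraction) * concentration), br, bc)
    p <- p_block[cbind(rep((seq_len(nr) - 1L) %/% block_px + 1L, times = nc),
                       rep((seq_len(nc) - 1L) %/% block_px + 1L, each = nr))]
    codes <- matrix(ifelse(stats::runif(nr * nc) < p, 2L, 1L), nr, nc)
  } else {
    codes <- matrix(ifelse(stats::runif(nr * nc) < true_fraction, 2L, 1L),
                    nr, nc)
  }
  if (cloud_fraction > 0) {
    codes[stats::runif(nr * nc) < cloud_fraction] <- 3L
  }
  if (margin_px > 0) {
    codes[c(seq_len(margin_px), nr - seq_len(margin_px) + 1L), ] <- 0L
    codes[, c(seq_len(margin_px), nc - seq_len(margin_px) + 1L)] <- 0L
  }
  g <- landcover_grid(codes, res_m)
  urban <- codes == 1L | codes == 2L
  g$true_fraction_target <- true_fraction
  attr(g, "true_fraction_realized") <-
    if (any(urban)) sum(codes == 2L) / sum(urban) else NA_real_
  g
}
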