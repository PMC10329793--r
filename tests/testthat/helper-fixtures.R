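# Shared fixture objects. Loading the RU table warns about two RUs whose
# printed canopy area / urban area ratio disagrees with the printed cover
# percentage beyond rounding slack; that is expected for the published data.
ru_fix <- suppressWarnings(load_ru_table())
city_fix <- load_city_table()

derived_densities <- derive_ecozone_densities(city_fix, ru_fix)
printed_densities <- load_printed_densities()

quiet_classify <- function(...) suppressWarnings(classify_ru(...))
quiet_mc <- function(...) suppressWarnings(run_monte_carlo(...))

national_row <- function(df) df[df$ru == "National", ]

# a small fully-urban test raster shared across canopy tests
make_urban_raster <- function(fraction, nr = 200, nc = 200, res_m = 50,
                              seed = 1, ...) {
  generate_raster(fraction, extent = c(nr, nc), res_m = res_m, seed = seed, ...)
}
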