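test_that("city canopy area is assessment area times RU canopy fraction", {
  hfx <- city_fix[city_fix$name == "Halifax", ]
  expect_equal(city_canopy_area(hfx, ru_fix[ru_fix$ru_id == 16, ]), 34635)

  sea <- city_fix[city_fix$name == "Seattle", ]
  # an override is returned unchanged, no RU needed
  expect_equal(city_canopy_area(sea), sea$canopy_area_override_ha)
  expect_equal(city_canopy_area(sea, ru_fix[1, ]), sea$canopy_area_override_ha)

  orphan <- hfx; orphan$canopy_area_override_ha <- NA_real_
  expect_error(city_canopy_area(orphan, NULL), "neither an RU")

  # zero canopy fraction guards the downstream density division
  ru0 <- ru_fix[ru_fix$ru_id == 16, ]; ru0$canopy_fraction <- 0
  expect_equal(city_canopy_area(hfx, ru0), 0)
  expect_error(city_densities(hfx, ru0), "zero canopy area")
})

test_that("single-city ecozones pool to the city's own ratio", {
  hfx <- pool_ecozone_density(city_fix[city_fix$name == "Halifax", ], ru_fix)
  expect_equal(hfx$storage_density, 2134697 / 34635)
  expect_equal(hfx$seq_rate, 118483 / 34635)
  expect_equal(round(hfx$storage_density, 1), 61.6)
  expect_equal(round(hfx$seq_rate, 1), 3.4)

  kel <- pool_ecozone_density(city_fix[city_fix$name == "Kelowna", ], ru_fix)
  expect_equal(round(kel$storage_density, 1), 22.6)
  expect_equal(round(kel$seq_rate, 1), 1.4)
  expect_equal(kel$storage_density, kel$storage_density_unweighted)
})

test_that("multi-city pooling is canopy-area weighted and matches print", {
  sub <- pool_ecozone_density(
    city_fix[city_fix$name %in% c("Calgary", "Edmonton"), ], ru_fix)
  expect_equal(sub$storage_density,
               (183595 + 615774) / ((55032 + 69985) * 0.116))
  # published value 54.7; the <1% gap is canopy-fraction rounding
  expect_lt(abs(sub$storage_density - 54.7) / 54.7, 0.01)
  expect_equal(round(sub$seq_rate, 1), 2.9)
  # the unweighted mean is far from print, which is why weighting is default
  expect_equal(round(sub$storage_density_unweighted, 1), 52.3)

  mw <- pool_ecozone_density(city_fix[city_fix$ru_id == 10, ], ru_fix)
  expect_equal(round(mw$storage_density, 1), 57.8)
  expect_equal(round(mw$seq_rate, 1), 2.4)
})

test_that("pooling is invariant to proportional city splits", {
  cities <- city_fix[city_fix$ru_id == 10, ]
  whole <- pool_ecozone_density(cities, ru_fix)
  first <- cities[1, ]
  halves <- rbind(first, first)
  for (col in c("assessment_area_ha", "carbon_storage_t", "seq_gross_t_yr")) {
    halves[[col]] <- c(0.3, 0.7) * first[[col]]
  }
  split_pool <- pool_ecozone_density(rbind(halves, cities[-1, ]), ru_fix)
  expect_equal(split_pool$storage_density, whole$storage_density)
  expect_equal(split_pool$seq_rate, whole$seq_rate)
})

test_that("derived ecozone map covers all nine urban ecozones with provenance", {
  d <- derived_densities
  expect_equal(sort(d$ecozone), sort(unique(ru_fix$ecozone)))
  expect_true(all(d$seq_rate_t_ha_yr < d$storage_density_t_ha))
  get <- function(eco) d[d$ecozone == eco, ]
  expect_equal(get("Boreal plains")$storage_density_t_ha, 40.0)
  expect_equal(get("Boreal plains")$seq_rate_t_ha_yr, 3.0)
  expect_equal(get("Boreal plains")$source, "FOREST_MODEL")
  # the Semiarid Prairies copy the Subhumid pooled pair exactly
  expect_equal(get("Semiarid prairies")$storage_density_t_ha,
               get("Subhumid prairies")$storage_density_t_ha)
  expect_equal(get("Semiarid prairies")$seq_rate_t_ha_yr,
               get("Subhumid prairies")$seq_rate_t_ha_yr)
  expect_equal(get("Pacific maritime")$source, "PROXY_CITY")
})

test_that("RU assignment propagates proxies and reports coverage gaps", {
  rd <- assign_ru_densities(ru_fix, derived_densities)
  expect_equal(nrow(rd), 18L)
  expect_equal(rd$storage_density_t_ha[rd$ru_id == 6], 40.0)
  expect_equal(rd$seq_rate_t_ha_yr[rd$ru_id == 6], 3.0)
  expect_equal(rd$storage_density_t_ha[rd$ru_id == 4],
               rd$storage_density_t_ha[rd$ru_id == 5])

  # dropping the boreal forest-model rule leaves the six boreal RUs uncovered
  no_boreal <- derived_densities[derived_densities$source != "FOREST_MODEL", ]
  expect_error(assign_ru_densities(ru_fix, no_boreal), "3, 6, 9, 11, 12, 18")

  rules <- load_ecozone_rules()
  rules$rule[rules$ecozone == "Montane cordillera"] <- "pool"
  no_city <- city_fix[city_fix$name != "Kelowna", ]
  expect_error(derive_ecozone_densities(no_city, ru_fix, rules),
               "no assigned city")
})

test_that("pooled densities recover a known truth from synthetic cities", {
  world <- synthetic_world(ru = ru_fix, cv = 0.05, seed = 99)
  pool_rus <- c(1, 2, 5, 8, 10, 13, 14, 15, 16, 17)
  cities <- generate_city_table(world, n_cities = 50, ru_ids = pool_rus,
                                seed = 99)
  d <- derive_ecozone_densities(cities, world$ru)
  truth <- world$true_densities
  for (i in seq_len(nrow(d))) {
    t_row <- truth[truth$ecozone == d$ecozone[i], ]
    expect_lt(abs(d$storage_density_t_ha[i] - t_row$storage_density_t_ha) /
                t_row$storage_density_t_ha, 0.01)
    expect_lt(abs(d$seq_rate_t_ha_yr[i] - t_row$seq_rate_t_ha_yr) /
                t_row$seq_rate_t_ha_yr, 0.01)
  }
})
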