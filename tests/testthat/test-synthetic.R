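test_that("a noise-free world generates exact city totals with zero SE", {
  world <- synthetic_world(ru = ru_fix, cv = 0, seed = 1)
  city <- generate_city(world, ru_id = 10, area_ha = 10000, n_plots = 200,
                        seed = 4)
  cf <- 0.224
  expect_equal(city$carbon_storage_t, 10000 * cf * 57.8)
  expect_equal(city$carbon_storage_se_t, 0)
  expect_equal(city$seq_gross_t_yr, 10000 * cf * 2.4)
  expect_equal(city$seq_gross_se_t_yr, 0)
})

test_that("a fixed seed regenerates the identical city", {
  world <- synthetic_world(ru = ru_fix, cv = 0.2, seed = 1)
  a <- generate_city(world, 10, 5000, 100, seed = 9)
  b <- generate_city(world, 10, 5000, 100, seed = 9)
  expect_identical(a, b)
})

test_that("reported SEs match the empirical spread of replicate cities", {
  world <- synthetic_world(ru = ru_fix, cv = 0.5, seed = 1)
  reps <- do.call(rbind, lapply(1:1000, function(s) {
    generate_city(world, 10, 10000, 100, seed = s)
  }))
  expect_lt(abs(sd(reps$carbon_storage_t) - reps$carbon_storage_se_t[1]) /
              reps$carbon_storage_se_t[1], 0.10)
  expect_lt(abs(sd(reps$seq_gross_t_yr) - reps$seq_gross_se_t_yr[1]) /
              reps$seq_gross_se_t_yr[1], 0.10)
})

test_that("lognormal noise keeps totals positive at high cv", {
  world <- synthetic_world(ru = ru_fix, cv = 4, noise = "lognormal", seed = 1)
  reps <- do.call(rbind, lapply(1:200, function(s) {
    generate_city(world, 10, 10000, 4, seed = s)
  }))
  expect_true(all(reps$carbon_storage_t > 0))
  # mean-one multiplicative noise preserves the truth on average
  truth <- 10000 * 0.224 * 57.8
  expect_lt(abs(mean(reps$carbon_storage_t) - truth) / truth,
            4 * sd(reps$carbon_storage_t) / sqrt(200) / truth)
})

test_that("synthetic rasters hit their target canopy fraction", {
  none <- generate_raster(0, extent = c(50, 50), seed = 2)
  expect_true(all(none$codes != 2L))

  big <- generate_raster(0.27, extent = c(1000, 1000), res_m = 10, seed = 3)
  realized <- attr(big, "true_fraction_realized")
  expect_lt(abs(realized - 0.27), 0.002)  # ~4.5 binomial SDs at 1e6 px

  margin <- generate_raster(0.3, extent = c(100, 100), seed = 4, margin_px = 10)
  expect_true(all(margin$codes[1:10, ] == 0L))
})

test_that("clustering keeps the marginal fraction but inflates cell variance", {
  cell_sds <- function(clustered) {
    g <- generate_raster(0.3, extent = c(200, 200), res_m = 50, seed = 21,
                         clustering = clustered, block_px = 20)
    cells <- select_cells(g, sampling_rate = 1, seed = 1)
    pts <- classify_points(g, do.call(rbind, lapply(
      seq_len(nrow(cells)), function(i) place_points(cells[i, ], 55))))
    kept <- pts[!pts$discarded, ]
    means <- tapply(kept$label == "canopy",
                    interaction(kept$cell_row, kept$cell_col, drop = TRUE),
                    mean)
    c(marginal = mean(kept$label == "canopy"), cell_sd = sd(means))
  }
  flat <- cell_sds(FALSE)
  blotchy <- cell_sds(TRUE)
  # block-level Beta spread leaves ~0.02 SE on the 100-cell marginal
  expect_lt(abs(blotchy[["marginal"]] - 0.3), 0.06)
  expect_gt(blotchy[["cell_sd"]], 2 * flat[["cell_sd"]])
})

test_that("the pipeline recovers true national totals from synthetic worlds", {
  pool_rus <- c(1, 2, 5, 8, 10, 13, 14, 15, 16, 17)

  exact_world <- synthetic_world(ru = ru_fix, cv = 0, seed = 7)
  cities <- generate_city_table(exact_world, 20, ru_ids = pool_rus, seed = 7)
  d <- derive_ecozone_densities(cities, exact_world$ru)
  acct <- build_account(exact_world$ru,
                        assign_ru_densities(exact_world$ru, d))
  truth <- true_national_totals(exact_world)
  expect_equal(acct$national[["storage_kt"]], truth[["storage_kt"]],
               tolerance = 1e-12)
  expect_equal(acct$national[["co2_net_kt"]], truth[["co2_net_kt"]],
               tolerance = 1e-12)

  noisy_world <- synthetic_world(ru = ru_fix, cv = 0.05, seed = 8)
  cities <- generate_city_table(noisy_world, 20, ru_ids = pool_rus, seed = 8)
  d <- derive_ecozone_densities(cities, noisy_world$ru)
  acct <- build_account(noisy_world$ru,
                        assign_ru_densities(noisy_world$ru, d))
  truth <- true_national_totals(noisy_world)
  expect_lt(abs(acct$national[["storage_kt"]] - truth[["storage_kt"]]) /
              truth[["storage_kt"]], 0.02)
  expect_lt(abs(acct$national[["seq_gross_kt"]] - truth[["seq_gross_kt"]]) /
              truth[["seq_gross_kt"]], 0.02)
})

test_that("MC intervals from generated SEs cover the true national value", {
  # fully city-covered worlds: one assessment spanning each RU's urban area,
  # so the only uncertainty is the generated plot-sampling error
  world <- synthetic_world(ru = ru_fix, cv = 0.5, seed = 123)
  urban_ha <- world$ru$urban_area_km2 * 100
  rules <- synthetic_rules(world)
  truth <- true_national_totals(world)[["storage_kt"]]
  cfg_rate_only <- function(seed) suppressWarnings(uncertainty_config(
    iterations = 1500, seed = seed, model_uncertainty = 0,
    canopy_uncertainty = 0, area_lower = 0, area_mode = 0, area_upper = 0))
  covered <- vapply(1:200, function(rep) {
    set.seed(rep)
    cities <- do.call(rbind, lapply(seq_len(nrow(world$ru)), function(i) {
      generate_city(world, world$ru$ru_id[i], urban_ha[i], n_plots = 100,
                    name = paste0("c", i))
    }))
    class(cities) <- c("city_table", "data.frame")
    d <- derive_ecozone_densities(cities, world$ru, rules)
    rd <- assign_ru_densities(world$ru, d)
    mc <- run_monte_carlo(world$ru, cities, rd, cfg_rate_only(rep))
    nat <- mc$storage[mc$storage$ru == "National", ]
    nat$p_low <= truth && truth <= nat$p_high
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.98)
})
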