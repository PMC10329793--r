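derived_ru_densities <- assign_ru_densities(ru_fix, derived_densities)

zeroed_config <- function(iterations = 2000, seed = 1) {
  suppressWarnings(uncertainty_config(
    iterations = iterations, seed = seed, model_uncertainty = 0,
    canopy_uncertainty = 0, area_lower = 0, area_mode = 0, area_upper = 0,
    rate_uncertainty_scale = 0))
}

test_that("RUs classify into the three uncertainty classes", {
  expect_warning(classify_ru(ru_fix, city_fix), "capped at 1")
  cls <- quiet_classify(ru_fix, city_fix)
  expect_equal(cls$class[cls$ru_id == 9], "PROXY")     # no assessed city
  expect_equal(cls$w_city[cls$ru_id == 9], 0)
  expect_equal(cls$class[cls$ru_id == 10], "PARTIAL")
  expect_equal(cls$w_city[cls$ru_id == 10], 202986 / 531700)
  # Halifax's study area exceeds RU 16's urban area: capped, fully covered
  expect_equal(cls$class[cls$ru_id == 16], "CITY_COVERED")
  expect_equal(cls$w_city[cls$ru_id == 16], 1)
  covered <- c(1, 2, 5, 10, 16)
  expect_true(all(cls$w_city[cls$ru_id %in% covered] > 0))
  expect_true(all(cls$w_city[!cls$ru_id %in% covered] == 0))
})

test_that("proxy SDs combine in quadrature (or additively on request)", {
  dists <- suppressWarnings(build_rate_distributions(
    ru_fix, city_fix, derived_ru_densities))
  sd_ic <- attr(dists, "sd_intercity")
  sd_ru <- attr(dists, "sd_interru")
  expect_equal(attr(dists, "reference_ecozone"), "Mixedwood plains")

  d9 <- dists[["9"]]
  expect_equal(d9$class, "PROXY")
  se_proxy <- derived_ru_densities$storage_density_se[
    derived_ru_densities$ru_id == 9]
  expect_equal(d9$storage$sd,
               sqrt(se_proxy^2 + sd_ic[["storage"]]^2 + sd_ru[["storage"]]^2))

  add <- suppressWarnings(build_rate_distributions(
    ru_fix, city_fix, derived_ru_densities,
    uncertainty_config(combine = "additive")))
  expect_equal(add[["9"]]$storage$sd,
               se_proxy + sd_ic[["storage"]] + sd_ru[["storage"]])

  # quadrature matches the SD of a sum of independent normal draws
  set.seed(3)
  parts <- c(2, 5, 7)
  draws <- rnorm(2e5, 0, parts[1]) + rnorm(2e5, 0, parts[2]) +
    rnorm(2e5, 0, parts[3])
  expect_equal(sd(draws), sqrt(sum(parts^2)), tolerance = 0.01)

  # mixture weights within each RU sum to one
  for (d in dists) {
    expect_equal(sum(d$storage$weight), 1, tolerance = 1e-12)
    expect_equal(sum(d$seq$weight), 1, tolerance = 1e-12)
  }
})

test_that("zeroing every uncertainty collapses bounds to the account", {
  acct <- build_account(ru_fix, derived_ru_densities)
  mc <- quiet_mc(ru_fix, city_fix, derived_ru_densities, zeroed_config())
  expect_equal(mc$storage$mean[1:18], acct$ru$storage_kt, tolerance = 1e-9)
  expect_equal(mc$seq_gross$mean[1:18], acct$ru$seq_gross_kt, tolerance = 1e-9)
  nat <- national_row(mc$seq_gross)
  expect_equal(nat$mean, acct$national[["seq_gross_kt"]], tolerance = 1e-9)
  expect_equal(nat$rel_low, 0, tolerance = 1e-12)
  expect_equal(nat$rel_high, 0, tolerance = 1e-12)
  expect_equal(mc$truncation_rate, 0)
})

test_that("triangular draws have the closed-form mean and respect bounds", {
  set.seed(42)
  x <- rtriangular(2e5, 0.9, 1, 1.33)
  expect_equal(mean(x), (0.9 + 1 + 1.33) / 3, tolerance = 0.002)
  expect_true(all(x >= 0.9 & x <= 1.33))
  expect_equal(rtriangular(5, 1, 1, 1), rep(1, 5))
})

test_that("a fixed seed reproduces bounds bit-exactly", {
  cfg <- uncertainty_config(iterations = 2000, seed = 77)
  a <- quiet_mc(ru_fix, city_fix, derived_ru_densities, cfg)
  b <- quiet_mc(ru_fix, city_fix, derived_ru_densities, cfg)
  expect_identical(a$storage, b$storage)
  expect_identical(a$seq_gross, b$seq_gross)
  c2 <- quiet_mc(ru_fix, city_fix, derived_ru_densities,
                 uncertainty_config(iterations = 2000, seed = 78))
  expect_false(identical(a$seq_gross$p_low, c2$seq_gross$p_low))
})

test_that("proxy RUs carry wider relative bounds than city-covered RUs", {
  mc <- quiet_mc(ru_fix, city_fix, derived_ru_densities,
                 uncertainty_config(iterations = 5000, seed = 11))
  width <- function(df) df$rel_high - df$rel_low
  w <- width(mc$seq_gross[1:18, ])
  cls <- mc$seq_gross$class[1:18]
  expect_true(all(w[cls == "PROXY"] > max(w[cls == "CITY_COVERED"])))
  ws <- width(mc$storage[1:18, ])
  expect_true(all(ws[cls == "PROXY"] > max(ws[cls == "CITY_COVERED"])))
})

test_that("MC means track the deterministic account times the area factor", {
  acct <- build_account(ru_fix, derived_ru_densities)
  cfg <- uncertainty_config(iterations = 20000, seed = 5)
  mc <- quiet_mc(ru_fix, city_fix, derived_ru_densities, cfg)
  tri_mean <- (3 + cfg$area_lower + cfg$area_mode + cfg$area_upper) / 3
  # checked on the fully city-covered RU, where rate truncation is negligible
  i <- which(mc$storage$class == "CITY_COVERED")
  mc_se <- mc$storage$sd[i] / sqrt(cfg$iterations)
  expect_lt(abs(mc$storage$mean[i] - acct$ru$storage_kt[i] * tri_mean),
            3 * mc_se)
  mc_se_q <- mc$seq_gross$sd[i] / sqrt(cfg$iterations)
  expect_lt(abs(mc$seq_gross$mean[i] - acct$ru$seq_gross_kt[i] * tri_mean),
            3 * mc_se_q)
})

test_that("degenerate configurations are rejected", {
  expect_error(uncertainty_config(iterations = 1), "at least 2")
  expect_warning(uncertainty_config(iterations = 500), "noisy")
  expect_error(uncertainty_config(area_lower = 0.1), "area_lower")
  one_missing <- derived_ru_densities[derived_ru_densities$ru_id != 9, ]
  expect_error(
    suppressWarnings(build_rate_distributions(ru_fix, city_fix, one_missing)),
    "proxy designation missing")
})
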