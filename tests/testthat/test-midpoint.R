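co2 <- default_pathways()$CO2

test_that("delta DIC follows the emission/dissolution arithmetic", {
  k <- model_constants()
  df <- dissolution_factor(co2)
  expect_equal(delta_dic(1, co2, k), df / (0.044 * 3.61e14), tolerance = 1e-12)
  expect_equal(delta_dic(1, co2, k), 1.727e-14, tolerance = 1e-3)
  expect_identical(delta_dic(0, co2, k), 0)
  expect_equal(delta_dic(2, co2, k), 2 * delta_dic(1, co2, k))  # linearity
  expect_error(delta_dic(-1, co2, k), "non-negative")
  expect_error(model_constants(area_A = -1), "positive")
})

test_that("fate factor matches the closed form and the published magnitude", {
  st <- data.frame(region_id = "r1", rf_mean = 12, spco2_mean = 40,
                   dic_mean = 2.1, n_obs = 10L)
  ff <- fate_factor(st, co2)
  want <- 40 * 12 * dissolution_factor(co2) / (0.044 * 3.61e14 * 2.1)
  expect_equal(ff$value, want, tolerance = 1e-12)
  expect_equal(ff$value, 3.95e-12, tolerance = 2e-3)
  # a typical surface state lands inside the published per-region span
  expect_gt(ff$value, 2.50e-12)
  expect_lt(ff$value, 5.76e-12)

  # no dissolution, no fate; and the substance ratio is exactly the DF ratio
  none <- substance_pathway("X", 1, 1, 0, 0)
  expect_equal(fate_factor(st, none)$value, 0)
  co <- default_pathways()$CO
  expect_equal(fate_factor(st, co)$value / ff$value,
               dissolution_factor(co) / dissolution_factor(co2),
               tolerance = 1e-12)
  expect_error(fate_factor(transform(st, dic_mean = 0), co2), "positive")
})

test_that("fate factor is monotone in the Revelle factor", {
  st <- data.frame(region_id = c("lo", "hi"), rf_mean = c(10, 15),
                   spco2_mean = 40, dic_mean = 2.1, n_obs = 10L)
  ff <- fate_factor(st, co2)
  expect_gt(ff$value[2], ff$value[1])
})

test_that("FSF regression recovers exact linear pH-spCO2 relations", {
  f <- linear_ph_fields(slopes = c(eco001 = -0.01, fao01 = -0.002))
  fsf <- fit_fsf(f, tiny_partition())
  expect_equal(fsf$slope[fsf$region_id == "eco001"], -0.01, tolerance = 1e-12)
  expect_equal(fsf$slope[fsf$region_id == "fao01"], -0.002, tolerance = 1e-12)
  expect_equal(fsf$r_squared, c(1, 1), tolerance = 1e-12)
  expect_identical(fsf$n_obs, c(12L, 12L))

  # flat pH gives a zero slope, not a failure
  fflat <- linear_ph_fields(slopes = c(eco001 = 0, fao01 = 0))
  expect_equal(fit_fsf(fflat, tiny_partition())$slope, c(0, 0), tolerance = 1e-12)
})

test_that("FSF recovers a noisy known slope within its standard error", {
  n <- 1200
  slope_true <- -2e-3
  set.seed(101)
  months <- sprintf("m%02d", 1:n)
  grid <- data.frame(lat = 0, lon = 0, ocean = TRUE)
  spco2 <- matrix(40 + stats::rnorm(n, 0, 2), n, 1)
  ph <- 8.18 + slope_true * spco2 + matrix(stats::rnorm(n, 0, 1e-3), n, 1)
  f <- ocean_fields(grid, months, matrix(12, n, 1), spco2, ph, matrix(2.1, n, 1))
  p <- region_partition(data.frame(region_id = "r", region_type = "fao",
                                   area_km2 = 1),
                        data.frame(lat = 0, lon = 0, region_id = "r"))
  fsf <- fit_fsf(f, p)
  se <- 1e-3 / (stats::sd(spco2) * sqrt(n))
  expect_lt(abs(fsf$slope - slope_true), 3 * se)
})

test_that("regions that cannot be fit are dropped with a warning", {
  f <- linear_ph_fields(n_months = 6)
  f$spco2[, 1:2] <- 40  # zero variance in eco001
  f$ph[, 1:2] <- 8.1
  expect_warning(fsf <- fit_fsf(f, tiny_partition()), "eco001")
  expect_identical(fsf$region_id, "fao01")
})

test_that("midpoint CF is the signed FF x FSF product", {
  ff <- data.frame(region_id = "r1", substance_id = "CO2", value = 3.95e-12)
  fsf <- data.frame(region_id = "r1", slope = -1e-3, intercept = 8.2,
                    r_squared = 1, n_obs = 12L)
  cf <- midpoint_cf(ff, fsf)
  expect_equal(cf$value, 3.95e-15, tolerance = 1e-12)

  # zero sensitivity, zero CF; positive slope warns and stays negative
  expect_equal(midpoint_cf(ff, transform(fsf, slope = 0))$value, 0)
  expect_warning(cf_pos <- midpoint_cf(ff, transform(fsf, slope = 1e-3)),
                 "positive")
  expect_lt(cf_pos$value, 0)
  expect_error(midpoint_cf(ff, transform(fsf, region_id = "other")), "no region")
})

test_that("area-weighted aggregation equals the explicit weighted loop", {
  p <- tiny_partition(area = c(1, 3))
  vals <- data.frame(region_id = c("eco001", "fao01"), value = c(0, 4))
  expect_equal(aggregate_regional(vals, p), 3)  # (1*0 + 3*4)/4

  # equal values collapse to that value regardless of the weights
  eq <- data.frame(region_id = c("eco001", "fao01"), value = c(7, 7))
  expect_equal(aggregate_regional(eq, p), 7)

  set.seed(202)
  n <- 40
  regions <- data.frame(region_id = sprintf("r%02d", 1:n),
                        region_type = "fao",
                        area_km2 = stats::runif(n, 1, 100))
  part <- region_partition(regions,
                           data.frame(lat = numeric(0), lon = numeric(0),
                                      region_id = character(0))) |>
    suppressWarnings()
  vals <- data.frame(region_id = regions$region_id, value = stats::rnorm(n))
  manual <- 0
  for (i in 1:n) {
    manual <- manual + vals$value[i] * regions$area_km2[i] / sum(regions$area_km2)
  }
  expect_equal(aggregate_regional(vals, part), manual, tolerance = 1e-12)
  expect_error(aggregate_regional(vals[0, ], part), "nothing")
})

test_that("normalization is exact for the reference substance", {
  agg <- c(CO2 = 4e-14, CO = 3.5e-14, CH4 = 3.3e-14)
  norm <- normalize_cfs(agg)
  expect_identical(norm[["CO2"]], 1)
  expect_equal(norm[["CO"]], 3.5 / 4)
  expect_error(normalize_cfs(c(CO = 1)), "CO2")
})

test_that("normalized CFs equal dissolution-factor ratios on any field set", {
  # the spatial terms cancel in the normalization: property over seeds
  p <- default_pathways()
  df_ratio <- c(CO2 = 1,
                CO = dissolution_factor(p$CO) / dissolution_factor(p$CO2),
                CH4 = dissolution_factor(p$CH4) / dissolution_factor(p$CO2))
  for (seed in c(3, 17, 91)) {
    w <- small_world(seed = seed)
    mp <- suppressWarnings(midpoint_pipeline(w$fields, w$partition))
    expect_equal(mp$normalized, df_ratio, tolerance = 1e-10)
  }
})

test_that("scenario comparison reports exact deltas", {
  w <- small_world(seed = 23)
  same <- suppressWarnings(compare_scenarios(w$fields, w$fields, w$partition))
  expect_equal(same$mean_delta_rf, 0)
  expect_equal(same$mean_delta_cf, 0)

  shifted <- w$fields
  shifted$rf <- shifted$rf + 1
  cmp <- suppressWarnings(compare_scenarios(w$fields, shifted, w$partition))
  expect_equal(cmp$mean_delta_rf, 1, tolerance = 1e-12)
  # FF is linear in RF, so each region's CF shifts by value/rf_mean
  st <- regional_average(w$fields, w$partition)
  fsf <- fit_fsf(w$fields, w$partition)
  cf <- suppressWarnings(midpoint_cf(fate_factor(st, co2), fsf))
  m <- merge(merge(cf, st[, c("region_id", "rf_mean")], by = "region_id"),
             fsf[, c("region_id", "slope")], by = "region_id")
  expect_equal(cmp$mean_delta_cf, mean(m$value / m$rf_mean), tolerance = 1e-9)

  bad <- w$fields
  bad$months <- c(bad$months[-1], "m99")
  expect_error(compare_scenarios(w$fields, bad, w$partition), "share grid")
})
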