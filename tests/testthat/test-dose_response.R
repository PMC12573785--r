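make_record <- function(tests = data.frame(ph = c(7.9, 7.6, 7.3),
                                           response = c(90, 50, 10)),
                        ...) {
  args <- list(experiment_id = "e1", species_id = "s1",
               trait = "calcification_rate",
               direction = "harm_decreases_response",
               ph_c = 8.1, r_c = 100, tests = tests,
               calcification = "strong", climate_zones = "temperate",
               trophic_level = 3)
  args[names(list(...))] <- list(...)
  do.call(experiment_record, args)
}

test_that("record validation enforces the experimental contract", {
  expect_s3_class(make_record(), "oa_experiment")
  expect_error(make_record(tests = data.frame(ph = c(7.9, 7.9),
                                              response = c(1, 2))), "distinct")
  expect_error(make_record(ph_c = 4.2), "\\[5, 9\\]")
  expect_error(make_record(r_c = 0), "control response")
  expect_error(make_record(calcification = "heavy"), "calcification")
  expect_error(make_record(climate_zones = character(0)), "climate_zones")
})

test_that("screening applies the inclusion rules without raising", {
  expect_true(screen_experiment(make_record())$accept)
  expect_match(screen_experiment(make_record(n_stressors = 2))$reason,
               "multiple stressors")
  expect_match(screen_experiment(make_record(kingdom = "plantae"))$reason,
               "animalia")
  expect_match(screen_experiment(make_record(trophic_level = 5))$reason,
               "trophic")
  two <- make_record(tests = data.frame(ph = c(7.9, 7.5), response = c(90, 30)))
  expect_match(screen_experiment(two)$reason, "insufficient")
})

test_that("empirical relative response follows the direction convention", {
  # harm-decreasing trait: eRR = 1 - Rt/Rc
  dec <- make_record(tests = data.frame(ph = c(7.9, 7.6, 7.3),
                                        response = c(100, 50, 0)))
  expect_equal(empirical_relative_response(dec)$err, c(0, 0.5, 1))

  # harm-increasing trait (bioerosion): eRR = 1 - Rc/Rt
  inc <- make_record(direction = "harm_increases_response", r_c = 2,
                     tests = data.frame(ph = c(7.9, 7.6, 7.3),
                                        response = c(2, 4, 8)))
  expect_equal(empirical_relative_response(inc)$err, c(0, 0.5, 0.75))

  # responses better than control give negative values, retained
  better <- make_record(tests = data.frame(ph = c(7.9, 7.6, 7.3),
                                           response = c(120, 60, 10)))
  expect_equal(empirical_relative_response(better)$err[1], -0.2)

  # scale invariance: multiplying all responses leaves eRR unchanged
  scaled <- make_record(r_c = 300,
                        tests = data.frame(ph = c(7.9, 7.6, 7.3),
                                           response = 3 * c(100, 50, 0)))
  expect_equal(empirical_relative_response(scaled)$err,
               empirical_relative_response(dec)$err)

  zero <- make_record(direction = "harm_increases_response",
                      tests = data.frame(ph = c(7.9, 7.6, 7.3),
                                         response = c(0, 4, 8)))
  expect_error(empirical_relative_response(zero), "zero test response")
})

test_that("noiseless logistic points are recovered to high precision", {
  ph <- c(8.1, 7.9, 7.7, 7.5, 7.3)
  pts <- data.frame(ph = ph, err = 1 / (1 + 10^((ph - 7.6) / 0.2)))
  fit <- fit_dose_response(pts)
  expect_true(fit$converged)
  expect_equal(fit$ph50, 7.6, tolerance = 1e-6)
  expect_equal(fit$beta, 0.2, tolerance = 1e-6)
  expect_lt(fit$residual_sse, 1e-12)
  expect_equal(predict(fit, 7.6), 0.5, tolerance = 1e-6)
  expect_equal(residuals(fit), rep(0, 5), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("degenerate and invalid dose-response inputs are handled", {
  flat <- data.frame(ph = c(8.0, 7.6, 7.2), err = c(0.5, 0.5, 0.5))
  fit <- fit_dose_response(flat)
  expect_false(fit$converged)
  expect_error(ph10_from_fit(fit), "unconverged")
  expect_error(predict(fit, 7.5), "unconverged")

  expect_error(fit_dose_response(data.frame(ph = c(8, 7.6), err = c(0.1, 0.9))),
               "3 distinct")
  expect_error(fit_dose_response(data.frame(ph = c(8, 7.6, NA),
                                            err = c(0.1, 0.9, 0.5))),
               "non-finite")
})

test_that("noisy fits recover the generating parameters within a wide band", {
  set.seed(77)
  ph <- c(8.1, 7.9, 7.7, 7.5, 7.3, 7.1)
  n_rep <- 40
  est <- t(vapply(seq_len(n_rep), function(i) {
    err <- 1 / (1 + 10^((ph - 7.5) / 0.15)) + stats::rnorm(length(ph), 0, 0.05)
    f <- fit_dose_response(data.frame(ph = ph, err = err))
    c(f$ph50, f$beta)
  }, numeric(2)))
  # simulation band: the true values sit inside the central 95% of estimates
  expect_gt(7.5, stats::quantile(est[, 1], 0.025))
  expect_lt(7.5, stats::quantile(est[, 1], 0.975))
  expect_lt(abs(mean(est[, 1]) - 7.5), 0.05)
})

test_that("pH10 closed form equals numerical inversion of the response curve", {
  fit <- fit_dose_response(data.frame(
    ph = c(8.1, 7.9, 7.7, 7.5, 7.3),
    err = 1 / (1 + 10^((c(8.1, 7.9, 7.7, 7.5, 7.3) - 7.6) / 0.2))))
  expect_equal(fit$ph10, 7.6 + 0.2 * log10(9), tolerance = 1e-6)
  expect_equal(fit$ph10, 7.7908, tolerance = 1e-4)

  # property over random parameter draws: closed form == root finding
  set.seed(9)
  for (i in 1:20) {
    ph50 <- stats::runif(1, 7, 8)
    beta <- stats::runif(1, 0.05, 0.5)
    f <- list(ph50 = ph50, beta = beta, converged = TRUE)
    class(f) <- "oa_drc"
    closed <- ph10_from_fit(f)
    root <- stats::uniroot(function(p) 1 / (1 + 10^((p - ph50) / beta)) - 0.10,
                           interval = c(5, 10), tol = 1e-12)$root
    expect_equal(closed, root, tolerance = 1e-9)
  }
})

test_that("species summaries average converged fits and keep categories", {
  recs <- list(
    make_record(),
    make_record(tests = data.frame(ph = c(7.9, 7.6, 7.3),
                                   response = c(95, 55, 15))),
    make_record(climate_zones = c("polar", "temperate"))
  )
  recs[[2]]$species_id <- "s1"
  recs[[3]]$species_id <- "s2"
  fits <- lapply(recs, function(r) fit_dose_response(empirical_relative_response(r)))
  ss <- species_summary(fits, recs)
  expect_identical(nrow(ss), 2L)
  expect_equal(ss$ph50[ss$species_id == "s1"],
               mean(c(fits[[1]]$ph50, fits[[2]]$ph50)))
  expect_identical(ss$n_experiments[ss$species_id == "s1"], 2L)
  expect_setequal(strsplit(ss$climate_zones[ss$species_id == "s2"], ";")[[1]],
                  c("polar", "temperate"))

  # a species whose only fit failed is dropped with a warning
  bad <- make_record(tests = data.frame(ph = c(7.9, 7.6, 7.3),
                                        response = c(50, 50, 50)))
  bad$species_id <- "s3"
  fits3 <- c(fits, list(fit_dose_response(empirical_relative_response(bad))))
  expect_warning(ss3 <- species_summary(fits3, c(recs, list(bad))), "s3")
  expect_identical(nrow(ss3), 2L)
})

test_that("experiments round-trip through the long CSV format", {
  recs <- generate_experiments(species_gen_config(n_species = 5, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_experiments_csv(recs, path)
  back <- read_experiments_csv(path)
  expect_identical(length(back), 5L)
  r0 <- recs[[3]]
  r1 <- back[[r0$experiment_id]]
  expect_equal(r1$tests$response, r0$tests$response, tolerance = 1e-9)
  expect_identical(r1$climate_zones, r0$climate_zones)
  expect_identical(r1$trophic_level, r0$trophic_level)
})
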