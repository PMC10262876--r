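test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_households = 15, seed = 7)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  for (nm in c("households", "acquisitions", "ffq_responses", "recalls",
               "ground_truth"))
    expect_identical(a[[nm]], b[[nm]])
  expect_false(identical(a$recalls,
                         simulate_study(simulation_config(n_households = 15,
                                                          seed = 8))$recalls))
})

test_that("degenerate noise collapses person-day intakes to exp(mu)", {
  cfg <- simulation_config(
    n_households = 10, seed = 3,
    prop_households_using_raw_flour = 0,
    child_intake_ratio = 1,
    vehicle_params = list(wheat_flour = list(mu_log = 3, sigma_between = 0,
                                             sigma_within = 0),
                          oil = list(mu_log = 1, sigma_between = 0,
                                     sigma_within = 0)))
  sim <- simulate_study(cfg)
  pdt <- person_day_totals(sim$recalls)
  expect_equal(pdt$grams[pdt$vehicle == "wheat_flour"],
               rep(exp(3), sum(pdt$vehicle == "wheat_flour")), tolerance = 1e-12)
  expect_equal(pdt$grams[pdt$vehicle == "oil"],
               rep(exp(1), sum(pdt$vehicle == "oil")), tolerance = 1e-12)
})

test_that("variance of log person-means matches the log-normal hierarchy", {
  cfg <- simulation_config(
    n_households = 500, seed = 11, recall_days_mother = 4,
    prop_households_using_raw_flour = 0,
    vehicle_params = list(wheat_flour = list(mu_log = 3, sigma_between = 0.5,
                                             sigma_within = 0.7)))
  sim <- simulate_study(cfg)
  pdt <- mothers_of(person_day_totals(sim$recalls, "wheat_flour"))
  person_means <- tapply(log(pdt$grams), pdt$person_id, mean)
  expect_length(person_means, 500)
  analytic <- sqrt(0.5^2 + 0.7^2 / 4)
  expect_lt(abs(sd(person_means) / analytic - 1), 0.10)
})

test_that("population mean of person-day intakes converges to the log-normal mean", {
  cfg <- simulation_config(
    n_households = 2000, seed = 5,
    prop_households_using_raw_flour = 0,
    vehicle_params = list(wheat_flour = list(mu_log = 3.4, sigma_between = 0.5,
                                             sigma_within = 0.7)))
  sim <- simulate_study(cfg)
  pdt <- mothers_of(person_day_totals(sim$recalls, "wheat_flour"))
  expect_lt(abs(mean(pdt$grams) / exp(3.4 + (0.5^2 + 0.7^2) / 2) - 1), 0.05)
})

test_that("raw-flour non-user fraction matches the configured proportion", {
  sim <- simulate_study(simulation_config(n_households = 400, seed = 9))
  acq <- sim$acquisitions
  p_nonuser <- mean(acq$uses_fortifiable[acq$vehicle == "wheat_flour"] == 0)
  expect_lt(abs(p_nonuser - 0.64), 3 * sqrt(0.36 * 0.64 / 400))
})

test_that("every household has one mother, one child, and 0-4 others", {
  sim <- simulate_study(simulation_config(n_households = 50, seed = 2))
  hh <- sim$households
  roles <- table(hh$household_id, hh$role)
  expect_true(all(roles[, "mother"] == 1))
  expect_true(all(roles[, "child"] == 1))
  expect_true(all(roles[, "other"] <= 4))
  mothers <- hh[hh$role == "mother", ]
  children <- hh[hh$role == "child", ]
  expect_true(all(mothers$age_years >= 18 & mothers$age_years <= 49))
  expect_true(all(mothers$sex == "F"))
  expect_true(all(children$age_years >= 1.0 & children$age_years <= 1.5))
})

test_that("fixtures round-trip through write_fixture and read_fixture", {
  sim <- simulate_study(simulation_config(n_households = 8, seed = 4))
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  back <- read_fixture(dir)
  for (nm in names(back))
    expect_equal(back[[nm]], sim[[nm]], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("empty tables serialise to header-only files", {
  sim <- simulate_study(simulation_config(n_households = 2, seed = 1))
  empty <- lapply(sim[c("households", "acquisitions", "ffq_responses",
                        "recalls", "ground_truth")], function(d) d[0, ])
  dir <- withr::local_tempdir()
  write_fixture(empty, dir)
  back <- read_fixture(dir)
  for (nm in names(back)) {
    expect_equal(nrow(back[[nm]]), 0)
    expect_named(back[[nm]], names(sim[[nm]]))
  }
})

test_that("a 120-household fixture loads quickly and has valid schemas", {
  sim <- simulate_study(simulation_config(n_households = 120, seed = 16))
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  elapsed <- system.time(back <- read_fixture(dir))[["elapsed"]]
  expect_lt(elapsed, 1)
  expect_true(all(c("household_id", "member_id", "role", "age_years", "sex")
                  %in% names(back$households)))
  expect_true(all(c("household_id", "vehicle", "uses_fortifiable", "amount_g",
                    "lasts_days") %in% names(back$acquisitions)))
  expect_true(all(c("person_id", "item_id", "times_per_7d", "portion_code")
                  %in% names(back$ffq_responses)))
  expect_true(all(c("person_id", "day_index", "food_id", "food_group",
                    "amount_g", "frac_wheat_flour", "frac_oil", "fortifiable")
                  %in% names(back$recalls)))
  # acquisition records of fortifiable users are internally consistent
  acq <- back$acquisitions
  users <- acq[acq$uses_fortifiable == 1, ]
  expect_true(all(users$amount_g >= 0 & users$lasts_days > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_households = 1), "n_households")
  expect_error(simulation_config(prop_households_using_raw_flour = 1.2),
               "fractions")
  expect_error(simulation_config(ffq_noise_sd = -0.1), "ffq_noise_sd")
  expect_error(simulation_config(
    vehicle_params = list(wheat_flour = list(mu_log = 3, sigma_between = -1,
                                             sigma_within = 0.5))), "SDs")
})
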