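est_df <- function(values, method = "FAPQ", group = "mother",
                   vehicle = "wheat_flour") {
  data.frame(person_id = sprintf("p%04d", seq_along(values)), group = group,
             method = method, vehicle = vehicle, grams_per_day = values)
}

test_that("outlier exclusion is a single-pass 3-SD rule on simplified methods only", {
  expect_equal(nrow(exclude_outliers(est_df(rep(5, 10)))$excluded), 0)

  withr::with_seed(51, x <- c(rnorm(50, 10, 2), 60))
  ex <- exclude_outliers(est_df(x))
  expect_equal(ex$excluded$person_id, "p0051")
  expect_equal(nrow(ex$kept), 50)

  # the recall stream passes through untouched even with an extreme value
  rec <- est_df(x, method = "RECALL24")
  expect_equal(nrow(exclude_outliers(rec)$excluded), 0)
  expect_equal(nrow(exclude_outliers(rec)$kept), 51)
})

test_that("outlier exclusion equals a brute-force z-score scan", {
  withr::with_seed(52, x <- rlnorm(1000, 2, 1.2))
  ex <- exclude_outliers(est_df(x, method = "SQFFQ"))
  manual <- which(abs(x - mean(x)) > 3 * sd(x))
  expect_setequal(ex$excluded$person_id, sprintf("p%04d", manual))
  expect_equal(nrow(ex$kept), 1000 - length(manual))
})

test_that("matching drops exactly the recall persons without a counterpart", {
  rec <- est_df(1:10, method = "RECALL24")
  simp <- est_df(1:10)
  expect_equal(nrow(match_observations(rec, simp)$dropped), 0)
  expect_equal(nrow(match_observations(rec, simp[0, ])$kept), 0)
  m <- match_observations(rec, simp[simp$person_id %in%
                                      sprintf("p%04d", c(1:6, 9)), ])
  expect_setequal(m$dropped$person_id, sprintf("p%04d", c(7, 8, 10)))
  # set-difference oracle
  expect_setequal(m$dropped$person_id,
                  setdiff(rec$person_id, sprintf("p%04d", c(1:6, 9))))
  # matching is per vehicle as well as per person
  rec2 <- rec
  rec2$vehicle <- "oil"
  expect_equal(nrow(match_observations(rec2, simp)$kept), 0)
})

test_that("summaries report mean, median and type-7 quartiles", {
  s <- summarize_estimates(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$median, 2.5)
  expect_equal(c(s$p25, s$p75), c(1.75, 3.25))
  s1 <- summarize_estimates(7)
  expect_equal(c(s1$mean, s1$median, s1$p25, s1$p75), rep(7, 4))
  expect_error(summarize_estimates(numeric(0)), "empty")

  # sort-based linear-interpolation oracle
  withr::with_seed(53, x <- runif(1000) * 100)
  q_oracle <- function(x, p) {
    xs <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[pmin(lo + 1, length(x))] - xs[lo])
  }
  s <- summarize_estimates(x)
  expect_equal(s$median, q_oracle(x, 0.5), tolerance = 1e-12)
  expect_equal(s$p25, q_oracle(x, 0.25), tolerance = 1e-12)
  expect_equal(s$p75, q_oracle(x, 0.75), tolerance = 1e-12)
})

test_that("method comparisons produce ratios and percent differences", {
  a <- list(mean = 14.1, median = 12.5)
  b <- list(mean = 2.2, median = 0)
  cmp <- compare_methods(a, b)
  expect_gt(cmp$ratio_of_means, 6)
  expect_true(cmp$undefined)  # zero median flagged

  same <- compare_methods(a, a)
  expect_equal(same$ratio_of_means, 1)
  expect_equal(same$pct_diff_means, 0)

  x <- list(mean = 51.5, median = 40.4)
  y <- list(mean = 42.3, median = 37.6)
  expect_equal(round(compare_methods(x, y)$pct_diff_means), 22)
  # swap antisymmetry: sign flips, ratio inverts
  fw <- compare_methods(x, y)
  bw <- compare_methods(y, x)
  expect_equal(fw$ratio_of_means, 1 / bw$ratio_of_means)
  expect_equal(sign(fw$pct_diff_means), -sign(bw$pct_diff_means))

  z <- list(mean = 0, median = 0)
  expect_true(is.na(compare_methods(a, z)$ratio_of_means))
})

test_that("source shares normalise to 100 percent", {
  one <- data.frame(person_id = "p1", food_group = "breads", grams_per_day = 5)
  expect_equal(source_shares(one)$share_pct, 100)

  two <- data.frame(person_id = c("p1", "p1"),
                    food_group = c("breads", "noodles"),
                    grams_per_day = c(5, 5))
  expect_equal(source_shares(two)$share_pct, c(50, 50))

  withr::with_seed(54, {
    rnd <- data.frame(person_id = sample(sprintf("p%02d", 1:20), 100, TRUE),
                      food_group = sample(c("breads", "noodles", "cakes",
                                            "crackers", "other"), 100, TRUE),
                      grams_per_day = runif(100, 0, 30))
  })
  expect_equal(sum(source_shares(rnd)$share_pct), 100, tolerance = 1e-9)
  zero <- data.frame(person_id = "p1", food_group = "breads", grams_per_day = 0)
  expect_error(source_shares(zero), "zero")
})

test_that("FFQ and recall source-share inputs cover the same food groups", {
  sim <- simulate_study(simulation_config(n_households = 25, seed = 61))
  ffq_pg <- ffq_group_intakes(sim$ffq_responses)
  rec_pg <- recall_group_intakes(sim$recalls)
  s1 <- source_shares(ffq_pg)
  s2 <- source_shares(rec_pg)
  expect_equal(sum(s1$share_pct), 100, tolerance = 1e-9)
  expect_equal(sum(s2$share_pct), 100, tolerance = 1e-9)
  expect_true(all(s2$food_group %in%
                    c("breads", "noodles", "crackers", "cakes", "other")))
})

test_that("the full report applies exclusions in the documented order", {
  withr::with_seed(55, {
    n <- 60
    base <- est_df(rlnorm(n, 2, 0.5), method = "RECALL24")
    fapq <- est_df(c(rlnorm(n - 5, 1, 0.5), 500), method = "FAPQ")  # n-4 persons
    ffq <- est_df(rlnorm(n - 2, 2.2, 0.5), method = "SQFFQ")
  })
  rep <- comparison_report(rbind(base, fapq, ffq))
  s_fapq <- rep$summaries[["FAPQ.mother.wheat_flour"]]
  expect_equal(s_fapq$n + s_fapq$excluded_outliers, n - 4)
  rec_vs_fapq <- rep$summaries[["RECALL24_vs.FAPQ.mother.wheat_flour"]]
  expect_equal(rec_vs_fapq$n + rec_vs_fapq$excluded_unmatched, n)
  expect_equal(rec_vs_fapq$n, s_fapq$n)
  cmp <- rep$comparisons[["FAPQ.mother.wheat_flour"]]
  expect_equal(cmp$pct_diff_means_report, round(cmp$pct_diff_means))
  # JSON round trip does not error
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  expect_true(file.exists(path))
})
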