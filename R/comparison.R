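#' Exclude outliers from simplified-method estimates
#'
#' Within each method x group x vehicle stratum of the simplified instruments
#' (FAPQ and SQ-FFQ), values more than 3 sample standard deviations from the
#' stratum mean are excluded. The mean and SD are computed once on the full
#' stratum (a single pass, no re-iteration after removal), and the rule is
#' never applied to the 24-h-recall stream, which passes through untouched.
#'
#' @param estimates Data.frame of individual estimates with columns
#'   `person_id`, `group`, `method`, `vehicle`, `grams_per_day`.
#' @param methods Methods subject to the rule (default the two simplified
#'   instruments).
#' @param n_sd Exclusion threshold in SD units (default 3).
#' @return List with `kept` (the filtered table) and `excluded` (the
#'   exclusion log: the removed rows plus the stratum `mean` and `sd`).
#' @export
exclude_outliers <- function(estimates, methods = c("FAPQ", "SQFFQ"), n_sd = 3) {
  assert_cols(estimates, c("person_id", "group", "method", "vehicle",
                           "grams_per_day"), "estimates")
  target <- estimates$method %in% methods
  strat <- interaction(estimates$method, estimates$group, estimates$vehicle,
                       drop = TRUE)
  drop <- logical(nrow(estimates))
  logs <- list()
  for (s in levels(strat)) {
    idx <- which(strat == s & target)
    if (length(idx) < 2L) next
    x <- estimates$grams_per_day[idx]
    m <- mean(x)
    sdev <- sd(x)
    if (sdev == 0) next
    out <- abs(x - m) > n_sd * sdev
    if (any(out)) {
      drop[idx[out]] <- TRUE
      logs[[s]] <- cbind(estimates[idx[out], , drop = FALSE],
                         stratum_mean = m, stratum_sd = sdev)
    }
  }
  excluded <- if (length(logs) > 0L) do.call(rbind, logs) else
    cbind(estimates[0, , drop = FALSE], stratum_mean = numeric(0),
          stratum_sd = numeric(0))
  rownames(excluded) <- NULL
  list(kept = estimates[!drop, , drop = FALSE], excluded = excluded)
}

#' Drop recall observations with no simplified-method counterpart
#'
#' Recall-based estimates are compared to each simplified instrument on the
#' persons both observed: recall rows whose `(person_id, vehicle)` has no
#' counterpart in the (post-outlier-exclusion) simplified set are excluded.
#' Because pairing is per method, the FAPQ-matched and SQ-FFQ-matched recall
#' sets may differ.
#'
#' @param recall Data.frame of recall-based estimates (`person_id`,
#'   `vehicle`, ...).
#' @param simplified Data.frame of one simplified method's estimates after
#'   outlier exclusion.
#' @return List with `kept` (matched recall rows) and `dropped`.
#' @export
match_observations <- function(recall, simplified) {
  assert_cols(recall, c("person_id", "vehicle"), "recall estimates")
  assert_cols(simplified, c("person_id", "vehicle"), "simplified estimates")
  keys <- function(d) paste(d$person_id, d$vehicle)
  keep <- keys(recall) %in% keys(simplified)
  list(kept = recall[keep, , drop = FALSE],
       dropped = recall[!keep, , drop = FALSE])
}

#' Summary statistics of a set of individual estimates
#'
#' Mean, median and the interquartile range, with quartiles computed by the
#' linear-interpolation (type 7) quantile convention.
#'
#' @param values Numeric vector (at least one value).
#' @param excluded_outliers,excluded_unmatched Bookkeeping counts carried
#'   into the summary.
#' @return Object of class `method_summary`: `n`, `mean`, `median`, `p25`,
#'   `p75`, `excluded_outliers`, `excluded_unmatched`.
#' @export
summarize_estimates <- function(values, excluded_outliers = 0L,
                                excluded_unmatched = 0L) {
  if (length(values) < 1L) stop_config("cannot summarise an empty estimate set")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(n = length(values), mean = mean(values),
                 median = median(values), p25 = q[1L], p75 = q[2L],
                 excluded_outliers = excluded_outliers,
                 excluded_unmatched = excluded_unmatched),
            class = "method_summary")
}

#' @export
print.method_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean %.2f, median %.2f, IQR %.2f-%.2f\n",
              x$n, x$mean, x$median, x$p25, x$p75))
  invisible(x)
}

#' Population-level comparison of two method summaries
#'
#' Ratio of means and percent differences of means and medians, the
#' quantities used to contrast the simplified instruments against the recall
#' reference. Values are returned unrounded; rounding to integer percent
#' happens only at the report layer.
#'
#' @param a,b `method_summary` objects (or lists with `mean` and `median`),
#'   compared as `a` relative to `b`.
#' @return List: `ratio_of_means`, `pct_diff_means`, `pct_diff_medians`,
#'   `undefined` (TRUE when `b` has zero mean/median making a quantity
#'   undefined).
#' @export
compare_methods <- function(a, b) {
  ratio <- if (b$mean == 0) NA_real_ else a$mean / b$mean
  pdm <- if (b$mean == 0) NA_real_ else 100 * (a$mean - b$mean) / b$mean
  pdmed <- if (b$median == 0) NA_real_ else 100 * (a$median - b$median) / b$median
  list(ratio_of_means = ratio, pct_diff_means = pdm, pct_diff_medians = pdmed,
       undefined = b$mean == 0 || b$median == 0)
}

#' Food-group shares of total fortifiable flour
#'
#' Computes each food group's percentage of total fortifiable wheat flour,
#' based on unadjusted means across persons: group means are averaged over
#' persons (a person contributes zero to groups they did not consume) and
#' normalised to sum to 100.
#'
#' @param person_group Data.frame `person_id`, `food_group`, `grams_per_day`
#'   of per-person mean daily flour from each group (see
#'   [ffq_group_intakes()] and [recall_group_intakes()]).
#' @return Data.frame `food_group`, `share_pct`, shares summing to 100.
#' @export
source_shares <- function(person_group) {
  assert_cols(person_group, c("person_id", "food_group", "grams_per_day"),
              "person-group intakes")
  tot <- tapply(person_group$grams_per_day, person_group$food_group, sum)
  if (sum(tot) <= 0) stop_config("total flour is zero: shares undefined")
  data.frame(food_group = names(tot),
             share_pct = 100 * as.numeric(tot) / sum(tot),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-person, per-food-group mean daily flour from recall entries
#'
#' Companion to [ffq_group_intakes()] for the recall stream: sums fortifiable
#' flour per person x food group across all entries and divides by the
#' person's number of recalled days, yielding unadjusted per-person daily
#' means by group.
#'
#' @param entries Recall entry table (see [person_day_totals()]).
#' @return Data.frame `person_id`, `food_group`, `grams_per_day`.
#' @export
recall_group_intakes <- function(entries) {
  assert_cols(entries, c("person_id", "day_index", "food_group"), "recall entries")
  g <- vehicle_grams(entries, "wheat_flour")
  ndays <- tapply(entries$day_index, entries$person_id,
                  function(d) length(unique(d)))
  agg <- aggregate(list(grams = g),
                   by = list(person_id = as.character(entries$person_id),
                             food_group = entries$food_group), FUN = sum)
  agg <- agg[agg$grams > 0, , drop = FALSE]
  data.frame(person_id = agg$person_id, food_group = agg$food_group,
             grams_per_day = agg$grams / as.numeric(ndays[agg$person_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full method-comparison report
#'
#' Applies the documented exclusion order — outlier exclusion on the
#' simplified instruments first, then per-method matching of recall
#' observations — and assembles summaries and pairwise comparisons for every
#' group x vehicle stratum.
#'
#' @param estimates Long table of individual estimates (`person_id`, `group`,
#'   `method` in FAPQ/SQFFQ/RECALL24, `vehicle`, `grams_per_day`).
#' @param round_report Round percent differences to integers in the
#'   `comparisons` element (raw values are always kept alongside).
#' @return A list with `summaries` (per method x group x vehicle),
#'   `comparisons` (each simplified method vs the matched recall set) and
#'   `exclusions` (outlier and matching logs). Serialisable with
#'   [write_report_json()].
#' @export
comparison_report <- function(estimates, round_report = TRUE) {
  ex <- exclude_outliers(estimates)
  kept <- ex$kept
  summaries <- list()
  comparisons <- list()
  for (grp in unique(kept$group)) {
    for (veh in unique(kept$vehicle)) {
      sub <- kept[kept$group == grp & kept$vehicle == veh, , drop = FALSE]
      recall <- sub[sub$method == "RECALL24", , drop = FALSE]
      for (m in intersect(c("FAPQ", "SQFFQ"), unique(sub$method))) {
        simp <- sub[sub$method == m, , drop = FALSE]
        n_out <- sum(ex$excluded$method == m & ex$excluded$group == grp &
                       ex$excluded$vehicle == veh)
        s_simp <- summarize_estimates(simp$grams_per_day,
                                      excluded_outliers = n_out)
        mt <- match_observations(recall, simp)
        key <- paste(m, grp, veh, sep = ".")
        summaries[[key]] <- s_simp
        if (nrow(mt$kept) > 0L) {
          s_rec <- summarize_estimates(mt$kept$grams_per_day,
                                       excluded_unmatched = nrow(mt$dropped))
          summaries[[paste("RECALL24_vs", m, grp, veh, sep = ".")]] <- s_rec
          cmp <- compare_methods(s_simp, s_rec)
          if (round_report) {
            cmp$pct_diff_means_report <- round(cmp$pct_diff_means)
            cmp$pct_diff_medians_report <- round(cmp$pct_diff_medians)
          }
          comparisons[[key]] <- cmp
        }
      }
    }
  }
  list(summaries = summaries, comparisons = comparisons,
       exclusions = list(outliers = ex$excluded))
}

#' Write a comparison report as JSON
#'
#' @param report Output of [comparison_report()] (any list works).
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, pretty = TRUE)
  invisible(path)
}
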