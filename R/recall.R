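#' Grams of a fortifiable vehicle in recalled food entries
#'
#' Each recalled food or mixed dish carries recipe-derived ingredient
#' fractions (`frac_wheat_flour`, `frac_oil`) and a `fortifiable` flag
#' (industrially processed and not made at home). The vehicle grams in an
#' entry are `amount_g * fraction * fortifiable`.
#'
#' @param entries Data.frame of recall entries with columns `amount_g`,
#'   `frac_wheat_flour`, `frac_oil`, `fortifiable` (0/1).
#' @param vehicle `"wheat_flour"` or `"oil"`.
#' @return Numeric vector of grams, one per entry row.
#' @export
vehicle_grams <- function(entries, vehicle = c("wheat_flour", "oil")) {
  vehicle <- match.arg(vehicle)
  assert_cols(entries, c("amount_g", "frac_wheat_flour", "frac_oil", "fortifiable"),
              "recall entries")
  validate_recall_entries(entries)
  frac <- entries[[paste0("frac_", vehicle)]]
  entries$amount_g * frac * as.numeric(as.logical(entries$fortifiable))
}

validate_recall_entries <- function(entries) {
  if (any(entries$amount_g < 0, na.rm = TRUE))
    stop_config("recall amount_g must be >= 0")
  f1 <- entries$frac_wheat_flour
  f2 <- entries$frac_oil
  if (any(f1 < 0 | f1 > 1 | f2 < 0 | f2 > 1, na.rm = TRUE))
    stop_config("recipe fractions must lie in [0, 1]")
  if (any(f1 + f2 > 1 + 1e-9, na.rm = TRUE))
    stop_config("frac_wheat_flour + frac_oil must not exceed 1")
  invisible(entries)
}

#' Person-day totals of fortifiable vehicles from recall entries
#'
#' Sums vehicle grams over all food entries of each person on each recalled
#' day. Every person-day present in the input yields one row per vehicle,
#' including explicit zeros for days on which no vehicle-containing food was
#' eaten; person-days absent from the input yield no row (missing, not zero).
#'
#' @param entries Recall entry table with `person_id`, `day_index` and the
#'   columns required by [vehicle_grams()]; an optional `source` column
#'   (`"recall"` or `"observation_plus_recall"`) is carried through.
#' @param vehicles Character vector of vehicles to total.
#' @return Data.frame `person_id`, `day_index`, `vehicle`, `grams`, `source`,
#'   one row per person x day x vehicle.
#' @export
person_day_totals <- function(entries, vehicles = c("wheat_flour", "oil")) {
  assert_cols(entries, c("person_id", "day_index"), "recall entries")
  validate_recall_entries(entries)
  src <- if ("source" %in% names(entries)) entries$source else
    rep("recall", nrow(entries))
  key <- interaction(entries$person_id, entries$day_index, drop = TRUE)
  day_src <- tapply(src, key, function(s) {
    u <- unique(s)
    if (length(u) > 1L)
      stop_config("conflicting source flags within one person-day")
    u
  })
  out <- do.call(rbind, lapply(vehicles, function(v) {
    g <- vehicle_grams(entries, v)
    tot <- tapply(g, key, sum)
    pid <- tapply(as.character(entries$person_id), key, `[`, 1L)
    day <- tapply(entries$day_index, key, `[`, 1L)
    data.frame(person_id = unname(pid), day_index = unname(day), vehicle = v,
               grams = unname(tot), source = unname(day_src[names(tot)]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$person_id, out$day_index, out$vehicle), , drop = FALSE]
  rownames(out) <- NULL
  out
}
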