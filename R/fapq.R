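#' Adult-male-equivalent (AME) lookup tables
#'
#' The AME method expresses each household member's energy requirement as a
#' fraction of an adult male's (18-29.9 y = 1.0) and apportions household-level
#' food use across members in proportion to those fractions. The shipped
#' default table derives its values from FAO/WHO/UNU energy-requirement
#' ratios; it is configuration, not a fixed constant of the method, and any
#' table with the same schema can be supplied instead.
#'
#' A valid table has columns `sex` (`"M"`/`"F"`), `age_min_years`,
#' `age_max_years` and `ame`. Bands are half-open `[age_min, age_max)` and
#' must partition `[0, Inf)` within each sex without overlap; all `ame`
#' values must be positive.
#'
#' @param path Path to a CSV file with the schema above.
#' @return A validated `data.frame` of AME bands.
#' @examples
#' tab <- default_ame_table()
#' ame_of(25, "M", tab)  # reference adult male -> 1
#' @export
default_ame_table <- function() {
  read_ame_table(system.file("extdata", "ame_table.csv", package = "fortintake"))
}

#' @rdname default_ame_table
#' @export
read_ame_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_ame_table(tab)
}

validate_ame_table <- function(tab) {
  assert_cols(tab, c("sex", "age_min_years", "age_max_years", "ame"), "AME table")
  if (any(tab$ame <= 0)) stop_config("AME values must be positive")
  for (s in unique(tab$sex)) {
    b <- tab[tab$sex == s, ]
    b <- b[order(b$age_min_years), ]
    if (b$age_min_years[1] != 0)
      stop_config("AME bands for sex %s must start at age 0", s)
    if (!is.infinite(b$age_max_years[nrow(b)]))
      stop_config("AME bands for sex %s must end at Inf", s)
    if (nrow(b) > 1 && any(b$age_min_years[-1] != b$age_max_years[-nrow(b)]))
      stop_config("AME bands for sex %s must be contiguous and non-overlapping", s)
  }
  tab
}

#' Daily household amount of a fortifiable vehicle
#'
#' Converts an acquisition record (amount obtained on the last occasion and
#' the duration it usually lasts) into grams per day. Households that report
#' not using a fortifiable form of the vehicle are assigned zero.
#'
#' @param acq A data.frame of acquisition records with columns
#'   `uses_fortifiable` (0/1), `amount_g` and `lasts_days`.
#' @return Numeric vector of grams/day, one per row of `acq`.
#' @examples
#' daily_household_amount(data.frame(uses_fortifiable = 1,
#'                                   amount_g = 1000, lasts_days = 10))
#' @export
daily_household_amount <- function(acq) {
  assert_cols(acq, c("uses_fortifiable", "amount_g", "lasts_days"), "acquisitions")
  uses <- as.logical(acq$uses_fortifiable)
  bad <- uses & (is.na(acq$lasts_days) | acq$lasts_days <= 0)
  if (any(bad))
    stop_config("acquisition rows %s use a fortifiable vehicle but have missing or non-positive lasts_days",
                paste(which(bad), collapse = ", "))
  if (any(uses & (is.na(acq$amount_g) | acq$amount_g < 0)))
    stop_config("amount_g must be >= 0 for fortifiable-vehicle users")
  ifelse(uses, acq$amount_g / acq$lasts_days, 0)
}

#' Look up the adult-male-equivalent of household members
#'
#' @param age_years Numeric vector of ages in years (fractions allowed, e.g.
#'   a 14.4-month-old child is 1.2 y).
#' @param sex Character vector (`"M"`/`"F"`), recycled against `age_years`.
#' @param table An AME table, see [default_ame_table()].
#' @param member_id Optional ids used in error messages.
#' @return Numeric vector of AME values.
#' @export
ame_of <- function(age_years, sex, table = default_ame_table(), member_id = NULL) {
  n <- max(length(age_years), length(sex))
  age_years <- rep_len(age_years, n)
  sex <- rep_len(sex, n)
  member_id <- if (is.null(member_id)) as.character(seq_len(n)) else rep_len(member_id, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hit <- which(table$sex == sex[i] &
                   table$age_min_years <= age_years[i] &
                   age_years[i] < table$age_max_years)
    if (length(hit) != 1L)
      stop_config("no unique AME band for member %s (age %s y, sex %s)",
                  member_id[i], format(age_years[i]), sex[i])
    out[i] <- table$ame[hit]
  }
  out
}

#' Apportion a household's daily vehicle use to its members
#'
#' Implements the AME apportionment: each member receives
#' `ame_i / sum(ame)` of the household's daily fortifiable amount — the
#' member's "apparent consumption" of the vehicle.
#'
#' @param roster Data.frame with one row per member: `member_id`, `age_years`,
#'   `sex` (a `household_id` column is carried through if present).
#' @param acq A single acquisition record (one-row data.frame) for this
#'   household and vehicle.
#' @param table AME table.
#' @param person_id Optionally restrict the result to one member.
#' @return Data.frame with columns `person_id`, `vehicle`, `grams_per_day`,
#'   `ame_share`, `household_grams_per_day`.
#' @examples
#' roster <- data.frame(member_id = c("a", "b"),
#'                      age_years = c(25, 4), sex = c("M", "F"))
#' acq <- data.frame(vehicle = "wheat_flour", uses_fortifiable = 1,
#'                   amount_g = 300, lasts_days = 10)
#' apportion(roster, acq, default_ame_table())
#' @export
apportion <- function(roster, acq, table = default_ame_table(), person_id = NULL) {
  assert_cols(roster, c("member_id", "age_years", "sex"), "roster")
  if (nrow(roster) < 1L) stop_config("empty household roster")
  if (nrow(acq) != 1L) stop_config("apportion expects a single acquisition record")
  ame <- ame_of(roster$age_years, roster$sex, table, roster$member_id)
  total <- sum(ame)
  if (total <= 0) stop_config("household AME total is zero")
  daily <- daily_household_amount(acq)
  out <- data.frame(person_id = roster$member_id,
                    vehicle = acq$vehicle %||% NA_character_,
                    grams_per_day = ame / total * daily,
                    ame_share = ame / total,
                    household_grams_per_day = daily,
                    stringsAsFactors = FALSE)
  if (!is.null(person_id)) {
    out <- out[out$person_id %in% person_id, , drop = FALSE]
    if (nrow(out) == 0L) stop_config("person_id %s not found in roster", person_id)
  }
  rownames(out) <- NULL
  out
}

#' Apparent consumption for every member of every household
#'
#' Batch wrapper around [apportion()]: joins a household roster table to one
#' acquisition record per household for the requested vehicle. Households with
#' no acquisition record contribute no rows (they have no FAPQ observation);
#' duplicated records for one household are an error.
#'
#' @param households Data.frame: `household_id`, `member_id`, `age_years`, `sex`.
#' @param acquisitions Data.frame of acquisition records with `household_id`
#'   and `vehicle` columns.
#' @param table AME table.
#' @param vehicle Which vehicle to estimate (`"wheat_flour"` or `"oil"`).
#' @return Data.frame with one row per household member, columns as in
#'   [apportion()] plus `household_id`.
#' @export
estimate_fapq <- function(households, acquisitions, table = default_ame_table(),
                          vehicle = "wheat_flour") {
  assert_cols(households, c("household_id", "member_id", "age_years", "sex"),
              "households")
  assert_cols(acquisitions, c("household_id", "vehicle"), "acquisitions")
  acq <- acquisitions[acquisitions$vehicle == vehicle, , drop = FALSE]
  if (anyDuplicated(acq$household_id))
    stop_config("more than one %s acquisition record for household(s): %s", vehicle,
                paste(unique(acq$household_id[duplicated(acq$household_id)]),
                      collapse = ", "))
  res <- lapply(seq_len(nrow(acq)), function(i) {
    hid <- acq$household_id[i]
    roster <- households[households$household_id == hid, , drop = FALSE]
    if (nrow(roster) == 0L)
      stop_config("acquisition for household %s has no roster", hid)
    cbind(household_id = hid, apportion(roster, acq[i, , drop = FALSE], table))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
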