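#' SQ-FFQ item tables
#'
#' The 7-day semiquantitative food frequency questionnaire is quantified
#' against an item table giving, for each food item and portion-size code, the
#' grams of food in the portion and the grams of fortifiable wheat flour it
#' contains. The shipped default table lists 25 commonly consumed wheat-flour
#' foods in five groups (breads, noodles, crackers, cakes, other) with three
#' portion codes each; its flour fractions are plausible values drawn from
#' food-composition conventions and are configuration — any table with the
#' same schema may be used.
#'
#' Schema: `item_id`, `name`, `food_group`, `portion_code`, `food_g`,
#' `flour_g`, one row per item x portion, with `0 <= flour_g <= food_g`.
#'
#' @param path Path to a CSV item table.
#' @return A validated `data.frame`.
#' @export
default_ffq_items <- function() {
  read_ffq_items(system.file("extdata", "ffq_items.csv", package = "fortintake"))
}

#' @rdname default_ffq_items
#' @export
read_ffq_items <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_ffq_items(tab)
}

validate_ffq_items <- function(tab) {
  assert_cols(tab, c("item_id", "food_group", "portion_code", "food_g", "flour_g"),
              "FFQ item table")
  if (any(tab$flour_g < 0) || any(tab$flour_g > tab$food_g))
    stop_config("FFQ item table requires 0 <= flour_g <= food_g")
  if (anyDuplicated(paste(tab$item_id, tab$portion_code)))
    stop_config("duplicate item_id x portion_code rows in FFQ item table")
  tab
}

#' Daily flour grams implied by one FFQ response
#'
#' Multiplies the grams of fortifiable wheat flour in the reported portion by
#' the weekly frequency and divides by seven. Items reported not consumed
#' (frequency zero) contribute zero grams.
#'
#' @param responses Data.frame with columns `item_id`, `times_per_7d`,
#'   `portion_code`.
#' @param items FFQ item table (see [default_ffq_items()]).
#' @return Numeric vector of grams/day, one per response row.
#' @examples
#' items <- data.frame(item_id = "bread", food_group = "breads",
#'                     portion_code = "M", food_g = 50, flour_g = 21)
#' item_daily_grams(data.frame(item_id = "bread", times_per_7d = 3,
#'                             portion_code = "M"), items)  # 9 g/day
#' @export
item_daily_grams <- function(responses, items) {
  assert_cols(responses, c("item_id", "times_per_7d", "portion_code"), "FFQ responses")
  if (any(responses$times_per_7d < 0, na.rm = TRUE))
    stop_config("times_per_7d must be >= 0")
  out <- numeric(nrow(responses))
  active <- which(!is.na(responses$times_per_7d) & responses$times_per_7d > 0)
  if (length(active) > 0L) {
    key <- paste(responses$item_id[active], responses$portion_code[active])
    idx <- match(key, paste(items$item_id, items$portion_code))
    if (anyNA(idx))
      stop_config("unknown item/portion in FFQ responses: %s",
                  paste(unique(key[is.na(idx)]), collapse = ", "))
    out[active] <- items$flour_g[idx] * responses$times_per_7d[active] / 7
  }
  out
}

#' Total daily fortifiable flour intake for one respondent
#'
#' Sums the per-item daily grams over every item the person reported, giving
#' the cumulative total grams of fortifiable wheat flour per day, with
#' per-item and per-food-group breakdowns.
#'
#' @param responses FFQ response table (may contain several persons).
#' @param items FFQ item table.
#' @param person_id The respondent to total.
#' @return A list of class `ffq_intake`: `person_id`, `grams_per_day`,
#'   `per_item` (named numeric), `per_group` (named numeric).
#' @export
ffq_person_total <- function(responses, items, person_id) {
  assert_cols(responses, c("person_id", "item_id", "times_per_7d", "portion_code"),
              "FFQ responses")
  resp <- responses[responses$person_id == person_id, , drop = FALSE]
  if (anyDuplicated(resp$item_id))
    stop_config("duplicate FFQ rows for person %s, item(s) %s", person_id,
                paste(unique(resp$item_id[duplicated(resp$item_id)]), collapse = ", "))
  g <- item_daily_grams(resp, items)
  per_item <- setNames(g, resp$item_id)
  grp <- items$food_group[match(resp$item_id, items$item_id)]
  if (anyNA(grp) && any(g[is.na(grp)] > 0))
    stop_config("unknown item(s) in FFQ responses for person %s", person_id)
  grp[is.na(grp)] <- "unknown"
  per_group <- if (length(g) > 0L) tapply(g, grp, sum) else numeric(0)
  structure(list(person_id = person_id,
                 grams_per_day = sum(g),
                 per_item = per_item,
                 per_group = c(per_group)),
            class = "ffq_intake")
}

#' SQ-FFQ daily flour intake for every respondent
#'
#' @param responses FFQ response table (`person_id`, `item_id`,
#'   `times_per_7d`, `portion_code`).
#' @param items FFQ item table.
#' @return Data.frame `person_id`, `grams_per_day` with one row per person.
#' @export
estimate_ffq <- function(responses, items = default_ffq_items()) {
  persons <- unique(responses$person_id)
  totals <- vapply(persons,
                   function(p) ffq_person_total(responses, items, p)$grams_per_day,
                   numeric(1))
  data.frame(person_id = persons, grams_per_day = unname(totals),
             stringsAsFactors = FALSE)
}

#' Per-person, per-food-group FFQ flour intake (long format)
#'
#' Input shape for [source_shares()]: one row per person x food group present
#' in that person's responses.
#'
#' @inheritParams estimate_ffq
#' @return Data.frame `person_id`, `food_group`, `grams_per_day`.
#' @export
ffq_group_intakes <- function(responses, items = default_ffq_items()) {
  persons <- unique(responses$person_id)
  rows <- lapply(persons, function(p) {
    pg <- ffq_person_total(responses, items, p)$per_group
    if (length(pg) == 0L) return(NULL)
    data.frame(person_id = p, food_group = names(pg), grams_per_day = unname(pg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(person_id = character(0), food_group = character(0),
                      grams_per_day = numeric(0))
  rownames(out) <- NULL
  out
}
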