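#' Fortification decision rules by intake band
#'
#' WHO guidance sets the fortificant concentration in wheat flour (mg of
#' nutrient per kg of flour) by categories of estimated per-capita flour
#' intake. A rule is an ordered set of contiguous half-open intake bands
#' `[intake_min, intake_max)` in g/day, each with a fortification level. A
#' boundary intake belongs to the upper band (so 75 g/day falls in the
#' 75-149 band).
#'
#' `default_fortification_rules()` loads the shipped `rules.yaml`, whose
#' folic-acid entry carries the WHO bands (<75 -> 5.0, 75-149 -> 2.6,
#' 150-300 -> 1.3, >300 -> 1.0 mg/kg). The file is editable configuration.
#' There are no recommended intake cutoffs for oil; [recommend()] with
#' `rule = NULL` returns an explicit no-rule result.
#'
#' @param nutrient Nutrient name.
#' @param bands Data.frame `intake_min_g_day`, `intake_max_g_day`,
#'   `level_mg_per_kg`.
#' @return Object of class `fortification_rule`.
#' @export
fortification_rule <- function(nutrient, bands) {
  assert_cols(bands, c("intake_min_g_day", "intake_max_g_day", "level_mg_per_kg"),
              "rule bands")
  bands <- bands[order(bands$intake_min_g_day), , drop = FALSE]
  if (bands$intake_min_g_day[1L] != 0)
    stop_config("bands must start at 0 g/day")
  if (nrow(bands) > 1L &&
      any(bands$intake_min_g_day[-1L] != bands$intake_max_g_day[-nrow(bands)]))
    stop_config("bands must be contiguous and non-overlapping")
  if (any(diff(bands$intake_min_g_day) <= 0))
    stop_config("bands must be strictly ascending")
  rownames(bands) <- NULL
  structure(list(nutrient = nutrient, bands = bands),
            class = "fortification_rule")
}

#' @rdname fortification_rule
#' @param path Path to a rules YAML file (`nutrient: bands: [{min, max,
#'   level_mg_per_kg}, ...]`; `max: .inf` for the open top band).
#' @export
load_fortification_rules <- function(path = system.file("extdata", "rules.yaml",
                                                        package = "fortintake")) {
  raw <- yaml::read_yaml(path)
  lapply(setNames(names(raw), names(raw)), function(nm) {
    b <- do.call(rbind, lapply(raw[[nm]]$bands, function(x)
      data.frame(intake_min_g_day = x$min,
                 intake_max_g_day = if (is.character(x$max)) Inf else x$max,
                 level_mg_per_kg = x$level_mg_per_kg)))
    fortification_rule(nm, b)
  })
}

#' @rdname fortification_rule
#' @export
default_fortification_rules <- function() load_fortification_rules()

locate_band <- function(mean_intake, rule) {
  b <- rule$bands
  hit <- which(b$intake_min_g_day <= mean_intake & mean_intake < b$intake_max_g_day)
  if (length(hit) != 1L)
    stop_config("intake %.3g g/day falls outside the %s rule's bands",
                mean_intake, rule$nutrient)
  hit
}

#' Fortification-level recommendation for a mean vehicle intake
#'
#' Locates the intake band containing `mean_intake` (half-open intervals,
#' boundary to the upper band) and returns the band's fortification level,
#' together with the percent increase in intake that would reach the next
#' band where one exists.
#'
#' @param mean_intake Population mean intake of the vehicle, g/day.
#' @param rule A [fortification_rule()]; `NULL` yields an explicit no-rule
#'   result (the case for oil, which has no recommended cutoffs).
#' @return List of class `fortification_recommendation`: `nutrient`,
#'   `mean_intake_g_day`, `band` (min/max), `level_mg_per_kg`,
#'   `pct_to_next_band` (NA in the top band or without a rule).
#' @examples
#' rule <- default_fortification_rules()$folic_acid
#' recommend(42.3, rule)$level_mg_per_kg   # 5.0
#' round(pct_to_next_band(51.5, rule))     # 46
#' @export
recommend <- function(mean_intake, rule) {
  if (is.null(rule)) {
    return(structure(list(nutrient = NA_character_,
                          mean_intake_g_day = mean_intake, band = NULL,
                          level_mg_per_kg = NA_real_,
                          pct_to_next_band = NA_real_,
                          note = "no recommended intake cutoffs for this vehicle"),
                     class = "fortification_recommendation"))
  }
  stopifnot(inherits(rule, "fortification_rule"))
  if (is.na(mean_intake) || mean_intake < 0)
    stop_config("mean_intake must be a non-negative number")
  i <- locate_band(mean_intake, rule)
  b <- rule$bands
  structure(list(nutrient = rule$nutrient, mean_intake_g_day = mean_intake,
                 band = c(min = b$intake_min_g_day[i],
                          max = b$intake_max_g_day[i]),
                 level_mg_per_kg = b$level_mg_per_kg[i],
                 pct_to_next_band = if (i < nrow(b))
                   pct_to_next_band(mean_intake, rule) else NA_real_),
            class = "fortification_recommendation")
}

#' @export
print.fortification_recommendation <- function(x, ...) {
  if (is.null(x$band)) {
    cat("No fortification-level rule:", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("%s: mean intake %.1f g/day is in band [%s, %s) -> %.1f mg/kg\n",
              x$nutrient, x$mean_intake_g_day, format(x$band["min"]),
              format(x$band["max"]), x$level_mg_per_kg))
  if (!is.na(x$pct_to_next_band))
    cat(sprintf("  %.0f%% higher intake would reach the next band\n",
                x$pct_to_next_band))
  invisible(x)
}

#' Percent increase needed to reach the next intake band
#'
#' `100 * (b - mean_intake) / mean_intake`, where `b` is the smallest band
#' lower edge at or above `mean_intake` (so an intake exactly on a boundary
#' is 0% from it). Returned unrounded; report layers round to the nearest
#' integer percent.
#'
#' @inheritParams recommend
#' @return Percent, or `NA` when no higher band exists.
#' @export
pct_to_next_band <- function(mean_intake, rule) {
  stopifnot(inherits(rule, "fortification_rule"))
  if (mean_intake <= 0) stop_config("mean_intake must be positive")
  edges <- rule$bands$intake_min_g_day
  nxt <- edges[edges >= mean_intake]
  if (length(nxt) == 0L) return(NA_real_)
  100 * (min(nxt) - mean_intake) / mean_intake
}
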