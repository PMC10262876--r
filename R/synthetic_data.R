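#' Configuration of the synthetic study generator
#'
#' Defines the mother-child survey frame the generator emulates: one mother
#' (18-49 y) and one child (12-18 mo) per household plus 0-4 other members,
#' repeated 24-h recalls (four scheduled for the child, two for the mother,
#' with a fifth child day standing in for the observed weighed record), a
#' minority of households using raw wheat flour at home, and right-skewed
#' person-day vehicle intakes with both between- and within-person variance.
#'
#' Person-day intakes of each vehicle follow a log-normal hierarchy
#' `exp(mu + u_i + e_ij)` with `u_i ~ N(0, sigma_between^2)` and
#' `e_ij ~ N(0, sigma_within^2)`; children's location is shifted by
#' `log(child_intake_ratio)`. Households using raw flour at home additionally
#' allocate their daily raw-flour use to members in proportion to AME, so the
#' household instrument sees only that component while recalls see the total.
#' Oil acquisitions exceed consumption by `1 / (1 - oil_discard_fraction)`,
#' the mechanism by which a household instrument overestimates oil intake
#' when cooking oil is discarded.
#'
#' @param n_households Number of mother-child households (>= 2).
#' @param recall_days_child,recall_days_mother Scheduled recall days.
#' @param child_extra_observation_day Add a fifth child day; about half of
#'   these days are flagged `observation_plus_recall`, the rest are an extra
#'   recall, so children average one more day than scheduled.
#' @param prop_households_using_raw_flour Fraction of households using raw
#'   fortifiable wheat flour at home (default 0.36, i.e. 64% non-users).
#' @param prop_households_using_oil Fraction of households using fortifiable
#'   oil.
#' @param home_flour_g_per_ame Daily raw-flour use of a flour-using
#'   household, g/day per unit of household AME.
#' @param oil_discard_fraction Fraction of acquired oil discarded after
#'   cooking rather than consumed (default 0).
#' @param child_intake_ratio Multiplier on `exp(mu_log)` for children.
#' @param vehicle_params Per-vehicle list with `mu_log` (adult log-scale
#'   location), `sigma_between`, `sigma_within` (log-scale SDs).
#' @param ffq_noise_sd SD of the multiplicative log-normal FFQ reporting
#'   error (0.2 = 20% CV; 0 makes the FFQ exactly consistent with the true
#'   usual intake).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_households = 120,
                              recall_days_child = 4,
                              recall_days_mother = 2,
                              child_extra_observation_day = TRUE,
                              prop_households_using_raw_flour = 0.36,
                              prop_households_using_oil = 1,
                              home_flour_g_per_ame = 17,
                              oil_discard_fraction = 0,
                              child_intake_ratio = 1 / 3,
                              vehicle_params = list(
                                wheat_flour = list(mu_log = 3.4,
                                                   sigma_between = 0.5,
                                                   sigma_within = 0.7),
                                oil = list(mu_log = 1.45,
                                           sigma_between = 0.5,
                                           sigma_within = 0.7)),
                              ffq_noise_sd = 0.2,
                              seed = 1L) {
  cfg <- list(n_households = n_households,
              recall_days_child = recall_days_child,
              recall_days_mother = recall_days_mother,
              child_extra_observation_day = child_extra_observation_day,
              prop_households_using_raw_flour = prop_households_using_raw_flour,
              prop_households_using_oil = prop_households_using_oil,
              home_flour_g_per_ame = home_flour_g_per_ame,
              oil_discard_fraction = oil_discard_fraction,
              child_intake_ratio = child_intake_ratio,
              vehicle_params = vehicle_params,
              ffq_noise_sd = ffq_noise_sd,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (!is.numeric(cfg$n_households) || cfg$n_households < 2)
    stop_config("n_households must be >= 2")
  fr <- c(cfg$prop_households_using_raw_flour, cfg$prop_households_using_oil,
          cfg$oil_discard_fraction)
  if (any(fr < 0 | fr > 1)) stop_config("fractions must lie in [0, 1]")
  if (cfg$oil_discard_fraction >= 1)
    stop_config("oil_discard_fraction must be < 1")
  if (cfg$ffq_noise_sd < 0) stop_config("ffq_noise_sd must be >= 0")
  if (cfg$recall_days_child < 1 || cfg$recall_days_mother < 1)
    stop_config("recall day counts must be >= 1")
  if (cfg$child_intake_ratio <= 0) stop_config("child_intake_ratio must be > 0")
  for (v in names(cfg$vehicle_params)) {
    p <- cfg$vehicle_params[[v]]
    if (is.null(p$mu_log) || is.null(p$sigma_between) || is.null(p$sigma_within))
      stop_config("vehicle_params$%s must supply mu_log, sigma_between, sigma_within", v)
    if (p$sigma_between < 0 || p$sigma_within < 0)
      stop_config("vehicle_params$%s: SDs must be >= 0", v)
  }
  invisible(cfg)
}

# Built-in foods used to decompose person-day vehicle totals into recall
# entries. Flour foods carry no oil and vice versa so person-day totals can
# be reconstructed exactly; mixed dishes are exercised in unit tests.
recall_food_table <- function() {
  data.frame(
    food_id = c("pandesal", "loaf_bread", "instant_noodles", "pancit_canton",
                "soda_crackers", "mamon", "doughnut", "siopao",
                "fried_rice", "fried_chicken", "fried_fish",
                "sauteed_vegetables",
                "boiled_rice", "banana", "homemade_bread"),
    food_group = c("breads", "breads", "noodles", "noodles", "crackers",
                   "cakes", "cakes", "other",
                   "fried_dishes", "fried_dishes", "fried_dishes",
                   "fried_dishes", "staples", "fruit", "breads"),
    frac_wheat_flour = c(0.56, 0.54, 0.30, 0.32, 0.65, 0.38, 0.45, 0.33,
                         0, 0, 0, 0, 0, 0, 0.50),
    frac_oil = c(0, 0, 0, 0, 0, 0, 0, 0, 0.06, 0.10, 0.09, 0.05, 0, 0, 0),
    fortifiable = c(rep(1L, 12), 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}

dirichlet_shares <- function(k) {
  g <- rgamma(k, shape = 2)
  g / sum(g)
}

#' Simulate a complete synthetic study
#'
#' Generates every pipeline input — household rosters, vehicle acquisition
#' records, SQ-FFQ responses and per-day recall entries — together with the
#' ground truth (each participant's true usual intake per vehicle and each
#' household's true daily vehicle use) from which they were derived, so every
#' estimator can be validated against known values.
#'
#' Construction guarantees, given the config:
#' * recall person-day totals of each vehicle equal the simulated person-day
#'   intakes exactly (entry amounts are back-computed from recipe fractions);
#' * with `ffq_noise_sd = 0`, each participant's FFQ-implied daily flour
#'   equals their true usual intake exactly (frequencies are real-valued for
#'   this reason);
#' * flour-using households allocate home raw flour to members exactly in
#'   proportion to AME, so AME apportionment is unbiased for the home
#'   component.
#'
#' @param config A [simulation_config()].
#' @return List of class `fortintake_simulation` with data.frames
#'   `households`, `acquisitions`, `ffq_responses`, `recalls`,
#'   `ground_truth`, plus the `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  validate_simulation_config(config)
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  nh <- as.integer(cfg$n_households)
  hid <- sprintf("H%04d", seq_len(nh))
  ame_tab <- default_ame_table()

  ## --- rosters -------------------------------------------------------------
  mother <- data.frame(household_id = hid,
                       member_id = paste0(hid, "_m"),
                       role = "mother",
                       age_years = round(runif(nh, 18, 49), 1),
                       sex = "F", stringsAsFactors = FALSE)
  child <- data.frame(household_id = hid,
                      member_id = paste0(hid, "_c"),
                      role = "child",
                      age_years = round(runif(nh, 1.0, 1.5), 2),
                      sex = sample(c("M", "F"), nh, replace = TRUE),
                      stringsAsFactors = FALSE)
  n_extra <- sample(0:4, nh, replace = TRUE)
  extras <- if (sum(n_extra) > 0) {
    eh <- rep(hid, n_extra)
    idx <- sequence(n_extra)
    band <- sample(1:4, sum(n_extra), replace = TRUE)
    lo <- c(0, 6, 18, 60)[band]
    hi <- c(6, 18, 60, 80)[band]
    data.frame(household_id = eh,
               member_id = paste0(eh, "_o", idx),
               role = "other",
               age_years = round(runif(sum(n_extra), lo, hi), 1),
               sex = sample(c("M", "F"), sum(n_extra), replace = TRUE),
               stringsAsFactors = FALSE)
  } else NULL
  households <- rbind(mother, child, extras)
  households <- households[order(households$household_id, households$member_id), ]
  rownames(households) <- NULL

  households$ame <- ame_of(households$age_years, households$sex, ame_tab,
                           households$member_id)
  hh_ame <- tapply(households$ame, households$household_id, sum)

  ## --- participants and person-day draws -----------------------------------
  participants <- households[households$role %in% c("mother", "child"), ]
  np <- nrow(participants)
  is_child <- participants$role == "child"
  n_days <- ifelse(is_child,
                   cfg$recall_days_child +
                     as.integer(cfg$child_extra_observation_day),
                   cfg$recall_days_mother)

  flour_user <- setNames(rbinom(nh, 1, cfg$prop_households_using_raw_flour) == 1,
                         hid)
  oil_user <- setNames(rbinom(nh, 1, cfg$prop_households_using_oil) == 1, hid)

  # household raw-flour use, allocated to members by AME share
  g_flour_hh <- ifelse(flour_user[hid],
                       cfg$home_flour_g_per_ame * as.numeric(hh_ame[hid]) *
                         rlnorm(nh, -0.5^2 / 2, 0.5),
                       0)
  names(g_flour_hh) <- hid
  home_flour <- as.numeric(g_flour_hh[participants$household_id]) *
    participants$ame / as.numeric(hh_ame[participants$household_id])

  vehicles <- names(cfg$vehicle_params)
  person_truth <- list()
  day_rows <- list()
  for (v in vehicles) {
    p <- cfg$vehicle_params[[v]]
    mu_p <- p$mu_log + ifelse(is_child, log(cfg$child_intake_ratio), 0)
    u <- rnorm(np, 0, p$sigma_between)
    away_usual <- exp(mu_p + u + p$sigma_within^2 / 2)
    home_p <- if (v == "wheat_flour") home_flour else rep(0, np)
    drop_oil <- v == "oil" & !oil_user[participants$household_id]
    eps <- rnorm(sum(n_days), 0, p$sigma_within)
    pd <- data.frame(
      person_id = rep(participants$member_id, n_days),
      household_id = rep(participants$household_id, n_days),
      role = rep(participants$role, n_days),
      day_index = sequence(n_days),
      vehicle = v,
      grams = rep(exp(mu_p + u), n_days) * exp(eps) + rep(home_p, n_days),
      stringsAsFactors = FALSE)
    if (any(drop_oil))
      pd$grams[pd$person_id %in% participants$member_id[drop_oil]] <- 0
    usual <- away_usual + home_p
    usual[drop_oil] <- 0
    person_truth[[v]] <- data.frame(
      level = "person", id = participants$member_id,
      household_id = participants$household_id, role = participants$role,
      vehicle = v, grams_per_day = usual, stringsAsFactors = FALSE)
    day_rows[[v]] <- pd
  }
  person_days <- do.call(rbind, day_rows)

  # day sources: the extra child day is a 12-h observation + 12-h recall for
  # about half the children, an additional recall otherwise
  obs_child <- setNames(rbinom(nh, 1, 0.5) == 1, paste0(hid, "_c"))
  obs_day <- cfg$recall_days_child + 1L
  person_days$source <- ifelse(
    cfg$child_extra_observation_day &
      person_days$role == "child" &
      person_days$day_index == obs_day &
      obs_child[person_days$person_id],
    "observation_plus_recall", "recall")

  ## --- acquisitions ---------------------------------------------------------
  oil_p <- cfg$vehicle_params$oil
  oil_rate_consumed <- if (!is.null(oil_p)) {
    adult_usual <- exp(oil_p$mu_log + oil_p$sigma_between^2 / 2 +
                         oil_p$sigma_within^2 / 2)
    adult_usual / 0.82 * as.numeric(hh_ame[hid]) *
      rlnorm(nh, -0.4^2 / 2, 0.4) * ifelse(oil_user[hid], 1, 0)
  } else rep(0, nh)
  oil_rate_acquired <- oil_rate_consumed / (1 - cfg$oil_discard_fraction)

  lasts_flour <- sample(c(7, 14, 30), nh, replace = TRUE)
  lasts_oil <- sample(c(14, 30, 60), nh, replace = TRUE)
  acquisitions <- rbind(
    data.frame(household_id = hid, vehicle = "wheat_flour",
               uses_fortifiable = as.integer(flour_user[hid]),
               amount_g = ifelse(flour_user[hid], g_flour_hh * lasts_flour, 0),
               lasts_days = ifelse(flour_user[hid], lasts_flour, NA_real_),
               stringsAsFactors = FALSE),
    if (!is.null(oil_p))
      data.frame(household_id = hid, vehicle = "oil",
                 uses_fortifiable = as.integer(oil_user[hid]),
                 amount_g = ifelse(oil_user[hid],
                                   oil_rate_acquired * lasts_oil, 0),
                 lasts_days = ifelse(oil_user[hid], lasts_oil, NA_real_),
                 stringsAsFactors = FALSE))
  rownames(acquisitions) <- NULL

  ## --- FFQ responses (flour only) -------------------------------------------
  items <- default_ffq_items()
  item_ids <- unique(items$item_id)
  truth_flour <- person_truth$wheat_flour
  ffq_rows <- lapply(seq_len(np), function(i) {
    target <- truth_flour$grams_per_day[i] *
      if (cfg$ffq_noise_sd > 0)
        rlnorm(1, -cfg$ffq_noise_sd^2 / 2, cfg$ffq_noise_sd) else 1
    k <- sample(2:5, 1)
    chosen <- sample(item_ids, k)
    shares <- dirichlet_shares(k)
    portions <- vapply(chosen, function(it)
      sample(items$portion_code[items$item_id == it], 1), character(1))
    flour_g <- items$flour_g[match(paste(chosen, portions),
                                   paste(items$item_id, items$portion_code))]
    data.frame(person_id = participants$member_id[i],
               item_id = chosen,
               times_per_7d = 7 * target * shares / flour_g,
               portion_code = portions, stringsAsFactors = FALSE)
  })
  ffq_responses <- do.call(rbind, ffq_rows)
  rownames(ffq_responses) <- NULL

  ## --- recall entries --------------------------------------------------------
  foods <- recall_food_table()
  flour_foods <- foods[foods$frac_wheat_flour > 0 & foods$fortifiable == 1, ]
  oil_foods <- foods[foods$frac_oil > 0, ]
  entry_rows <- function(pd, pool, frac_col, kmax) {
    pd <- pd[pd$grams > 0, , drop = FALSE]
    if (nrow(pd) == 0L) return(NULL)
    k <- sample(seq_len(kmax), nrow(pd), replace = TRUE)
    rid <- rep(seq_len(nrow(pd)), k)
    share <- as.numeric(unlist(lapply(k, dirichlet_shares)))
    fi <- sample(seq_len(nrow(pool)), length(rid), replace = TRUE)
    grams <- pd$grams[rid] * share
    data.frame(person_id = pd$person_id[rid],
               day_index = pd$day_index[rid],
               food_id = pool$food_id[fi],
               food_group = pool$food_group[fi],
               amount_g = grams / pool[[frac_col]][fi],
               frac_wheat_flour = pool$frac_wheat_flour[fi],
               frac_oil = pool$frac_oil[fi],
               fortifiable = pool$fortifiable[fi],
               source = pd$source[rid], stringsAsFactors = FALSE)
  }
  flour_entries <- entry_rows(person_days[person_days$vehicle == "wheat_flour", ],
                              flour_foods, "frac_wheat_flour", 3L)
  oil_entries <- if ("oil" %in% vehicles)
    entry_rows(person_days[person_days$vehicle == "oil", ],
               oil_foods, "frac_oil", 2L) else NULL

  # non-vehicle staples and occasional non-fortifiable (home-made) flour
  # foods, so aggregation must rely on fractions and the fortifiable flag
  pd1 <- person_days[person_days$vehicle == vehicles[1L], ]
  rice <- data.frame(person_id = pd1$person_id, day_index = pd1$day_index,
                     food_id = "boiled_rice", food_group = "staples",
                     amount_g = round(runif(nrow(pd1), 80, 250), 1),
                     frac_wheat_flour = 0, frac_oil = 0, fortifiable = 0L,
                     source = pd1$source, stringsAsFactors = FALSE)
  hm <- runif(nrow(pd1)) < 0.1
  homemade <- if (any(hm)) {
    data.frame(person_id = pd1$person_id[hm], day_index = pd1$day_index[hm],
               food_id = "homemade_bread", food_group = "breads",
               amount_g = round(runif(sum(hm), 20, 80), 1),
               frac_wheat_flour = 0.5, frac_oil = 0, fortifiable = 0L,
               source = pd1$source[hm], stringsAsFactors = FALSE)
  } else NULL
  recalls <- rbind(flour_entries, oil_entries, rice, homemade)
  recalls <- recalls[order(recalls$person_id, recalls$day_index,
                           recalls$food_id), ]
  rownames(recalls) <- NULL

  ## --- ground truth ----------------------------------------------------------
  hh_truth <- rbind(
    data.frame(level = "household", id = hid, household_id = hid,
               role = NA_character_, vehicle = "wheat_flour",
               grams_per_day = as.numeric(g_flour_hh), stringsAsFactors = FALSE),
    if (!is.null(oil_p))
      data.frame(level = "household", id = hid, household_id = hid,
                 role = NA_character_, vehicle = "oil",
                 grams_per_day = oil_rate_consumed, stringsAsFactors = FALSE))
  ground_truth <- rbind(do.call(rbind, person_truth), hh_truth)
  rownames(ground_truth) <- NULL

  households$ame <- NULL
  structure(list(households = households, acquisitions = acquisitions,
                 ffq_responses = ffq_responses, recalls = recalls,
                 ground_truth = ground_truth, config = cfg),
            class = "fortintake_simulation")
}

fixture_files <- c(households = "households.csv",
                   acquisitions = "acquisitions.csv",
                   ffq_responses = "ffq_responses.csv",
                   recalls = "recalls.csv",
                   ground_truth = "ground_truth.csv")

#' Write or read a simulated dataset as a CSV fixture
#'
#' `write_fixture()` serialises the five tables of a
#' [simulate_study()] result as CSV files (`households.csv`,
#' `acquisitions.csv`, `ffq_responses.csv`, `recalls.csv`,
#' `ground_truth.csv`); `read_fixture()` reads them back. The round trip is
#' lossless up to floating-point text representation (15 significant
#' digits).
#'
#' @param dataset A `fortintake_simulation` (or any list holding the five
#'   tables).
#' @param directory Output/input directory; created if missing.
#' @return `write_fixture()` the directory (invisibly); `read_fixture()` a
#'   list of the five data.frames.
#' @export
write_fixture <- function(dataset, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_config("cannot create directory %s", directory)
  }
  for (nm in names(fixture_files)) {
    tab <- dataset[[nm]]
    if (is.null(tab)) stop_config("dataset is missing table %s", nm)
    write.csv(tab, file.path(directory, fixture_files[[nm]]),
              row.names = FALSE, na = "")
  }
  invisible(directory)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(directory) {
  out <- lapply(fixture_files, function(f) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop_config("fixture file %s not found", path)
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  })
  names(out) <- names(fixture_files)
  out
}
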