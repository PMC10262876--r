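# Shared fixtures built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Log-normal person/day hierarchy drawn directly (independently of the
# package's study generator) for usual-intake recovery checks.
sim_hierarchy <- function(n_persons, n_days, mu, sigma_u, sigma_e, seed) {
  withr::with_seed(seed, {
    u <- rnorm(n_persons, 0, sigma_u)
    data.frame(
      person_id = rep(sprintf("p%04d", seq_len(n_persons)), each = n_days),
      grams = exp(rep(mu + u, each = n_days) +
                    rnorm(n_persons * n_days, 0, sigma_e)),
      stringsAsFactors = FALSE)
  })
}

# A two-band-per-sex AME table with simple values, so tests do not depend on
# the shipped default table.
toy_ame_table <- function() {
  data.frame(sex = c("M", "M", "F", "F"),
             age_min_years = c(0, 18, 0, 18),
             age_max_years = c(18, Inf, 18, Inf),
             ame = c(0.5, 1.0, 0.5, 0.8),
             stringsAsFactors = FALSE)
}

# A two-item FFQ table with one portion each.
toy_ffq_items <- function() {
  data.frame(item_id = c("bread", "noodles", "plain_rice"),
             name = c("Bread", "Noodles", "Rice"),
             food_group = c("breads", "noodles", "staples"),
             portion_code = "M",
             food_g = c(50, 180, 150),
             flour_g = c(14, 21, 0),
             stringsAsFactors = FALSE)
}

mothers_of <- function(df, col = "person_id") df[grepl("_m$", df[[col]]), , drop = FALSE]
children_of <- function(df, col = "person_id") df[grepl("_c$", df[[col]]), , drop = FALSE]
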