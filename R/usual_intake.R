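#' Box-Cox transformation and its inverse
#'
#' `boxcox_transform(y)` computes `((y + offset)^lambda - 1) / lambda`, with
#' the `log(y + offset)` limit at `lambda = 0`. `inv_boxcox()` inverts it,
#' clamping `lambda * z + 1` at zero so back-transformed intakes are never
#' complex or negative before the offset is removed.
#'
#' @param y Non-negative amounts (grams); `y + offset` must be positive.
#' @param z Transformed-scale values.
#' @param lambda Box-Cox exponent.
#' @param offset Grams added before transforming (used to admit zero-intake
#'   days in the amount-only model).
#' @return Numeric vector.
#' @examples
#' boxcox_transform(5, lambda = 1)      # 4
#' boxcox_transform(exp(1), lambda = 0) # 1
#' @export
boxcox_transform <- function(y, lambda, offset = 0) {
  x <- y + offset
  if (any(x <= 0))
    stop_config("Box-Cox transform requires y + offset > 0")
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @export
inv_boxcox <- function(z, lambda, offset = 0) {
  if (abs(lambda) < 1e-8) exp(z) - offset
  else pmax(lambda * z + 1, 0)^(1 / lambda) - offset
}

# Marginal log-likelihood of the one-way random-intercept model with
# compound-symmetry covariance, evaluated per person (used for the
# method-of-moments fallback so the Box-Cox profile stays comparable).
oneway_loglik <- function(z, pid, mu, sigma_u2, sigma_e2) {
  if (sigma_e2 <= 0) return(-Inf)
  ni <- tabulate(pid)
  xbar <- tapply(z, pid, mean)
  ss_within <- sum((z - xbar[pid])^2)
  d <- sigma_e2 + ni * sigma_u2
  ll <- -0.5 * length(z) * log(2 * pi) -
    0.5 * sum((ni - 1) * log(sigma_e2) + log(d)) -
    0.5 * ss_within / sigma_e2 -
    0.5 * sum(ni * (xbar - mu)^2 / d)
  as.numeric(ll)
}

fit_oneway_lme4 <- function(z, pid, reml) {
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(z ~ 1 + (1 | pid), REML = reml,
               data = data.frame(z = z, pid = pid))))
  vc <- lme4::VarCorr(fit)
  list(beta0 = unname(lme4::fixef(fit)[1L]),
       sigma_u2 = as.numeric(vc$pid[1L, 1L]),
       sigma_e2 = unname(attr(vc, "sc"))^2,
       loglik = as.numeric(stats::logLik(fit)))
}

fit_oneway_mom <- function(z, pid) {
  ni <- tabulate(pid)
  k <- length(ni)
  n <- length(z)
  xbar <- tapply(z, pid, mean)
  grand <- mean(z)
  ssw <- sum((z - xbar[pid])^2)
  ssb <- sum(ni * (xbar - grand)^2)
  msw <- ssw / max(n - k, 1L)
  msb <- if (k > 1L) ssb / (k - 1L) else 0
  n0 <- if (k > 1L) (n - sum(ni^2) / n) / (k - 1L) else 1
  sigma_e2 <- msw
  sigma_u2 <- max((msb - msw) / n0, 0)
  list(beta0 = grand, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
       loglik = oneway_loglik(z, pid, grand, sigma_u2, sigma_e2))
}

fit_oneway <- function(z, pid, reml, method) {
  if (method == "mom") return(fit_oneway_mom(z, pid))
  tryCatch(fit_oneway_lme4(z, pid, reml),
           error = function(e) fit_oneway_mom(z, pid))
}

#' Fit the amount-only usual-intake measurement-error model
#'
#' Repeated person-day amounts of a non-episodically consumed food are
#' shifted by an offset, Box-Cox transformed toward normality, and modelled
#' with a person-level random intercept: `z_ij = beta0 + u_i + e_ij`,
#' `u_i ~ N(0, sigma_u2)` (between-person), `e_ij ~ N(0, sigma_e2)`
#' (within-person). The Box-Cox exponent is chosen from a grid by maximising
#' the profile log-likelihood of that model (ML fit, transformation Jacobian
#' included); the reported variance components are then re-estimated by REML
#' at the selected exponent (method of moments is available as a fallback or
#' by request).
#'
#' @param daily Data.frame of person-day amounts with columns `person_id` and
#'   `grams` (the output of [person_day_totals()] filtered to one vehicle
#'   works directly; supplying several vehicles at once is an error).
#' @param lambda_grid Candidate Box-Cox exponents (default -1 to 1 by 0.05).
#' @param offset Grams added before transforming. The default (`NULL`) uses
#'   half the minimum positive amount when zero-intake days are present, and
#'   0 otherwise.
#' @param method `"reml"` (default) or `"mom"` for the variance components.
#' @return An object of class `usual_intake_model`: `lambda`, `beta0`,
#'   `sigma_u2`, `sigma_e2`, `offset`, `n_persons`, `n_days_total`, plus a
#'   `persons` table (transformed-scale person means and day counts) used for
#'   BLUP shrinkage.
#' @seealso [usual_intake_distribution()], [shrink_person()]
#' @export
fit_usual_intake <- function(daily, lambda_grid = seq(-1, 1, by = 0.05),
                             offset = NULL, method = c("reml", "mom")) {
  method <- match.arg(method)
  assert_cols(daily, c("person_id", "grams"), "daily amounts")
  if ("vehicle" %in% names(daily) && length(unique(daily$vehicle)) > 1L)
    stop_config("fit one vehicle at a time (several found in `daily`)")
  y <- daily$grams
  if (any(is.na(y)) || any(y < 0)) stop_config("amounts must be non-negative and non-missing")
  pid <- factor(daily$person_id)
  ni <- tabulate(pid)
  if (nlevels(pid) < 2L) stop_config("need at least 2 persons")
  if (max(ni) < 2L)
    stop_config("within-person variance is unidentifiable: no person has 2 or more days")
  if (is.null(offset)) offset <- if (any(y == 0)) min(y[y > 0]) / 2 else 0
  if (offset < 0) stop_config("offset must be >= 0")
  if (all(y + offset <= 0)) stop_config("all amounts are zero and offset is 0")

  new_model <- function(lambda, beta0, su2, se2, fitted_by) {
    z <- boxcox_transform(y, lambda, offset)
    persons <- data.frame(person_id = levels(pid), n_days = ni,
                          mean_z = as.numeric(tapply(z, pid, mean)),
                          stringsAsFactors = FALSE)
    structure(list(lambda = lambda, beta0 = beta0, sigma_u2 = su2,
                   sigma_e2 = se2, offset = offset,
                   n_persons = nlevels(pid), n_days_total = length(y),
                   persons = persons, fitted_by = fitted_by),
              class = "usual_intake_model")
  }

  if (var(y) == 0) {
    warning("all amounts identical: degenerate model with zero variance components")
    lam <- if (1 %in% lambda_grid) 1 else lambda_grid[1L]
    return(new_model(lam, boxcox_transform(y[1L], lam, offset), 0, 0, "degenerate"))
  }

  jac <- sum(log(y + offset))
  prof <- vapply(lambda_grid, function(lam) {
    z <- boxcox_transform(y, lam, offset)
    fit_oneway(z, pid, reml = FALSE, method = method)$loglik + (lam - 1) * jac
  }, numeric(1))
  lam <- lambda_grid[which.max(prof)]
  z <- boxcox_transform(y, lam, offset)
  final <- fit_oneway(z, pid, reml = TRUE, method = method)
  m <- new_model(lam, final$beta0, final$sigma_u2, final$sigma_e2, method)
  m$profile <- data.frame(lambda = lambda_grid, loglik = prof)
  m
}

#' @export
print.usual_intake_model <- function(x, ...) {
  cat("Amount-only usual-intake model\n")
  cat(sprintf("  lambda = %.2f, offset = %.4g g\n", x$lambda, x$offset))
  cat(sprintf("  beta0 = %.4f, sigma_u^2 = %.4f, sigma_e^2 = %.4f (transformed scale)\n",
              x$beta0, x$sigma_u2, x$sigma_e2))
  cat(sprintf("  %d persons, %d person-days (%s)\n",
              x$n_persons, x$n_days_total, x$fitted_by))
  invisible(x)
}

gh9 <- function() pracma::gaussHermite(9)

# Expectation over the within-person deviation of the back-transformed
# intake, by 9-point Gauss-Hermite quadrature; `b` is a vector of
# transformed-scale person locations.
gh_back_transform <- function(b, sigma_e2, lambda, offset) {
  gh <- gh9()
  se <- sqrt(sigma_e2)
  out <- numeric(length(b))
  for (k in seq_along(gh$x)) {
    out <- out + gh$w[k] / sqrt(pi) *
      pmax(inv_boxcox(b + sqrt(2) * se * gh$x[k], lambda, offset), 0)
  }
  out
}

#' Simulate the usual-intake distribution from a fitted model
#'
#' Draws person-level effects `u ~ N(0, sigma_u2)`; each draw's usual intake
#' is the 9-point Gauss-Hermite expectation, over the within-person deviation
#' `e ~ N(0, sigma_e2)`, of the inverse Box-Cox transform of
#' `beta0 + u + e`, floored at zero. Percentiles use the linear-interpolation
#' (type 7) quantile convention.
#'
#' @param model A fitted [fit_usual_intake()] model.
#' @param n_draws Monte-Carlo draws (default 100000; fewer than 1000 gives
#'   unstable tails and triggers a warning).
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param keep_draws Retain the simulated usual intakes in the result.
#' @return Object of class `usual_intake_distribution`: `percentiles` (named,
#'   at 1/5/10/25/50/75/90/95/99), `mean`, `sd`, `n_draws`, `seed`, and
#'   optionally `draws`.
#' @export
usual_intake_distribution <- function(model, n_draws = 1e5, seed = 1L,
                                      keep_draws = FALSE) {
  stopifnot(inherits(model, "usual_intake_model"))
  if (n_draws < 1000)
    warning("n_draws < 1000: percentile tails will be unstable")
  u <- withr::with_seed(seed, rnorm(n_draws, 0, sqrt(model$sigma_u2)))
  vals <- gh_back_transform(model$beta0 + u, model$sigma_e2, model$lambda,
                            model$offset)
  probs <- c(1, 5, 10, 25, 50, 75, 90, 95, 99) / 100
  pct <- quantile(vals, probs, type = 7, names = FALSE)
  structure(list(percentiles = setNames(pct, paste0("p", probs * 100)),
                 mean = mean(vals), sd = sd(vals),
                 n_draws = n_draws, seed = seed,
                 draws = if (keep_draws) vals else NULL),
            class = "usual_intake_distribution")
}

#' @export
print.usual_intake_distribution <- function(x, ...) {
  cat("Usual-intake distribution (", x$n_draws, " draws, seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  mean %.2f g/day, sd %.2f\n", x$mean, x$sd))
  print(round(x$percentiles, 2))
  invisible(x)
}

#' Per-person usual-intake estimates by BLUP shrinkage
#'
#' Shrinks each person's transformed-scale mean toward the population mean in
#' proportion to the within-person noise of their day count:
#' `blup_i = beta0 + sigma_u2 / (sigma_u2 + sigma_e2 / n_i) * (mean_i - beta0)`,
#' then back-transforms through the same 9-point Gauss-Hermite expectation as
#' [usual_intake_distribution()].
#'
#' @param model A fitted [fit_usual_intake()] model.
#' @param person_id Optional subset of persons.
#' @return Data.frame `person_id`, `n_days`, `blup_z` (transformed scale),
#'   `grams_per_day`.
#' @export
shrink_person <- function(model, person_id = NULL) {
  stopifnot(inherits(model, "usual_intake_model"))
  p <- model$persons
  if (!is.null(person_id)) p <- p[p$person_id %in% person_id, , drop = FALSE]
  shrink <- model$sigma_u2 / (model$sigma_u2 + model$sigma_e2 / p$n_days)
  shrink[is.nan(shrink)] <- 0  # sigma_u2 = sigma_e2 = 0
  blup <- model$beta0 + shrink * (p$mean_z - model$beta0)
  data.frame(person_id = p$person_id, n_days = p$n_days, blup_z = blup,
             grams_per_day = gh_back_transform(blup, model$sigma_e2,
                                               model$lambda, model$offset),
             stringsAsFactors = FALSE)
}
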