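# Trial-level behavioral models: accuracy and response time on difficulty
# and testing day, with repeated-measure grouping by scan within participant.

behavior_mixed_fit <- function(d, formula_nested, formula_simple, outcome) {
  notes <- character(0)
  # a usable fit must also yield finite coefficient standard errors
  try_mixed <- function(fml) tryCatch({
    m <- suppressMessages(lme4::lmer(fml, data = d, REML = TRUE))
    stopifnot(all(is.finite(summary(m)$coefficients[, "Std. Error"])))
    m
  }, error = function(e) NULL)
  m <- try_mixed(formula_nested)
  if (is.null(m) || lme4::isSingular(m, tol = 1e-5)) {
    m2 <- try_mixed(formula_simple)
    if (!is.null(m2)) {
      if (!is.null(m)) notes <- c(notes, "nested random structure singular; simplified to participant-only")
      else notes <- c(notes, "nested fit failed; simplified to participant-only")
      m <- m2
    } else if (!is.null(m)) {
      notes <- c(notes, "nested random structure singular; kept (simpler fit also failed)")
    }
  }
  if (is.null(m)) {
    notes <- c(notes, "mixed fits failed; fixed-effect fallback")
    warning("mixed model failed to converge; using fixed participant intercepts")
    m <- stats::lm(stats::reformulate(c("difficulty", "day", "factor(participant)"),
                                      response = outcome), data = d)
    cf <- summary(m)$coefficients
    df <- m$df.residual
  } else {
    cf <- summary(m)$coefficients
    df <- stats::nobs(m) - nrow(cf)
  }
  slope <- cf["difficulty", "Estimate"]
  se <- cf["difficulty", "Std. Error"]
  tval <- cf["difficulty", "t value"]
  crit <- stats::qt(0.975, df)
  day <- if ("day" %in% rownames(cf)) {
    c(slope = cf["day", "Estimate"],
      p = 2 * stats::pt(-abs(cf["day", "t value"]), df))
  } else c(slope = NA_real_, p = NA_real_)
  list(slope = slope, se = se, t_stat = tval, df = df,
       p_value = 2 * stats::pt(-abs(tval), df),
       ci = c(slope - crit * se, slope + crit * se),
       day_effect = day, notes = notes, n = nrow(d))
}

#' Fit the trial-level accuracy model
#'
#' Models binary trial correctness on ordinal difficulty (0/1/2) and testing
#' day with scan-within-participant random intercepts. The default
#' identity-link (linear-probability) family makes the difficulty
#' coefficient directly a per-level change in probability (percentage
#' points / 100); a logistic alternative reports a log-odds slope.
#' Convergence failures fall back to participant-only random intercepts and
#' then to fixed participant intercepts, with a warning.
#'
#' @param trials A behavior-filled `trial_table`.
#' @param family `"linear"` or `"logistic"`.
#' @return Object of class `behavior_fit`: `outcome`, `slope_difficulty`,
#'   `ci_low`, `ci_high`, `t_stat`, `df`, `p_value`, `day_effect`
#'   (slope, p), `n`, `family`, `notes`.
#' @export
fit_accuracy_model <- function(trials, family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (length(unique(trials$difficulty)) < 2L)
    stop("need at least 2 difficulty levels")
  if (length(unique(trials$participant)) < 2L)
    stop("need at least 2 participants")
  if (anyNA(trials$correct)) stop("correct contains NA; generate behavior first")
  if (!all(trials$correct %in% c(TRUE, FALSE)))
    stop("accuracy outcome must be binary")
  d <- data.frame(acc = as.numeric(trials$correct),
                  difficulty = trials$difficulty,
                  day = trials$day - 1,
                  participant = factor(trials$participant),
                  scan = factor(trials$scan))
  if (family == "logistic") {
    m <- suppressMessages(lme4::glmer(
      acc ~ difficulty + day + (1 | participant/scan), data = d,
      family = stats::binomial()))
    cf <- summary(m)$coefficients
    slope <- cf["difficulty", "Estimate"]; se <- cf["difficulty", "Std. Error"]
    z <- cf["difficulty", "z value"]
    fit <- list(slope = slope, se = se, t_stat = z, df = Inf,
                p_value = 2 * stats::pnorm(-abs(z)),
                ci = slope + c(-1, 1) * stats::qnorm(0.975) * se,
                day_effect = c(slope = cf["day", "Estimate"],
                               p = 2 * stats::pnorm(-abs(cf["day", "z value"]))),
                notes = character(0), n = nrow(d))
  } else {
    fit <- behavior_mixed_fit(d, acc ~ difficulty + day + (1 | participant/scan),
                              acc ~ difficulty + day + (1 | participant), "acc")
  }
  structure(list(outcome = "accuracy", slope_difficulty = fit$slope,
                 ci_low = fit$ci[1L], ci_high = fit$ci[2L],
                 t_stat = fit$t_stat, df = fit$df, p_value = fit$p_value,
                 day_effect = fit$day_effect, n = fit$n, family = family,
                 notes = fit$notes),
            class = "behavior_fit")
}

#' Fit the trial-level response-time model
#'
#' Models RT (seconds) on ordinal difficulty and testing day with
#' scan-within-participant random intercepts, excluding incorrect trials by
#' default (errors can reflect non-task processes).
#'
#' @param trials A behavior-filled `trial_table`.
#' @param correct_only Drop incorrect trials before fitting.
#' @return A `behavior_fit` (see [fit_accuracy_model()]); `n` equals the
#'   number of trials retained.
#' @export
fit_rt_model <- function(trials, correct_only = TRUE) {
  if (anyNA(trials$correct)) stop("correct contains NA; generate behavior first")
  if (correct_only) {
    by_level <- tapply(trials$correct, trials$difficulty, sum)
    if (any(by_level == 0))
      stop("no correct trials at difficulty level(s): ",
           paste(names(by_level)[by_level == 0], collapse = ", "))
    trials <- trials[trials$correct, , drop = FALSE]
  }
  d <- data.frame(rt = trials$rt, difficulty = trials$difficulty,
                  day = trials$day - 1,
                  participant = factor(trials$participant),
                  scan = factor(trials$scan))
  fit <- behavior_mixed_fit(d, rt ~ difficulty + day + (1 | participant/scan),
                            rt ~ difficulty + day + (1 | participant), "rt")
  structure(list(outcome = "rt", slope_difficulty = fit$slope,
                 ci_low = fit$ci[1L], ci_high = fit$ci[2L],
                 t_stat = fit$t_stat, df = fit$df, p_value = fit$p_value,
                 day_effect = fit$day_effect, n = fit$n, family = "linear",
                 notes = fit$notes),
            class = "behavior_fit")
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat(sprintf("Behavioral model (%s, %s link): n = %d trials\n",
              x$outcome, x$family, x$n))
  cat(sprintf("  difficulty slope = %.4f  (95%% CI %.4f, %.4f)\n",
              x$slope_difficulty, x$ci_low, x$ci_high))
  cat(sprintf("  t(%s) = %.2f, p = %.3g\n",
              format(x$df), x$t_stat, x$p_value))
  cat(sprintf("  day effect = %.4f (p = %.3g)\n",
              x$day_effect[["slope"]], x$day_effect[["p"]]))
  invisible(x)
}
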