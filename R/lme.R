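## Random-intercept linear mixed-effects trend fit.
##
## value_ij = (beta0 + b0_i) + beta1 * t_ij + eps_ij, with b0_i the
## per-subject random intercept.  Repeated measurements from the same eye
## are correlated; the random intercept absorbs the stable between-subject
## differences so beta1 estimates the common annual trend.

#' Fit a random-intercept linear trend to longitudinal observations
#'
#' Fits `value ~ t_years + (1 | subject)` by REML (lme4).  Confidence
#' intervals for the fixed effects use the estimated fixed-effect covariance
#' with normal quantiles, and the slope p-value is the corresponding Wald
#' test.  Degenerate inputs do not error: a single subject, or data on which
#' the mixed model cannot be estimated (e.g. zero residual variance),
#' fall back to ordinary least squares with the random-intercept SD reported
#' as 0 and a warning.
#'
#' @param observations data.frame with columns `subject`, `t_years`,
#'   `value` (alternative column names `subject_id` and a parameter column
#'   are accepted via `value_col`).
#' @param parameter optional label stored in the result.
#' @param value_col,subject_col,time_col column names, if non-standard.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `lme_fit`: `beta0`, `beta0_ci`, `beta1`
#'   (units/year), `beta1_ci`, `p_beta1`, `random_intercept_sd`,
#'   `residual_sd`, `n_subjects`, `n_observations`.
#' @export
fit_lme <- function(observations, parameter = "value",
                    value_col = "value", subject_col = "subject",
                    time_col = "t_years", conf_level = 0.95) {
  d <- as.data.frame(observations)
  if (!subject_col %in% names(d) && "subject_id" %in% names(d))
    subject_col <- "subject_id"
  for (col in c(value_col, subject_col, time_col))
    if (!col %in% names(d)) stop("observations miss column '", col, "'")
  d <- data.frame(subject = factor(d[[subject_col]]),
                  t_years = as.numeric(d[[time_col]]),
                  value = as.numeric(d[[value_col]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_subj <- nlevels(droplevels(d$subject))
  if (nrow(d) < 2L || length(unique(d$t_years)) < 2L)
    stop("need observations at >= 2 time points")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  finish <- function(beta, vc, ri_sd, res_sd) {
    se <- sqrt(diag(vc))
    p1 <- if (se[2L] == 0) (if (beta[2L] == 0) 1 else 0) else
      2 * stats::pnorm(-abs(beta[2L] / se[2L]))
    structure(list(parameter = parameter,
                   beta0 = unname(beta[1L]),
                   beta0_ci = unname(beta[1L] + c(-1, 1) * z * se[1L]),
                   beta1 = unname(beta[2L]),
                   beta1_ci = unname(beta[2L] + c(-1, 1) * z * se[2L]),
                   p_beta1 = p1,
                   random_intercept_sd = ri_sd, residual_sd = res_sd,
                   n_subjects = n_subj, n_observations = nrow(d),
                   conf_level = conf_level),
              class = "lme_fit")
  }

  ols <- function(msg = NULL) {
    if (!is.null(msg))
      warning("mixed model degenerate (", msg,
              "); falling back to pooled OLS with random-intercept SD 0",
              call. = FALSE)
    fit <- stats::lm(value ~ t_years, data = d)
    beta <- stats::coef(fit)
    res_sd <- sqrt(sum(stats::residuals(fit)^2) /
                     max(1L, stats::df.residual(fit)))
    vc <- if (res_sd > 0) stats::vcov(fit) else matrix(0, 2L, 2L)
    finish(beta, vc, 0, res_sd)
  }

  if (n_subj < 2L) return(ols())
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ t_years + (1 | subject), data = d, REML = TRUE))),
    error = function(e) e)
  if (inherits(fit, "error")) return(ols(conditionMessage(fit)))
  vc_comp <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc_comp$sdcor[vc_comp$grp == "subject"]
  res_sd <- vc_comp$sdcor[vc_comp$grp == "Residual"]
  if (lme4::isSingular(fit, tol = 1e-5) && ri_sd < 1e-8)
    warning("between-subject variance estimated as 0 (singular fit)",
            call. = FALSE)
  finish(lme4::fixef(fit), as.matrix(stats::vcov(fit)), ri_sd, res_sd)
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("Random-intercept linear trend for %s (%d subjects, %d observations)\n",
              x$parameter, x$n_subjects, x$n_observations))
  cat(sprintf("  intercept beta0 = %.2f (CI %.2f; %.2f)\n",
              x$beta0, x$beta0_ci[1L], x$beta0_ci[2L]))
  cat(sprintf("  slope     beta1 = %.2f /year (CI %.2f; %.2f), P = %.4g\n",
              x$beta1, x$beta1_ci[1L], x$beta1_ci[2L], x$p_beta1))
  cat(sprintf("  random intercept SD = %.2f, residual SD = %.2f\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}

#' Random-intercept trend for one cohort parameter
#'
#' Convenience wrapper assembling the `(subject, t_years, value)` triplets of
#' one parameter from a cohort and calling [fit_lme()].
#'
#' @param cohort an `lcd_cohort` or canonical cohort data.frame.
#' @param parameter one of [PARAMETERS].
#' @return An `lme_fit`.
#' @export
cohort_lme <- function(cohort, parameter) {
  cohort <- as_lcd_cohort(cohort)
  col <- parameter_column(parameter)
  cf <- cohort_frame(cohort)
  fit_lme(data.frame(subject = cf$subject_id, t_years = cf$t_months / 12,
                     value = cf[[col]]),
          parameter = parameter)
}
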