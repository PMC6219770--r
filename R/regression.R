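## Univariate linear regression with CIs, bidirectional stepwise screening,
## and visit-wise descriptive summaries with paired rank tests.

#' Univariate linear regression
#'
#' Ordinary least squares of `response` on a single `predictor`, reporting
#' the slope with its t-based confidence interval (n - 2 df), the Pearson
#' correlation coefficient and the two-sided p-value.
#'
#' @param response,predictor numeric vectors; incomplete pairs are dropped.
#' @param conf_level confidence level (default 0.95).
#' @param response_name,predictor_name labels stored in the result.
#' @return An object of class `regression_result`: `beta`, `beta_ci`, `R`,
#'   `p`, `n`, plus intercept.
#' @export
univariate_regression <- function(response, predictor, conf_level = 0.95,
                                  response_name = "response",
                                  predictor_name = "predictor") {
  ok <- stats::complete.cases(response, predictor)
  y <- as.numeric(response[ok]); x <- as.numeric(predictor[ok])
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n)
  if (stats::sd(x) == 0) stop("predictor '", predictor_name,
                              "' has zero variance")
  fit <- stats::lm(y ~ x)
  beta <- unname(stats::coef(fit)[2L])
  se <- sqrt(diag(stats::vcov(fit)))[2L]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2L)
  R <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  p <- if (se == 0) (if (beta == 0) 1 else 0) else
    2 * stats::pt(-abs(beta / se), df = n - 2L)
  structure(list(response = response_name, predictor = predictor_name,
                 beta = beta, beta_ci = unname(beta + c(-1, 1) * tq * se),
                 R = unname(R), p = unname(p), n = n,
                 intercept = unname(stats::coef(fit)[1L])),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: beta = %.4g (CI %.4g to %.4g), R = %.3f, P = %.4g (n = %d)\n",
              x$response, x$predictor, x$beta, x$beta_ci[1L], x$beta_ci[2L],
              x$R, x$p, x$n))
  invisible(x)
}

## p-value of each coefficient (except intercept) of an OLS fit.
coef_pvalues <- function(y, X) {
  fit <- stats::lm(y ~ ., data = X)
  cf <- summary(fit)$coefficients
  keep <- rownames(cf) != "(Intercept)"
  stats::setNames(cf[keep, "Pr(>|t|)"], rownames(cf)[keep])
}

#' Stepwise multivariate screening of pre-screened candidates
#'
#' Reproduces the classical p-value-driven stepwise workflow used by
#' commercial statistics packages: candidates are first screened at the
#' univariate level (`p <= screen_p`, default 0.10) and for functional
#' dependence (any candidate that is an exact affine function of an earlier
#' candidate is dropped with a warning); the survivors then enter a
#' bidirectional selection with forward entry at `p_enter` (default 0.05)
#' and backward removal at `p_remove` (default 0.10).  Every candidate is
#' labelled `In` or `Out`; `In` rows carry their final-model p-value, `Out`
#' rows the p-value the variable would have if added to the final model
#' (the convention used when such tables are reported).
#'
#' @param response numeric response vector.
#' @param predictors data.frame of candidate predictors (numeric columns).
#' @param screen_p univariate screening threshold (default 0.10).
#' @param p_enter forward-entry threshold (default 0.05).
#' @param p_remove backward-removal threshold (default 0.10).
#' @param response_name label used in the output.
#' @return data.frame with one row per candidate: univariate `beta`,
#'   `beta_lo`, `beta_hi`, `R`, `p`, selection `status` (`In`/`Out`) and
#'   `multi_p`.  Candidates failing the univariate screen are reported with
#'   status `Out` and `multi_p = NA`.
#' @export
stepwise_multivariate <- function(response, predictors, screen_p = 0.10,
                                  p_enter = 0.05, p_remove = 0.10,
                                  response_name = "response") {
  predictors <- as.data.frame(predictors)
  stopifnot(ncol(predictors) >= 1L)
  # candidates too sparse to model are set aside before listwise deletion,
  # so one empty column cannot wipe out the complete-case set
  usable <- vapply(predictors, function(col) sum(!is.na(col)) >= 4L,
                   logical(1))
  ok <- stats::complete.cases(response, predictors[, usable, drop = FALSE])
  y <- as.numeric(response[ok])
  X <- predictors[ok, usable, drop = FALSE]
  if (length(y) < 4L) stop("too few complete observations for stepwise selection")

  uni <- lapply(names(X), function(v)
    tryCatch(univariate_regression(y, X[[v]], response_name = response_name,
                                   predictor_name = v),
             error = function(e)  # e.g. zero-variance candidate
               list(beta = NA_real_, beta_ci = c(NA_real_, NA_real_),
                    R = NA_real_, p = NA_real_)))
  names(uni) <- names(X)
  uni_p <- vapply(uni, `[[`, numeric(1), "p")
  candidates <- names(X)[!is.na(uni_p) & uni_p <= screen_p]

  # functional-dependence screen: exact affine dependence on an earlier
  # candidate (|cor| == 1 within tolerance) drops the later-listed one
  dropped_dep <- character(0)
  if (length(candidates) > 1L) {
    keep <- candidates[1L]
    for (v in candidates[-1L]) {
      r_max <- max(abs(stats::cor(X[[v]], X[, keep, drop = FALSE])))
      if (r_max > 1 - 1e-10) {
        dropped_dep <- c(dropped_dep, v)
        warning("candidate '", v, "' is functionally dependent on an ",
                "earlier candidate; dropped", call. = FALSE)
      } else keep <- c(keep, v)
    }
    candidates <- keep
  }

  # bidirectional stepwise on p-values
  model <- character(0)
  repeat {
    changed <- FALSE
    # forward entry
    outside <- setdiff(candidates, model)
    if (length(outside)) {
      entry_p <- vapply(outside, function(v) {
        Xt <- X[, c(model, v), drop = FALSE]
        if (qr(cbind(1, as.matrix(Xt)))$rank < ncol(Xt) + 1L)
          return(NA_real_)  # collinear with current model
        coef_pvalues(y, Xt)[[v]]
      }, numeric(1))
      entry_p <- entry_p[!is.na(entry_p)]
      if (length(entry_p) && min(entry_p) <= p_enter) {
        model <- c(model, names(entry_p)[which.min(entry_p)])
        changed <- TRUE
      }
    }
    # backward removal
    if (length(model)) {
      pv <- coef_pvalues(y, X[, model, drop = FALSE])
      if (max(pv) > p_remove) {
        model <- setdiff(model, names(pv)[which.max(pv)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  multi_p <- stats::setNames(rep(NA_real_, ncol(X)), names(X))
  if (length(model))
    multi_p[model] <- coef_pvalues(y, X[, model, drop = FALSE])[model]
  for (v in setdiff(candidates, model)) {
    Xt <- X[, c(model, v), drop = FALSE]
    multi_p[v] <- if (qr(cbind(1, as.matrix(Xt)))$rank < ncol(Xt) + 1L)
      NA_real_ else coef_pvalues(y, Xt)[[v]]
  }

  out <- data.frame(
    response = response_name, predictor = names(X),
    beta = vapply(uni, `[[`, numeric(1), "beta"),
    beta_lo = vapply(uni, function(u) u$beta_ci[1L], numeric(1)),
    beta_hi = vapply(uni, function(u) u$beta_ci[2L], numeric(1)),
    R = vapply(uni, `[[`, numeric(1), "R"),
    p = uni_p,
    screened = names(X) %in% c(candidates, dropped_dep),
    status = ifelse(names(X) %in% model, "In", "Out"),
    multi_p = unname(multi_p),
    stringsAsFactors = FALSE)
  if (any(!usable))  # sparse candidates set aside before modelling
    out <- rbind(out, data.frame(
      response = response_name, predictor = names(predictors)[!usable],
      beta = NA_real_, beta_lo = NA_real_, beta_hi = NA_real_, R = NA_real_,
      p = NA_real_, screened = FALSE, status = "Out", multi_p = NA_real_,
      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Visit-wise summary of one parameter with paired rank tests
#'
#' Mean and SD of the parameter at every visit, with two-sided Wilcoxon
#' signed-rank p-values against baseline and against the previous visit
#' (paired within subject; subjects missing either visit are excluded from
#' that comparison).
#'
#' @param cohort an `lcd_cohort` or canonical cohort data.frame.
#' @param parameter one of [PARAMETERS].
#' @return data.frame: `visit`, `t_months_mean`, `n`, `mean`, `sd`,
#'   `p_vs_base`, `p_vs_prev`.
#' @export
visitwise_summary <- function(cohort, parameter) {
  cohort <- as_lcd_cohort(cohort)
  col <- parameter_column(parameter)
  cf <- cohort_frame(cohort)
  visits <- intersect(VISIT_LABELS, unique(cf$visit_label))
  value_at <- function(visit) {
    v <- cf[cf$visit_label == visit, c("subject_id", col, "t_months")]
    stats::setNames(v[[col]], v$subject_id)
  }
  paired_p <- function(va, vb) {
    common <- intersect(names(va), names(vb))
    d <- va[common] - vb[common]
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(NA_real_)
    suppressWarnings(wilcoxon_signed_rank(d)$p)
  }
  base_vals <- if ("base" %in% visits) value_at("base") else NULL
  out <- do.call(rbind, lapply(seq_along(visits), function(i) {
    vals <- value_at(visits[i])
    vv <- vals[!is.na(vals)]
    tm <- cf$t_months[cf$visit_label == visits[i]]
    data.frame(
      visit = visits[i], t_months_mean = mean(tm), n = length(vv),
      mean = if (length(vv)) mean(vv) else NA_real_,
      sd = if (length(vv) > 1L) stats::sd(vv) else NA_real_,
      p_vs_base = if (visits[i] == "base" || is.null(base_vals)) NA_real_
                  else paired_p(vals, base_vals),
      p_vs_prev = if (i == 1L) NA_real_
                  else paired_p(vals, value_at(visits[i - 1L])),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
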