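## Annualized per-subject rates of change and the aging-adjusted RNFL
## progression rule.  Time is converted with exactly 1 month = 1/12 year.

#' Annualized rate of change between two visits
#'
#' `(value_to - value_from) / ((t_to_months - t_from_months) / 12)`, in
#' parameter units per year.  Vectorized.  A missing endpoint yields a
#' missing rate (`NA`), never zero.
#'
#' @param value_from,value_to parameter values at the two visits.
#' @param t_from_months,t_to_months times since surgery, months;
#'   `t_to_months` must exceed `t_from_months`.
#' @return rate in units/year.
#' @examples
#' rate(61, 47, 0, 20)   # -8.4 um/year
#' @export
rate <- function(value_from, value_to, t_from_months, t_to_months) {
  dt <- (t_to_months - t_from_months) / 12
  if (any(dt <= 0, na.rm = TRUE))
    stop("t_to_months must be strictly greater than t_from_months")
  (value_to - value_from) / dt
}

#' Monthly change implied by an annualized rate
#'
#' @param rate rate in units/year.
#' @return units/month (`rate / 12`).
#' @examples
#' monthly_change(-187.4)  # -15.6167 mmHg in one month
#' @export
monthly_change <- function(rate) rate / 12

#' Aging-adjusted RNFL progression criterion
#'
#' Normative aging alone thins the global RNFL; the default criterion takes
#' the normative aging rate as -0.54 +/- 0.23 um/year and flags progression
#' when a measured rate falls below `aging_mean - z * aging_sd` (one-sided
#' z = 1.96), i.e. below -0.9908 um/year, so that thinning attributable to
#' aging alone is not called glaucomatous progression.
#'
#' @param aging_mean normative aging rate, um/year.
#' @param aging_sd normative aging rate SD, um/year.
#' @param z standard-normal multiplier.
#' @return An object of class `progression_criterion`.
#' @export
progression_criterion <- function(aging_mean = -0.54, aging_sd = 0.23,
                                  z = 1.96) {
  stopifnot(is.finite(aging_mean), is.finite(aging_sd), aging_sd >= 0,
            is.finite(z))
  structure(list(aging_mean = aging_mean, aging_sd = aging_sd, z = z,
                 threshold = aging_mean - z * aging_sd),
            class = "progression_criterion")
}

#' @export
print.progression_criterion <- function(x, ...) {
  cat(sprintf(
    "RNFL progression criterion: rate < %.4f um/year (aging %.2f +/- %.2f, z = %.2f)\n",
    x$threshold, x$aging_mean, x$aging_sd, x$z))
  invisible(x)
}

#' Progression threshold of a criterion
#' @param criterion a [progression_criterion()].
#' @return threshold in um/year (`aging_mean - z * aging_sd`).
#' @export
progression_threshold <- function(criterion = progression_criterion()) {
  stopifnot(inherits(criterion, "progression_criterion"))
  criterion$threshold
}

#' Classify global-RNFL rates as progressive or not
#'
#' Strict rule: progressive iff `rate < threshold`; a rate exactly at the
#' threshold is non-progressive.  Missing rates stay unclassified (`NA`).
#'
#' @param rate annualized global RNFL rate(s), um/year.
#' @param criterion a [progression_criterion()].
#' @return factor with levels `progressive`, `non-progressive`.
#' @export
classify_progression <- function(rate, criterion = progression_criterion()) {
  thr <- progression_threshold(criterion)
  factor(ifelse(is.na(rate), NA,
                ifelse(rate < thr, "progressive", "non-progressive")),
         levels = c("progressive", "non-progressive"))
}

## Build the per-subject rate records for one parameter and anchoring.
rate_records_one <- function(series, parameter, anchor) {
  v <- series$visits
  col <- parameter_column(parameter)
  pairs <- switch(anchor,
    baseline = {
      to <- setdiff(v$visit_label, "base")
      if (!"base" %in% v$visit_label || !length(to)) return(NULL)
      data.frame(from = "base", to = to, stringsAsFactors = FALSE)
    },
    consecutive = if (nrow(v) < 2L) NULL else
      data.frame(from = v$visit_label[-nrow(v)], to = v$visit_label[-1L],
                 stringsAsFactors = FALSE),
    `fu-vs-6m` = data.frame(from = "6pv", to = "FUpv",
                            stringsAsFactors = FALSE),
    stop("unknown anchor: ", anchor))
  if (is.null(pairs) || nrow(pairs) == 0L) return(NULL)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    fi <- match(pairs$from[i], v$visit_label)
    ti <- match(pairs$to[i], v$visit_label)
    if (is.na(fi) || is.na(ti)) return(NULL)
    dt <- (v$t_months[ti] - v$t_months[fi]) / 12
    data.frame(subject_id = series$subject_id, parameter = parameter,
               from_visit = pairs$from[i], to_visit = pairs$to[i],
               delta_t_years = dt,
               rate = rate(v[[col]][fi], v[[col]][ti],
                           v$t_months[fi], v$t_months[ti]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-subject rate table with visit-wise summaries
#'
#' Computes the annualized rate of change of one parameter for every subject
#' of a cohort, with one of three anchorings: `"baseline"` (baseline to each
#' later visit), `"consecutive"` (each visit to the next) or `"fu-vs-6m"`
#' (6-month visit to final follow-up).  Subjects missing either endpoint of
#' an interval are excluded from that row (their rate is `NA`).
#'
#' @param cohort an `lcd_cohort` or canonical cohort data.frame.
#' @param parameter one of [PARAMETERS].
#' @param anchor `"baseline"`, `"consecutive"` or `"fu-vs-6m"`.
#' @return An object of class `rate_table`: list with `rates` (one row per
#'   subject-interval) and `summary` (per interval: n with a computable rate,
#'   mean, SD, min, max -- the presentation used for rate-of-thinning
#'   tables).
#' @export
cohort_rate_table <- function(cohort, parameter,
                              anchor = c("baseline", "consecutive",
                                         "fu-vs-6m")) {
  cohort <- as_lcd_cohort(cohort)
  anchor <- match.arg(anchor)
  stopifnot(length(cohort) >= 1L)
  rates <- do.call(rbind, lapply(cohort, rate_records_one, parameter, anchor))
  if (is.null(rates))
    stop("no computable rate intervals for parameter ", parameter)
  rownames(rates) <- NULL
  key <- paste(rates$from_visit, rates$to_visit, sep = "->")
  ord <- unique(key)
  summ <- do.call(rbind, lapply(ord, function(kk) {
    r <- rates$rate[key == kk]
    r_ok <- r[!is.na(r)]
    data.frame(interval = kk, n = length(r_ok),
               mean = if (length(r_ok)) mean(r_ok) else NA_real_,
               sd = if (length(r_ok) > 1L) stats::sd(r_ok) else NA_real_,
               min = if (length(r_ok)) min(r_ok) else NA_real_,
               max = if (length(r_ok)) max(r_ok) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(parameter = parameter, anchor = anchor, rates = rates,
                 summary = summ),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, digits = 1, ...) {
  cat(sprintf("Rates of change of %s (%s anchoring), units/year\n",
              x$parameter, x$anchor))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s n=%2d  %6.*f +/- %.*f  (%.*f, %.*f)\n",
                s$interval[i], s$n[i], digits, s$mean[i], digits, s$sd[i],
                digits, s$min[i], digits, s$max[i]))
  invisible(x)
}

#' Baseline-to-follow-up global RNFL rate per subject
#' @keywords internal
fu_rnfl_rates <- function(cohort) {
  cohort <- as_lcd_cohort(cohort)
  vapply(cohort, function(s) {
    v <- s$visits
    fi <- match("base", v$visit_label); ti <- match("FUpv", v$visit_label)
    if (is.na(fi) || is.na(ti)) return(NA_real_)
    rate(v$rnfl_G[fi], v$rnfl_G[ti], v$t_months[fi], v$t_months[ti])
  }, numeric(1))
}

#' Split a cohort into progressive and non-progressive groups
#'
#' Applies [classify_progression()] to each subject's baseline-to-follow-up
#' global RNFL rate (or 6-month-to-follow-up with `anchor = "fu-vs-6m"`) and
#' summarizes the baseline characteristics of the two groups.
#'
#' @param cohort an `lcd_cohort` or canonical cohort data.frame.
#' @param criterion a [progression_criterion()].
#' @param anchor `"baseline"` (default, baseline to FUpv) or `"fu-vs-6m"`.
#' @return An object of class `progression_split`: list with
#'   `classification` (subject_id, rate, group), the two sub-cohorts
#'   `progressive` and `non_progressive`, and `baseline_summary` (per-group
#'   n, mean +/- SD of baseline age, LCD and global RNFL, and surgery-type
#'   counts).
#' @export
split_by_progression <- function(cohort,
                                 criterion = progression_criterion(),
                                 anchor = c("baseline", "fu-vs-6m")) {
  cohort <- as_lcd_cohort(cohort)
  anchor <- match.arg(anchor)
  r <- if (anchor == "baseline") fu_rnfl_rates(cohort) else
    vapply(cohort, function(s) {
      v <- s$visits
      fi <- match("6pv", v$visit_label); ti <- match("FUpv", v$visit_label)
      if (is.na(fi) || is.na(ti)) return(NA_real_)
      rate(v$rnfl_G[fi], v$rnfl_G[ti], v$t_months[fi], v$t_months[ti])
    }, numeric(1))
  grp <- classify_progression(r, criterion)
  cls <- data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
                    rate = r, group = grp, stringsAsFactors = FALSE)
  prog <- structure(cohort[!is.na(grp) & grp == "progressive"],
                    class = "lcd_cohort")
  nonp <- structure(cohort[!is.na(grp) & grp == "non-progressive"],
                    class = "lcd_cohort")
  base_stats <- function(sub) {
    if (length(sub) == 0L)
      return(data.frame(n = 0L, age_mean = NA_real_, age_sd = NA_real_,
                        lcd_mean = NA_real_, lcd_sd = NA_real_,
                        rnfl_mean = NA_real_, rnfl_sd = NA_real_,
                        n_trabeculectomy = 0L, n_npds = 0L))
    b <- do.call(rbind, lapply(sub, function(s)
      s$visits[s$visits$visit_label == "base", , drop = FALSE]))
    data.frame(n = length(sub),
               age_mean = mean(b$age_years, na.rm = TRUE),
               age_sd = stats::sd(b$age_years, na.rm = TRUE),
               lcd_mean = mean(b$lcd_um, na.rm = TRUE),
               lcd_sd = stats::sd(b$lcd_um, na.rm = TRUE),
               rnfl_mean = mean(b$rnfl_G, na.rm = TRUE),
               rnfl_sd = stats::sd(b$rnfl_G, na.rm = TRUE),
               n_trabeculectomy = sum(b$surgery == "trabeculectomy",
                                      na.rm = TRUE),
               n_npds = sum(b$surgery == "NPDS", na.rm = TRUE))
  }
  summ <- rbind(cbind(group = "progressive", base_stats(prog)),
                cbind(group = "non-progressive", base_stats(nonp)))
  structure(list(classification = cls, progressive = prog,
                 non_progressive = nonp, baseline_summary = summ,
                 criterion = criterion, anchor = anchor),
            class = "progression_split")
}

#' @export
print.progression_split <- function(x, ...) {
  cat(sprintf("Progression split (%s global-RNFL rate): %d progressive, %d non-progressive, %d unclassified\n",
              x$anchor, length(x$progressive), length(x$non_progressive),
              sum(is.na(x$classification$group))))
  invisible(x)
}
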