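test_that("annualized rates reproduce the worked-example arithmetic", {
  expect_equal(rate(61, 47, 0, 20), -8.4)            # case-A global RNFL
  expect_equal(round(rate(86, 64, 0, 21), 1), -12.6) # case-B global RNFL
  expect_equal(rate(50, 50, 0, 7), 0)
  # antisymmetry
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rate(a, b, 0, 13), -rate(b, a, 0, 13))
  expect_error(rate(1, 2, 6, 6), "strictly greater")
  expect_error(rate(1, 2, 8, 6), "strictly greater")
  expect_true(is.na(rate(NA, 47, 0, 20)))            # missing marker, not 0
})

test_that("monthly change is the rate over twelve", {
  expect_equal(abs(monthly_change(-187.4)), 187.4 / 12)
  expect_equal(round(abs(monthly_change(-187.4)), 2), 15.62)
  expect_equal(abs(monthly_change(-748.6)), 748.6 / 12)
  expect_equal(round(abs(monthly_change(-748.6)), 2), 62.38)
  expect_equal(monthly_change(0), 0)
})

test_that("cohort rate tables summarize per-subject rates by interval", {
  # constant per-subject slope, no noise: every baseline-anchored rate = s
  t_months <- c(0, 1, 3, 6, 18)
  s <- -6
  df <- make_cohort_df(sprintf("P%d", 1:4), VISIT_LABELS, t_months,
                       sapply(1:4, function(i) 70 + s * t_months / 12))
  rt <- cohort_rate_table(df, "RNFL.G", anchor = "baseline")
  expect_equal(rt$rates$rate, rep(s, nrow(rt$rates)))

  # two subjects with baseline-to-FU rates -4 and -2
  df2 <- make_cohort_df(c("A", "B"), c("base", "FUpv"), c(0, 24),
                        cbind(c(60, 52), c(60, 56)))
  rt2 <- cohort_rate_table(df2, "RNFL.G", anchor = "baseline")
  expect_equal(rt2$summary$mean, -3)
  expect_equal(rt2$summary$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(rt2$summary$min, -4)
  expect_equal(rt2$summary$max, -2)

  # representative-case LCD course: 641 -> 522 over 6 months, then -> 388
  fx <- fixture_fig5_fig6()
  base6 <- cohort_rate_table(fx, "LCD", anchor = "baseline")
  expect_equal(base6$rates$rate[base6$rates$subject_id == "case-A" &
                                  base6$rates$to_visit == "6pv"], -238)
  fu6 <- cohort_rate_table(fx, "LCD", anchor = "fu-vs-6m")
  expect_equal(fu6$rates$rate[fu6$rates$subject_id == "case-A"],
               (388 - 522) / (14 / 12), tolerance = 1e-12)
  expect_equal(fu6$rates$rate[fu6$rates$subject_id == "case-A"],
               -114.857142857, tolerance = 1e-9)

  # a subject missing an endpoint is excluded from that interval row
  df3 <- rbind(df2, data.frame(subject_id = "C", visit_label = "base",
                               t_months = 0, rnfl_G = 58))
  rt3 <- cohort_rate_table(df3, "RNFL.G", anchor = "baseline")
  expect_identical(rt3$summary$n, 2L)
  expect_true(is.na(rt3$rates$rate[rt3$rates$subject_id == "C"]) ||
                !"C" %in% rt3$rates$subject_id)
})

test_that("baseline-anchored rates telescope over consecutive intervals", {
  sim <- generate_cohort(cohort_config(), seed = 21)
  base_rt <- cohort_rate_table(sim$cohort, "LCD", anchor = "baseline")$rates
  cons_rt <- cohort_rate_table(sim$cohort, "LCD", anchor = "consecutive")$rates
  for (sid in unique(base_rt$subject_id)) {
    b <- base_rt[base_rt$subject_id == sid, ]
    cc <- cons_rt[cons_rt$subject_id == sid, ]
    for (i in seq_len(nrow(b))) {
      upto <- match(b$to_visit[i], cc$to_visit)
      # time-weighted mean of consecutive rates equals the anchored rate
      w <- cc$delta_t_years[1:upto]
      expect_equal(b$rate[i], sum(cc$rate[1:upto] * w) / sum(w),
                   tolerance = 1e-9)
    }
  }
})

test_that("the aging-adjusted threshold follows the criterion algebra", {
  expect_equal(progression_threshold(progression_criterion()), -0.9908)
  expect_equal(progression_threshold(progression_criterion(z = 0)), -0.54)
  expect_equal(progression_threshold(progression_criterion(aging_sd = 0)),
               -0.54)
  crit <- progression_criterion()
  expect_lt(crit$threshold, crit$aging_mean)
})

test_that("progression classification is strict and monotone", {
  crit <- progression_criterion()
  expect_identical(as.character(classify_progression(-2.8, crit)),
                   "progressive")
  expect_identical(as.character(classify_progression(-0.6, crit)),
                   "non-progressive")
  # exactly at the boundary: non-progressive ("less than" is strict)
  expect_identical(as.character(classify_progression(-0.9908, crit)),
                   "non-progressive")
  expect_true(is.na(classify_progression(NA_real_, crit)))
  # monotone: making a rate more negative never flips back
  set.seed(9)
  r <- runif(200, -15, 8)
  cls <- classify_progression(r, crit)
  worse <- classify_progression(r - runif(200, 0, 10), crit)
  expect_false(any(cls == "progressive" & worse == "non-progressive"))
})

test_that("the progressive split partitions the classifiable subjects", {
  # 21 subjects thinning at -3 um/year, 8 improving at +1 um/year
  n <- 29; rates <- rep(c(-3, 1), c(21, 8))
  df <- make_cohort_df(sprintf("S%02d", 1:n), c("base", "FUpv"), c(0, 18),
                       rbind(rep(60, n), 60 + rates * 1.5))
  df$lcd_um <- rep(c(435, 544), c(21, 8))[match(df$subject_id,
                                                sprintf("S%02d", 1:n))]
  split <- split_by_progression(df)
  expect_length(split$progressive, 21L)
  expect_length(split$non_progressive, 8L)
  expect_equal(sum(!is.na(split$classification$group)),
               length(split$progressive) + length(split$non_progressive))
  gs <- split$baseline_summary
  expect_equal(gs$lcd_mean[gs$group == "progressive"], 435)
  expect_equal(gs$lcd_mean[gs$group == "non-progressive"], 544)

  # all rates above threshold: empty progressive group
  df_up <- make_cohort_df(c("A", "B"), c("base", "FUpv"), c(0, 18),
                          rbind(c(60, 60), c(61, 62)))
  split_up <- split_by_progression(df_up)
  expect_length(split_up$progressive, 0L)
  expect_length(split_up$non_progressive, 2L)

  # subjects without a follow-up rate stay unclassified
  df_na <- rbind(df, data.frame(subject_id = "S30", visit_label = "base",
                                t_months = 0, rnfl_G = 55, lcd_um = 500))
  split_na <- split_by_progression(df_na)
  expect_equal(sum(is.na(split_na$classification$group)), 1L)
  expect_length(split_na$progressive, 21L)
})
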