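## Seedable synthetic data with known ground truth: (a) longitudinal cohorts
## emulating the statistical structure of a post-surgical glaucoma study
## (IOP relaxation after filtration surgery, biphasic anterior LC
## displacement, transient 1-month RNFL swelling followed by thinning whose
## per-subject rate is negatively correlated with the LCD-reduction rate) and
## (b) per-eye B-scan landmark annotations over a parabolic LC surface.
##
## Trajectory model, t in months:
##   value(t) = plateau + (baseline - plateau) * exp(-t / tau)
##              + slope * t / 12
##              + swelling * bump(t)            (RNFL only)
##              + iid measurement noise,
## where bump() is a Gaussian centred at 1 month, rescaled to be 0 at t = 0
## and 1 at t = 1 so the baseline stays uncontaminated.

#' Configuration of the synthetic longitudinal cohort generator
#'
#' Defaults emulate a 29-subject surgical cohort: visits at 0, 1, 3 and 6
#' months plus a follow-up drawn uniformly from 12-29 months; IOP falling
#' from 24.0 +/- 8.9 mmHg towards a post-surgical floor around 9 mmHg with a
#' slow late recovery; LCD starting at 465.3 +/- 136.4 um with a fast
#' anterior displacement (mean 62 um within the first month) followed by a
#' slow drift; global RNFL starting at 59.3 +/- 15.8 um with a transient
#' +5.6 um swelling at 1 month (gone by 3 months) and per-subject thinning
#' rates of -2.8 +/- 4.0 um/year.  Per-subject (LCD slope, RNFL slope) are
#' bivariate normal with correlation `rate_correlation`; baseline IOP shares
#' a factor with the LCD slope (`iop_lcd_rate_correlation`), so eyes with
#' higher preoperative IOP have faster (more negative) LCD change.
#'
#' @param n_subjects number of fully followed subjects.
#' @param visit_months named vector of fixed visit times (months).
#' @param fu_range range (months) the follow-up visit is drawn from.
#' @param iop_baseline_mean,iop_baseline_sd preoperative IOP, mmHg.
#' @param iop_floor_mean,iop_floor_sd post-surgical IOP plateau, mmHg.
#' @param iop_tau_months IOP relaxation time constant, months.
#' @param iop_late_slope_mean,iop_late_slope_sd late IOP drift, mmHg/year.
#' @param lcd_baseline_mean,lcd_baseline_sd preoperative LCD, um.
#' @param lcd_fast_drop_mean,lcd_fast_drop_sd fast-phase anterior LC
#'   displacement completed within about the first month, um (negative draws
#'   allowed: a minority of eyes deepen transiently).
#' @param lcd_fast_drop_baseline_cor correlation of the fast drop with the
#'   baseline depth (deeper laminae rebound more).
#' @param lcd_tau_months fast-phase time constant, months.
#' @param lcd_slope_mean,lcd_slope_sd slow-phase LCD drift, um/year.
#' @param rnfl_baseline_mean,rnfl_baseline_sd baseline global RNFL, um.
#' @param rnfl_swelling_mean,rnfl_swelling_sd 1-month swelling amplitude, um.
#' @param rnfl_swelling_width_months width of the swelling bump, months.
#' @param rnfl_slope_mean,rnfl_slope_sd per-subject thinning rate, um/year.
#' @param rate_correlation correlation between per-subject LCD and RNFL
#'   slopes (default -0.6: faster LC advance, faster thinning).
#' @param iop_lcd_rate_correlation correlation between baseline IOP and the
#'   LCD slope.
#' @param noise_iop,noise_lcd,noise_rnfl measurement noise SDs (mmHg, um,
#'   um).
#' @param sector_offsets,sector_multipliers per-sector RNFL offsets (um) and
#'   thinning-rate multipliers relative to the global value.
#' @param sector_offset_sd per-subject jitter of the sector offsets, um.
#' @param age_mean,age_sd subject age, years.
#' @param n_trabeculectomy number of fully followed subjects assigned
#'   trabeculectomy (the rest get NPDS).
#' @param n_lost_early,n_lost_late additional subjects lost to follow-up
#'   shortly after surgery (visits base and 1pv only) or after six months
#'   (no FUpv), exercising missing-data paths.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(
    n_subjects = 29L,
    visit_months = c(base = 0, `1pv` = 1, `3pv` = 3, `6pv` = 6),
    fu_range = c(12, 29),
    iop_baseline_mean = 24.0, iop_baseline_sd = 8.9,
    iop_floor_mean = 9, iop_floor_sd = 2,
    iop_tau_months = 0.35,
    iop_late_slope_mean = 2.2, iop_late_slope_sd = 1,
    lcd_baseline_mean = 465.3, lcd_baseline_sd = 136.4,
    lcd_fast_drop_mean = 62, lcd_fast_drop_sd = 35,
    lcd_fast_drop_baseline_cor = 0.4,
    lcd_tau_months = 0.4,
    lcd_slope_mean = -38.6, lcd_slope_sd = 30,
    rnfl_baseline_mean = 59.3, rnfl_baseline_sd = 15.8,
    rnfl_swelling_mean = 5.6, rnfl_swelling_sd = 3,
    rnfl_swelling_width_months = 0.45,
    rnfl_slope_mean = -2.8, rnfl_slope_sd = 4.0,
    rate_correlation = -0.6,
    iop_lcd_rate_correlation = -0.5,
    noise_iop = 1.5, noise_lcd = 15, noise_rnfl = 2,
    sector_offsets = c(TS = 14, T = -18, TI = 16, NS = 6, N = -10, NI = 12),
    sector_multipliers = c(TS = 1.46, T = 0.50, TI = 1.64, NS = 1.14,
                           N = 0.75, NI = 1.32),
    sector_offset_sd = 4,
    age_mean = 65.8, age_sd = 10.8,
    n_trabeculectomy = NULL,
    n_lost_early = 0L, n_lost_late = 0L) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_trabeculectomy))  # 16:13 split, scaled to the cohort
    cfg$n_trabeculectomy <- round(16 / 29 * cfg$n_subjects)
  sds <- cfg[grepl("_sd$|^noise_", names(cfg))]
  stopifnot(all(unlist(sds) >= 0))
  if (abs(cfg$rate_correlation) > 1 ||
      abs(cfg$iop_lcd_rate_correlation) > 1 ||
      abs(cfg$lcd_fast_drop_baseline_cor) > 1)
    stop("correlations must lie in [-1, 1] (correlation matrix not positive ",
         "semi-definite)")
  stopifnot(cfg$fu_range[1L] >= 12, cfg$fu_range[2L] <= 29,
            cfg$fu_range[1L] <= cfg$fu_range[2L],
            cfg$n_subjects >= 1L,
            cfg$n_trabeculectomy <= cfg$n_subjects)
  stopifnot(identical(sort(names(cfg$sector_offsets)),
                      sort(setdiff(SECTOR_CODES, "G"))),
            identical(sort(names(cfg$sector_multipliers)),
                      sort(setdiff(SECTOR_CODES, "G"))))
  structure(cfg, class = "cohort_config")
}

## Swelling bump: Gaussian centred at 1 month, anchored so bump(0) = 0 and
## bump(1) = 1; essentially zero by the 3-month visit.
swelling_bump <- function(t_months, width) {
  phi <- exp(-0.5 * ((t_months - 1) / width)^2)
  phi0 <- exp(-0.5 * (1 / width)^2)
  (phi - phi0) / (1 - phi0)
}

#' Generate a synthetic longitudinal cohort with ground truth
#'
#' Draws per-subject latent parameters (baselines, slopes, transient
#' amplitudes) from the configured distributions, evaluates the trajectory
#' model at the visit times, adds measurement noise, and returns both the
#' cohort and every latent used, so parameter-recovery tests can compare
#' estimates against the generating truth.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return list with `cohort` (an `lcd_cohort`), `data` (the canonical long
#'   table) and `truth` (one row per subject: all latent parameters).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  cfg <- config
  n_total <- cfg$n_subjects + cfg$n_lost_early + cfg$n_lost_late
  ids <- sprintf("S%02d", seq_len(n_total))

  # correlated latent normals
  z_lcd <- stats::rnorm(n_total)
  rho <- cfg$rate_correlation
  z_rnfl <- rho * z_lcd + sqrt(1 - rho^2) * stats::rnorm(n_total)
  rho_i <- cfg$iop_lcd_rate_correlation
  z_iop <- rho_i * z_lcd + sqrt(1 - rho_i^2) * stats::rnorm(n_total)
  z_base <- stats::rnorm(n_total)
  rho_d <- cfg$lcd_fast_drop_baseline_cor
  z_drop <- rho_d * z_base + sqrt(1 - rho_d^2) * stats::rnorm(n_total)

  truth <- data.frame(
    subject_id = ids,
    age_years = round(pmin(pmax(cfg$age_mean + cfg$age_sd *
                                  stats::rnorm(n_total), 40), 90)),
    surgery = sample(rep(c("trabeculectomy", "NPDS"),
                         c(cfg$n_trabeculectomy,
                           n_total - cfg$n_trabeculectomy))),
    fu_months = round(stats::runif(n_total, cfg$fu_range[1L],
                                   cfg$fu_range[2L]), 1),
    iop_base = pmax(cfg$iop_baseline_mean + cfg$iop_baseline_sd * z_iop, 12),
    iop_floor = pmax(cfg$iop_floor_mean + cfg$iop_floor_sd *
                       stats::rnorm(n_total), 4),
    iop_slope = cfg$iop_late_slope_mean + cfg$iop_late_slope_sd *
      stats::rnorm(n_total),
    lcd_base = pmax(cfg$lcd_baseline_mean + cfg$lcd_baseline_sd * z_base,
                    120),
    lcd_fast_drop = cfg$lcd_fast_drop_mean + cfg$lcd_fast_drop_sd * z_drop,
    lcd_slope = cfg$lcd_slope_mean + cfg$lcd_slope_sd * z_lcd,
    rnfl_base = pmax(cfg$rnfl_baseline_mean + cfg$rnfl_baseline_sd *
                       stats::rnorm(n_total), 28),
    rnfl_swelling = cfg$rnfl_swelling_mean + cfg$rnfl_swelling_sd *
      stats::rnorm(n_total),
    rnfl_slope = cfg$rnfl_slope_mean + cfg$rnfl_slope_sd * z_rnfl,
    cct_um = round(530 + 25 * stats::rnorm(n_total)),
    al_mm = round(23.5 + 1.1 * stats::rnorm(n_total), 2),
    vf_md_db = round(pmin(-1, -15 + 10.9 * stats::rnorm(n_total)), 2),
    vf_psd_db = round(pmax(1, 6.3 + 3.2 * stats::rnorm(n_total)), 1),
    n_meds = sample(2:4, n_total, replace = TRUE),
    lost = rep(c("no", "early", "late"),
               c(cfg$n_subjects, cfg$n_lost_early, cfg$n_lost_late)),
    stringsAsFactors = FALSE)

  sector_names <- setdiff(SECTOR_CODES, "G")
  offsets <- matrix(stats::rnorm(n_total * 6, 0, cfg$sector_offset_sd),
                    n_total, 6, dimnames = list(NULL, sector_names))
  offsets <- sweep(offsets, 2L, cfg$sector_offsets[sector_names], `+`)

  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    tt <- c(cfg$visit_months, FUpv = truth$fu_months[i])
    labels <- names(tt)
    keep <- switch(truth$lost[i],
                   no = rep(TRUE, length(tt)),
                   early = labels %in% c("base", "1pv"),
                   late = labels != "FUpv")
    tt <- tt[keep]; labels <- labels[keep]
    ty <- tt / 12
    iop <- truth$iop_floor[i] +
      (truth$iop_base[i] - truth$iop_floor[i]) * exp(-tt / cfg$iop_tau_months) +
      truth$iop_slope[i] * ty
    lcd <- truth$lcd_base[i] -
      truth$lcd_fast_drop[i] * (1 - exp(-tt / cfg$lcd_tau_months)) +
      truth$lcd_slope[i] * ty
    bump <- swelling_bump(tt, cfg$rnfl_swelling_width_months)
    rnfl_g <- truth$rnfl_base[i] + truth$rnfl_swelling[i] * bump +
      truth$rnfl_slope[i] * ty
    m <- length(tt)
    iop <- pmax(iop + stats::rnorm(m, 0, cfg$noise_iop), 1)
    lcd <- lcd + stats::rnorm(m, 0, cfg$noise_lcd)
    rnfl_g <- pmax(rnfl_g + stats::rnorm(m, 0, cfg$noise_rnfl), 5)
    sect <- sapply(sector_names, function(s)
      pmax(truth$rnfl_base[i] + offsets[i, s] +
             truth$rnfl_swelling[i] * bump +
             truth$rnfl_slope[i] * cfg$sector_multipliers[[s]] * ty +
             stats::rnorm(m, 0, cfg$noise_rnfl), 5))
    if (m == 1L) sect <- matrix(sect, nrow = 1L,
                                dimnames = list(NULL, sector_names))
    rows[[i]] <- data.frame(
      subject_id = ids[i], visit_label = labels, t_months = unname(tt),
      iop_mmHg = round(iop, 1), rnfl_G = round(rnfl_g, 1),
      rnfl_TS = round(sect[, "TS"], 1), rnfl_T = round(sect[, "T"], 1),
      rnfl_TI = round(sect[, "TI"], 1), rnfl_NS = round(sect[, "NS"], 1),
      rnfl_N = round(sect[, "N"], 1), rnfl_NI = round(sect[, "NI"], 1),
      lcd_um = round(lcd, 1), age_years = truth$age_years[i],
      cct_um = truth$cct_um[i], al_mm = truth$al_mm[i],
      vf_md_db = truth$vf_md_db[i], vf_psd_db = truth$vf_psd_db[i],
      surgery = truth$surgery[i], n_meds = truth$n_meds[i],
      stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(cohort = as_lcd_cohort(data), data = data, truth = truth)
}

#' Configuration of the synthetic eye-annotation generator
#'
#' Models the anterior LC surface of one eye as a paraboloid bowl of apex
#' depth `apex_depth_um` below the BMO plane, sampled by parallel B-scans;
#' each annotated scan gets 2 BMO landmarks on the disc margin and 8
#' anterior-LC landmarks (one exactly at the scan's apex) on the parabolic
#' section, optionally tilted (the BMO line angle alpha), translated, and
#' jittered with isotropic Gaussian landmark noise.
#'
#' @param n_scans scans in the volume (default 75).
#' @param scan_spacing_um distance between neighbouring scans, um.
#' @param disc_radius_um radius of the (circular) BMO disc, um.
#' @param apex_depth_um depth of the paraboloid apex below the BMO plane, um
#'   (> 0 for a glaucoma-like posteriorly bowed lamina).
#' @param jitter_sd_um landmark placement noise SD, um.
#' @param tilt_deg_range range the per-eye BMO tilt angle is drawn from,
#'   degrees.
#' @param annotate_band fraction of the disc radius within which scans are
#'   annotated (marginal scans cut the disc too obliquely to annotate).
#' @return An object of class `eye_geometry_config`.
#' @export
eye_geometry_config <- function(n_scans = 75L, scan_spacing_um = 32,
                                disc_radius_um = 800, apex_depth_um = 465.3,
                                jitter_sd_um = 0,
                                tilt_deg_range = c(-10, 10),
                                annotate_band = 0.9) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_scans >= 1L, cfg$scan_spacing_um > 0,
            cfg$disc_radius_um > 0, cfg$apex_depth_um > 0,
            cfg$jitter_sd_um >= 0, length(cfg$tilt_deg_range) == 2L,
            cfg$annotate_band > 0, cfg$annotate_band <= 1)
  structure(cfg, class = "eye_geometry_config")
}

#' Generate synthetic B-scan annotations for one eye
#'
#' @param config an [eye_geometry_config()].
#' @param seed integer RNG seed.
#' @param eye_id identifier stored in the annotation set.
#' @return list with `annotations` (an [eye_annotations()] object),
#'   `truth` (data.frame `scan_index`, `depth_um`: the exact per-scan apex
#'   depth, equal to the noise-free [scan_lcd()]), `tilt_deg` and
#'   `true_mean_lcd(scan_indices)`, a helper returning the exact mean depth
#'   over any scan selection.
#' @export
generate_eye_annotations <- function(config = eye_geometry_config(),
                                     seed = 1L, eye_id = "synthetic-eye") {
  stopifnot(inherits(config, "eye_geometry_config"))
  set.seed(as.integer(seed))
  cfg <- config
  tilt <- stats::runif(1, cfg$tilt_deg_range[1L], cfg$tilt_deg_range[2L])
  shift <- stats::runif(2, -500, 500)
  theta <- tilt * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  # 8 LC sampling stations as fractions of the scan half-width; one exactly
  # at the apex so the noise-free maximum distance equals the apex depth
  stations <- c(-0.9, -0.65, -0.4, -0.15, 0, 0.3, 0.6, 0.9)
  centre <- (cfg$n_scans - 1) / 2
  d <- (seq_len(cfg$n_scans) - 1 - centre) * cfg$scan_spacing_um
  annotated <- which(abs(d) <= cfg$annotate_band * cfg$disc_radius_um)
  scans <- vector("list", length(annotated))
  depth <- numeric(length(annotated))
  for (j in seq_along(annotated)) {
    s <- annotated[j]
    u <- d[s] / cfg$disc_radius_um
    w <- cfg$disc_radius_um * sqrt(1 - u^2)     # chord half-width
    depth[j] <- cfg$apex_depth_um * (1 - u^2)   # paraboloid section apex
    x <- stations * w
    lc <- cbind(x, depth[j] * (1 - (x / w)^2))
    bmo <- rbind(c(-w, 0), c(w, 0))
    bmo <- sweep(bmo %*% t(rot), 2L, shift, `+`)
    lc <- sweep(lc %*% t(rot), 2L, shift, `+`)
    if (cfg$jitter_sd_um > 0) {
      bmo <- bmo + stats::rnorm(length(bmo), 0, cfg$jitter_sd_um)
      lc <- lc + stats::rnorm(length(lc), 0, cfg$jitter_sd_um)
    }
    scans[[j]] <- bscan_annotation(s - 1L, bmo, lc,
                                   axial_positive_is_posterior = TRUE)
  }
  truth <- data.frame(scan_index = annotated - 1L, depth_um = depth)
  list(annotations = eye_annotations(scans, eye_id),
       truth = truth, tilt_deg = tilt,
       true_mean_lcd = function(scan_indices = truth$scan_index) {
         stopifnot(all(scan_indices %in% truth$scan_index))
         mean(truth$depth_um[match(scan_indices, truth$scan_index)])
       })
}

#' Worked-example fixtures: two representative postoperative courses
#'
#' Two hard-coded subject series reproducing published representative cases:
#' a trabeculectomy eye of a 62-year-old (LCD 641 -> 522 um at 6 months ->
#' 388 um at the 20-month follow-up; global RNFL 61 -> 47 -> 47 um) and an
#' NPDS eye of an 81-year-old (LCD 330 -> 258 -> 232 um; RNFL 86 -> 77 ->
#' 64 um, follow-up at 21 months).  Their baseline-to-follow-up RNFL rates
#' are -8.4 and -12.57 (printed as -12.6) um/year.
#'
#' @return An `lcd_cohort` of the two series, subjects `case-A` and
#'   `case-B`.
#' @export
fixture_fig5_fig6 <- function() {
  as_lcd_cohort(data.frame(
    subject_id = rep(c("case-A", "case-B"), each = 3L),
    visit_label = rep(c("base", "6pv", "FUpv"), 2L),
    t_months = c(0, 6, 20, 0, 6, 21),
    lcd_um = c(641, 522, 388, 330, 258, 232),
    rnfl_G = c(61, 47, 47, 86, 77, 64),
    age_years = rep(c(62, 81), each = 3L),
    surgery = rep(c("trabeculectomy", "NPDS"), each = 3L),
    stringsAsFactors = FALSE))
}
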