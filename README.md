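# lcdtrack

Landmark-based lamina cribrosa depth (LCD) morphometry and longitudinal
glaucoma-progression analysis in R.

After glaucoma filtration surgery the intraocular pressure (IOP) drops
abruptly, the lamina cribrosa — the mesh at the optic nerve head through
which retinal ganglion-cell axons exit the eye — moves anteriorly, and the
circumpapillary retinal nerve fiber layer (RNFL) may keep thinning anyway.
`lcdtrack` is for researchers analysing that kind of longitudinal OCT
dataset: it turns manual B-scan landmark annotations into depth
measurements, visit tables into annualized rates of change, rates into an
aging-adjusted progression classification, and cohorts into the standard
inferential summaries (mixed-effects trends, rank tests, stepwise
regression tables).

## What it computes

* **LCD per B-scan** — the maximum perpendicular distance from the
  anterior-LC landmarks to the line joining the two Bruch's membrane
  opening (BMO) points:
  `LCD = max_k d⊥(p_k, BMO line)`, signed with posterior positive; the
  eye-level LCD is the mean over 12–16 central scans.
* **Annualized rates** — `ΔX/Δt = (X₂ − X₁) / ((t₂ − t₁)/12)` with time in
  months, for IOP (mmHg/year), LCD (μm/year) and the global plus six-sector
  RNFL (μm/year), anchored baseline→visit, consecutive, or 6-month→final
  follow-up.
* **Aging-adjusted progression** — an eye is *progressive* when its global
  RNFL rate is below `−0.54 − 1.96 × 0.23 = −0.9908` μm/year, i.e. thins
  faster than normative aging can explain.
* **Cohort inference** — random-intercept trends
  `X_ij = (β₀ + b₀ᵢ) + β₁·T_ij + ε_ij` (REML via lme4); Wilcoxon
  signed-rank and Mann-Whitney tests with *exact* small-sample p-values
  (ties included); univariate regression with CIs and a bidirectional
  p-value stepwise screen.
* **Synthetic data** — a seedable generator of study-like cohorts (IOP
  relaxation, biphasic LC displacement, transient 1-month RNFL swelling,
  correlated per-subject LCD/RNFL slopes) and of per-eye landmark
  annotation files with exactly known ground truth.

See `vignettes/lcdtrack-methods.Rmd` for the model details and design
decisions.

## Worked example

```r
library(lcdtrack)

# one annotated B-scan: 2 BMO points, 5 anterior-LC points (μm)
ann <- bscan_annotation(
  scan_index = 0,
  bmo = rbind(c(-700, 12), c(705, -9)),
  lc  = rbind(c(-520, 300), c(-260, 420), c(0, 468), c(250, 430), c(510, 310)))
bmo_reference_line(ann)
#> BMO reference line: alpha = -0.856 deg
lcd <- scan_lcd(ann)
sprintf("scan LCD: %.1f um (point %d)", lcd, attr(lcd, "which_point"))
#> "scan LCD: 466.4 um (point 3)"
```

The BMO line is tilted −0.86° to the horizontal; the deepest landmark (the
third) sits 466.4 μm posterior to it — a typical glaucomatous depth.

```r
# two bundled representative postoperative courses
fx <- fixture_fig5_fig6()
cohort_rate_table(fx, "RNFL.G", anchor = "baseline")
#> Rates of change of RNFL.G (baseline anchoring), units/year
#>   base->6pv    n= 2   -23.0 +/- 7.1  (-28.0, -18.0)
#>   base->FUpv   n= 2   -10.5 +/- 2.9  (-12.6, -8.4)
r <- cohort_rate_table(fx, "RNFL.G", anchor = "baseline")$rates
classify_progression(r$rate[r$to_visit == "FUpv"])
#> [1] progressive progressive
```

Both eyes thin far faster than the −0.9908 μm/year aging-adjusted
threshold (−8.4 and −12.6 μm/year baseline→follow-up), so both are
classified progressive.

```r
# a synthetic 29-subject cohort with known ground truth
sim <- generate_cohort(cohort_config(), seed = 1)
cohort_lme(sim$cohort, "LCD")
#> Random-intercept linear trend for LCD (29 subjects, 145 observations)
#>   intercept beta0 = 451.48 (CI 410.32; 492.63)
#>   slope     beta1 = -55.71 /year (CI -66.08; -45.33), P = 6.598e-26
#> random intercept SD = 110.50, residual SD = 42.33
split_by_progression(sim$cohort)
#> Progression split (baseline global-RNFL rate): 20 progressive,
#> 9 non-progressive, 0 unclassified
```

The fitted LCD trend (−55.7 μm/year) combines the slow drift with the fast
first-month displacement; the split lands near 20/9 under the default
generator, mirroring the structure such cohorts show.

`run_pipeline(cohort, out_dir)` writes the whole report bundle (visit-wise
summaries, rate tables, sector table, classification, trend fits,
regression table, text summary), each file stamped with the seed and a
configuration hash. A thin command-line wrapper lives in
`inst/cli/lcdtrack.R` (`measure`, `rates`, `classify`, `simulate`, `run`).

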