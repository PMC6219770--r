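---
title: "Methods: lamina cribrosa depth morphometry and longitudinal progression analysis"
author: "lcdtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lamina cribrosa depth morphometry and longitudinal progression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcdtrack)
```

## The measurement problem

In glaucoma, the lamina cribrosa (LC) — the collagenous mesh through which
retinal ganglion-cell axons leave the eye — bows posteriorly under
intraocular pressure (IOP), and the circumpapillary retinal nerve fiber
layer (RNFL) thins as axons are lost. After filtration surgery
(trabeculectomy or non-penetrating deep sclerectomy), IOP falls abruptly and
the LC moves forward again. The scientific question this package supports
is *dynamic*: is continued RNFL thinning after surgery related to where the
LC sits, or to how fast it is moving?

`lcdtrack` implements the full measurement-and-inference chain for that
question:

1. **LCD morphometry** from manual landmarks on OCT B-scans,
2. **annualized rates of change** of LCD, RNFL and IOP per subject,
3. an **aging-adjusted RNFL progression classifier**,
4. **cohort statistics** (random-intercept mixed-effects trends, exact rank
   tests, univariate and stepwise multivariate regression), and
5. a **synthetic cohort generator** with known ground truth, so every stage
   is testable without patient data.

## Lamina cribrosa depth from landmarks

Each B-scan is annotated with two Bruch's membrane opening (BMO) points and
1–8 anterior-LC points, in physical micrometres. The *BMO reference line*
joins the two BMO points; its angle to the horizontal, $\alpha$, is reported
in $(-90^\circ, 90^\circ]$. The scan-level LCD is

$$\mathrm{LCD} = \max_k \; d_\perp(p_k,\; \mathrm{BMO\ line}),$$

the largest perpendicular distance from any anterior-LC landmark $p_k$ to
the line — the "maximally depressed point". Measuring the perpendicular
distance directly is equivalent to rotating the image by $\alpha$ and
reading vertical distances, so no rotation step is performed.

Numerical choices:

* **Signed distance, posterior positive.** An LC lying entirely anterior to
  the BMO line yields a *negative* depth rather than an error; no clipping
  at zero is applied, preserving information in unusual annotations.
* **Sign anchor.** The posterior side is identified through the recorded
  axial-axis convention of the image (`axial_positive_is_posterior`). The
  measurement is therefore exactly invariant under rigid motions with
  anatomically plausible BMO tilts (it is exercised in the tests up to
  $\pm 60^\circ$ combined tilt); a rotation large enough to turn the image
  upside down would flip the sign, which is intended — the sign convention
  belongs to the image axes, not to the point cloud.
* **Ties** between equally deep landmarks break towards the lowest point
  index. **No interpolation** between landmarks is done: depth is measured
  on the marked points only.
* Eye-level LCD is the arithmetic mean over selected central scans.
  Protocols typically average 12–16 central B-scans; selections outside
  that range warn but do not fail.

`select_central_scans(n_total, k, coverage)` provides a deterministic stand-
in for the manual scan choice: `k` indices, symmetric about the central
scan, equally spaced within the central `coverage` fraction of the index
range, with band edges snapped inward to the integer grid and half-integer
positions rounded away from the centre (keeping the selection symmetric).
In practice scans were chosen by hand wherever all landmarks could be
placed without doubt, so an explicit index list always overrides the
policy. Note that `coverage` refers to the *scan volume*; when the volume
is wider than the optic disc, a smaller coverage (or an explicit list)
keeps the selection inside the annotatable band.

## Annualized rates and the aging-adjusted classifier

Rates are simple two-point slopes,
$\Delta X/\Delta t = (X_{t_2}-X_{t_1}) / ((t_2-t_1)/12)$ with time in months
and **exactly one month = 1/12 year** (no calendar-day conversion). Missing
endpoints give missing rates, never zero. Internally rates keep full
precision; rounding to one decimal happens only at the presentation layer.

Normative aging alone thins the global RNFL at about $-0.54 \pm 0.23$
μm/year. The progression rule flags an eye when its annualized global RNFL
rate falls *strictly below*

$$\mathrm{threshold} = \mu_{\mathrm{aging}} - z\,\sigma_{\mathrm{aging}}
  = -0.54 - 1.96 \times 0.23 = -0.9908\ \mu m/\mathrm{year},$$

so thinning explainable by aging is not called glaucomatous progression. A
rate exactly at the threshold is non-progressive. The grouping rate is the
baseline-to-final-follow-up global RNFL rate by default (the
6-month-to-follow-up rate is available via `anchor = "fu-vs-6m"` for
sensitivity analyses); the classifier is a pure threshold rule — no
additional per-subject trend test is applied, because none is defined for
two-point rates.

## Cohort statistics

**Mixed-effects trend.** `fit_lme()` fits the random-intercept model
$X_{ij} = (\beta_0 + b_{0i}) + \beta_1 T_{ij} + \varepsilon_{ij}$ with
$T$ in years since surgery (not visit index), by REML through `lme4`.
Confidence intervals use the fixed-effect covariance with normal quantiles
and the slope p-value is the Wald test — the default behaviour of the
commercial packages such analyses are usually run in. Degenerate inputs
(single subject, zero residual variance) fall back to ordinary least
squares with the random-intercept SD reported as 0 and a warning, never an
error.

**Rank tests.** `wilcoxon_signed_rank()` and `mann_whitney()` compute
*exact* two-sided p-values for small samples — including tied data, via
midranks — by dynamic programming over the doubled (hence integer) rank
weights; this is equivalent to enumerating all $2^n$ sign assignments or
all $\binom{n_1+n_2}{n_1}$ group splits, and the test suite checks exact
agreement with literal brute-force enumeration up to $n = 15$ and
$n_1+n_2 = 16$, with and without ties. Larger samples use the
tie-corrected normal approximation with continuity correction. The exact
path is the reason these tests are implemented in the package rather than
delegated: the standard implementation falls back to the approximation as
soon as ties appear. Zero differences are discarded (classic Wilcoxon); an
all-zero sample returns $p = 1$ with a warning.

**Regression.** `univariate_regression()` is ordinary least squares with a
t-based slope CI ($n-2$ df) and Pearson correlation.
`stepwise_multivariate()` reproduces the classical p-value-driven stepwise
workflow: candidates are screened at univariate $p \le 0.10$, exact affine
dependencies (e.g. a rate and its own monthly rescaling) are dropped, and a
bidirectional selection runs with forward entry at $p \le 0.05$ and
backward removal at $p > 0.10$ — the defaults of the commercial stepwise
implementations, since only the univariate screen is usually stated.
Candidates with fewer than four observed values are set aside before
listwise deletion so a sparse column cannot empty the complete-case set.
`Out` rows report the p-value the variable would have if added to the final
model. No multiple-testing correction is applied, matching the usual
reporting of such tables; users can correct downstream if desired.

## The synthetic cohort generator

`generate_cohort()` draws per-subject latent parameters and evaluates, at
months $t \in \{0, 1, 3, 6, \mathrm{FU}\sim U(12,29)\}$:

$$X(t) = \mathrm{plateau} + (\mathrm{baseline}-\mathrm{plateau})
         e^{-t/\tau} + \mathrm{slope}\cdot t/12 +
         \mathrm{swelling}\cdot \mathrm{bump}(t) + \epsilon$$

* **IOP**: baseline $24.0 \pm 8.9$ mmHg relaxing towards a floor of
  $9 \pm 2$ mmHg with $\tau = 0.35$ months, plus a late recovery drift of
  $+2.2$ mmHg/year (both the floor pattern and the drift are read off the
  printed visit-wise means of the study the defaults emulate).
* **LCD**: baseline $465.3 \pm 136.4$ μm, a fast anterior displacement of
  $62 \pm 35$ μm completed within the first month ($\tau = 0.4$ months,
  correlated $0.4$ with baseline depth; negative draws allowed — a minority
  of eyes deepen transiently), plus a slow drift of $-38.6 \pm 30$ μm/year
  (the mean derived from the printed 1-month-to-follow-up course; the SD is
  an assumption).
* **RNFL (global)**: baseline $59.3 \pm 15.8$ μm, a transient swelling of
  $+5.6 \pm 3$ μm — a Gaussian bump centred at 1 month, width 0.45 months,
  renormalized to be 0 at $t=0$ and 1 at $t=1$ so the baseline stays
  uncontaminated and the bump is gone by 3 months — plus per-subject
  thinning at $-2.8 \pm 4.0$ μm/year.
* **Coupling**: per-subject (LCD slope, RNFL slope) are bivariate normal
  with correlation $-0.6$; baseline IOP shares a factor with the LCD slope
  (correlation $-0.5$), so eyes with higher preoperative pressure show
  faster LC advance.
* **Sectors**: each of TS/T/TI/NS/N/NI is the global value plus a
  subject-jittered offset, thinning at the global rate times a sector
  multiplier (temporal-inferior and nasal-inferior fastest). The global
  value is generated directly, not as the weighted sector mean.
* **Noise**: i.i.d. measurement noise of 1.5 mmHg (IOP), 15 μm (LCD) and
  2 μm (RNFL) — free parameters documented as assumptions, since
  within-subject repeatability is not published for this design.

What the generator does *not* emulate: real segmentation error structure
(noise is i.i.d., real re-scan error is correlated within visit), floor
effects in advanced damage, the coupling of choroidal thickness changes to
the BMO reference level, or informative loss to follow-up (dropout is
assignable but independent of trajectory). Passing recovery tests on this
generator therefore shows the estimators are consistent under the stated
longitudinal structure, not that they are robust to every artefact of real
OCT data.

`generate_eye_annotations()` builds one eye's landmark files over a
parabolic LC bowl (apex depth configurable, default 465.3 μm) sampled by 75
parallel scans 32 μm apart across an 800-μm-radius disc, with one LC
station placed exactly at each scan's apex — so the noise-free `scan_lcd()`
equals the generating depth identically, and rigid tilts and landmark
jitter can be layered on top with the truth still known.

## The slope-recovery experiment

The acceptance experiment configures the generator's slope means to the
cohort-trend estimates of the emulated study ($-53.2$ μm/year LCD, $-3.8$
μm/year RNFL) and switches the fast-phase drop and the swelling amplitude
to zero, then fits `fit_lme()` on 20 seeded replicates of the 29-subject
design. Two deliberate design choices:

* **Transients off.** The fixed slope of a linear mixed model is a
  recoverable truth only when the generating trajectory is linear; with the
  biphasic transient on, the population-level linear slope is a compound of
  the drift and the early drop (for the default LCD settings it is steeper
  by roughly $-17$ μm/year), and "recovery of the configured slope" would
  be ill-posed.
* **Coverage against the realized cohort mean.** The 95% CI is checked
  against the *realized* mean slope of each simulated cohort (the
  conditional estimand of the fixed effect for that sample). Between-
  subject slope variability (SD 30 and 4.0 μm/year) is real in the
  generator but not represented in a random-intercept-only model, so the
  Wald CI does not — and should not be expected to — cover the *population*
  slope at nominal rate; that is a known property of the intercept-only
  model shared by the original analysis, not an implementation defect.

Problem sizes throughout the test suite (1000-annotation geometry sweeps,
enumeration oracles to $n=15$/$n_1{+}n_2=16$, 20-seed recovery runs,
200-seed jitter bias checks, one 2000-subject moment check) were chosen as
the smallest sizes at which the Monte-Carlo error is comfortably below each
assertion's tolerance.

## Known limitations

* LCD is referenced to the BMO line and therefore inherits any choroidal
  thickness change after surgery; no compensation is attempted.
* The scan-selection policy is a deterministic stand-in for a manual,
  quality-driven choice; real analyses should pass explicit indices.
* The stepwise procedure is the classical p-value dialect; it is provided
  for comparability with legacy tables, not as a recommendation over
  penalized or information-criterion selection.
* The IOP time course is poorly served by a straight line (the trend fit is
  reported anyway, as reference analyses do); nonlinear mixed models are
  out of scope.
* Supplementary-spreadsheet ingestion is mapping-driven and makes no
  assumption about sheet layout; group counts recorded at baseline versus
  after dropout can legitimately differ, and the ingester does not try to
  reconcile them.
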