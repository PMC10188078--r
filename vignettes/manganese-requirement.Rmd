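---
title: "Estimating trace-mineral requirements and source bio-efficacy from layer dose-response trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating trace-mineral requirements and source bio-efficacy from layer dose-response trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layreq)
```

## The problem

Commercial laying hens, especially aged flocks, respond to dietary manganese
(Mn) with improved egg production and eggshell quality up to some dietary
concentration, beyond which the response plateaus. Two questions drive a
supplementation trial:

1. **Requirement** — at what total dietary Mn concentration does the response
   stop improving?
2. **Relative bio-efficacy (RBE)** — how do alternative Mn sources (oxide,
   sulphate, organic amino-acid complex) compare per mg of added Mn?

`layreq` implements the full analysis chain for a trial of the classical
design: one unsupplemented control plus several sources fed at several added
levels, with the cage/pen replicate as the experimental unit. The built-in
reference design (`mn_reference_design()`) emulates a published trial in aged
Hy-Line W-36 hens: 10 treatments (control at basal 10.3 mg/kg Mn; three
sources at nominally +30, +60, +90 mg/kg), 6 replicates of 12 hens, three
28-day periods, with chemically analysed total Mn per diet.

## Traits

From replicate-level laying records the package derives, per
(treatment, replicate, period) and for an `"overall"` aggregate:

- hen-day egg production `EP = 100 × eggs / hen-days` (%),
- mean egg weight (g) and egg mass `EM = EP/100 × egg weight` (g/bird/day),
- feed intake `FI = (offered − residual) / hen-days` (g/bird/day),
- feed conversion ratio `FCR` = total feed / total egg mass — always a ratio
  of summed totals, because a mean of per-period ratios is a different (and
  biased) quantity when egg mass varies between periods.

Hen-days are realised bird-days, so mortality adjustment is built into every
denominator. The overall aggregate is hen-day-weighted by default
(`compute_traits(..., overall = "simple")` gives plain period means instead;
with equal hen-days the two coincide).

Egg-level records yield shape index (`100 × width/length`), relative
eggshell weight (g shell / 100 g egg), mean shell thickness over three
sites, albumen weight by subtraction, and the Haugh unit

$$HU = 100\,\log_{10}\!\left(h + 7.57 - 1.7\,W^{0.37}\right),$$

with albumen height $h$ in mm and egg weight $W$ in g. This is the standard
Haugh form with the exponent 0.37 on the egg weight; report tables sometimes
typeset the exponent against the whole product or drop a digit, but only the
standard form produces Haugh units on the familiar 70–95 scale for table
eggs, so that is what the package computes. The log argument must be
positive; a non-positive argument (tiny albumen height on a heavy egg)
raises a diagnostic error rather than returning `NaN`.

## Treatment ANOVA and dose contrasts

`one_way_anova()` is the classical fixed-effects decomposition with the
replicate as the unit, reporting the pooled error mean square, SEM
$=\sqrt{MSE/r}$, and a Tukey compact letter display built by the
insert-and-absorb algorithm (`tukey_cld()`); with unequal replication it
falls back to Tukey–Kramer critical differences and per-treatment SEMs, with
a warning. Letter assignment ties are broken by treatment order in the
design, so relabelling treatments permutes but never changes the grouping
structure.

`poly_dose_contrasts()` builds single-degree-of-freedom linear and quadratic
contrasts *at the actual dose values*, which in this design are unequally
spaced (10.4, 40.2, 70.75, 100.6 mg/kg analysed in the oxide arm). The
coefficients come from QR orthogonalisation of $(x, x^2)$ against the
constant vector (`stats::poly`), which reduces to the familiar tabulated
coefficients when doses are equally spaced. Each source arm shares the
control and is tested against the pooled 10-treatment error term
(`dose_response_anova()`). Whether the published analysis used analysed or
nominal concentrations for these contrasts is not stated in such reports;
both are supported (`dose_scale`), with analysed as the default since the
fitted dose-response figures are drawn on the analysed axis.

## Broken-line requirement estimation

The two plateau models are

$$Y = L + U\,(R - X)\,I \qquad \text{(LBL)}$$
$$Y = L + U\,(R - X)^2\,I \qquad \text{(QBL)}$$

with $I = 1$ below the break point $R$ and $0$ above it. $L$ is the plateau,
$U$ the signed rate constant (negative for traits maximised, positive for
FCR whose sub-plateau limb rises), and $R$ the estimated requirement.

`bl_fit()` profiles $R$: at fixed $R$ the model is linear in $(L, U)$, so
the conditional least-squares solution gives a one-dimensional SSE profile.
The profile is evaluated on a 0.1 mg/kg grid spanning the dose range (one
step in from each edge) and the minimiser is refined with Brent's method
(`stats::optimize`, golden-section plus parabolic interpolation) on the
bracketing cells — so the final SSE can never exceed the best grid
candidate. Standard errors for $(L, U, R)$ use the Gauss–Newton
approximation at the optimum; a profile SSE that is flat to within $10^{-9}$
across more than one grid step sets the `flat_profile` flag, and an estimate
within a step of the range edge sets `boundary`.

**Degenerate profiles deserve care.** When only one dose lies below the true
break — as happens for the QBL form when the break sits just below the
second dose level — *every* candidate break between the first and second
dose fits the data perfectly, and $R$ is simply not identifiable. The
package does not pretend otherwise: it flags the fit and reports the
supremum of the SSE-minimising set (located by bisection with a sharpened
$10^{-12}$ threshold), i.e. the largest requirement consistent with the
data. This is the conservative choice for a requirement estimate and it is
unique, unlike any interior point of the flat region. A flat response
(constant $Y$) returns $U = 0$ with $R$ undefined and the `degenerate` flag.

Fit quality (`fit_quality()`) uses $R^2 = (SST - SSE)/SST$,
$RMSE = \sqrt{SSE/N}$ and $AIC = N \ln(SSE/N) + 2P$ with $P = k + 1$
($k = 3$ parameters for either form, plus the error variance). Adjusted
$R^2$ is the standard residual-df form $1 - (1 - R^2)(N-1)/(N-P)$; the
algebraically collapsed variant occasionally printed in reports (both
denominators $N-1$) is just $R^2$ and is not reported separately. A perfect
fit returns $AIC = -\infty$ with a flag rather than an error, so noise-free
recovery tests rank cleanly. `select_model()` ranks candidates by AIC,
breaking near-ties ($|\Delta AIC| < 2$) by RMSE and then adjusted $R^2$,
preserving input order on exact ties.

## Slope-ratio relative bio-efficacy

With per-source supplemental dose columns $X_1, X_2, X_3$ (one-hot by
source, control all-zero; `encode_doses()`), the common-intercept model

$$Y = a + b_1 X_1 + b_2 X_2 + b_3 X_3$$

is fitted by OLS (`fit_slope_ratio()`), and `rbe()` reports
$100\,b_s/b_{\mathrm{ref}}$ with the organic source as the default
reference. RBE is invariant to rescaling the dose columns, so nominal
(0/30/60/90) versus analysed-minus-basal encodings change the slopes but
not the ratios; nominal is the default because source reports tabulate the
slopes against supplementary levels. Confidence intervals are given both by
Fieller's theorem (correct for a ratio of jointly normal estimates; bounds
are undefined when the reference slope is not distinguishable from zero)
and by the delta method, clearly labelled — source reports typically print
neither. Reported RBE is rounded to integer percent with full precision
retained.

## The synthetic trial generator

`simulate_replicates()` inverts the analysis: per-source broken-line truths
(`mn_reference_truth()` carries the reference trial's fitted EP models) are
evaluated at each treatment's analysed concentration and replicate-level
Gaussian noise is added, then internally consistent records (egg counts and
masses, feed offered/residual) are emitted so that `compute_traits()`
recovers exactly the intended EP/EM/FI/FCR. Choices worth knowing:

- **Noise is replicate-level**, sd calibrated as $SEM \times \sqrt{6}$ from
  the reference trial's treatment SEMs (EP 1.67 → 4.1; egg weight 0.57 →
  1.4; FI 1.57 → 3.8). This assumes homoscedasticity across treatments —
  what a pooled-MSE SEM implies but table formatting cannot confirm.
- **EP is clipped** to [0, 100] with a counted warning rather than resampled,
  preserving record bookkeeping.
- **Egg counts are exact expectations by default** so that noise-free
  simulation round-trips to the generative values at machine precision;
  `round_eggs = TRUE` gives integer counts with the rounding remainder
  carried across periods (the EP quantum with 336 hen-days is 0.3 percentage
  points, negligible against the 4.1 replicate sd but fatal to exact
  round-trip checks).
- The control diet's expected EP under per-source truths is the average of
  the source curves at the control dose, since a shared control has no
  source of its own.
- `simulate_eggs()` draws six sampled eggs per replicate-period around
  treatment means, enforcing width ≤ length, yolk + shell < egg and
  positivity by bounded rejection sampling (inconsistent means raise an
  error rather than spinning).
- The default seed is 20230315; every stochastic entry point takes an
  explicit seed and identical inputs give byte-identical CSV output.

What the generator does **not** emulate: within-replicate bird heterogeneity,
day-to-day laying sequences, moult, seasonal drift, or period-by-treatment
interaction. Passing recovery tests on these simulations therefore
demonstrates correctness of the estimators under the stated noise model, not
robustness to every feature of real flock data.

## Problem sizes and numerical checks

The test-suite simulations use the reference design (10 × 6 replicates,
3 periods), 10⁴ replicates for Monte-Carlo mean checks (3-sigma bands), 500
seeds for stochastic break-point recovery at replicate noise 4.1, and 100
random datasets for the grid-dominance oracle — sizes chosen so each check
is statistically sharp while the whole suite runs in well under a minute.
Break-point recovery on the reference oxide arm (break 82 mg/kg, three
sub-plateau doses) is exact to numerical tolerance on noise-free data; the
sulphate QBL arm (break 40, a single sub-plateau dose) is the canonical
non-identifiable case discussed above, where the fitter reports the flagged
supremum ≈ 40.25.

## Known limitations

- Periods are analysed separately (or pooled into the overall aggregate);
  no repeated-measures correlation structure is modelled.
- Only the two plateau forms are offered — no two-slope segmented or
  Bayesian break-point models.
- Egg specific gravity is a measured, not derived, quantity and is outside
  the trait module.
- The slope-ratio model assumes a common intercept and linearity through
  the supplemental range; it is a bioassay convention, not a mechanistic
  claim, and will be biased if the response saturates within the fitted
  range.
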