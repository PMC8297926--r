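---
title: "Modelling the neurochemistry of mathematical achievement across development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the neurochemistry of mathematical achievement across development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mrsma)
```

## The scientific question and the shape of the pipeline

Glutamate and GABA, the brain's principal excitatory and inhibitory
neurotransmitters, are measurable in vivo with magnetic resonance
spectroscopy (MRS) and have been tied to plasticity and learning. Whether
and how their concentrations in the left intraparietal sulcus (IPS) and
middle frontal gyrus (MFG) track a slowly acquired academic skill -
mathematical achievement (MA) - and whether that link changes between
childhood and adulthood, is a moderation question: the effect of a
concentration on achievement is allowed to depend on age. `mrsma`
implements the full analysis as a reusable pipeline:

1. **Quantification** - correct water-referenced absolute concentrations
   for voxel tissue composition and (optionally) T2 relaxation; apply
   quality control.
2. **Scoring** - build a composite MA score from two untimed achievement
   subtests and a timed arithmetic-fluency test; score matrix reasoning as
   a general-ability covariate.
3. **Modelling** - fit age-moderated regressions with standardized
   coefficients and heteroscedasticity-consistent (HC0) inference.
4. **Probing** - characterize significant interactions via simple slopes
   and Johnson-Neyman significance regions.
5. **Diagnostics** - Breusch-Pagan, Shapiro-Wilk, and variance inflation
   factors per model.
6. **Simulation** - a synthetic cohort generator emulating the study
   design, so every stage is testable without participant data.

## Concentration correction

The tissue correction rescales the absolute concentration by the voxel's
gray matter (GM), white matter (WM), and cerebrospinal fluid (CSF)
fractions:

$$C_{\mathrm{tissue}} = \frac{\tfrac{43300}{55556}\,f_{GM} +
\tfrac{35880}{55556}\,f_{WM} + 1\cdot f_{CSF}}{1 - f_{CSF}}\; C_{\mathrm{abs}}$$

The constants are water-visibility factors of parenchyma relative to pure
water (43300 and 35880 versus 55556 mmol/kg). The correction is linear in
the concentration and undefined for a pure-CSF voxel (`csf_fraction = 1`
raises an error).

The alternative quantification additionally scales by the transverse
relaxation decay at the acquisition echo time,
$C_{T2} = C_{\mathrm{tissue}} \cdot e^{-TE/T_2}$, with $T_2$ estimated
per region x metabolite from a 13-echo-time series (32 to 4,040 ms) by a
mono-exponential least-squares fit (log-linear initialization refined by
Levenberg-Marquardt). As printed, this factor *attenuates* the
concentration; a physical relaxation-loss correction would divide by it.
We implement the printed convention as the default and expose
`convention = "physical"` for the inverted one, rather than guessing the
intent. Because the group-level $T_2$ factor is a single rescaling per
region x metabolite, the choice does not affect standardized coefficients
downstream - only the concentration scale.

```{r}
tissue_correct(2.5, gm_fraction = 0.6, wm_fraction = 0.3, csf_fraction = 0.1)
t2_correct(1, te_ms = 32, t2_ms = 100)   # exp(-0.32)
```

## Quality control

Three exclusion rules, applied in a single non-iterative pass:

* CRLB > 50% - the spectral fit error is too large; the metabolite is
  treated as not detectable (strict inequality, matching the
  "not detectable" wording).
* SNR or concentration beyond 3 SD of its cell mean, cells being
  age-group x region x metabolite (x timepoint). Cell statistics are
  computed once on the pre-exclusion data: recomputing after each removal
  would make the result depend on processing order, while the single pass
  is reproducible and order-independent. Cells with fewer than 3 members
  skip the outlier screen (recorded in the report).

Records failing QC are dropped for that region x metabolite only; the
participant's other measures are kept (models do their own listwise
deletion). A separate gate checks that the mean spectral-fit
cross-correlation of the glutamate-glutamine and glutamate-GABA pairs
stays below .5 per region, the condition for reporting the concentrations
as separate measures.

## Achievement scoring

Per participant and timepoint:

* proportion correct on the numerical-operations subtest;
* proportion correct on the mathematical-reasoning subtest;
* a timed efficiency score: proportion correct on the first two columns of
  the arithmetic-fluency test divided by (solving time / 300 s). The
  divisor uses the full 300 s at disposal even though only the first two
  60-s columns are scored; we keep that definition verbatim from the
  instrument's published scoring rather than "fixing" it, since the score
  only enters after z-scoring.

The three components are z-scored over the participants tested at the same
occasion (cross-timepoint pooling is available behind
`pool_timepoints = TRUE`) and averaged. When a component is missing the
composite defaults to the mean of the available z components with a
completeness flag; `na_policy = "complete"` switches to listwise behaviour.
The composite is invariant to affine rescaling of any raw component and to
participant order.

## The moderation model

For one neurochemical measure $x$, age moderator $a$, and outcome MA:

$$\mathrm{MA} = \beta_0 + \beta_1 x + \beta_2 a + \beta_3\, x a + \varepsilon$$

All variables are z-scored on the analysis sample (listwise-complete cases
for that model); the interaction regressor is the product of the
standardized parents. This is the conventional standardized-moderation
form; because a product of z-scores is not itself unit-variance, a
`standardize_product = TRUE` switch exists for sensitivity (it rescales
the interaction beta but leaves its t statistic unchanged). Binary
covariates (gender) enter as mean-centred indicators.

Inference is heteroscedasticity-robust: the coefficient covariance is
White's HC0 sandwich $(X'X)^{-1} X' \mathrm{diag}(e^2) X (X'X)^{-1}$ with
no small-sample scaling, and $t = \hat\beta / \mathrm{SE}_{HC0}$ is
referred to the t distribution on the residual df (not the normal), since
results are reported as $t(df)$. Classical SEs are always reported
alongside. Model-level summaries are the adjusted $R^2$ and its change
versus the same model with the interaction terms removed
($\Delta R^2_{adj}$).

The battery (`standard_battery()`) mirrors the full analysis sequence:
eight main models (2 regions x 2 metabolites x 2 timepoints),
matrix-reasoning- and gender-adjusted variants, a four-measure
"specificity" model per timepoint (all measures and their age interactions
jointly), and prediction models in which Time-2 MA is regressed on Time-1
measures, Time-1 age, their product, and Time-2 age as a covariate.

## Johnson-Neyman probing

The conditional effect of the measure at moderator value $m$ is
$\theta(m) = b_1 + b_3 z(m)$ with variance
$v_{11} + 2 z(m) v_{13} + z(m)^2 v_{33}$ taken from the selected
covariance. Boundaries of the significance region solve
$\theta(m)^2 = t^2_{crit}\,\mathrm{var}(\theta(m))$, a quadratic with 0, 1
or 2 real roots, solved in the numerically stable form. Roots are reported
in months (years in parentheses at the reporting layer only); roots
outside the observed age range are flagged, and the significance direction
is evaluated on each side of the boundaries. When the quadratic is fully
degenerate ($b_3 = 0$ with zero variance) the result is a no-boundary
region - significant everywhere or nowhere, decided at the range midpoint -
not an exception.

The default covariance for probing is HC0, consistent with the robust
inferential framework; since the choice is not externally documented for
this technique, the pipeline's reports emit both HC0 and classical
regions. Simple slopes are anchored at the age mean and +/- 1 SD, and the
plotting export contains fitted lines with 95% confidence bands obtained
from the full coefficient covariance.

## Diagnostics

* **Breusch-Pagan**: auxiliary regression of squared residuals on the
  model's predictors. The studentized (Koenker) variant, $n R^2_{aux}$, is
  the default - robust to non-normality; the classic ESS/2 variant is also
  emitted.
* **Shapiro-Wilk** on raw residuals (which residual set was tested
  externally is undocumented; raw is the neutral choice). The check is the
  contribution here, not the algorithm, so the vetted standard routine is
  used.
* **VIF**: $1/(1-R^2_j)$ per predictor. In prediction models the Time-2
  age covariate is exempt: it is near-collinear with Time-1 age by design
  of the follow-up. The exemption removes the term from the screen
  entirely - from the maximum *and* from the auxiliary pool - because
  leaving it in the pool would let Time-1 age inherit a VIF in the
  hundreds from the deliberate collinearity, and the screen could never
  pass. The exempt term's own VIF is still reported for transparency.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated:

* **Design**: 5 age bands (labelled 6, 10, 14, 16, 18+ years) with 51
  participants each (n = 255); truncated-normal ages within band. Band
  means/SDs are package choices: 80 (4), 126 (5), 172 (5), 197 (4), and
  240 (16) months, the last representing a university sample aged 18-25.
  Attrition at Time 2 is 31%, missing completely at random; the follow-up
  gap is 20.97 (SD 3.83) months, truncated below at 6.
* **Achievement latent**:
  $A = \beta_0 + \beta_{age} z(a) + \sum_m [\beta_{met,m} z_m +
  \beta_{int,m} z_m z(a)] + \varepsilon$ with
  $sd(\varepsilon) = base\,(1 + h\,|z(a)|)$. The base residual SD is
  solved at generation time so the latent has unit variance; the
  generating coefficients are then directly the standardized betas the
  models should recover. Defaults carry the developmental sign reversal:
  $\beta_{int}$ = +0.13 (IPS glutamate), -0.14 (IPS GABA), +0.11 (MFG
  glutamate), 0 (MFG GABA), with $\beta_{age} = 0.9$ (achievement is
  overwhelmingly age-driven across a 6-25 year span, yielding model
  $R^2_{adj} \approx .84$) and small main effects (0.05).
* **Heteroscedasticity**: `hetero_slope` defaults to 0.5 (residual SD
  ~2x larger at the age extremes than the centre) - achievement is more
  variable at the extremes of the age range, and the robust-inference
  machinery exists precisely because homoscedasticity fails. Note that
  nonzero measure-by-age interactions are a *second*, structural source of
  heteroscedasticity for any single-measure model: the omitted measures'
  interaction effects sit in the residual with variance growing in
  $z(a)^2$. Calibration checks of the homoscedastic case therefore need
  both `hetero_slope = 0` and null interactions.
* **Concentrations** are generated at tissue level (unit-variance latent,
  institutional-unit scale, CV 0.12), with a mild age association
  (|r| = 0.3; glutamate declining, GABA rising with age, glutamine flat).
  The stored "absolute" concentration is the tissue-level value divided by
  the voxel's composition factor (Dirichlet-drawn fractions), so the
  tissue correction recovers the generating quantity exactly. Time-1 to
  Time-2 stability of the age-independent component defaults to 0.9:
  prediction-model interaction effects in the emulated study are nearly as
  large as the concurrent ones, which is only possible with high
  within-participant stability. This parameter is a design choice, not an
  estimate.
* **Cognitive scores** are affine maps of the latent with additive,
  constant-variance score noise, clipping bounds sitting beyond ~2.5
  latent SDs: number-correct scores for the untimed subtests, a full
  80-item attempted count for the timed test, and a nearly flat solving
  time. Affinity is deliberate: varying attempted counts or slope in both
  numerator and denominator of the efficiency ratio would inject
  level-dependent noise and curvature that register as spurious
  heteroscedasticity. The cost is an unrealistically reliable battery and
  a speed component that carries little age signal; both are acceptable
  because component-level psychometrics are not the object of study.
  Matrix reasoning loads 0.8 on the achievement latent, putting the raw
  Spearman correlation with MA near .8 and the age-partialled Pearson
  correlation near .45-.5.
* **QC fields** (CRLB ~ Gamma(2, scale 4)%, SNR ~ N(40, 8)) are drawn
  independently of everything else. Missingness is voxel-level
  (participant x region x timepoint, 6%): a failed acquisition loses all
  metabolites of the voxel together, which is both how spectra fail and
  the only structure consistent with the listwise-deletion df pattern of
  multi-measure models (independent per-metabolite missingness would
  collapse four-measure complete cases far below what single-measure
  models retain).
* **Streams**: every output table draws from its own pseudo-random stream
  derived from the master seed, so adding a table never perturbs existing
  ones, and a fixed seed reproduces every table bit-for-bit.

What the generator does *not* emulate: spectra and spectral fitting,
item-level test administration (start points, discontinuation), scanner
drift, voxel misplacement, informative drop-out, or practice effects.
Passing tests therefore demonstrate the statistical machinery under the
assumed data-generating structure, not robustness to those real-world
complications.

## Numerical choices

* The Johnson-Neyman quadratic is solved with the sign-stable form
  $q = -(b + \mathrm{sign}(b)\sqrt{disc})/2$, roots $q/a$ and $c/q$, and a
  scale-relative degeneracy threshold.
* The explained-variance share used to solve the latent's base residual SD
  is capped at 0.97 so sampling fluctuation of the systematic variance in
  a finite cohort cannot produce a zero or imaginary residual SD;
  configurations whose population explained variance reaches 0.95 are
  rejected outright.
* The T2 fit requires at least 3 distinct echo times and a negative
  log-linear slope; non-decaying or constant series raise a fit error
  rather than returning a silent default.
* QC outlier screening is single-pass by contract (see above); a cell SD
  of zero flags nothing.
* A covariate that duplicates the outcome is rejected explicitly
  (an exact-correlation check), since it would otherwise absorb all
  variance and silently zero every other coefficient.

## Problem sizes in the validation suite

The test suite validates the statistical claims by Monte Carlo at sizes
chosen to keep the full run in a few minutes while leaving assertion
margins well above Monte-Carlo noise: 200 random designs for the sandwich
and Johnson-Neyman oracles, 500 replicates for parameter recovery and
confidence coverage, 2,000 for the type-I error comparison of HC0 versus
classical inference, 800 for Breusch-Pagan calibration, and 100 for the
full battery sign-pattern study.

## Known limitations

* HC0 carries no small-sample correction; with ~160 cases, 11 parameters
  and strong heteroscedasticity its null rejection rate for interaction
  terms runs a few points above nominal. That behaviour is inherent to the
  estimator the pipeline reproduces (HC3-style corrections are out of
  scope because the emulated analysis used HC0).
* The T2 correction convention is implemented as printed (attenuating);
  see above.
* Attrition is modelled as completely random; informative drop-out would
  bias Time-2 and prediction models in ways the generator cannot reveal.
* The generator's concentration test-retest stability is a free parameter;
  conclusions about prediction-model power are conditional on it.
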