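---
title: "Dissecting global and specific transcriptional regulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting global and specific transcriptional regulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promdecon)
```

## The model

Promoter activity in a growing bacterium is set jointly by the
condition-dependent activity of the shared expression machinery and by the
promoter's dedicated transcription factors. A multiplicative description —
machinery activity raised to a promoter-specific exponent, times Hill-type
factors for each transcription factor — becomes additive after taking
logarithms and normalising:

$$\Delta\log(pa_{ij}) \;=\; \underbrace{\alpha_i\,\Delta\log(E_j)}_{G,\ \text{global}}
\;+\; \underbrace{\textstyle\sum_l \alpha_{li}\,\Delta\log(TF_{lj})}_{S,\ \text{specific}}$$

for promoter $i$ in condition $j$. The global term is a rank-1 structure: a
per-condition machinery signal scaled by a per-promoter sensitivity. The
package therefore estimates $G$ as the first singular component of the
row-wise z-scored ln-activity matrix $X$ (promoters as variables,
conditions as observations): the per-condition *global score* is
$t_j = \sigma_1 u_{1j}$, the per-promoter *loading* is $v_{1i}$, and the
specific component is the exact residual
$S = X - v_1\,t^\top$. Since every row of $X$ is centred and scaled, this
singular value decomposition coincides with a principal component analysis;
the machinery activity, its exponents, and individual transcription-factor
activities are deliberately never estimated separately — they are latent
and absorbed into scores, loadings and regression slopes.

Two identities are worth stating because the tests rely on them: the rank-1
part plus $S$ reconstructs $X$ exactly, and
$\lVert S\rVert_F^2 = \sum_{k\ge 2}\sigma_k^2$, so "variance explained by
the global component" is $\sigma_1^2/\sum_k \sigma_k^2$ without
approximation.

Because the SVD sign is arbitrary, the pair $(u_1, v_1)$ is flipped jointly
so that the scores correlate *positively* with growth rate. Every reported
quantity is invariant under this joint flip; the convention merely makes
outputs reproducible across linear-algebra backends.

The specific component is then explained by metabolites. When a metabolite
$M_k$ sets the activity of a transcription factor that regulates promoter
$i$, the lumped model is

$$S_{ij} \;\approx\; p_{ik}\,\Delta\log(M_{kj}),$$

a straight line through the origin. The no-intercept form is not an
oversight: $S$ is a residual of row-centred data, and absolutely quantified
metabolites are ln-transformed and centred by their mean across (unmasked)
conditions, so a free intercept would only absorb noise. Relatively
quantified metabolites are ln-ratios to a reference condition and are
deliberately left uncentred, mirroring how such data are reported; this
asymmetry is a known, documented quirk of the procedure rather than a bug.

## Quantification from plate-reader time courses

Raw OD600/GFP series are blank-corrected (cell-free blank wells, or a
supplied constant), smoothed with a centred 3-point moving average whose
edge windows are truncated rather than padded (no invented data at series
ends), and differentiated two-point at interval midpoints:
$\mu(t) = \Delta\ln \mathrm{OD}/\Delta t$ and
$pa(t) = \Delta \mathrm{GFP}/(\Delta t\cdot \mathrm{OD})$, with the
denominator OD taken as the mean of the two flanking measurements. The
ln-difference makes $\mu$ *exact* for exponential growth at any sampling
interval; for the activity the flanking-mean OD leaves a relative error of
order $(\mu\,\Delta t)^2/12$ — about $2\times10^{-4}$ at 6-minute sampling
and $\mu = 0.5$/h, far below biological noise. Offsets in GFP (slow-maturing
background fluorescence, instrument offsets) cancel in the difference, so
steady-state activity is invariant to adding a constant to the GFP channel.

Two steps that are described qualitatively in this kind of experiment are
automated here with explicit, tunable rules:

* **Exponential-phase window** (visual inspection replaced by a rule): the
  longest contiguous run of at least `min_points = 5` midpoints whose OD
  lies within `od_range = c(0.05, 0.5)` and whose growth rate stays within
  `growth_tol = 15%` of its running median. The selected window is recorded
  in every steady-state record for audit.
* **Detection threshold** for discarding inactive promoters: mean plus
  `threshold_sd = 3` standard deviations of the promoter-less control's
  apparent activity across conditions, compared against each promoter's
  activity *before* background subtraction. Raising the threshold can only
  shrink the active set (a tested monotonicity property).

Replicate wells are processed individually and averaged afterwards, so a
single aberrant replicate is visible in the per-well records.

## Tunable parameters

| parameter | default | where | why |
|---|---|---|---|
| smoothing window | 3 points | `preprocess()` | matches common plate-reader practice; odd, truncated edges |
| OD window | 0.05–0.5 | `steady_state()` | above blank noise, below saturation/oxygen limitation |
| growth tolerance | ±15% of running median | `steady_state()` | admits measurement jitter, rejects lag/stationary drift |
| detection threshold | mean + 3 sd of control | `filter_inactive()` | conventional false-positive control for "active in ≥ 1 condition" |
| correlation cutoff | \|r\| ≥ 0.75 | `screen_all()`, `recovery_quadrants()` | the screening operating point for calling a candidate regulator |
| cluster cutoff | 0.225 on 1 − r | `cluster_promoters()` | dendrogram cut height for response-shape groups (z-scored, *not* ln-transformed activities) |
| ΔAIC margin | 10 | `pair_scan()` | see below |
| enrichment p | < 0.1 | `map_metabolite_to_tf()` | lenient, as the test is one-sided over a small universe |
| polynomial degree | 2 (fixed) | `fit_growth_poly()` | degree-2 is the intended shape of the score–growth relation; OLS, unweighted |

Sample standard deviations (denominator $n-1$) are used for z-scoring, and
the row means/sds are stored so `invert_log_zscore()` is an exact inverse —
variance-explained figures are therefore reproducible from the stored
statistics alone.

## Why the pair-acceptance margin is ΔAIC ≥ 10, not 2

A metabolite pair is accepted over the best single metabolite when
$\Delta AIC = AIC_{\text{best single}} - AIC_{\text{best pair}}$ exceeds a
margin. The textbook rule of thumb that a model is meaningfully better at
$\Delta AIC \ge 2$ applies to *one* pre-specified comparison. Here the best
pair is selected over roughly a thousand candidate pairs
($\binom{47}{2} = 1081$), so under a single-input null the maximum chance
improvement is far larger than 2: with $N$ conditions a pair beats the
single by $\Delta AIC \ge 2$ whenever its extra regressor has partial
$r^2 \ge 1 - e^{-4/N}$ (about 0.14 at $N = 26$), and the *maximum* partial
$r^2$ over ~46 admissible second regressors exceeds that for most null
promoters. A margin of 2 would therefore flag a spurious pair for the
large majority of single-input promoters. The package default of 10 — the
conventional "essentially no support for the worse model" boundary —
absorbs this selection effect: the dedicated null simulation (200
single-input promoters, 23 conditions, the full pair scan) in the test
suite verifies the false-positive rate stays at or below 10%, while planted
pairs are still detected with margins an order of magnitude larger. The
margin is an explicit argument (`delta_aic`) for users who want the naive
rule.

Ties for the best single metabolite are broken by larger \|Spearman\|, then
lexicographic metabolite id, making the screen fully deterministic. Masked
(carbon-source/secreted) conditions are dropped per fit, pairwise; pair
fits additionally skip near-collinear metabolite pairs (condition number of
the 2×2 normal matrix above `1e10`), which otherwise produce huge unstable
slopes of opposite sign.

## Transcription-factor mapping

The enrichment universe — the finite population for the hypergeometric
test — is taken as the assayed, active promoters restricted to those
annotated in the network source. This is the most conservative finite
population: enlarging it can only make overlaps look more surprising.
Dual-effect edges count toward target overlap regardless of the inferred
sign (overlap is sign-blind; signs matter only in the recovery-quadrant
analysis). Enrichment is computed only for the transcription factor with
the largest overlap, and only for metabolites with more than two inferred
targets, because with one or two targets the test degenerates and favours
single-target regulators. The hypergeometric tail is verified in the test
suite against exhaustive enumeration of all draws for universes up to 25.

## Cross-validation

Leave-one-condition-out folds re-fit *only* the interaction slopes; the
global scores and loadings are kept from the full decomposition. This
mirrors the asymmetry of the procedure — the global component is a
property of the whole compendium, the metabolite slopes are the inferred
parameters under test. The overall goodness of fit is reported as the
squared Pearson correlation between measured and predicted ln-activities
over all (promoter, condition) cells; the linear-scale value is emitted
alongside, since the scale of such a summary is a genuine ambiguity, and
the log scale (on which the model is linear) is the primary one. Cells
whose metabolite is masked in the held-out condition are predicted from
global regulation alone and flagged.

## What the synthetic generator emulates — and what it does not

`generate_truth()` and its companions generate studies with the structure
this analysis assumes, at the dimensions of a realistic compendium:
26 conditions with growth rates evenly spaced over 0.1–1.5/h, 64 active
promoters, 47 metabolites. Specifically:

* **Global signal**: a quadratic score $g(\mu) = -1 + 1.8\mu - 0.6\mu^2$,
  monotone on the growth range, so the downstream degree-2 polynomial fit
  is well-specified by construction. The coefficients were additionally
  chosen so that $\mu\,g'(\mu) < 1/\max(\text{loading})$ everywhere, which
  makes simulated reporter *concentration* ($pa/\mu$) decline with growth
  rate for every promoter — the well-documented dilution behaviour of
  constitutively expressed proteins, and the basis of the package's
  qualitative concentration check.
* **Metabolome correlation**: metabolites come in blocks (default five
  blocks of six) sharing a latent factor,
  $m_k = \sqrt{\rho}\,z_b + \sqrt{1-\rho}\,\varepsilon_k$ with target
  within-block correlation $\rho = 0.83$ — the simplest mechanism that
  reproduces the strong cross-correlation real metabolome compendia show,
  and the reason single-metabolite attributions inside a block are only
  identifiable up to the block.
* **Couplings**: by default 10 promoters receive one metabolite input each,
  distributed over 3 regulatory metabolites (specific regulation carried by
  few hub signals), with slopes of magnitude 0.3–0.8 ln-units and random
  sign; all other coupling entries are exactly zero.
* **Noise**: i.i.d. Gaussian on ln-activity with sd 0.15, matching 10–20%
  day-to-day variability of reporter measurements and the least-squares
  machinery downstream. The recovery test suite uses sd 0.05, the regime in
  which slopes are expected back within 20%.
* **Time courses**: exponential OD from OD 0.01 and the *exact* closed-form
  GFP integral $\mathrm{GFP}(t) = (pa + bg)\,\mathrm{OD}_0(e^{\mu t}-1)/\mu$
  (linear limit at $\mu = 0$), plus blank offsets, promoter-less control
  wells and cell-free blanks. Using the closed form rather than numerical
  integration means round-trip errors are attributable to the
  differentiation scheme alone.

The generator does **not** emulate: Hill-type saturation or cooperativity
of transcription-factor binding (couplings are lumped linear slopes),
stochastic gene expression, GFP maturation delay, plasmid copy-number
effects, non-exponential growth phases, or structured (batch/day)
measurement error. Passing tests therefore demonstrate that the pipeline
recovers what it assumes — linearisable regulation with independent
Gaussian noise — not that real promoters obey that model; on real data the
correlation cutoffs and the leave-one-out stability check
(`loco_stability()`) carry the burden that the noise model carries here.

## Numerical and degenerate-input choices

* Promoters constant across conditions cannot be z-scored and are rejected
  with an error naming them, as are non-positive activities (the ln scale
  is mandatory, so upstream background subtraction must leave activities
  positive; the inactive-promoter filter removes the usual culprits).
* A numerically perfect regression fit (RSS below 1e−12) reports AIC −∞
  with a warning rather than an error, so noise-free synthetic data flow
  through the screen.
* Non-positive OD points are dropped from differentiation with a warning;
  $\mu = 0$ wells take the linear limit of the GFP integral rather than
  dividing by zero.
* Predictions from growth rate outside the training range are returned
  with an extrapolation warning rather than refused (diauxic-shift lag
  phases sit at $\mu = 0$, below any steady-state training point).
* Fits using fewer than 3 shared unmasked conditions are skipped with a
  recorded reason; leave-one-out stability requires at least 4.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run entirely on synthetic data
generated at run time: the study-shaped runs use the default
64 × 26 × 47 dimensions; the quantification round trip uses one condition
at 6-minute sampling over 9 h; the null calibration of the pair test uses
200 single-input promoters at 23 conditions; hypergeometric enumeration is
checked for universes up to 25. These sizes keep the whole suite in the
tens of seconds while exercising every stage at realistic dimensionality.

## Known limitations

* The global component is defined as exactly one singular component;
  promoters whose "global" response needs two shared factors will leak
  structure into $S$ and may pick up spurious metabolite candidates. The
  per-promoter reconstruction correlation (`promoter_fit_r()`) should be
  inspected before trusting the specific component of poorly reconstructed
  promoters.
* Correlation-based inference cannot distinguish members of a tightly
  correlated metabolite block, and does not establish causality; the
  TF-overlap step only narrows candidates where network annotation exists.
* The enrichment universe is a modelling choice; results for marginal
  metabolites can shift with it, which is why the universe is an explicit
  argument rather than a hidden default.
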