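# promdecon

Dissecting bacterial promoter activity into growth-rate-dependent **global
regulation** and transcription-factor-mediated **specific regulation**, and
inferring the regulatory metabolites behind the specific part.

## The problem

When a bacterium such as *E. coli* moves between growth conditions, the
activity of almost every promoter changes — but much of that change has
nothing to do with dedicated transcription factors. The availability of the
gene-expression machinery (RNA polymerase, ribosomes) scales with growth
rate and shifts the output of *all* promoters together. Any attempt to read
transcription-factor logic out of expression data must first remove this
confounding global component. `promdecon` implements, as a tested and
reusable R package, a pipeline for doing exactly that with steady-state
reporter data:

1. **Quantify** promoter activity and growth rate from plate-reader
   OD600/GFP time courses: after blank correction and a 3-point moving
   average, pa = dGFP/(dt·OD) and μ = d ln(OD)/dt by two-point finite
   differences, averaged over an automatically selected exponential-phase
   window, background-corrected against a promoter-less control strain.
   Promoters below the control-derived detection threshold in every
   condition are discarded.
2. **Decompose.** With `X` the row-wise z-scored ln-activity matrix
   (promoters × conditions), the model is

   Δlog(pa<sub>ij</sub>) = G + S,  G = loading<sub>i</sub> · score<sub>j</sub>

   where the per-condition global score is σ₁u₁ from the singular value
   decomposition of `X` (conditions as observations) and the specific
   component `S = X − loading ⊗ score` is the exact rank-1 residual. The
   score is strongly growth-rate dependent and is modelled by a quadratic
   in μ, which also predicts activities in new conditions from their growth
   rate alone.
3. **Infer regulatory metabolites.** Each promoter's specific component is
   regressed without intercept on each ln-normalized metabolite,
   s = p·m, candidates are kept at |r| ≥ 0.75, and two-metabolite models
   s = p₁m₁ + p₂m₂ are accepted only when decisively preferred by
   AIC = N·ln(RSS/N) + 2K. Conditions where a metabolite is a carbon source
   or secreted are masked.
4. **Map to transcription factors.** Metabolites with more than two inferred
   targets are matched to the known TF whose regulon overlaps those targets
   most, with one-sided hypergeometric enrichment over the assayed promoter
   universe.
5. **Validate** by leave-one-condition-out cross-validation of the combined
   global + metabolite model, re-fitting only the interaction slopes per
   fold.

A first-class synthetic-data module (`generate_truth()`,
`simulate_metabolome()`, `simulate_activity_matrix()`,
`simulate_plate_timecourses()`) generates studies with the same statistical
structure — 26 conditions spanning 0.1–1.5/h, 64 promoters, 47 metabolites
in strongly cross-correlated blocks, sparse planted couplings — so every
stage of the pipeline is verifiable offline against known ground truth.

## Worked example

```r
library(promdecon)

truth      <- generate_truth(sim_config(noise_sd_ln = 0.05), seed = 73)
metabolome <- simulate_metabolome(truth)
activity   <- simulate_activity_matrix(truth, metabolome)
activity
#> Activity table: 64 promoters x 26 conditions, growth 0.10-1.50/h

fit <- decompose(log_zscore(activity))
summary(fit)
#> Variance captured by leading components:
#>  component singular_value variance_fraction cumulative
#>          1          37.51           0.87936      0.879
#>          2          10.22           0.06530      0.945
#>          3           7.58           0.03587      0.981
#>          4           3.06           0.00586      0.986
#>          5           1.60           0.00160      0.988
#> cor(global score, growth rate) = 0.964
#> median per-promoter reconstruction r (rank-1) = 0.992

screen <- screen_all(residuals(fit), metabolome)
screen
#> Metabolite screen: 3008 fits, cutoff |r| >= 0.75
#>   10 of 64 promoters have a passing best single metabolite

head(subset(screen$best, passed_cutoff), 3)
#>    promoter_id metabolite_id      slope n_used  pearson_r       sign
#> 2         P002           M09  1.0206026     26  0.9968002 activation
#> 15        P015           M11 -0.9392103     26 -0.9875055 inhibition
#> 17        P017           M41 -0.6433020     26 -0.9549682 inhibition
```

The first singular component captures ~88% of the variance (the shared,
growth-linked signal); the ten promoters given a planted metabolite input
by the generator — and only those — come back with a passing single
metabolite, with the correct metabolite, sign, and slope. `plot(fit)` draws
the global score against growth rate with its quadratic fit and 95%
confidence band; `predict(fit, mu = 0.8)` returns linear-scale activities
expected at a given growth rate. `run_pipeline()` chains all stages
(optionally starting from plate CSVs) and emits CSV/JSON outputs.

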