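# symdynhrv

Symbolic-dynamics analysis of heart-rate variability (HRV) for
within-subject crossover trials, with Bayesian and repeated-measures
inference. The package targets studies of cardiac autonomic modulation —
for example, caffeine supplementation trials in cyclists — where
beat-to-beat RR intervals are recorded supine and during a 16 km cycling
time trial under three conditions (placebo–placebo PP, placebo–caffeine
PC, caffeine–caffeine CC), and the question is whether the intervention
shifts the sympathovagal balance.

## What it computes

**Symbolic dynamics.** An RR segment is quantized into ξ = 6 equal-width
levels over its range; every overlapping 3-beat word is classified by its
number of adjacent changes into the pattern families

- **V0** (no variation, all three symbols equal) — sympathetic
  predominance marker,
- **V1** (one variation) — mixed modulation,
- **V2** (two variations, like or unlike) — parasympathetic (vagal)
  modulation marker,

and the family percentages are reported (of the 6³ = 216 possible words,
6 are V0, 60 are V1, 150 are V2).

**Preprocessing.** Local-median artifact filtering; smoothness-priors
detrending `trend = (I + λ² D₂ᵀD₂)⁻¹ z` with λ = 500 (sparse solve);
selection of the opening 5-min supine window; and a deterministic
stationarity score that replaces visual inspection when picking the
1000-beat segment analysed in each third of a time trial.

**Inference.** Pairwise JZS default Bayes factors (Cauchy prior on the
effect size, r = 1/√2, adaptive quadrature over the bounded-transformed
g-integral) with Westfall multiplicity-corrected prior odds
`(1 − 0.5^(2/k)) / 0.5^(2/k)` (= 0.587 for k = 3 conditions), posterior
odds = prior odds × BF₁₀, posterior probability = 100·BF₁₀/(BF₁₀+1), and
Lee–Wagenmakers evidence bands. Frequentist side: one/two-way
within-subject ANOVA with Mauchly sphericity test, Greenhouse–Geisser
correction, partial η², Tukey HSD on the within-subject error term, a
Shapiro–Wilk normality gate with a Kruskal–Wallis fallback, condition
deltas versus placebo, and a G*Power-convention noncentral-F a priori
sample-size routine.

**Synthetic cohorts.** A seeded two-oscillator (0.1 Hz / 0.25 Hz) plus
drift plus noise beat-domain generator produces RR recordings and full
cohorts with configurable condition effects, so the whole pipeline is
testable without any physiological recordings.

## Worked example

```r
library(symdynhrv)

spec <- cohort_spec(n_subjects = 6, seed = 17,
                    contexts = c("tt_beginning", "tt_midway", "tt_final"))
res <- run_pipeline(spec)

fin <- subset(res$symbolic, context == "tt_final")
round(tapply(fin$v2_pct, fin$condition, mean), 1)
#>   CC   PC   PP
#> 41.4 41.7 27.1

res$bayes$tt_v2_pct[, c("contrast", "prior_odds", "posterior_odds",
                        "bf10", "probability_pct", "code")]
#>   contrast prior_odds posterior_odds      bf10 probability_pct code
#> 1    CC-PC  0.5874011      0.2199286 0.3744097        27.24149    a
#> 2    CC-PP  0.5874011      5.3169949 9.0517286        90.05146    M
#> 3    PC-PP  0.5874011      3.5786615 6.0923648        85.90033    M
```

The V2 (vagal) occupancy at the end of the time trial is higher under
both caffeine conditions than under placebo; even at this small
illustration size (6 subjects) the Bayes factors for the
caffeine-vs-placebo contrasts are moderate (BF₁₀ ≈ 6–9, posterior
probability ≥ 86%) while the two caffeine conditions are
indistinguishable (BF₁₀ < 1). Power analysis:

```r
rm_sample_size(f = 0.36, m = 3)  # 14 subjects
rm_sample_size(f = 0.41, m = 3)  # 12 subjects
```

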