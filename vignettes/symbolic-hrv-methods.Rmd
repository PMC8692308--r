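---
title: "Symbolic HRV dynamics in a crossover design: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic HRV dynamics in a crossover design: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symdynhrv)
```

## The problem

Beat-to-beat RR intervals carry a readout of autonomic control of the
heart: respiratory-band oscillations (~0.25 Hz) are vagally mediated,
slower Mayer-wave oscillations (~0.1 Hz) carry a sympathetic component,
and slow drifts reflect non-autonomic trends. Symbolic dynamics
compresses this into three interpretable numbers per segment: quantize
the intervals into ξ discrete levels, slide a 3-beat window, and count
words with zero (V0), one (V1) or two (V2) adjacent changes. A shift
toward V2 indicates stronger vagal modulation; a shift toward V0,
sympathetic predominance. `symdynhrv` implements this analysis end to
end for a three-condition crossover (PP/PC/CC caffeine supplementation
with a 16 km cycling time trial), together with the inferential layer
used to compare conditions.

## Symbolic analysis

`rr_quantize()` spreads ξ = 6 equal-width bins over the segment's own
`[min, max]` range (half-open bins, last bin closed at the maximum), so
the profile is invariant to adding a constant and to positive rescaling.
Words of length 3 at stride 1 are classified by `classify_word()`;
`symbolic_profile()` reports percentages that sum to 100 by
construction. Choices worth making explicit:

- **ξ = 6, stride 1** follow the established full-range uniform
  quantization variant of the method; both are exposed as configuration.
- **Bins are per-segment**, not per-recording: each analysed segment is
  scaled to its own dynamic range. A per-recording variant would couple
  segments; the per-segment form is the standard one and is what the
  enumeration-oracle tests pin down.
- **Degenerate segments** (range below 1 nominal ms of float tolerance)
  map to V0 = 100% rather than erroring: the limit of vanishing
  variability is the total absence of variation patterns.
- The two-variation "like"/"unlike" subfamilies are computed internally
  (`split_v2 = TRUE`) but reported merged as V2.

## Preprocessing

**Artifact filter.** Beat i is flagged when it deviates from the median
of the centred 5-beat window by more than 20% of that median (a standard
local-median rule; the threshold is a parameter) and replaced by the
local median. Above 5% replacements the segment is suspicious (warning);
above 20% it is rejected.

**Detrending.** The smoothness-priors trend is the minimiser of
`||z − x||² + λ²||D₂x||²` with `D₂` the second-difference operator,
i.e. `x = (I + λ²D₂ᵀD₂)⁻¹z`, computed by a sparse Cholesky solve
(`Matrix`), which handles 10⁵ beats in well under a second. λ = 500 is
the conventional setting for short-term HRV and the package default;
λ = 0 is the identity limit and any linear series detrends to zero
(second-difference null space) — both are asserted as tests. Detrending
precedes symbolization by default and can be disabled
(`detrend = FALSE` in `run_pipeline()`); symbolic families are driven by
beat-to-beat structure, so the effect of removing slow trends is mild
but makes segments comparable.

**Segment selection.** Supine recordings contribute the beats whose
onsets lie in `[0, 300)` s. For the time trial, the recording is split
into thirds *by beat count* (whether the original protocol's "thirds"
were beat-, time- or distance-defined is not decidable; beat count is
the documented choice here), and within the requested third every
1000-beat window at stride 50 is scored by a quartile-homogeneity
statistic: the window is cut into four quarters and the score is the
maximum standardised deviation of quarter means from the window mean
plus the maximum relative deviation of quarter SDs from the window SD.
The minimal-score window wins, ties to the earliest start. This is a
deterministic surrogate for the visual stationarity inspection
traditionally used — reproducibility requires an algorithmic rule — and
the stride/window are tunables. An exhaustive scorer in the test suite
confirms the selector attains the grid optimum and avoids injected
level steps whenever a step-free window exists.

## Bayesian pairwise comparisons

Pairwise condition contrasts in a crossover are paired, so the JZS
default Bayes factor is computed in its one-sample form on the
subject-matched differences: a Cauchy(0, r = 1/√2) prior on the
standardised effect, expressed as a normal mixture over the prior
variance g with an inverse-gamma(1/2, r²/2) mixing density. The
g-integral is evaluated by adaptive quadrature after the transform
u = g/(1+g) (bounded domain), in log space with the peak subtracted, to
~1e−8 relative accuracy; an independent Monte-Carlo integration oracle
in the tests bounds the error at 3 MC standard errors across a (t, n)
grid. An independent-samples form (`jzs_bf10_indep()`) is provided for
completeness.

Multiplicity is handled on the prior odds: the prior probability that
*all* nulls hold is fixed at 0.5, giving per-comparison null probability
`p0 = 0.5^(2/k)` and prior odds `(1−p0)/p0` — 0.5874 for k = 3, which is
also directly settable so any other convention can be injected (the
cross-k behaviour of this formula is a convention; only k = 3 is pinned
by the published tables the package reproduces). Posterior odds are
prior odds × BF₁₀; the "posterior probability" column is
100·BF₁₀/(BF₁₀+1), i.e. the posterior probability of H1 at even prior
odds. Full precision is kept internally; publication rounding (BF 2–3
dp, odds 2 dp, probability 1 dp) happens only in `emit_bayes_table()`.
BF₁₀ = 1 is labelled anecdotal-for-H1 by convention so the
Lee–Wagenmakers bands partition the positive axis.

## Frequentist layer

The crossover is fully within-subject, so the "mixed ANOVA" of the
original workflow is implemented as a one/two-way repeated-measures
decomposition (`rm_anova()`): every effect is tested against its own
subject-interaction mean square, partial η² is
SS_effect/(SS_effect+SS_error), Mauchly's W is computed from the
orthonormal-contrast covariance with Box's chi-square approximation
(including the second-order term), and the Greenhouse–Geisser
ε = tr(S̃)²/((m−1)tr(S̃²)) corrects the degrees of freedom when Mauchly
rejects at 0.05 (`gg = "always"` applies it unconditionally). Tukey HSD
contrasts on the first factor use the within-subject error term and run
by default only when the omnibus test is significant, mirroring the
conventional workflow. A Shapiro–Wilk gate routes non-normal variables
to Kruskal–Wallis (`kruskal_fallback()`), and routing is data-driven
because the original variable-by-variable routing is not itemised. The
implementation is cross-checked in the tests against a brute-force
mean-subtraction oracle and against `car::Anova`; the only tolerated
difference is R's idiosyncratic use of the raw cell dimension in
Mauchly's second-order term (third decimal of the p-value).

**Sample size.** `rm_sample_size()` reproduces the G*Power
"ANOVA: repeated measures, within factors" convention for one group:
noncentrality λ = f²·N·m·ε/(1−ρ), df₁ = (m−1)ε, df₂ = (N−1)(m−1)ε, with
ρ = 0.5 and ε = 1 as defaults (the calculator's defaults; they reproduce
both published design sizes, n = 14 at f = 0.36 and n = 12 at f = 0.41,
α = 0.05, power 0.80, m = 3). N is found by an increasing scan, valid
because power is nondecreasing in N.

## The synthetic cohort generator

No raw recordings are distributable, so `generate_rr_series()` implements
a transparent beat-domain model: interval_i = mean_rr + LF·sin(2πf_LF t)
+ HF·sin(2πf_HF t) + drift·i + ε, with t the running beat time (the time
axis is built from the generated intervals themselves). A two-oscillator
model was chosen over integral-pulse-frequency-modulation for
transparency: it controls exactly the fast (V2-driving) and slow
(V0-driving) variability that symbolic analysis measures, and the
symbolic consumer operates on beats, not continuous time. Hard guards
keep every interval in the physiological band (200, 2500) ms.

Cohort defaults are fixed once, from the published summary statistics
where available:

- supine contexts: mean RR 900 ms, LF 30 ms, HF 40 ms, noise 15 ms;
- time trial: mean RR 450/400/370–380 ms across thirds with HF rising
  toward the final; at TT-final the caffeine conditions get HF 16 ms
  versus placebo's 6 ms with smaller LF/drift — a very large vagal
  effect, consistent with the published effect size for that contrast
  (partial η² ≈ 0.9);
- TT time: placebo mean 1560 s (16 km at a realistic ~37 km/h; only
  deltas are published), caffeine deltas −43.4 s (PC) and −39.3 s (CC);
  within-subject residual SD 35 s, *derived* from the published
  treatment F (≈6.5) and η²p (≈1/3) at n = 14; between-subject SD 70 s;
- power output: means around 199.67 W with overall deltas +6.17 W (PC)
  and +5.55 W (CC) concentrated at the trial beginning.

Per-recording RNG streams are derived from
(master seed, subject, condition, context) by a fixed linear splitting
rule, so enlarging a cohort never perturbs already-generated series.
The generator emulates stationary-in-mean oscillatory HRV with white
jitter; it does **not** model respiration coupling, 1/f structure,
ectopy, or caffeine pharmacokinetics, so passing tests demonstrate the
pipeline's correctness and sensitivity under the assumed signal model,
not performance on real recordings.

## Problem sizes and numerical choices

The shipped tests run the analysis at deliberate desk scale: 1300-beat
time-trial thirds (so every third holds a 1000-beat window), 400-beat
supine recordings, 20 replicate cohorts of 14 subjects for the
parameter-recovery property, 500 null simulations for the type-I
calibration of the gate-plus-ANOVA route (expected rejection in
[3.5%, 6.5%] at nominal 5%), and 5×10⁵-draw Monte-Carlo validation of
the Bayes-factor quadrature. Quadrature tolerance is 1e−8 relative;
detrending uses exact sparse algebra; stationarity ties break to the
earliest window; all percentages are exact ratios scaled by 100.

## Known limitations

- The Westfall prior-odds formula is pinned only at k = 3 by published
  values; other k follow the stated convention.
- Thirds by beat count and the quartile stationarity score are
  principled replacements for unstated or manual steps, not validated
  reconstructions of them.
- The Wmax extrapolation `output + (t/113)·45` is kept as published even
  though 113 coincides with the protocol's starting load and the
  conventional form divides by the 120 s stage duration; `divisor = 120`
  selects the conventional form.
- `rm_anova()` requires balanced complete data; subjects with missing
  cells must be handled upstream.
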