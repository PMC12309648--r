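---
title: "Methods: meta-analysis of paired MPA monitoring surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of paired MPA monitoring surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mpameta)
```

# The estimation problem

A network of marine protected areas (MPAs) is monitored with a paired
design: replicate sampling units (seine hauls in the surf zone, transects
in kelp forest and deep reef, hook-and-line fishing cells on the shallow
reef) are surveyed inside each MPA and at a neighbouring fished reference
site, in several ecosystems and years. The quantity of interest is the
effect of regulatory protection on fish biomass, species richness and
Shannon diversity, summarised per ecosystem–MPA pair and then pooled
across the network.

`mpameta` treats each ecosystem–MPA combination as one "study" in a
random-effects meta-analysis. That framing has three assumptions worth
stating plainly:

* the replicate units on each side are exchangeable samples of the local
  fish community, so their mean and standard deviation describe the
  sampling distribution of the side-level mean;
* different ecosystem–MPA combinations are independent given their true
  effects (spatial dependence between neighbouring MPAs is ignored);
* heterogeneity between combinations is captured by a single additive
  between-study variance τ².

Nontargeted (unfished) species act as a quasi-control: they experience
only indirect effects of protection, so a stronger positive response of
targeted species relative to nontargeted species is the fingerprint of a
protection effect rather than of an environmental gradient.

# Effect sizes

## Log response ratio

For MPA *j* in year *i*, `log_response_ratio()` computes
\[
Y_{j,i} = \ln\left(\frac{\bar{X}^{inside}_{j,i}}{\bar{X}^{outside}_{j,i}}\right),
\]
with natural logarithms throughout (so an effect of 0.5 corresponds to a
65 % higher metric inside). Y is antisymmetric under swapping the sides
and invariant to rescaling both means, and its sign indicates the side
with the higher metric.

## Zero adjustment

A zero mean on either side leaves Y undefined. `zero_adjust()` therefore
adds a *fractional* constant — 10 % of the mean of all values in the same
stratum — to **both** members of any pair containing a zero. Strata are
keyed by ecosystem, year, protection level and side (and by the
status or metric column when present: targeted and nontargeted biomass,
or richness and diversity, are not commensurable values, so their
constants are computed separately). The choices embedded here:

* a fractional rather than fixed constant tracks interannual variability
  in the scale of the data, so the adjustment cannot systematically
  favour either side;
* adding to only the zero side would bias Y; both members receive their
  respective side's stratum constant;
* by default only pairs containing a zero are adjusted
  (`mode = "zero_pairs"`); `mode = "all_pairs"` applies the constant
  stratum-wide for sensitivity analysis;
* a stratum whose values are all zero yields a constant of 0; its pairs
  stay undefined and are routed to the exclusion report with reason
  `all_zero_stratum` rather than silently dropped. In practice this is
  how nontargeted species drop out of the shallow reef, where
  hook-and-line gear never records them.

## Within-study variance

`within_study_variance()` offers two forms. The default (`as_printed`)
is
\[
v = \frac{\sigma^2_{in}}{n_{in}\,\bar{X}_{in}} +
    \frac{\sigma^2_{out}}{n_{out}\,\bar{X}_{out}},
\]
with the means entering to the first power. This form is **not**
invariant to the measurement units: rescaling the data by λ scales v by
λ, so with biomass in grams the variances (and hence pooled standard
errors) are large and significance statements are conservative. The
`delta` method replaces the means by their squares — the standard
delta-method variance of a log ratio, invariant to unit changes — and is
what the package's statistical-calibration tests use. Both methods
record themselves in the output; the default is kept as `as_printed`
for fidelity to the framework the package implements.

Variances require at least two replicates per side; pairs that fail this
are excluded with reason `insufficient_replication`. A pair with zero
standard deviations on both sides yields v = 0 and receives a floor of
one tenth of the smallest positive variance in its pooling group before
weighting (an infinite weight would otherwise silence every other
study).

## Most recent year

When an MPA is surveyed repeatedly in an ecosystem, only the most recent
year enters pooling (`most_recent_filter()`), reflecting the longest
duration of protection; ties are broken deterministically by row order,
and different ecosystems of one MPA may retain different years. Annual
effect sizes are still computed and kept — the feature model uses them.

# Random-effects pooling

Written down naively, the weighting equations are circular (weights
depend on τ², τ² on Q, Q on weights). `pooled_effect()` resolves the
circularity with the standard method-of-moments ordering:

1. fixed-effect weights 1/vᵢ give the fixed-effect mean and
   Q = Σ wᵢ(Yᵢ − R̄)²;
2. τ̂² = max(0, (Q − (k−1))/c), truncated at zero and flagged when
   truncated;
3. random-effects weights wᵢ = 1/(vᵢ + τ̂²);
4. R̄ = Σ wᵢYᵢ / Σ wᵢ, se = (Σ wᵢ)^{−1/2}, a 95 % normal CI and a
   two-sided normal p-value (`reference = "t"` switches to a t reference
   with k−1 df for small-k sensitivity).

Two choices deserve emphasis:

* **The constant c.** The default `tau2_method = "as_printed"` uses
  c = k−1. That constant has the units of the Q statistic, not of the
  effect sizes: it coincides with the DerSimonian–Laird constant
  c = Σwᵢ − Σwᵢ²/Σwᵢ exactly when all vᵢ = 1, and inflates τ̂² by
  roughly 1/v otherwise. With v ≪ 1 the resulting intervals are far too
  wide for the test to hold its nominal level — no choice of simulation
  design fixes this, it is a property of the estimator. The package
  therefore also provides `tau2_method = "dl"`, and all calibration
  claims (type-I error, CI coverage) are made, and verified, under
  `dl` with delta variances. Under that combination, 1000 simulated
  meta-analyses of k = 10 studies with n = 20 lognormal replicates per
  side give a type-I error of ≈ 4–5 % and 95 % CI coverage of ≈ 0.95.
* **k.** In grouped pooling k is the number of pooled effect sizes in
  the group, whatever mixture of ecosystems and MPAs the group contains.

`pool_at_scale()` applies this machinery at four scales — per MPA across
its ecosystems, per ecosystem across MPAs, per region, and for the whole
network — always stratified by target status and protection level. A
single-study group returns its own effect with se = √v and a
`single_study` flag.

# Biodiversity

Richness and Shannon diversity (natural log, via `vegan::diversity()`)
are computed at the MPA level: abundances are summed across replicates
of a (MPA, ecosystem, year, side) before the metrics are taken, because
sampling is depth-stratified and replicate-level community metrics would
be dominated by depth. Their log response ratios reuse the
zero-adjustment machinery with strata keyed by metric. Significance is a
two-tailed one-sample t-test of the responses against zero per ecosystem
and metric. By default one response per MPA (its most recent year)
enters the test, avoiding pseudo-replication; `most_recent_only = FALSE`
pools all MPA-years. Groups with fewer than two responses or zero
variance are flagged, not tested. Richness is the raw observed species
count — no rarefaction — so unequal survey effort between sides will
bias it; the simulation keeps effort balanced, real data may not.

# The feature model

`build_model_frame()` restricts to no-take MPAs and targeted species —
holding the most restrictive protection constant so the
feature–performance relationship is not confounded by regulations — and
keeps *annual* effect sizes, since year enters the model. Observation
weights are wᵢ = 1/(vᵢ + τ̂²) with τ̂² from the network-level pool of the
same stratum.

`fit_weighted_gam()` fits a Gaussian additive model (via `mgcv::gam`)
with cubic regression spline smooths for the eight features, a cyclic
cubic spline for year (periodic trends), and smoothing parameters chosen
by GCV. Numerical guards: basis dimension 5 per feature smooth by
default (replication per predictor is modest); a feature with fewer than
4 distinct values enters linearly; the year smooth is dropped below 3
distinct years; a frame with fewer rows than total basis dimension
signals an ill-posed-model error instead of letting the solver fail
obscurely.

`forward_select_gcv()` starts from the intercept + cyclic-year base
model and greedily adds the candidate smooth whose addition most reduces
GCV, stopping when the best relative reduction falls below `tol`
(default 0.02). The tolerance was calibrated on simulated frames of
~300 rows before the validation suite was frozen: under a pure-noise
response the best of eight candidate terms improves GCV by ~1 % purely
by chance quite often (tolerances of 10⁻⁴–10⁻³ admit a spurious term in
more than 80 % of null replicates), while true drivers of the strength
used in the recovery studies improve GCV by tens of percent, so power is
insensitive to the tolerance over two orders of magnitude. At
`tol = 0.02` the selection includes both true drivers in ≈ 95–100 % of
signal replicates and selects nothing in ≈ 80–95 % of null replicates.

# The synthetic-data generator

`simulate_mpa_dataset()` emulates the monitoring design so that every
downstream stage has a parameter-recovery surface with known truth:

* 4 ecosystems × 4 regions; each MPA is monitored in a subsample of
  ecosystems (`ecosystem_coverage`, default 0.75);
* a species pool with log-uniform allometric parameters
  (a ∈ [0.005, 0.05], b ∈ [2.5, 3.5]), catch volumes consistent with the
  true target status, and gear catchabilities — zero for nontargeted
  species on the shallow reef, where hook-and-line gear is used;
* the true log protection effect for targeted species in MPA *j*, year
  *t*: m_j (β₀ + β_age a_{jt} + β_hd H_j + b_j), with b_j ∼ N(0, σ_b²),
  m_j = 1 for no-take and 0.4 for partial-take MPAs, and 0 before
  implementation. Nontargeted species respond with an attenuated
  multiple (0.25) of the targeted effect — the quasi-control assumption.
  Defaults: β₀ = 0.5, β_age = 0.02 yr⁻¹, β_hd = 0.15, σ_b = 0.2;
* per-replicate, per-species counts are negative-binomial
  (dispersion size 4 — survey counts are overdispersed) with the inside
  mean equal to the outside mean times exp(effect); individual body
  lengths are lognormal around the species median (CV 0.25), identical
  inside and outside by default (`inside_length_shift` emulates size
  effects if wanted);
* outside replicates are recorded all-zero with probability 0.05,
  emulating occasional empty reference hauls;
* 4–8 replicate units per MPA × ecosystem × year × side — plausible
  defaults for such monitoring programmes, not asserted values — with a
  floor of 2 so variances exist;
* one global seed; species, network and survey draws use documented
  offsets (seed, seed+1, seed+2) of it, and identical configurations
  reproduce byte-identical tables.

What the generator does **not** emulate: temporal autocorrelation,
marine heatwaves or other regime shifts, spatial dependence between
MPAs, observer or gear drift, and species' length responses to
protection (unless the shift knob is used). Passing recovery tests on
these data therefore demonstrates correctness of the estimators under
the stated sampling model, not robustness to every feature of real
monitoring data.

One subtlety matters for recovery studies: outside zero-inflation
multiplies the realized outside mean by (1 − z), shifting the realized
log-ratio by −ln(1 − z) ≈ +0.05 at the default z = 0.05. The recorded
per-MPA truth refers to the negative-binomial mean, so recovery runs
that compare pooled estimates against the recorded truth set
`zero_inflation_outside = 0` (and use delta variances, whose weights are
unit-free). The validation suite's recovery study uses 50 MPAs with a
constant true no-take effect of 0.5; the network-scale pooled estimate
falls within three standard errors of the truth, and the nontargeted
stratum recovers the attenuated truth 0.125.

# Problem sizes in the test suite

The shipped validation suite runs on one CPU in a few minutes: the
pooling equivalence check enumerates all ≈ 15,500 ≤ 5-study instances on
a grid of effect sizes and variances against an independently written
transcription of the formulas (agreement to 10⁻¹⁰); calibration uses
1000 simulated meta-analyses; the diversity null uses 600 replicates of
a 25-MPA, 4-ecosystem, 15-species community; selection operating
characteristics use 100 signal and 100 null frames of ~312 rows.

# Known limitations

* The as-printed variance's unit dependence (above) makes pooled
  standard errors under the default configuration depend on the biomass
  unit; conclusions about *significance* should be drawn under
  `variance_method = "delta"`, or after deliberately choosing the unit.
* No hierarchical modelling: an MPA contributing effects to several
  ecosystems is treated as independent studies.
* No publication-bias or influence diagnostics; the pipeline assumes a
  complete monitoring design rather than a literature sample.
* GCV-based selection is greedy and can be order-dependent when
  candidates are collinear (e.g. habitat richness and habitat
  diversity); the selection trace records every evaluated step so such
  paths are auditable.
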