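---
title: "Methods: seasonal stability periods and picophytoplankton amplicon analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal stability periods and picophytoplankton amplicon analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picocycle)
```

## The problem

Subtropical ocean time series such as the one this package targets show a
strongly seasonal water column: an annual deep convective mixing event
entrains nutrients into the euphotic zone, followed by spring shoaling of
the mixed layer, a stratified summer with a deep chlorophyll maximum (DCM),
and an autumn deepening that entrains the DCM back into the mixed layer.
Picoeukaryotic phytoplankton — prasinophytes in particular — track these
phases both in time and in depth. `picocycle` implements the quantitative
machinery to analyse this coupling from two routine data streams: CTD casts
(density, fluorescence, PAR) and marker-gene amplicon tables (plastid 16S
V1–V2 alongside 18S V4), with every stage exercisable on a bundled
synthetic-data generator that plants known ground truth.

## Hydrographic features

**Mixed-layer depth (MLD).** The depth where sigma-t first reaches the
surface value plus Δσ = 0.125 kg m⁻³. The crossing is located by linear
interpolation in sigma-t between the bracketing samples; the shallowest
sample is the "surface". A cast that never crosses (fully mixed to the
bottom of the cast) returns the deepest sampled depth with a
`bottom_limited` flag rather than an undefined value, so deep-mixing
detection still works on 300-m casts.

**Light depths.** The euphotic-zone depth is where PAR falls to 0.1% of its
value at the shallowest sample, and the comparison level for the DCM during
deep mixing is the 1% level. Interpolation is linear in log(PAR) against
depth, which is exact under exponential attenuation; zero PAR readings are
excluded from the fit. With attenuation k = 0.046 m⁻¹ the 1% and 0.1%
levels sit near 100 m and 150 m.

**DCM region.** The depth of maximum in-vivo fluorescence (shallowest on
ties) plus the contiguous interval around it where fluorescence stays at or
above 65% of the maximum, with linearly interpolated boundaries. The
"within 35% of the maximum" rule admits two readings — a fractional drop
from the maximum, or an absolute depth span — and the fractional reading is
used because the absolute one is unit-dependent. The region counts as a
true DCM only when the mixed layer is shallower than its upper bound.

**Stability periods.** A four-state machine labels each cast:

* **DM** (deep mixing): MLD deeper than the euphotic depth. This trigger
  has precedence from *any* state, so a mid-winter restratification
  followed by renewed convection re-enters DM.
* **ST** (spring transition): from DM, once the DM trigger fails and the
  MLD has shoaled to the transition threshold (default 100 m — the "~100 m"
  of the source rule is made exact and configurable).
* **SS** (stratified summer): from ST, once a DCM exists and the MLD is
  above its upper bound.
* **AT** (autumn transition): from SS, once the deepening MLD reaches the
  DCM's upper bound — the first entrainment of the DCM into the mixed
  layer, read as MLD ≥ the region's top rather than its centre.

Labels persist between casts until a transition fires, and casts lacking
the features a transition needs simply carry the previous label. Within one
observation the transitions are iterated to a fixed point; this makes the
labelling idempotent under repeated observation of the same cast (a dense
process-cruise burst cannot change the labels a monthly series would get).
An optional running-median MLD smoother (off by default) can damp noisy
cast sequences.

**Vertical zones.** Samples are assigned the first matching zone of:
surface (≤ 5 m); DCM (inside the region, stratified casts); the 1%-light
band (± 10 m, deep-mixing casts — discrete bottle depths require a
tolerance); mixed layer; below the euphotic zone; other. The rules
partition: every sample receives exactly one zone, and a rule whose feature
is missing is skipped rather than raising an error.

## Community analyses

**Saturation filter.** The endpoint slope of the analytical rarefaction
curve, E[S(N)] − E[S(N−1)], reduces in closed form to f₁/N (the singleton
fraction), and samples with slope < 0.1 are kept. Samples with fewer than
50 plastid amplicons are flagged, not dropped, so whole-community analyses
retain deep casts while plastid-denominator analyses can exclude them.

**Normalisation.** Per-sample fractions against three denominators: total
amplicons, plastid amplicons, and prasinophyte amplicons (Class VI
Prasinodermophyta included, identified by the `prasinophyte*` group
prefix). Samples with a zero denominator yield absent values, never zeros.

**Quadrant analysis.** Over samples at ≤ 140 m with both chlorophyll a and
the prasinophyte fraction present, the 75th percentiles of each variable
(linear-interpolation percentile, R type 7 — documented because the
thresholds feed the assignment) split the samples into four quadrants.
Values exactly at a threshold fall in the "≤" half, so the
high–high quadrant requires strict exceedance on both axes.

**Persistence.** Restricted to ≤ 140 m and the analysis years
(default 2017–2019), each ASV's detections (count ≥ 1; a configurable
abundance floor exists but defaults to presence) are collapsed to the set
of stability periods and years. One period = ephemeral, four = persistent,
and an explicit intermediate category (2–3) makes the spectrum complete.
"Singleton" is read as one read in the restricted data (not one sample of
occurrence); singletons are removed before categorisation. Exclusive
period-combination and year-combination set counts (the UpSet/Venn
numbers) are derived from the same detections.

**Cross-marker linking.** 16S ASVs without species-level placement are
compared to 18S-defined candidate species via within-genus relative
abundances: for each pair, the samples where either side is detected and
where the genus reaches 10 amplicons *in each marker* (the filter is
applied per marker; applying it to one marker only is the plausible
alternative) are correlated with Spearman's rho. A link requires p < 0.05
with positive rho — a significant negative correlation is reported but
never flagged, since negative co-occurrence cannot indicate identity.
Samples where the genus passes the filter but the unit has zero reads
enter with fraction 0.

## Rank statistics

All four tests are implemented at the formula level with midranks
throughout, and each is validated in the test suite against an independent
oracle (rank-then-Pearson, base R `kruskal.test`, a hand-evaluated Dunn
formula, exhaustive label enumeration, and `vegan::anosim`):

* Spearman: Pearson correlation of midranks; two-sided p from the t
  approximation at n ≥ 10 and from exact enumeration of all n!
  permutations below that.
* Kruskal–Wallis: H with the tie correction 1 − ΣT/(N³−N); all-identical
  values give H = 0, p = 1 by convention.
* Dunn: zᵢⱼ = (R̄ᵢ − R̄ⱼ)/√[(N(N+1)/12 − ΣT/(12(N−1)))(1/nᵢ + 1/nⱼ)],
  two-sided normal p, Holm adjustment by default (the source names the
  tests but not the adjustment; Holm dominates Bonferroni at no cost).
* ANOSIM: R = (r̄_B − r̄_W)/(M/2) on midranked distances, permutation p
  with the add-one estimator and a seeded generator; 9,999 permutations by
  default. The distance for Hellinger-transformed abundances is Euclidean
  (equivalently the Hellinger distance); the source does not state its
  metric, and Bray–Curtis can be supplied simply by passing a `dist`
  object.
* Hellinger: √(count/row total) per sample.

Normality pre-testing is deliberately omitted: the nonparametric tests are
applied unconditionally, matching how every reported comparison was made.

## The synthetic generator

`simulate_physics()` emits casts on a 1-m grid from a planted calendar
(day-of-year transitions at 100/130/300/350 by default) and a seasonal MLD
curve interpolated in log depth through knots chosen so casts sit centrally
inside each period's MLD band: winter mixing to 230–250 m (beyond the
150-m euphotic depth), spring-transition casts near 90 m (between the
DCM top at ~81 m and the 100-m threshold), summer at 20 m, autumn at
100–130 m. Sigma-t is uniform above the planted MLD with a 0.13 kg m⁻³
step plus a 0.008 kg m⁻³ m⁻¹ pycnocline below, so the 0.125 crossing
recovers the planted MLD within one grid step; fluorescence is a Gaussian
DCM (centre 100 m, sd 20 m) when stratified and an elevated uniform
mixed-layer signal during deep mixing; PAR decays exponentially. Noise
defaults — 0.003 kg m⁻³ sigma-t, 5% multiplicative fluorescence and 2% PAR
noise, 2 m MLD displacement — are calibrated so the planted calendar is
perturbed but not erased: the spring-transition MLD band is only ~15 m
wide, and the displacement sd keeps transition casts several sd from the
classification thresholds, which is what the recovery experiment (≥ 90%
label recovery, exact DM→ST→SS→AT sequence) demands of the default
conditions. Zero-noise runs recover planted labels exactly by
construction.

`simulate_community()` draws, per bottle sample, a composition from a
Dirichlet around the planted (period, habitat) template, a library size
from a lognormal with mean 60,279 and sd 26,939, and counts multinomially.
The deep-mixing mixed-layer template puts the prasinophyte fraction of
plastid amplicons at 0.463; by Dirichlet aggregation that fraction is
Beta-distributed, and the concentration (9) was set analytically so its
sample-to-sample sd is near the observed 0.242. Two Class II ASVs are
planted persistent; two Class IX ASVs are planted summer-only ephemerals
and ride their own lognormal latent rather than the heavily overdispersed
community Dirichlet (whose per-ASV α ≪ 1 would make "planted" presence a
coin flip). The four Micromonas species are a shared latent between
markers: 16S species ASVs receive the latent shares directly, 18S species
abundances are the latent times per-species copy-number multipliers
(1–5×, emulating 18S copy-number inflation — only rank agreement matters)
with 25% lognormal noise. The planted null pair's 18S genus share is taken
from a fully independent draw and the linked species renormalised into the
remainder; replacing only the null species' latent would leave a
compositional echo of the 16S side in its denominator and is exactly the
subtle non-null this construction avoids. Bottle chlorophyll follows the
planted fluorescence profile; nutrients exist only to exercise the
detection-limit rule and summaries — no nutrient–biology coupling is
modelled.

What the generator does *not* emulate: advection and eddies, multi-year
trends, sequence-level artefacts (chimeras, errors), taxonomic
misannotation, and correlated library-size or extraction biases. Passing
tests therefore show that the algorithms recover structure of the planted
kind at realistic noise; they do not certify performance against every
failure mode of field data.

## Validation problem sizes

The test suite validates against: 100 analytically constructed casts
(closed-form MLD/light/DCM answers, tolerances 10⁻⁶ m and one grid step);
10 noisy synthetic years for period recovery; 1,000 random count vectors
plus a 10,000-rep subsampling oracle for the rarefaction slope; 200 random
small datasets against the rank-statistic oracles (10⁻¹⁰), exhaustive
ANOSIM enumeration at n = 6, and 2,000 shuffled-label replicates for
p-value uniformity (Kolmogorov–Smirnov, α = 0.01); 200 linked and 1,000
null cross-marker replicates at 30 shared samples; 100 synthetic years for
persistence recovery; and 200-sample group means for the composition
templates. These sizes give stable Monte-Carlo margins (3 standard errors
throughout) while keeping the full suite in the minutes range.

## Known limitations

* The state machine observes only sampled casts: a transition occurring
  between casts is dated at the first cast that exhibits it, and two
  transitions between consecutive casts collapse into the fixed-point
  label of the later state.
* The DCM boundary estimate inherits the grid resolution and, under
  multiplicative fluorescence noise, the detected maximum is biased
  slightly high, narrowing the region by a few metres — the zone tolerance
  absorbs this.
* Cross-marker links are correlational; identical seasonal niches can in
  principle link distinct taxa, which is why the procedure reports rho and
  n rather than asserting identity.
* The percentile and quadrant conventions (type-7 percentiles, "≤" at
  thresholds) are decisions, stated here because alternative conventions
  move boundary samples between quadrants.
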