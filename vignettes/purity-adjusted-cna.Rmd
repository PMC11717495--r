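---
title: "Purity-adjusted copy number calling: model, assumptions, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-adjusted copy number calling: model, assumptions, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnpurity)
```

## The problem

Bulk tumour samples are mixtures: DNA extracted from a block contains
tumour cells alongside stromal, immune, and other normal diploid cells.
Any copy number signal read from such a sample is diluted toward
diploid in proportion to the normal fraction, so interpreting somatic
copy number alterations (CNAs) requires an estimate of tumour purity —
and the interpretation inherits whatever bias that estimate carries.
Purity can be estimated by a pathologist's visual review (conventional
pathology, CP, reported at 5% steps), by deconvolution of expression
(ESTIMATE-style) or methylation (InfiniumPurify-style) data, or by
counting tumour versus non-tumour cells detected on an H&E slide by a
cell-detection model within pathologist-annotated regions of interest
(ROIs). These method families disagree systematically: deconvolution
methods tend to overestimate purity, pathologist scores to
underestimate it. `cnpurity` implements the analysis chain that
quantifies what those disagreements do to downstream copy number
calls.

## The model

### Cell-count purity

For a slide with `TC` detected tumour cells and `BC` background
(non-tumour) cells inside the ROI union, purity is simply

$$\mathrm{TPE} = 100 \cdot \frac{TC}{TC + BC} \quad (\%).$$

Cells are counted by boundary-inclusive point-in-polygon membership
(even-odd rule, so ring holes are excluded; overlapping polygons count
a point once). Boundary inclusivity is a deliberate choice: it is
deterministic and mirrors the raster-mask semantics of whole-slide
pipelines, where a nucleus centroid on the annotation border belongs
to the annotation. Detections are not confidence-thresholded by
default (`min_confidence = 0`): a cell detector's own post-processing
already decides what counts as a detected cell, so further filtering
is opt-in.

### Mixture inversion

A bulk sample at tumour purity $p \in (0, 1]$ with tumour copy number
$c_T$ over some interval shows the observed copy number

$$c_{obs} = p\,c_T + 2(1 - p),$$

i.e. a convex combination of the tumour state and the diploid normal
background. Observed copies come from SEG-style log2 ratios as
$c_{obs} = 2 \cdot 2^{l}$. Adjustment inverts the mixture:

$$\hat c_T = \max\!\left(0,\; \frac{c_{obs} - 2(1 - p)}{p}\right).$$

Two consequences drive everything downstream. First, adjusting with a
*wrong* purity $\hat p$ instead of the true $p$ gives the exact
identity

$$\hat c_T = 2 + \frac{p}{\hat p}(c_T - 2)$$

(before clipping at zero): deviations from diploid are scaled by
$p/\hat p$, while diploid segments are a fixed point regardless of the
purity used. Overestimated purity ($\hat p > p$) therefore *shrinks*
deviations — real CNAs get missed (undercalling) but neutral arms stay
neutral; underestimated purity ($\hat p < p$) *amplifies* deviations,
including measurement noise — spurious CNAs appear (overcalling) but
true CNAs survive. Second, the direction of miscalling is monotone, so
cohort-level under/over-calling shares directly diagnose the sign of a
method's purity bias.

Purity estimates below 5% are clamped to 5% (with a warning) before
the division: near-zero purity makes the inversion explode, and
samples that impure would fail molecular QC before profiling anyway.
The floor is exposed as `purity_floor` everywhere it applies.

### Classification and arm aggregation

Adjusted copy numbers are classified by rounding half-away-from-zero
to the nearest integer: rounded values $\ge 3$ are gains, $\le 1$
losses, 2 neutral — equivalently cut points at 1.5 and 2.5, with 2.5
itself a gain. The integer-enumeration form ("3 or more is a gain, 1
or less a loss") is the field's convention; rounding first makes the
real-valued rule reproduce it exactly.

Arm-level calls aggregate segment calls over each of 39 autosomal
chromosome arms by **length-weighted plurality** of the overlapping
segment calls, with ties broken toward neutral. No consensus rule for
this step is standard; plurality with a neutral tie-break is the
conservative choice (a call must carry more covered length than any
alternative to displace neutral or another call). Arms with no
segment coverage are called neutral and retained, so every sample
contributes exactly 39 calls and cohort cross-tabulations have the
clean sample-count × 39 total.

The packaged karyotype (`default_karyotype()`) uses GRCh37/hg19 arm
boundaries from the centromere gap annotation, autosomes only, with
the five acrocentric p-arms (13p, 14p, 15p, 21p, 22p) absent — their
short arms are satellite/rDNA material with no unique copy number
signal. Any BED4 arm table can replace it; no assembly-specific logic
exists outside the fixture.

### WGII

The whole genome instability index is the aberrant fraction of the
genome by length: summed lengths of loss or gain calls divided by the
total length considered. The default computes it at **arm**
resolution against the arm-table total (consistent with arm-level
calls being the unit of analysis); `level = "segment"` computes it
over classified segments against the segment-covered length instead.
The denominator is autosomal: sex chromosomes are outside the
karyotype, so hemizygous X in males never inflates the index.

### Concordance and the under/over-calling partition

Two adjustment runs over the same samples and arms are compared by a
3×3 cross-tabulation (reference call × comparator call).
*Undercalling* counts the off-diagonal cells where the comparator is
neutral — a reference CNA was missed. *Overcalling* is every other
disagreement, i.e. the comparator called a CNA the reference did not
make. The rare loss↔gain switches are counted as overcalling: the
comparator asserts an aberration the reference does not support, and
published cross-tabulations of this design resolve the ambiguity the
same way. Percentages are reported to one decimal, rounded half away
from zero; full precision is kept internally and rounding happens
only at display/serialisation.

## The synthetic cohort generator

Real multi-omic cohorts with paired H&E slides cannot ship with a
package, so `simulate_cohort()` generates cohorts with the statistical
structure the analysis assumes:

* **Truth purity**: Gaussian with mean 58.9 and SD 16.3 (percent),
  truncated to [5, 95]. These are the published marginals of
  cell-count purity in the cohorts this design emulates, taken as the
  closest available stand-in for truth — a modelling choice, not a
  claim that cell counting is error-free. Truncation keeps samples
  inside the QC-plausible range; it shrinks the realised SD slightly
  (to ≈15.6) relative to the nominal value.
* **Truth copy number**: each of the 39 arms is aberrant with
  probability `cna_rate` (default 0.3); aberrant states are drawn
  from weights {0: 0.05, 1: 0.45, 3: 0.40, 4: 0.10} — a predominance
  of single-copy events, colorectal-like.
* **Observed segments**: the forward mixture at the sample's true
  purity, observed through probes spaced every `bin_spacing` = 3 Mb
  (the resolution of a sparse targeted SNP backbone). Each probe's
  log2 ratio carries independent Gaussian noise with SD `noise_sd` =
  0.15 — a typical per-probe log2 dispersion — and the probes of an
  arm are averaged into one segment. Per-probe noise averaged over
  `length / 3 Mb` probes is what makes large arms reliable and small
  arms (e.g. 18p, ~5 probes) the first to miscall at low purity.
* **Biased observers**: each non-reference method is an
  affine-plus-noise observer of truth,
  $v = m + a\,(t - \mu)\,\sigma_{target}/\sigma_{truth} + \varepsilon$,
  with residual noise sized so the marginal SD equals the method's
  target SD. Calibration targets: ESTIMATE-like mean 79.2 / SD 10.5,
  InfiniumPurify-like 62.7 / 11.8, CP-like 35.9 / 13.1 with values
  rounded to 5% steps. Attenuation $a$ defaults to 0.6 for all three,
  matching the mid-range correlations such methods show against
  cell-count purity. Values are clamped to [1, 100] before
  granularity rounding (so a CP-like score can round to 0).
* **Paired slides**: two measurements share the true purity and get
  independent Gaussian perturbations of SD `replicate_sd` = 5
  percentage points, clamped to [0, 100]. The implied paired-slide
  correlation is the classical attenuation
  $r = \sigma^2_{truth}/(\sigma^2_{truth} + \sigma^2_{rep}) \approx
  0.91$ at the defaults.
* **Cell point patterns**: Poisson(density × area) points uniform in
  a square ROI, tumour-labelled with probability purity/100. Default
  density 19,000 cells/mm² (resection-like; biopsies run nearer
  26,000).

Each component draws from its own RNG stream, seeded deterministically
from the master seed, so adding or re-running one component never
perturbs another and a bundle is bit-reproducible from `(config,
seed)`.

What the generator does **not** emulate: spatial tumour
heterogeneity, subclonal CNAs, segmentation artefacts (segments align
exactly with arms), wavy GC biases, allele-specific signal, ploidy
shifts (near-tetraploid genomes that mimic diploid ones), or any
image-level structure beyond labelled points. Tests passing on
synthetic cohorts therefore demonstrate that the *chain of
computations* is correct and that the *directional* consequences of
purity bias follow from the mixture algebra — not that any particular
real cohort's numbers would be reproduced.

```{r cohort-example}
cfg <- simulation_config(seed = 7, n_samples = 40)
cohort <- simulate_cohort(cfg)
cohort

calls_ref <- suppressWarnings(adjust_cohort(
  cohort$segments, pmax(cohort_purity(cohort, "softctm_he1"), 1)))
calls_est <- suppressWarnings(adjust_cohort(
  cohort$segments, cohort_purity(cohort, "estimate")))
concordance_stats(cross_tabulate(calls_ref, calls_est))
```

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (BED convention);
  SEG-dialect files are 1-based inclusive on disk and converted on
  read/write, so round-trips are exact and no off-by-one can drift
  through the chain.
* Interval intersection runs on `GenomicRanges`; per-segment summed
  overlap never exceeds segment length, and segments on chromosomes
  missing from the arm table are skipped with one warning.
* `classify_cn` rejects negative input; `mixture_adjust` rejects
  purity outside (0, 1] and clips adjusted copies at 0.
* A slide with zero counted cells raises an undefined-purity error
  rather than silently reporting 0%.
* Pearson CIs use the Fisher z-transform with SE $1/\sqrt{n-3}$ (via
  `stats::cor.test`); degenerate (zero-variance) input and $n < 4$
  are errors, and a paired t-test on identical vectors is an error
  rather than NaN.
* Differences in t-tests and Bland–Altman summaries are always
  first-minus-second, stated in the outputs.

## Problem sizes used by the test-suite

The packaged checks run cohorts of 300 samples × 39 arms for call
recovery and discordance direction, 334 pairs for slide-replicate
attenuation (the size of the larger published reproducibility set),
5,000 draws for observer-marginal calibration, and 80–150 samples for
the WGII ordering checks — sizes at which the binomial/Fisher
tolerances asserted are comfortably discriminating while the whole
suite runs in well under a minute.

## Known limitations

* The mixture inversion is linear in copy number space; tools that
  rescale in log space differ in second-order detail, and equivalence
  with any specific caller's purity correction is not claimed.
* Arm aggregation by plurality discards within-arm structure; a
  focal high-level amplification inside an otherwise neutral arm does
  not make the arm a gain. That is intended at this resolution but
  wrong for gene-level questions.
* Purity truncation and clamping mean the simulated observer
  marginals land within a few percent of, not exactly on, their
  calibration targets.
* The under/over-calling partition is defined relative to a chosen
  reference; it measures disagreement and its direction, not accuracy
  against truth (except in simulation, where truth is known).
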