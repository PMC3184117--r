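---
title: "Benchmarking miRNA qRT-PCR panels with synthetic spike-ins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking miRNA qRT-PCR panels with synthetic spike-ins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeval)
```

## The problem

Circulating microRNAs are candidate plasma biomarkers, but plasma
carries very little RNA, so any qRT-PCR panel used on such samples must
be trusted at the low end of its dynamic range. The standard way to
establish that trust is a spike-in experiment: a set of synthetic
miRNAs of known sequence and quantity is measured by the platform, and
the platform's output is scored against the known truth. `spikeval`
implements that scoring as a reusable pipeline with four stages:

* **Specificity.** For a sample of known content, every assay whose
  designed target is absent is a potential false positive. Sweeping the
  Ct detection threshold produces the false-positive-rate curve
  FP / (FP + TN) (equal to 1 − specificity), and no-RT controls anchor
  the choice of threshold. False positives are then attributed to
  sequence homology with the species that *are* present.
* **Recovery.** Two samples built from the same species at reciprocal
  4:1 pool ratios imply a known ±2 ΔCt for every species; the pipeline
  reports how faithfully each platform recovers that difference.
* **Reproducibility.** Pearson correlation of duplicate RT + qPCR
  measurements per sample.
* **Sensitivity and linearity.** A five-point 10-fold dilution series
  yields per-point detection counts (compared between platforms with
  Fisher's exact test) and a per-assay r² of Ct against log10 input.

Because the underlying study's raw Ct tables are not publicly
deposited, the package also ships a parametric simulator
(`simulate_study()`) that generates Ct data with the statistical
structure the analysis assumes. Every pipeline stage is exercised, and
its behaviour verified, against this generator's known ground truth.

## The measurement model

A qPCR measurement is modeled log-linearly: with per-cycle
amplification factor $1 + E$ (efficiency $E \in (0, 1]$),

$$\mathrm{Ct}(c) \;=\; \mathrm{Ct}_{\mathrm{ref}}
  - \frac{\log(c / c_{\mathrm{ref}})}{\log(1 + E)}
  - n_{\mathrm{preamp}},$$

so at $E = 1$ each two-fold template increase lowers Ct by one cycle
and a four-fold difference is exactly 2 cycles — the design anchor of
the whole benchmark. ΔCt between samples is reported as
Ct(second sample) − Ct(first sample), so a species four-fold more
abundant in the first sample scores +2. Pre-amplification is modeled
as a pure downward Ct offset ($n_{\mathrm{preamp}}$ cycles); this is
sufficient to reproduce the qualitative signature that matters for the
analysis (signals, including false positives, appearing at lower Ct on
a pre-amplified platform) without simulating the enrichment chemistry.

## Homology screening

Cross-reactivity candidates are found by aligning each assay's target
sequence against every panel miRNA with Smith–Waterman local alignment
(+1 match, −1 mismatch, −1 linear gap by default; scores
configurable). A pair is homologous when the best alignment has at
most 4 mismatches and at most 8 unaligned bases of overhang at either
end (both bounds inclusive, both configurable).

One definition in this screen deserves care. A score-maximizing local
alignment will happily trim a mismatch-rich end off the alignment, and
if those trimmed bases were counted as "overhang" the bound would
admit any centrally placed ~6-nt exact match between two unrelated
22-mers — nearly every random sequence pair would qualify as a
homolog, which is useless as a cross-reaction screen and contradicts
the "nucleotide difference of 4 or less" reading of the bound.
`align_pair()` therefore reports mismatches over the full end-to-end
overlap the alignment implies: core mismatch columns (substitutions
plus, by default, gap columns) plus the differences found when the
core is extended diagonally through the trimmed flanks. Overhang
counts only the genuine end offset — the bases by which one sequence
extends past the other. With gaps disabled this reduces exactly to the
natural "slide one sequence along the other and count differences in
the overlap" procedure, which is how the implementation is verified
(an exhaustive offset-sliding oracle in the test suite).

Ties among equal-scoring alignments are broken deterministically:
fewest mismatches, then smallest total overhang, then leftmost start.
An assay's own designed target is never listed among its homologs.
Whether indel columns count as mismatches is a flag
(`count_indels_as_mismatches`, default on), since either convention is
defensible; overhang bounds apply per end, not summed.

A consequence worth knowing: even genuinely unrelated random 22-mers
satisfy the ≤4-mismatch/≤8-overhang bound with probability of order
10⁻³ per pair (an offset-8 overlap of 14 bases with 10 chance matches
qualifies). Against a 174-species panel this makes a noticeable
fraction of random off-panel assays "homologous by chance", so the
simulator's expected homology fraction (~0.5 with the default
off-panel universe) sits well above the ~16–18% seen with real miRNA
catalogs. This is a property of random sequences, not a bug; all
specificity statistics are computed against the expected fraction of
the universe actually in use, so the analysis remains internally
consistent.

## Detection rules

Two replicate rules are used at different points, and both are
explicit in `platform_config()`:

* `any_replicate` — an assay is detected if at least one replicate has
  numeric Ct ≤ threshold. Used for false-positive counting: a single
  spurious replicate already constitutes a spurious signal.
* `all_replicates` — every replicate must pass. Used for "n detected"
  summaries and for recovery inclusion, mirroring the rule that an
  assay is excluded from recovery when any one of its four
  measurements is undetected or beyond the threshold.

The detection comparator is inclusive (Ct ≤ threshold): a threshold
"at cycle 38" is meant to admit signals at 38. `suggest_threshold()`
returns the floor of a low quantile (default 0.01) of the numeric
no-RT Ct values, or the run length when the no-RT control is silent —
with background signals in the (38, 40) window this lands at 38, and
with an essentially silent no-RT control at 40.

## Statistics

The statistical kernels are deliberately thin wrappers over base R
with the conventions pinned down and labeled in every result:
Fisher's exact test uses the two-sided "sum of tables as or less
probable" convention; the Mann–Whitney U test uses the exact null
distribution when the smaller sample has ≤8 observations and no ties,
and the tie- and continuity-corrected normal approximation otherwise;
the variance comparison is the two-sided variance-ratio F test; the
homology enrichment test is the upper tail of a Poisson with
λ = n_FP × expected fraction (a binomial tail is available as the
arguably more exact alternative, and both are reported). Each of these
is checked against exhaustive enumeration oracles in the test suite
(all 2×2 tables and all Mann–Whitney shapes with total n ≤ 16, to
1e−12). The recovery summaries use linear-interpolation quartiles
(`quantile` type 7) and the n−1 sample variance; the quartile
convention is configurable since published interquartile ranges rarely
state one.

For per-assay linearity, undetected wells are imputed at the
platform's detection threshold (the background level), every replicate
measurement enters the regression as its own point, the independent
variable is log10 copies per PCR, and the lowest dilution point is
excluded by default (neither platform profile produces acceptable
measurements there — at half a copy per reaction most wells are
physically empty). Assays with zero Ct variance after imputation get
r² = 0 and are flagged rather than dropped. Outlying wells are never
removed heuristically; the only exclusion mechanism is an explicit
per-point assay list (`exclude_assays`), reproducing the manual
curation such studies report.

## The simulator

`simulate_ct_table()` draws each well independently given the design:

1. **Effective template.** The assay's own target copies plus
   cross-reactive contributions from homologous present species,
   each weighted by
   `crossreact_base_fraction × 10^(−penalty × mismatches)` (defaults
   0.5 and 1.0: a perfect off-target contributes half weight, each
   mismatch costs ten-fold). The homology map that drives the analysis
   also drives the simulation, so cross-reactive false positives are
   homology-related by construction.
2. **Occupancy.** The number of template molecules in the well is
   Poisson with mean = effective copies × `input_fraction`. This gives
   dropout its mechanistic, parameter-free form: the detected fraction
   at mean λ can never exceed 1 − e^(−λ), and at 0.5 copies per
   reaction ≈ 39% of wells are simply empty. Occupancy can be switched
   off (`occupancy_dropout = FALSE`) for noise-free arithmetic checks.
3. **Signal.** Ct = expected Ct at the realized occupancy + Gaussian
   noise (`noise_sd`, default 0.3 cycles per well, a typical qPCR
   duplicate spread).
4. **Background.** Independently of template, each well emits a
   template-free signal with probability `background_rate`, uniform in
   `background_ct_range` (default (38, 40)) — the no-RT phenomenon.
   The observed Ct is the earlier of template and background signal.
5. **Outlier wells.** With probability `outlier_well_rate` a well
   amplifies poorly (+`outlier_shift` cycles, default +6, or becomes
   undetected when the shift is `NA`).
6. Ct values beyond `max_cycles` (default 40) are undetected.

Two stylized platform presets bundle these parameters
(`platform_profile()`), emulating the qualitative contrast between a
universal-RT/LNA-style platform and a stem-loop/pre-amplification
style platform without claiming any real product's parameters:

| parameter | `mircury_like` | `taqman_like` | why |
|---|---|---|---|
| detection threshold (Ct) | 38 | 30 | no-RT-driven vs matched-FP-rate choice |
| `preamp_cycles` | 0 | 12 | pre-amplification as Ct offset |
| `background_rate` | 66/689 ≈ 0.096 | 0.005 | one platform shows ~10% no-RT signals, the other almost none |
| `input_fraction` | 1.0 | 0.1 | the pre-amplified platform loses sensitivity at low copies despite lower Ct, emulated as a smaller sampled template fraction |
| `outlier_well_rate` | 0.002 | 0.02 | sporadic poorly amplifying wells, concentrated on one platform |
| panel coverage | 143/174 | 155/174 | incomplete panel representation; the common set (~125) is used for cross-platform comparisons |

`noise_sd` stays at the shared default 0.3 for both profiles: the
outlier-well mechanism alone reproduces the recovery-variance contrast
between the platforms, which is also the mechanistic explanation such
studies give. The study roster built by `study_design()` is: two
synthetic samples (pools A and B at 0.25×10⁶ and 1×10⁶ copies per
reaction, mixed 1:4 and 4:1), two spiked plasma samples (the same
spikes over an endogenous background of 100 off-panel species at
log-uniform 10²–10⁵ copies), pure plasma, a no-RT control (no
template; background only), and a five-point 10-fold dilution series
of spiked plasma sample 1 starting at 5000 (pool A) / 20000 (pool B)
copies per PCR, ending at 0.5/2.

### What the simulator does and does not emulate

It reproduces the features the analysis is sensitive to: the ±2 ΔCt
design, duplicate structure, threshold-dependent false positives with
mismatch-graded cross-reaction, no-RT background, Poisson-limited
sensitivity, and poorly amplifying outlier wells. It does **not**
model RNA extraction efficiency, carrier effects or plasma inhibitors
(it starts at copies per reaction), thermodynamic cross-hybridization
(cross-reaction is purely sequence-count based), pre-amplification
bias beyond a fixed offset, or the sequence composition of real miRNA
families (panels are random sequences; planted homolog pairs provide
the mismatch structure). Tests passing on simulated data therefore
demonstrate the pipeline's correctness and calibration under this
generative model, not the performance of any real platform.

## Problem sizes and numerical choices

The test-suite and acceptance runs use the full study geometry
(88 + 86 panel species, 385 unrelated off-panel species plus
3/18/34/52/60 planted homologs at 0–4 mismatches, duplicate wells,
five dilution points) for the end-to-end checks, and reduced
geometries (e.g. 30 + 30 panels) where many seeded repetitions are
needed; both sizes were chosen so a complete run stays comfortable on
a single CPU while keeping group sizes large enough that medians over
~60 assays resolve 0.1 Ct. Alignment dynamic programming is in C++;
the homology screen for a full catalog pair (~730 assays × 174
species, twice) takes a few seconds, and everything downstream is
vectorized R. All randomness flows from explicit integer seeds;
analysis stages are purely deterministic, which the suite asserts by
re-running them on identical inputs.

Degenerate inputs are handled explicitly rather than silently:
duplicate measurement keys, out-of-range Ct values and unknown alphabet
characters are hard errors naming the offending record; correlations
over fewer than three detected assays are flagged `NA` (the printed
"na" convention for an empty no-RT column); the expected homology
fraction is an error when no assay targets an absent species; platform
comparisons refuse to run on fewer than three common included assays;
and zero-variance residual vectors (possible in noise-free simulations)
yield flagged `NA` statistics instead of division errors.

## Known limitations

* The homology bound admits chance homologs between random sequences
  (see above); with real catalogs the expected fraction is much lower.
* The mismatch-penalty defaults make cross-reaction from 0–4 mismatch
  homologs almost always detectable at the default thresholds, so the
  simulated mismatch-stratified false-positive gradient is flat near
  100% (monotone non-increasing, as required, but without the decline
  real platforms show); a steeper `crossreact_log10_penalty_per_mismatch`
  (~1.3–1.5) places the 4-mismatch stratum at the detection edge if a
  gradient is wanted.
* Replicate correlations restricted to the spike-in set compress the
  Ct range to ~2 cycles, which deflates r relative to full-panel
  correlations — visible in the reproducibility section and inherent
  to correlation over a narrow dynamic range.
* The Mann–Whitney comparison of recovered fold changes is run per
  expected-direction group; pooling |ΔCt| across directions is the
  other defensible reading of such comparisons.
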