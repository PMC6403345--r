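---
title: "Models, randomization schemes and design choices in erpmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, randomization schemes and design choices in erpmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erpmicro)
```

This vignette documents the statistical models the package implements, the
assumptions behind them, the tunable parameters with their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the methodology was genuinely open.

## The data model

All statistics operate on a `study_dataset`: one average-referenced ERP
matrix (channels x time, in microvolts) per subject per cell of a 2x2
within-subject design — task (color-naming, word-reading) crossed with
congruency (congruent, incongruent), in the fixed cell order `cC, cI, wC,
wI`. Time is in milliseconds with sample 0 at stimulus onset; all window
arithmetic uses half-open intervals `[onset, offset)`, so `duration =
offset - onset` exactly and adjacent microstate windows tile the epoch (the
offset of one map is the onset of the next). The average reference is the
only reference the topographic statistics are defined under; it is enforced
at construction and is idempotent and linear.

Preprocessing helpers mirror standard ERP practice: amplitude-criterion
epoch rejection (defaults: 50 uV maximal step between consecutive samples,
150 uV maximal range within 200 ms, 100 uV absolute bound — an epoch is
rejected if any channel violates any criterion), trial averaging over kept
epochs, and bad-channel repair. Bad channels are rebuilt by
inverse-distance-weighted averaging of the k = 4 nearest good electrodes;
full spherical-spline interpolation was deliberately not implemented because
no downstream statistic is sensitive to the difference at the smoothness
scales involved, and the weighted form is transparent and testable against
a closed-form oracle.

## Reference-free topographic statistics

**GFP.** The global field power of a map u is `sqrt(mean(u_i^2))` over
channels — the RMS with divisor N, not N - 1 (a documented constant; some
of the literature uses N - 1).

**Dissimilarity.** The GFP of the difference of the two GFP-normalized
maps, equal to `sqrt(2 - 2 cos)` with cos the cosine in channel space. It
is symmetric, invariant to positive rescaling of either map, and ranges
from 0 (proportional maps) to 2 (polarity-reversed maps).

**TCT.** Per timepoint the observed statistic is the GFP of the
across-subject grand-mean map. Under the null of no consistent topography,
shuffling electrode values within each subject's map is exchangeable; each
randomization run draws one electrode permutation per subject and applies
it at every timepoint, preserving the temporal structure of the null runs
(the duration control below depends on this). Whether maps should be
GFP-normalized before the TCT is not settled usage; the package exposes
`normalize` with default `FALSE`.

**TANOVA.** Per timepoint, every subject x cell map is scaled to GFP 1
(strictest reading of amplitude normalization: per subject, per condition,
per timepoint), the effect topography is the difference of marginal mean
maps (main effects) or the double difference (interaction), and the
statistic is its GFP. The null shuffles the four condition labels within
each subject — one shuffle per subject per run, shared by all timepoints
and reused for every effect, so a single randomization count serves the
whole factorial analysis. p values use the +1 convention
`p = (#{perm >= obs} + 1) / (n_perm + 1)` with ties counted as exceeding
(conservative); a relative tolerance of 1e-9 on the comparison makes exact
degenerate ties (identical cells) robust to floating-point noise. Whether
interaction permutations should be restricted to preserve main effects is
undecided in the methodology; the package documents the unrestricted
scheme and additionally offers `scheme = "paired_swap"` (flip only the
tested factor's levels, one coin per subject), which is also the group the
exhaustive-enumeration tests use on 2-3-subject toys.

**Duration control.** Point-wise randomization tests over hundreds of
timepoints need multiple-testing control. Every retained run is ranked
against all runs per timepoint (a pseudo-p series per run); the longest run
of consecutive pseudo-p < alpha is recorded; and the duration threshold is
the smallest length d such that at most `1 - percentile/100` of runs reach
d (default percentile 95). Observed significant periods shorter than d are
discarded. Because run lengths are integers the attained family-wise rate
sits at or just below the nominal 5%; the calibration experiment in the
acceptance suite measures it empirically.

## Microstate analysis

**Clustering.** Modified k-means on the grand-mean maps: winner-take-all
assignment by spatial correlation, prototype update as the GFP-normalized
mean of assigned maps (polarity-sensitive) or their first principal
direction (polarity-insensitive), iterated until the labels stabilize
(cap 100), best of `n_init` restarts by global explained variance
`GEV = sum((GFP_t corr_t)^2) / sum(GFP_t^2)`. Polarity-sensitive is the
default: ERP components are event-locked, so polarity is meaningful;
the insensitive mode exists for parity with resting-state conventions.
Assignment ties break toward the lower prototype index; dead prototypes
reseize the worst-fitted map. Prototypes are reported in canonical order of
mean assigned time; when the training matrix concatenates condition blocks
the order averages within-block mean positions (`blocks` argument), which
stays correct when the same sequence has different window lengths across
conditions.

**Choosing k.** Subjects are split at random into halves; the training
half's grand means (all four cells concatenated) are clustered at each k;
the prototypes are scored on the held-out half's per-cell grand means under
ordered-contiguous fitting. Selection is by the predictive residual
inflated by the classic microstate complexity factor,
`(1 - GEV_test) * ((C - 1) / (C - 1 - k))^2` with C channels, minimized
over k. The inflation factor is essential: held-out GEV alone is weakly
*monotone increasing* in k, because surplus prototypes — near-duplicates of
true maps, or boundary-mixture maps created by between-subject latency
jitter — always generalize slightly. In generator experiments the
uninflated argmax selected the largest k tested at every seed, while the
inflated criterion recovers the planted k reliably; the uninflated rule
remains available via `selection = "max_gev"`.

**Fitting and parameters.** The default `ordered-contiguous` mode assigns
each prototype exactly one contiguous window in canonical order by a
dynamic program maximizing the summed GFP-weighted correlation (O(kT) after
cumulative sums); windows tile the epoch, matching the single-window
structure that condition-wise parameter tables assume. `free` mode
(winner-take-all per timepoint) is retained for diagnostics, e.g. checking
that both conditions traverse the same sequence of maps. Parameters per map
and condition: onset, offset, duration, and `AUC = sum(GFP) * dt` over the
window (ms x uV), identically duration times mean GFP.

**Parameter randomization tests.** The fixed prototypes are refitted to the
grand mean of each effect level (for the interaction: to all four cell
means, combined as a double difference), the statistic is the absolute
level difference per map and parameter, and the null rebuilds the level
means from within-subject label shuffles and refits. A map unassigned in a
permuted refit would contribute +Inf (most extreme, conservative); under
ordered-contiguous fitting this cannot occur. Note that stretching one map
inside a fixed epoch necessarily changes its neighbors' windows too (the
epoch end absorbs the shift), so a planted stretch of map m is expected to
flag map m *and* the trailing map it compresses — the bookkeeping the
acceptance experiments assert.

## Source level

The toy head model places scalar (fixed-orientation) dipoles on a regular
grid inside the unit head sphere with far-field gains
`o_v . (r_i - p_v)/|r_i - p_v|^3`, average-referenced and column-scaled to
unit sensor GFP. Scalar voxels were chosen over free 3-orientation dipoles
because every downstream statistic is a scalar per voxel and the
standardization reduces cleanly. The inverse kernel is
`K = L'(L L' + alpha H)^+` (H the average-reference centering operator),
with the pseudo-inverse computed by eigendecomposition at relative cutoff
1e-10 — `L L'` is always rank-deficient under the average reference, so a
plain solve would be ill-posed. Voxel estimates are standardized by the
diagonal of the resolution matrix `K L`; with `alpha = 0` the argmax of
standardized power recovers a noiseless point source exactly at every
voxel (Cauchy-Schwarz in the resolution inner product), which the test
suite verifies exhaustively on a 6-sensor grid.

Voxel-wise inference uses paired t statistics on window-averaged source
maps, with sign-flip permutations of subject difference maps and the
max-statistic rule: the corrected critical t is the (1 - alpha) quantile of
the permutation distribution of the maximum t over voxels (one-tailed by
default, matching directional region hypotheses). Subject maps are first
divided by their mean over voxels (`normalize_subjects`, default on),
removing global gain differences; the exact normalization used by the
original tooling chain is not printed anywhere authoritative, so this is a
documented default, not an assertion about other software.

ROI activity is the plain mean of (standardized) voxel power over the ROI.
The window-wise Bayes table averages each subject's ROI activity over *that
condition's own* microstate window — condition-specific windows are the
point: if a process lasts longer but is equally strong, per-window means
match. Evidence is quantified by the JZS Bayes factor for the paired
design: BF01 is the central-t likelihood of the observed t divided by its
noncentral-t likelihood integrated over a Cauchy(0, r) prior on the
standardized effect (adaptive quadrature, relative tolerance 1e-8;
`r = sqrt(2)/2`, the framework's common default — exposed and recorded in
the output since analyses differ on it).

## The synthetic-data generator

The generator is the package's ground-truth surface. A study is built from
k orthogonal, average-referenced, unit-GFP template maps (orthogonality
guarantees the pairwise dissimilarity floor of 0.5), one contiguous window
per template per cell, a smooth positive GFP envelope (two-bump profile
between ~1.5 and ~5.5 uV), and noise:

- sensor noise SD 2 uV per channel and sample;
- spatial correlation from a Gaussian distance kernel on the montage
  (length 0.5 on the unit sphere) — real EEG noise is spatially smooth;
- temporal correlation from a Gaussian kernel along time (length 20 ms) —
  ERP recording pipelines band-limit the data (typically ~0.3-30 Hz), so
  residual noise is temporally smooth; temporally white noise
  would also collapse the null run-length distribution of the duration
  control onto 1-2 samples and make its calibration degenerate;
- per-subject multiplicative gain (log-SD 0.2) and a common latency shift
  of all boundaries (SD 5 ms) — amplitude and latency dispersion are the
  dominant between-subject factors in ERP averages, and a common shift is
  the simplest mechanism that preserves the fixed map order.

The planted congruency effect lengthens designated late maps by 50 ms in
the incongruent cells; the final map absorbs the shift so the epoch length
is fixed. The desk-scale defaults (12 subjects, 32 channels, 256 Hz,
1000 ms, 5 maps) scale the full study design the generator emulates (38
subjects, 64 channels, 1024 Hz, 10 maps — available as
`preset = "paper"`) down to sizes where 500-replicate calibration
experiments run in minutes;
electrode montages are Fibonacci lattices on the upper hemisphere.

Source studies replace templates by source configurations: compact voxel
clusters with fixed patterns, one designated segment activating the ROI of
interest. Each segment is active at a *constant* amplitude over its window
(drawn once, 2-4 uV scalp equivalent). This piecewise-constant profile is
the microstate assumption itself (quasi-stable strength per state) and is
what makes the "longer" effect a pure timing manipulation: the stretched
window has the same per-sample amplitude, so window means stay equal and
BF01 correctly supports the null of equal strength, while a "stronger"
effect scales the amplitude and leaves timing alone.

What the generator does **not** emulate: single-trial variability and
trial counts (ERPs are drawn directly at the average level), ocular or
movement artifacts, volume-conducted correlation structure from a real
head model, topography drift within a microstate, and behavioral response
coupling. Passing calibration and recovery tests therefore demonstrates
the statistics' correctness under the stated model, not robustness to
every property of real recordings.

## Numerical choices and degenerate inputs

- Randomization p values are never 0 (+1 convention); ties count as
  exceeding; tie comparison uses a 1e-9 relative tolerance.
- Flat maps (GFP 0) cannot be normalized or assigned; TANOVA under
  normalization reports the offending subject/cell/timepoint; t-maps report
  zero-variance channels as `NA` rather than infinite t.
- The 200 ms rejection window and all ms quantities convert to samples by
  rounding `sfreq * ms / 1000` to the nearest integer.
- The DP fit breaks boundary ties toward earlier splits; k-means assignment
  ties break toward the lower prototype index; both are deterministic.
- One global seed drives everything; the pipeline expands it into fixed
  per-stage seeds so disabling one stage cannot shift another stage's
  randomness (verified bit-for-bit in the tests).

## Problem sizes used by the tests and the acceptance script

Calibration experiments use 500 replicate null studies (12 subjects, 32
channels, 256 Hz for TANOVA and duration control; 16 sensors, 48 voxels,
128 Hz, 500 ms for the voxel test) at 99 randomization runs — the smallest
count at which p <= 0.05 is attainable exactly. Recovery experiments use 20
seeded studies for cross-validation (10 splits, 4 restarts each) and 5
seeded studies for the planted stretch at 199 runs. The conceptual
replication runs the full pipeline at 199 runs with k fixed at the planted
5 (the cross-validation stage is validated separately). These sizes keep
the entire suite within minutes while leaving every binomial check with
useful power; all of them are configuration, not constants in the code.

## Known limitations

- The duration threshold is integer-valued, so its attained family-wise
  rate is conservative between attainable levels.
- The microstate parameter test statistics are quantized by the sample
  grid; near-boundary permutations can tie with the observed statistic,
  so "floor-level" p values occasionally sit a few counts above the exact
  floor.
- The CV criterion's complexity factor assumes k well below the channel
  count; `k_range` close to C - 1 is rejected.
- The toy head model is generic rather than anatomical: localization
  statements are about operator properties, not brain geometry.
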