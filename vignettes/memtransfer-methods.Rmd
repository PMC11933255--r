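---
title: "Multidimensional memory decoding: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional memory decoding: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding model

`memtransfer` predicts, trial by trial, whether an event being encoded
into episodic memory will later be remembered (hit) or forgotten (miss),
using EEG alone.  The premise is that encoding success is not a
unidimensional state: it reflects the joint engagement of perceptual and
attentional processes.  Each of those processes is indexed by a separate
"source" task in which high and low performance states are directly
observable — correct vs. incorrect color-majority judgments for visual
perception, and fastest-40% vs. slowest-40% correct reaction times for
sustained and selective attention.  Transfer learning then asks, for each
200-ms window of the encoding epoch, "how strongly does this window's
activity resemble the source's high state?", and the resulting evidence
scores are integrated into a single memory prediction.

### Spatial filtering

All feature extraction is covariance-based.  A trial's
channels-by-samples matrix $X$ (per stream: broadband voltage at 250 Hz,
or a log band-power series at 50 Hz) gives the trace-normalized
covariance $C = XX^\top / \mathrm{trace}(XX^\top)$, which removes global
amplitude and makes trials commensurable.  Common Spatial Patterns
maximizes $w^\top \bar C_1 w / w^\top \bar C_2 w$ over filters $w$; we
solve it by whitening the denominator covariance and eigendecomposing
the whitened numerator, which is numerically stable for symmetric PSD
inputs.  Filters are sorted by descending generalized eigenvalue, so the
first rows emphasize class-1 variance and the last rows class-2
variance.

For transfer, the class covariances entering the objective are blends
$\alpha \bar C^s_i + (1-\alpha)\bar C^t_i$ of source- and target-task
covariances (source high aligned with target hit), and the denominator
receives a channel penalty $\beta\, w^\top D w$.  The penalty matrices
are diagonal with entries $1/w_{1j}^2$ (or $1/w_{31j}^2$), i.e. channels
that the most discriminative unpenalized filters barely use are
penalized hardest, pulling the regularized solution toward the channels
that matter.  Because $D$ is defined through the solution's own extreme
filters, the definition is circular; we resolve it with a deterministic
two-pass scheme: pass 1 solves plain CSP on the blended covariances and
its first/last rows define $D_1$/$D_{31}$ (entries clipped to machine
epsilon in magnitude before inversion); pass 2 solves the two penalized
problems, keeping the top $m$ eigenvectors of the $D_1$ problem and the
bottom $m$ of the $D_{31}$ problem.  The penalty matrices are built per
stream, since each stream's pass-1 filters differ.  With
$\alpha=\beta=0$ both passes collapse to target-only CSP, which the test
suite verifies filter-by-filter.

### Classification and integration

Per stream, the variances of the $2m$ selected projected series are the
features ($2 \times 15$ rows $\times$ 5 streams = 150 by default).
Selection is filter-then-wrapper: Fisher scores
$(\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)$ keep the top 40, then
sequential forward selection keeps the 5 features maximizing
inner-cross-validated balanced accuracy of a Gaussian naive Bayes
(variance floor $10^{-9}$ per feature).  SMOTE balances the training
classes before selection so that synthetic samples can never be informed
by test trials.  The evidence score of a (source, window) pair is the
naive-Bayes posterior of the high/hit-aligned class.

Scores from all sources and all 14 windows enter an ordinary
least-squares regression of the 0/1 outcome; a fitted memory score above
0.5 is called a hit.  We include an intercept even though the pure
weighted-sum form has none: without it the 0.5 threshold is miscalibrated
whenever class priors are unequal (`intercept = FALSE` restores the
literal form).  A fitted score of exactly 0.5 is conservatively called a
miss.  Everything — filters, selection, SMOTE, classifier, $\alpha/\beta$
choice, and the integration fit — is computed inside each outer fold
from its training trials alone; `refit_fold()` re-derives a fold
bit-for-bit, and the acceptance suite asserts this identity.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `m` | 15 | CSP filter pairs per stream (30 rows of 31) |
| `filter_k` / `select_k` | 40 / 5 | Fisher filter size / wrapper selection size |
| `alpha_grid` | 0, 0.25, 0.5, 0.75, 1 | source-target blend weights searched |
| `beta_grid` | 0, 0.01, 0.1, 1 | channel-penalty weights searched |
| `outer_folds` / `inner_folds` | 5 / 5 | nested cross-validation structure |
| windows | 14 x 200 ms, step 100 ms | encoding windows over 0-1500 ms |
| source windows | 200 ms in 0-600 ms | candidates for the optimal source window |
| `smote_k` | 5 | SMOTE neighborhood size |

The $\alpha/\beta$ grids are a pragmatic choice: the weights are meant to
be "chosen during cross-validation", and a small log-ish grid keeps the
inner search tractable; they are optimized per (source, window) pair.
During that inner search, candidate weights are ranked with
Fisher-top-`select_k` features rather than the full wrapper path — the
wrapper is run once at the chosen weights — trading a small amount of
fidelity for a large constant factor.  Candidate source windows span
0-600 ms post-stimulus because the source tasks' discriminative evoked
activity is early; the optimal window is chosen at the group level when
several participants are supplied.  Whether the wrapper objective is
balanced or plain accuracy is not pinned down by the originating
description; we use balanced accuracy throughout for consistency.

## The synthetic generator

`simulate_epochs()` draws each trial as
$X = \sigma Z + \sqrt{a_i}\, B F$ with iid normal $Z$ (sensor noise) and
$F$ (factor series), so the spatial covariance
$\sigma^2 I + a_i BB^\top$ is PSD by construction.  The factor amplitude
follows a per-trial latent level: class mean (1 for high/hit, 0 for
low/miss), plus a linear drift `drift_slope` per trial, plus stationary
AR(1) noise (`ar_phi`, `state_sd`).  Source tasks share a fraction
$\gamma$ of the rank-$k$ loading matrix $B$ with the target (remaining
columns drawn orthogonal to the whole target subspace, so the overlap is
exactly $\gamma$); $k = 3$ by default, small enough to interpret and
large enough that partial overlap is meaningful.  A global `amp_scale`
emulates feature-range shifts between recording contexts — invisible to
the trace-normalized filters but fatal to an unadjusted decision
boundary, which is exactly what the no-adjustment control probes.
Default $\gamma = 0.8$ encodes strong but imperfect cross-task overlap,
the regime in which transfer is useful at all.  Behavioral tables use
exact condition counts (e.g. 30% sustained-attention targets, 16
mini-blocks of 15 encoding trials) with seed-controlled ordering;
response accuracy is planted at 80% (perception) / 95% (attention
tasks), typical of near-threshold perception and ceiling-level attention
performance, and the memory hit rate at 60%.  RT ties at the 40% cutoffs
are broken by ascending trial index for reproducibility.

What the generator does *not* emulate: ERP morphology, 1/f spectra,
ocular or muscle artifacts, volume-conduction topographies, or
non-stationary noise.  Passing tests on this generator therefore show
that the pipeline recovers planted covariance structure, drift, and
history dependence under controlled conditions — not that it would reach
any particular accuracy on recorded EEG.

## Dynamics analyses

Evidence per trial and source is the mean score across the 14 windows.
For time-on-task, each memory condition's series is completed over all
trial positions by carrying the nearest preceding value of that
condition (leading gaps copy the first real value; next-value and
mean-of-neighbors variants are available and agree when the flanking
values agree), then collapsed to 16 mini-block means whose Pearson
correlation with block index is the slope statistic.  For
encoding history, windows are collapsed to early/middle/late 500-ms
chunks by window midpoint (windows 1-4, 5-9, 10-14; the 200-ms grid does
not align exactly with 500-ms boundaries, so the midpoint rule is the
package's choice), events are grouped by the previous (or next) event's
outcome, and the cell means enter a Memory x Source x Time
repeated-measures ANOVA with subjects as the error stratum
(`Error(subject/(memory*source*time))`), each effect tested against its
own subject-interaction stratum with partial $\eta^2$ reported.  Other
error-term constructions exist (and published degrees of freedom cannot
always be reproduced from a text description); ours is the standard
fully-within-subject layout and is validated against brute-force sums of
squares in the tests.

## Numerical choices

- Covariances are symmetrized and ridge-stabilized ($10^{-8} I$) when
  their condition number exceeds $10^{10}$.
- Eigenvector sign is fixed by making each filter's largest-magnitude
  entry positive, so results are reproducible across LAPACK builds.
- Morlet transforms (5 cycles, 78 linear frequencies 3-80 Hz) run on the
  full epoch via FFT convolution with L2-normalized kernels, then are
  windowed, so windows carry no per-window edge artifacts; band power is
  log-transformed per frequency before band averaging, and the band
  series is decimated to 50 Hz.
- Band-power streams are not baseline-corrected (baseline correction is
  applied to voltage epochs only); `baseline_correct()` is exposed
  separately so power can be corrected upstream if desired.
- Windows are half-open `[start, end)` in ms; a sample at time $t$
  belongs to the window iff $start \le t < end$.
- Fold assignments are stratified and derived deterministically from the
  configuration seed; all resampling uses an isolated RNG stream so
  library calls cannot perturb reproducibility.

## Problem sizes in the test suite

The packaged tests exercise the full 31-channel, 5-stream geometry for
structural checks, and run the simulation studies at reduced size —
8-16 channels, voltage stream only, $m = 2$, 60-240 target trials,
100-300 source trials, 20 seeds per qualitative claim — which keeps the
complete suite to a few minutes while leaving every decision path of the
pipeline (covariance blending, penalties, selection, SMOTE, nested
folds, integration, controls, dynamics) on.

## Known limitations

- The generator's white-noise background means band-power streams carry
  the same planted structure as voltage; the five streams are therefore
  redundant in simulation in a way they are not in recorded EEG.
- The no-adjustment control integrates scores by unweighted averaging,
  since fitting integration weights would require exactly the target
  training data the control withholds.
- `control_shuffled_sources()` re-runs the full pipeline with permuted
  source labels; with $\alpha$ grids containing 0 the inner search can
  fall back to target-only filters, so shuffled performance is bounded
  below by the unidimensional pipeline rather than by chance — the
  relevant comparison is against the intact transfer run.
- Artifact rejection, ICA, and electrode interpolation are assumed to
  have happened upstream; the package consumes clean epochs.
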