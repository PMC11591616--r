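---
title: "Topographic ERP microstate analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic ERP microstate analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpmicro)
```

## The model

Event-related potentials (ERPs) can be read not as stacks of per-electrode
waveforms but as a sequence of quasi-stable scalp field configurations —
*microstates* — each occupying a contiguous stretch of time and separated
by rapid transitions. Because a topography is a property of the whole
field, it is independent of the recording reference, and a change of
topography necessarily implies a change in the configuration of the
underlying generators. This package implements that analysis for a
2 × 2 within-subject design (language L1/L2 × motor/non-motor verb
embodiment), from evoked matrices to condition statistics.

Three primitives carry everything:

* **Global field power.** `gfp(u)` is the spatial standard deviation of
  the average-referenced map, with the population (1/N) normalization:
  $\mathrm{GFP}(u) = \sqrt{\tfrac1N \sum_i (u_i - \bar u)^2}$. It is
  reference-free and scale-equivariant.
* **Spatial correlation.** `spatial_correlation(u, v)` is the Pearson
  correlation across channels of the average-referenced maps — blind to
  field strength, sensitive to configuration. It is *polarity-sensitive*:
  for latency-locked evoked components (P1, N1, ...) the sign of the field
  is meaningful, so a map and its inverse are different states. (The
  polarity-invariant convention belongs to resting-state analysis, not
  here.)
* **Template maps** are zero-mean, unit-GFP channel vectors
  (`normalize_map()`), so that clustering and back-fitting see only
  configuration.

### Segmentation

`segment_microstates()` concatenates the four condition grand averages
over the post-stimulus analysis window, GFP-normalizes every timepoint
map, and runs atomize–agglomerate hierarchical clustering (AAHC): every
map starts as its own cluster; the *worst* cluster is dissolved and each
freed map joins the cluster whose centroid it correlates with best;
centroids are recomputed; one solution is recorded for every cluster count
$k \le k_\max$ (default 20 — ample headroom above the map counts ERP
segmentations settle on).

The quantity optimized is the global explained variance
$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t \,
C(u_t, T_{\ell(t)})\big)^2}{\sum_t \mathrm{GFP}_t^2},$$
with $C$ the signed spatial correlation and $\ell(t)$ the label of sample
$t$: strong fields count for more, and a sample's contribution is the
squared quality of its assigned template.

Three numerical choices deserve explanation, because the obvious
alternatives fail in reproducible ways:

* **Centroids** are the GFP-normalized arithmetic mean of the member
  *maps* (strength included). Averaging normalized copies instead gives
  every member unit weight, and timepoints with near-zero field — which
  carry no topographic information — then corrupt the centroid direction.
* **The worst cluster** is, once the count is near the recorded range,
  the cluster whose atomization *loses* the least explained variance: its
  GEV contribution minus what its members immediately recover under the
  remaining centroids. The naive rule (smallest raw contribution) can
  dissolve a genuine low-power map while two redundant near-duplicate
  centroids of one high-power map both survive — we observed exactly this
  on synthetic data, where the N1 map split into two correlation-1.000
  clusters and the P1 map was sacrificed. The marginal form dissolves the
  redundant twin first (its members are recovered at no cost). While the
  cluster count is still large the raw-contribution rule is used, where it
  is both cheap and adequate.
* **Stabilization.** Each recorded solution is relaxed by winner-take-all
  reassignment and centroid updates until stationary. The greedy
  atomization path alone can sit several percent below the explained
  variance that the same number of clusters supports.

Ties — equal correlations, equal criterion ranks — always break toward
the lower map or cluster index; segmentation is deterministic end to end.
Timepoints with zero GFP (possible in noise-free synthetic data) are
excluded from clustering and back-fitting rather than given an arbitrary
label.

### Choosing the number of maps

No single index reliably picks $k$; the package combines four
(`meta_criterion_select()`), each casting a vote:

* the **cross-validation criterion**, residual variance inflated by
  $\big((N_{ch}-1)/(N_{ch}-1-k)\big)^2$ — its minimum penalizes $k$
  directly;
* the **Krzanowski–Lai index**, the ratio of successive dispersion
  differences — its maximum marks the knee of the dispersion curve;
* a **dispersion-ratio** rule: the smallest $k$ for which
  $(W_k/W_{k+1}-1)(T-k-1)$ drops below 10, i.e. the first $k$ after which
  one more cluster no longer buys a substantial drop;
* a **silhouette** index on spatial-correlation distances, taking the
  smallest $k$ within 0.02 (the index's meaningful resolution) of the
  maximum.

A candidate $k$ is ranked per criterion by its distance to that
criterion's vote, and the best median rank wins, ties toward smaller $k$.
We settled on votes rather than raw score ranks after observing that
silhouette and Krzanowski–Lai *ranks* amplify meaningless fluctuations on
unstructured data: on pure noise the raw-rank median happily selected six
maps, whereas the vote form selects two, and it recovers a planted
four-map structure in 50 of 50 probe seeds. $k = 1$ is never a candidate
(no criterion has a contrast there).

### Temporal constraint

Scalp states shorter than about 10 ms are physiologically implausible, so
label runs under `min_segment_ms` (default 10) are dissolved: each sample
of a short run is handed to whichever flanking run's map it correlates
with best, shortest run first, iterating until stable; stragglers are
then merged wholesale into the better-correlated flank. Runs at or above
threshold are never touched, and the constraint can only lose explained
variance, never gain it. A fully degenerate labeling (nothing long enough
to absorb into) falls back to the single best map, with a warning.

### Back-fitting and statistics

`backfit_subject()` (also available as `predict()` on a fitted
segmentation) assigns each in-window sample of a subject's ERP to the
template with maximal signed correlation and extracts, per map: GEV, mean
GFP over the samples the map wins, and total duration in ms. By default
all selected templates compete over the full post-stimulus window
(`fit_scope = "epoch"` in the pipeline's terms) rather than only inside
the grand-average windows; fixing per-map windows from the grand average
would bias individual durations toward the group solution. Maps that
never win a sample score zero on all three measures.

`rm_anova_2x2()` is the classical balanced within-subject decomposition;
each effect is tested against its own effect-by-subject stratum, F with
(1, n−1) degrees of freedom. Both partial and generalized $\eta^2$ are
reported: published tables in this literature do not always state which
variant they print, and the two can differ by a factor of two or more, so
emitting both keeps the comparison honest. No sphericity correction is
applied — every effect has a single degree of freedom, so there is no
sphericity to violate; nonsphericity $\varepsilon$ enters only the power
calculator.

`rm_anova_power_n()` inverts the noncentral-F power function for a
one-group repeated-measures design: noncentrality
$\lambda = f^2 n m \varepsilon/(1-\rho)$, degrees of freedom
$(m-1)\varepsilon$ and $(n-1)(m-1)\varepsilon$. At $\alpha = 0.05$,
$f = 0.25$, target power 0.8, $\rho = 0.5$, $\varepsilon = 1$ and $m = 4$
it returns a minimal total sample size of 24, with power(23) ≈ 0.797
just under target — the canonical a-priori calculation for this design.

## The synthetic generator

`simulate_dataset()` exists so the whole pipeline can be validated
against known ground truth. It emulates the layout of a 29-subject,
128-channel, 1024-Hz evoked study with a −100…700 ms epoch:

* a quasi-uniform upper-hemisphere montage (Fibonacci lattice);
* four smooth template topographies built from random dipole-like sources
  inside the head sphere, with pairwise |correlation| bounded (default
  0.5);
* a timeline placing them in the canonical visual-word windows —
  P1-like 100–150 ms, N1-like 150–300 ms, P2-like 300–400 ms, N400-like
  400–500 ms — each under a Hann (half-cosine) envelope with 3 µV peak
  GFP. The smooth envelope avoids step discontinuities that a band-pass
  filter would ring on;
* condition effects as multiplicative GFP factors per (map, cell). The
  defaults plant the qualitative pattern the pipeline is meant to detect:
  N1 × 1.3 for motor verbs; P1, P2, N400 × 1.3 in L2; P1 × 1.15 for
  non-motor with an extra 1.1 in L2 non-motor (so P1 is strongest in L2
  non-motor);
* multiplicative log-normal subject effects (σ = 0.2 on the log scale,
  mean 1) correlated across the four cells at ρ = 0.5 through a Gaussian
  copula — matching the correlation-among-measures assumption of the
  power analysis and keeping strengths positive;
* spatially white Gaussian sensor noise (default 0.5 µV) everywhere,
  noise only before stimulus onset, baseline-corrected per channel.

What it deliberately does **not** emulate: biophysical forward models and
realistic spatial noise covariance, ocular or myogenic artifacts, latency
jitter between subjects, trial-level variability (it works at the evoked
level, since per-condition trial counts after artifact rejection are not
part of the emulated design). Passing tests on this generator therefore
demonstrate that the algorithms recover what they are defined to recover;
they do not certify performance on real recordings with structured noise.

## Preprocessing contract

`bandpass_filter()` applies a 2nd-order Butterworth band-pass
(0.5–40 Hz), coefficients from the `signal` package, in two passes —
forward and backward — eliminating the phase shift; the effective
magnitude response is the squared single-pass response (amplitude 0.5 at
the band edges). Channel means are removed first and the signal is
extended by odd reflection over three times the effective
impulse-response length (bounded by the record) to suppress edge
transients. Epochs are −100…700 ms, sample count round-half-up of
duration × rate (819 at 1024 Hz), half-open `[start, end)`; the
per-channel mean over the −100…0 ms baseline is subtracted. Artifact
screening is a deterministic peak-to-peak threshold (default 150 µV per
channel): a reproducible pipeline cannot contain a visual-inspection
step. Filtering operates on the continuous record before epoching;
per-epoch filtering is not offered.

## Problem sizes in the test-suite

The validation suite runs the full pipeline hundreds of times, so its
Monte-Carlo studies use reduced spatial and temporal resolution — 16–32
channels and 128–512 Hz — while keeping the design-level parameters (29
subjects, ρ = 0.5, multiplier 1.3, noise 0.5 µV) at their defaults. The
topographic primitives are resolution-independent, and clustering quality
improves with channel count, so these sizes make the checks conservative
rather than lenient. Specific studies: planted-effect recovery (50
datasets, 32 channels, 128 Hz), type-I calibration under the
all-multipliers-equal null (500 datasets, same size), k-selection
recovery (50 seeds, 256 Hz), window recovery (512 Hz).

Two measurement conventions in those checks are worth stating. Back-fit
label accuracy is scored where the planted instantaneous SNR is at least
5 — at the Hann envelope's feet the planted field vanishes and no method
could (or should) recover the label. Window-recovery overlap is scored
over the signal-bearing part of the epoch: outside the planted windows
the field is pure noise and winner-take-all labels there are arbitrary
*at any noise level*, carrying no information about recovery.

## Known limitations

* AAHC is greedy; with the stabilization pass it matches exhaustive
  enumeration on structured toy problems, but no global-optimality claim
  is made.
* The signed-correlation convention means polarity-inverted occurrences
  of a map are different states by design; on data where polarity is
  arbitrary (isotropic noise), squared-correlation objectives admit
  groupings that no polarity-sensitive method will produce.
* The temporal constraint is a minimum-duration rule only; no smoothness
  prior beyond it.
* The ANOVA layer assumes one value per subject and cell and a complete
  balanced design; unbalanced data need a mixed-model treatment outside
  this package's scope.
* Per-map ANOVAs are reported uncorrected for the number of maps,
  mirroring standard practice in this literature; correct across maps
  downstream if desired.
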