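---
title: "Co-activation pattern analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activation pattern analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Resting-state fMRI is usually summarized by functional connectivity —
time-averaged correlations between regions — which hides how the brain moves
between transient activity states. Co-activation pattern (CAP) analysis takes
the opposite view: every single time frame is a sample of a brain-wide
activation state, and clustering frames by spatial similarity recovers a small
repertoire of states (typically 6–10). `capdyn` implements this analysis for
voxel-level data: frames are z-scored per voxel, each frame is thresholded to
its activation extremes, and the frames of all subjects are concatenated and
clustered with K-means++ under correlation distance
$d(z_j, c_k) = 1 - \mathrm{corr}(z_j, c_k)$, minimizing

$$D = \sum_{k=1}^{K} \sum_{j \in k} d^2(z_j, c_k).$$

Model selection uses the explained-variance curve: within-cluster variance
$V_w = D/N$, between-cluster variance
$V_B = \frac1N \sum_k n_k\, d^2(c_k, c)$ with the size-weighted global
centroid $c = \sum_k \frac{n_k}{N} c_k$, and $EV = V_B/(V_w+V_B)$. The
number of states is the elbow of $EV(K)$, operationalized through the
fractional gain $(EV_K - EV_{K-1})/EV_{K-1}$: the smallest $K$ beyond which
every gain stays below 0.5%. The literature is ambiguous about whether the
rule is "the first K whose own gain is below threshold" or "all subsequent
gains below threshold"; we default to the stricter *all-subsequent* reading
and expose `rule = "next_only"` as the alternative. On the worked sequence
`EV = (.30, .40, .48, .50, .501, .5012)` the two rules return 5 and 6
respectively — a genuine one-step ambiguity users should be aware of.

CAP maps are voxel-wise averages of the *unthresholded* z-scored frames in a
cluster, at cohort level and per genotype-age cell; the cohort map is exactly
the frame-count-weighted mean of the cell maps. CAPs are displayed as
anti-correlated pairs (greedy pairing on the most negative map correlation,
strongest pair first, higher-occurrence CAP first within a pair), reflecting
the empirical organization of CAPs into state/anti-state pairs.

## Temporal statistics and transitions

Per scan, *occurrence* is the percentage of frames assigned to a CAP (sums
to 100 by construction) and *duration* is the mean maximal-run length in
frames; runs touching the scan boundary count as ordinary runs, a negligible
bias at ~1,000 frames per scan. On a chain with self-transition probability
$q$ the expected duration is $1/(1-q)$, which the tests exploit.

Transitions are analyzed at the group level by pooling consecutive-frame
pairs within scans (never across scan boundaries). Persistence is
$c_{ii}/\sum_j c_{ij}$; the inter-CAP transition probability
$p_{ij} = c_{ij} / \sum_{j' \ne i} c_{ij'}$ conditions on leaving state $i$.
Significance is assessed against surrogate ensembles built by permuting each
subject's label sequence uniformly (preserving label multisets), recomputing
the pooled statistics through the *same code path* as the observed data.
Permutation p-values use the add-one convention
$p = (1 + \#\{p^{sur} \ge p^{obs}\})/(1+n)$ so that extreme observations do
not produce exact zeros, which would break BH-FDR. Directionality
($p_{ij}$ vs $p_{ji}$) is tested one-sided in the direction of the observed
preference, only for pairs significant in at least one direction;
inter-group differences compare $\Delta = p^A_{ij} - p^B_{ij}$ two-sided
against paired surrogate differences (the s-th surrogate of each ensemble).
Pair tests and persistence tests form separate FDR families.

A caveat the calibration tests make explicit: permutation surrogates destroy
*all* temporal structure. On strongly persistent data the surrogate null is
therefore rejected by design — that sensitivity is what finds significant
pathways. Only on exchangeable (i.i.d.) sequences is the test an exact null,
which is the regime our calibration criterion uses.

## Classification

Subjects are classified into genotype(-age) groups from CAP features with
ridge-penalized multinomial logistic regression (`glmnet`, `alpha = 0`,
fixed `lambda = 1`; the regularization strength is deliberately fixed
rather than tuned, trading a little accuracy for determinism). Leakage
control is structural: per split, reference CAPs, the significant-voxel
union defining spatial features (one-sample T, Bonferroni p < 0.01 within
training groups), and feature standardization statistics are derived from
training subjects only; a test perturbs held-out scans and asserts the
training-side artifacts are unchanged. Splits are stratified at the
*subject* level, so a subject's two ages never straddle the split — the
source material is silent on this, and keeping identities on one side is
the conservative choice. Per-class training counts follow
`round(0.8 n)` with at least one test subject. The chance baseline refits
each split with shuffled training labels, and the paired Wilcoxon
signed-rank test compares the two accuracy distributions.

## The synthetic world

The generator states a fixed world rather than a tunable benchmark: six
spatial topographies on 500 mask voxels (10×10×5 grid) organized as three
sign-flipped anti-pairs — each a compact hub (10% of voxels, loading ~3 sd)
on weak Gaussian background, mimicking localized co-activation hubs; a
shared Markov chain with persistence 0.85 and uniform off-diagonal mass
(uniform stationary distribution, initial state drawn from it); 980 frames
per scan (a 1,000-frame acquisition minus the 6+4 frames trimmed per end by
conditioning); Gaussian voxel noise with sd 0.3 in z-units; and a 2×2
genotype (WT/TG) × age (4M/6M) longitudinal design. Group effects are
multiplicative only (amplitude scaling of named voxel subsets, optionally
per state), and Markov matrices can be overridden per cell. Effect sizes
for planted group differences are free parameters — the source reports none
— so the classifier tests use a 50% amplitude reduction of one state's hub
in the transgenic cells, a "co-activation loss" of the kind the analysis is
meant to detect.

What the generator does *not* emulate: hemodynamic convolution,
physiological noise, motion, spatial autocorrelation of noise, and
between-subject topography variability. A green recovery test therefore
establishes algorithmic correctness on well-posed data, not field
performance on real scans.

## Signal conditioning and numerical choices

The conditioning chain is fixed: trim 6 frames per end → 0.01–0.2 Hz
Butterworth band-pass (order 2, applied forward–backward for zero phase;
the order and zero-phase application are unstated in the source literature
and documented here as configurable defaults) → trim 4 more frames per end
→ quadratic detrend → nuisance regression (implicit intercept;
rank-deficient regressor sets fall back to a pseudoinverse projection with
a warning) → voxel-wise z-scoring with the sample (n−1) variance.
Zero-variance voxels are removed from the mask with a logged message rather
than failing the run. The filter is designed from the analog prototype via
the band-pass transform and bilinear transform, and applied with
odd-reflection padding and step-response initial conditions; it matches a
reference DSP implementation to ~1e−13, and those coefficients are frozen
in the tests.

One property deserves emphasis because it shapes a test: voxel-wise
z-scoring compresses hub voxels (a voxel's temporal sd grows with its
loading), so state-mean maps recovered after conditioning correlate with
the *raw* planted topography at only ~0.94 no matter how much data is
pooled. Against the planted pattern *as it exists in post-conditioning
space* (the noiseless scan pushed through the identical chain) recovery
exceeds 0.95 comfortably; the test asserts both, with the raw-pattern bound
relaxed to 0.90.

Other numerical conventions, fixed for bit-reproducibility: frame
thresholding keeps the top `ceiling(0.10 m)` and bottom `ceiling(0.05 m)`
values by rank with ties broken by voxel index (all-equal frames are zeroed
and logged); K-means uses 10 seeded restarts by default, keeps the best
objective, and repairs empty clusters by reseeding at the frame farthest
from its centroid; frame assignment to reference centroids breaks exact
ties toward the lower CAP index; a degenerate size-weighted global centroid
(possible when centroids cancel exactly) is assigned correlation 0 so that
zero-within-spread partitions get EV = 1.

For the voxel-wise genotype × age ANOVA we use Type II sums of squares,
vectorized across voxels: the interaction is dropped when p > 0.05 and main
effects come from the additive refit, mirroring the interaction-dropping
procedure. Post-hoc WT−TG contrasts run per age on interaction-retained
voxels that are significant in at least one group's one-sample map, with
BH-FDR across all tested voxel-age hypotheses followed by the in-plane
cluster-extent rule (8-connected components within a slice, minimum 10
voxels; FDR first, extent second). Temporal metrics use the classical
repeated-measures two-way ANOVA (`aov` with a subject error stratum), age
as the within-subject factor.

## Known limitations

- K-means under correlation distance is a local optimizer; the EV curve is
  only non-decreasing up to restart noise (tested at 1e−6 tolerance).
- The surrogate inter-group test pairs the s-th surrogates of the two
  ensembles; the source material does not specify the pairing, and other
  constructions (e.g. all cross pairs) would change p-value resolution but
  not the statistic.
- The minimal NIfTI-1 reader/writer supports little-endian single-file
  images with scalar datatypes only — sufficient for this pipeline and its
  synthetic cohorts, not a general neuroimaging I/O layer.
- Runtime scales linearly in frames × voxels × K per Lloyd iteration; the
  desk-scale defaults run in minutes on one CPU, but a 2:30 K-range scan at
  full 96×96×12 resolution would call for the restart and K-range controls
  exposed on every entry point.
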