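# capdyn — co-activation pattern analysis of resting-state fMRI

Static functional connectivity averages away how the brain moves between
transient activity states. Co-activation pattern (CAP) analysis treats every
fMRI time frame as a sample of a brain-wide state: frames are z-scored,
thresholded to their activation extremes, pooled across subjects, and
clustered by spatial similarity. The cluster centroids are the brain's
recurring states; the label sequence per scan carries the dynamics. This is
the analysis used to characterize early network-state changes in rodent
models of neurodegeneration — e.g. comparing transgenic (TG) and wild-type
(WT) animals at pre- and early-plaque ages — where the interesting signal
is not *which* states exist but how often they occur, how long they last,
and which state-to-state transitions are preferred.

`capdyn` implements the full pipeline for voxel-level NIfTI data, plus a
synthetic-cohort generator with known ground truth so every stage is
testable without any restricted dataset:

- **Signal conditioning** — frame trimming, 0.01–0.2 Hz zero-phase
  Butterworth band-pass, quadratic detrending, nuisance regression,
  voxel-wise z-scoring (`condition_series()`).
- **CAP extraction** — top-10%/bottom-5% rank thresholding, K-means++ under
  correlation distance minimizing
  `D = Σ_k Σ_{j∈k} (1 − corr(z_j, c_k))²`, explained variance
  `EV = V_B/(V_w+V_B)` with `V_w = D/N`,
  `V_B = (1/N) Σ_k n_k d²(c_k, c)`, elbow selection by the 0.5%
  fractional-gain rule, CAP maps ordered as anti-correlated pairs
  (`extract_caps()`).
- **Statistics** — one-sample T maps (Bonferroni p < 0.01), voxel-wise
  genotype × age ANOVA with interaction dropping, BH-FDR post-hocs with
  in-plane 10-voxel cluster-extent correction, occurrence/duration metrics
  with repeated-measures ANOVA (`one_sample_t_map()`,
  `voxelwise_two_way_anova()`, `rm_anova_temporal()`).
- **Classification** — leakage-controlled ridge multinomial logistic
  regression on CAP spatial or temporal features, 50 stratified 80/20
  splits, shuffled-label chance baseline, Wilcoxon comparison
  (`train_eval()`).
- **Transitions** — group-pooled persistence and non-self transition
  probabilities `p_ij`, 10,000 per-subject label-permutation surrogates,
  FDR-corrected pathway significance, `p_ij` vs `p_ji` directionality, and
  inter-group difference tests (`analyze_transitions()`,
  `intergroup_difference_test()`).

## Worked example

Generate the default synthetic cohort (6 anti-paired states on 500 mask
voxels, Markov persistence 0.85, 8 scans × 980 frames, noise sd 0.3) and
run extraction and transition analysis:

```r
library(capdyn)
states <- state_spec(n_states = 6, n_voxels = 500, seed = 1)
design <- cohort_design(n_per_cell = 2, n_frames = 980, noise_sd = 0.3,
                        states = states, seed = 1)
cohort <- generate_cohort(design)
ex <- extract_caps(cohort$scans, k_range = 2:10, seed = 1, n_restarts = 3)

counts <- count_transitions(ex$sequences, ex$K)
wt4 <- ex$sequences[paste0("WT0", 1:2, ".4M")]
tab <- analyze_transitions(wt4, ex$K, n_surrogates = 1000, seed = 2)
```

This prints (exact output of the code above):

```
elbow K = 6
EV at K: 0.958
occurrence % : 18.3 18.3 17.6 15.9 16.5 13.5
anti-pair correlations: -1.000 -1.000 -1.000
persistence: 0.858 0.870 0.856 0.852 0.859 0.832
significant pathways (WT 4M): 8 of 30
```

Reading the numbers: the fractional-gain elbow recovers the planted 6
states, which explain ~96% of between-frame variance at this noise level
(real data sits far lower — around half — because biological noise dominates);
the six CAPs occur with near-uniform frequency, matching the uniform
stationary distribution of the generator; the three recovered CAP/anti-CAP
pairs are perfect sign-flips (correlation −1); per-CAP persistence estimates
cluster around the planted 0.85; and 8 of the 30 ordered transition pathways
beat the permutation chance level after FDR in this small two-subject group.

The same pipeline runs from one config:

```sh
Rscript inst/cli/capdyn.R all --config run.yaml --out rundir --seed 1
```

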