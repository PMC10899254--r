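# mbcsft

Does soil microbial biomass carbon (MBC) decline under warming? Global
machine-learning extrapolations trained on *spatial* MBC compilations have
reported a temporal decline over 1992–2013 attributed to rising
temperature, while field warming experiments and long-term in-situ
monitoring largely show no consistent MBC response. `mbcsft` implements,
as tested and reproducible building blocks, the three analyses needed to
interrogate that tension:

1. **Effect-size meta-analysis.** Paired warming/control records are
   converted to log response ratios, LN(RR) = ln(MBC_t) − ln(MBC_c), with
   delta-method sampling variances, pooled by a DerSimonian–Laird
   random-effects model overall and within warming-magnitude
   (<1, 1–2, 2–3, 3–4, 4–5 °C) and duration bins, plus a quadratic fit of
   LN(RR) on warming magnitude.
2. **Publication bias.** Egger regression (standardized effect on
   precision) and iterative Duval–Tweedie trim-and-fill with re-pooling.
3. **Long-term site regressions.** Per-site OLS of MBC on annual
   temperature with t-based CIs for 3–10-year series.
4. **The space-for-time (SFT) bootstrap diagnostic.** 200 replicates of an
   m-out-of-n bootstrap (m = 500 of n = 762): each replicate trains a
   Random Forest on ten predictors, predicts global MBC annually for
   1992–2013 under a coverage mask (Mahalanobis distance or dissimilarity
   index), and records the predicted change rate (% yr⁻¹) together with
   the subsample's spatial MBC–temperature slope. A positive correlation
   between the two — steeper spatial gradients predicting steeper
   "temporal" declines — is the fingerprint of space-for-time substitution.

A synthetic-data module generates all three input families with known
ground truth (true bin effects, true temporal sensitivity, injected
publication bias, a world grid whose spatial gradient and temporal
sensitivity are independent dials), so every stage has a
parameter-recovery test. The package is for soil-carbon and global-change
researchers who want these diagnostics as auditable code rather than
one-off scripts.

## Worked example

A synthetic world with a spatial MBC–temperature gradient of
−8 mmol kg⁻¹ °C⁻¹, **zero** true temporal sensitivity, and 0.28 °C of
warming over 1992–2013:

```r
library(mbcsft)

world <- generate_world(world_sim_config(seed = 11))
spatial_slope(world$observations)
#> [1] -8.157775

sft <- bootstrap_sft(world$observations, world$grid,
                     m = 500, reps = 200, seed = 3, num_trees = 200)
sft
#> Space-for-time bootstrap: 200 reps of m = 500 from n = 762 (mahalanobis mask)
#>   mean change rate: -0.0431% yr-1 [-0.0434, -0.0428]
#>   change rate vs spatial slope: Pearson r = 0.477, p = 9.06e-13
```

Although the world's true global MBC series is exactly flat
(`true_global_series(world$grid)` is constant), the forest predicts a
significantly negative change rate, and replicates with steeper spatial
slopes predict steeper declines — a pure space-for-time artifact.
Regenerating the world with `spatial_slope_true = 0` collapses the mean
change rate to a CI covering zero, and augmenting the training set with
flat-gradient observations (`generate_extra_observations()`) shrinks the
artifact.

The meta-analysis side, on a synthetic 130-pair compilation in which only
warming above 4 °C truly reduces MBC:

```r
cfg <- warming_sim_config(
  n_pairs = 130,
  bin_effects = c("<1" = 0, "1-2" = 0.1, "2-3" = 0, "3-4" = 0, "4-5" = -0.3),
  seed = 7)
es <- log_response_ratio(generate_warming_pairs(cfg))
subgroup_analysis(es)[, c("bin", "k", "mu", "ci_low", "ci_high")]
#>   bin  k           mu      ci_low     ci_high
#> 1  <1 22  0.007018072 -0.05920426  0.07324041
#> 2 1-2 35  0.058009061 -0.00869502  0.12471314
#> 3 2-3 24  0.008431619 -0.05287101  0.06973425
#> 4 3-4 27  0.027719294 -0.02791917  0.08335776
#> 5 4-5 22 -0.300552062 -0.36311778 -0.23798634
```

Only the 4–5 °C bin's CI excludes zero from below: the pooled effects
recover the generating truth, including the absence of any decline at
realistic warming magnitudes.

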