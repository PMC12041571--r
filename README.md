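# comboscreen

Simulation and machine-learning analysis of drug-combination synergy
screens.

High-throughput combination screens test every unordered pair of a panel of
active compounds in duplicate 10×10 dose–response blocks and summarise each
block with a gamma-style synergy score (γ = 1 for no interaction, γ < 0.95
synergistic, γ < 0.5 strongly synergistic). Models trained on such a screen
— e.g. 32 actives → 496 combinations — are then used to rank millions of
virtual candidate pairs for prospective testing. `comboscreen` implements
that workflow end to end for anyone building or benchmarking combination
models:

- **Synthetic screens** with a known mechanism-of-action (MoA) ground
  truth: compound library with SMILES, potencies and MoA annotations;
  duplicate dose–response blocks; gamma scores with calibrated replicate
  correlation (`generate_library()`, `simulate_screen()`,
  `calibrate_noise()`).
- **Reference-model synergy surfaces**: Bliss independence
  `s(A) + s(B) − s(A)s(B)`, highest single agent, and excess summaries over
  10×10 blocks (`bliss_expected()`, `hsa_expected()`, `excess_surface()`).
- **Pair featurization**: circular and path fingerprints, physicochemical
  descriptors, element-wise average/sum composition, MoA presence vectors,
  potency appending, mixture graphs; pluggable registry for external
  descriptor tables.
- **Combination-aware validation**: one-compound-out and everything-out
  folds, Y-randomization, rank-based AUC, confusion metrics with the
  published rounding conventions (`one_compound_out_folds()`,
  `confusion_metrics()`, `roc_auc()`, `hit_rate()`).
- **Learners and consensus**: bagged trees, boosted trees and a
  feed-forward network (implemented natively), regression
  pseudo-probabilities, average/majority consensus, and a multi-task
  surrogate scoring pairs by the Bliss residual
  `c(AB) − (s(A)+s(B)−s(A)s(B))` (`fit_predict()`,
  `surrogate_combo_model()`).
- **Nomination**: plain top-k, quota'd three-tier selection, and
  diversity-capped top-k (at most five appearances per compound).
- **MoA networks**: co-occurrence networks over synergistic combinations
  with a permutation null and per-edge significance
  (`build_network()`, `permutation_null()`, `empirical_significance()`).

Everything is tibble-in/tibble-out and pipe-friendly; result objects have
`tidy()`/`glance()` methods and `autoplot()` for blocks and networks.

## Worked example

Simulate a screen whose replicate agreement is calibrated to Pearson
r ≈ 0.83, then cross-validate a synergy classifier compound-out:

```r
library(comboscreen)

lib     <- generate_library(screen_config(n_library = 160), seed = 7)
actives <- dplyr::filter(lib, is_active)
truth   <- calibrate_noise(actives, default_truth_model(actives, seed = 7),
                           target_pearson = 0.83, seed = 7)
screen  <- simulate_screen(actives, truth, seed = 7)
rec     <- screen$records
head(rec, 3)
#> # A tibble: 3 × 7
#>   compound_1 compound_2 gamma_rep1 gamma_rep2 gamma_mean label
#> 1 CMPD-0001  CMPD-0005        1.09      1.12       1.11  FALSE
#> 2 CMPD-0001  CMPD-0006        1.07      0.727      0.898 TRUE
#> 3 CMPD-0001  CMPD-0007        1.04      1.05       1.05  FALSE
cor(rec$gamma_rep1, rec$gamma_rep2)
#> [1] 0.82
mean(rec$label)
#> [1] 0.601

feats <- featurize_pairs(rec, actives, descriptor_name = "none",
                         moa = TRUE, potency = TRUE,
                         vocabulary = moa_vocabulary(lib))
folds <- one_compound_out_folds(actives, rec)
cv    <- cross_validate(folds, feats, rec,
                        learner_spec("bagged_trees", "classification"), seed = 7)
cv$auc
#> [1] 0.813
```

The 496 rows of `rec` are the screen: one canonical pair per row, two
replicate gammas, their mean, and the γ < 0.95 synergy label. 60% of pairs
come out synergistic because the generator's default truth places negative
effects on the most frequent mechanism pairs among the actives. The
one-compound-out AUC of 0.81 says the classifier ranks combinations of a
*withheld* compound largely correctly from mechanism and potency features;
the same pipeline on Y-randomized labels (`y_randomize(rec)`) gives AUC
≈ 0.5.

The full driver — simulate, featurize, cross-validate, score a virtual
candidate pool, nominate three ways, evaluate hit rates against the
generator's truth, and run the MoA network analysis — is one call:

```r
res <- run_pipeline(pipeline_config(), seed = 1, out_dir = "run")
```

writing `compounds.csv`, `combinations.csv`, `predictions.csv`, nomination
lists, `metrics.csv`, `hit_rates.csv`, the network edge list/GraphML and a
manifest with the seed and config hash.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from the installed package
— library generation, noise calibration, the duplicate screen, compound-out
cross-validation with a Y-randomized control, candidate scoring, nomination
and the network analysis — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Run artifacts land next to the report under `results/run/`.
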