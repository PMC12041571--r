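---
title: "Simulating and modelling drug-combination synergy screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and modelling drug-combination synergy screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboscreen)
```

## The problem

All-vs-all combination matrix screens test every unordered pair of a small
set of active compounds in dose-response blocks and summarise each block
with a synergy score. In the screen geometry this package emulates, 32
active anticancer compounds (log10 IC50 between -8.7 and -5.5, i.e. roughly
2 nM to 3 µM) produce 32·31/2 = 496 combinations, each screened twice as a
10×10 block: a vehicle well plus nine 1:2 serial dilutions per compound,
with the concentration range placed so the IC50 falls mid-range. The
platform's gamma score is 1 for non-interacting pairs; `gamma < 0.95` is
called synergistic and `gamma < 0.5` strongly synergistic, with the boundary
value classified non-synergistic. Machine-learning models trained on the 496
labelled pairs are then asked to rank a virtual library of ~1.6 million
candidate pairs, and the top nominations go back into the lab.

The package implements this whole workflow — synthetic screen generation,
pair featurization, combination-aware cross-validation, learner consensus,
nomination, and mechanism-of-action (MoA) network analysis — as composable
tibble-in/tibble-out functions, with `run_pipeline()` as the end-to-end
driver.

## The synthetic screen: a stated world

Real combination screens cannot ship inside a package, so every downstream
stage is exercised against a generator whose right answers are known by
construction.

* **Library.** `generate_library()` draws structures from a bundled list of
  48 valid drug-like SMILES, cycled with homologation variants (prepending
  methylenes), to the configured library size (default 1785 compounds, 821
  MoA vocabulary entries, 32 actives — the emulated screen's values). Each
  base scaffold carries a primary mechanism drawn from a rank-skewed
  distribution (`1/rank^1.2`), so mechanisms are redundant across the
  library as in a real annotated collection and structure is informative of
  mechanism; compounds carry 1–2 labels. Actives sit on distinct scaffolds
  so their fingerprints are distinguishable.
* **Truth model.** Gamma for a pair is
  `baseline + sum(MoA-pair effects) + pair noise + replicate noise`, clipped
  to [0, 2]. `default_truth_model()` puts negative effects (uniform in
  [-0.5, -0.2]) on the eight most frequent cross-compound mechanism pairs of
  the actives. The resulting screens have roughly half of pairs synergistic
  with a minority strongly so, matching the prevalence of the emulated
  screen (256 of 496, 26 strong).
* **Noise calibration.** The emulated assay reproduces at a replicate
  Pearson correlation of about 0.83. `calibrate_noise()` sets the
  replicate-level noise by bisection over simulated screens until the
  correlation is on target; pair-level noise (shared by both replicates)
  defaults to sd 0.08 and is what keeps replicates from agreeing perfectly
  with the mechanism signal alone.
* **Dose-response blocks.** `simulate_matrix()` builds margins from Hill
  curves (slope 1, maximal inhibition 0.7 — the screen's actives reach at
  least 50% efficacy) and interiors as the Bliss expectation of the margins
  plus `kappa·(1 - gamma)` on nonzero-dose cells, `kappa = 0.25`. Gamma is
  simulated directly rather than derived from the blocks, because the
  platform's exact gamma formula is published elsewhere and not
  re-implemented here; the blocks are generated *consistently* (excess-Bliss
  proportional to `1 - gamma`), which the tests verify as a negative
  Spearman correlation, not as exact functional agreement.

A green test suite therefore establishes that the pipeline recovers
mechanism-driven synergy structure it was pointed at, with realistic
prevalence and replicate noise. It does not establish performance on real
chemistry: the synthetic structure–mechanism link is cleaner than nature's,
single-agent curves are ideal Hill curves, and the virtual library reuses
scaffolds.

## Featurization

`featurize_pairs()` composes per-compound descriptors into pair vectors by
element-wise average or sum (both order-invariant). The descriptor registry
ships Morgan-style circular fingerprints (radius 2; 1024/2048 bits),
path-based fingerprints of the same shape (registered under the avalon-*
names; the original Avalon algorithm is toolkit-specific and is represented
here by a linear-path family), a small physicochemical battery, the
821-dimensional MoA presence vector (union encoding: a mechanism shared by
both compounds contributes a single 1), and canonical-ordered appending of
the two log IC50 values. External descriptor families plug in from CSV via
`register_descriptor_csv()` without touching callers. `mixture_graph()`
builds the block-diagonal direct sum of two molecules' adjacency matrices
with stacked node features for graph-based models.

Because no cheminformatics toolkit is assumed, the package carries its own
minimal SMILES parser covering the organic subset, bracket atoms, branches
and ring closures; it is strict by design — a structure that does not parse
is an error naming the compound, never a silent zero vector.

## Validation and learners

Pair data leak through shared compounds, so random pair splits flatter the
models. `one_compound_out_folds()` gives one fold per compound (validation =
every pair containing it: 32 folds of 31 pairs for the full screen, every
pair validated twice); `everything_out_folds()` partitions compounds into
groups and validates only pairs with both members unseen.
`y_randomize()` permutes the responses to give the no-signal baseline.

Three learner families are implemented natively (the environment provides
no tree-ensemble or neural-network package): bagged CART-style trees with
per-node feature subsampling (`mtry = sqrt(p)`, the random-forest
convention), gradient-boosted trees with Newton leaf values (default
learning rate 0.01, the screen's tuned value), and a dense feed-forward
network trained with Adam (default hidden layers 700/500/300, learning rate
1e-4, batch 128, 70 epochs — the published architecture; the default
pipeline uses the tree learners, which reach the same out-of-fold AUC on
the synthetic screen in a fraction of the time). Split search is vectorised
across all candidate (feature, threshold) columns simultaneously, which is
what makes pure-R tree induction practical on fingerprint matrices.

Classifier probabilities and regression pseudo-probabilities (min-max scale
the predicted gammas, then `1 - scaled`, so the lowest gamma maps to 1) are
combined by `average_consensus()`; `majority_vote()` is the secondary rule,
with an even split called synergistic. The min-max scale is computed over
the prediction batch being converted — the alternative (training-range
scaling) is not used, and the scope is recorded in the result's attributes.

The multi-task surrogate (`surrogate_combo_model()`) is a shared-encoder
network: compound fingerprints (or a fixed seeded graph-convolution
embedding — the trainable stack sits on top of it, a desk-scale choice)
feed a tanh encoder; a single-agent head predicts each compound's inhibition
at a reference dose and a combination head predicts the pair's inhibition
from summed embeddings. Its synergy score is the Bliss residual
`c(AB) - (s(A) + s(B) - s(A)s(B))`, higher = more synergistic, bounded in
[-1, 1] with all outputs squashed to [0, 1]. Auxiliary screens can be
attached as extra combination heads to emulate multi-task pretraining.

## Nomination and the MoA network

`topk_nomination()` takes the k highest scores (ties to the canonical
earlier key). `tiered_nomination()` applies fixed quotas of 12/12/6:
tier 1 — consensus score > 0.7, both compounds active, exactly one in
training, mechanism pair among the selected synergistic MoA pairs
(`synergistic_moa_pairs()`: at least 3 representative training pairs and
mean label ≥ 0.66, computed over the compounds' primary mechanisms); tier 2
— best descriptor-only candidates whose mechanism pair is *not* selected;
tier 3 — best consensus candidates with neither compound in training.
Shortfalls are reported, never backfilled across tiers, so the quotas stay
mutually exclusive. `diversity_capped_topk()` walks the ranking greedily,
skipping pairs that would push a compound past five appearances.

`build_network()` counts mechanisms and cross-compound mechanism pairs over
the synergistic records (full label cross-product by default; switchable to
primary-only). `permutation_null()` draws the same number of distinct random
pairs from the same compound pool (without replacement within a replicate,
mirroring a set of distinct combinations) and tabulates null edge counts.

## Numerical choices

* Boundary gamma = 0.95 is non-synergistic; mean gamma over replicates is
  the unweighted arithmetic mean.
* Published-style metric tables round to 2 decimals, half away from zero
  (`format_metrics()`); undefined ratios (0/0) are `NA`, never 0 — note that
  an NPV printed as 0.00 can still be the defined value 0/1.
* CCR is reported as balanced accuracy (mean of sensitivity and
  specificity); the terms are used synonymously.
* `empirical_significance()` returns the add-one permutation p-value
  `(1 + #{null ≥ obs}) / (1 + n)` *and* a normal-tail p from the null's
  mean/sd. The two differ in the tail: for a null with mean ≈ 4.3 and
  sd ≈ 1.9, an observed count of 9 has an exact permutation tail of ~0.02
  but a mean/sd normal tail below 0.01 — the form in which screen analyses
  typically quote such results. Both are reported so the user can choose.
* CSV round-trips are exact: doubles are written with 17 significant digits
  and re-parsed through base `strtod` (the fast vroom float path can be one
  ulp off).
* All randomness flows from one root seed, split per stage by a hash, so a
  single integer reproduces a full run; derived seeds stay below 2^31.

## Limitations

The gamma formula is modelled, not reproduced; dose-response blocks are
consistent with gamma but not derived from a response-surface fit. Learner
implementations favour clarity and desk-scale speed over large-scale
performance. The structure–mechanism association in the generator is
stronger than in real libraries, so absolute AUCs on synthetic screens
should not be read as estimates of real-screen performance — the package's
validation claims are about *relative* structure (signal vs. Y-randomized
baseline, fold leakage, recoverability of planted effects).
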