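# Synthetic combination screen generator.
#
# Emulates an annotated-oncology-library combination screen: a large
# annotated virtual library, a small set of active compounds with log10(IC50)
# in a stated range, duplicate 10x10 combination blocks, and gamma-style
# synergy scores driven by a known mechanism-of-action ground truth. The
# generator's job is to give every downstream stage (featurization,
# cross-validation, consensus, nomination, network analysis) a world whose
# right answers are known by construction.

# Drug-like base structures the generator cycles over. All parse with
# parse_smiles(); variants are built by homologation (prepending methylenes)
# so fingerprints differ between variants of one base while the scaffold --
# and hence the assigned mechanism -- is shared.
BUNDLED_SMILES <- c(
  "CC(=O)Oc1ccccc1C(=O)O",            # acetylsalicylic acid
  "CC(=O)Nc1ccc(O)cc1",               # paracetamol
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",       # ibuprofen
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",       # caffeine
  "Clc1ccccc1C(=O)Nc1ccncc1",         # amide-linked pyridine
  "COc1ccc2cc(ccc2c1)C(C)C(=O)O",     # naproxen
  "NC(=O)c1ccc(N)cc1",                # aminobenzamide
  "OC(=O)c1ccccc1O",                  # salicylic acid
  "Nc1ncnc2c1ncn2C1CCCCO1",           # nucleoside-like
  "CC1=CC(=O)C=CC1=O",                # quinone
  "COc1cc2c(cc1OC)CC(N)C2",           # aminotetralin
  "CN1CCC(CC1)Oc1ccccc1",             # piperidine ether
  "Fc1ccc(cc1)C(=O)c1ccc(F)cc1",      # difluorobenzophenone
  "O=C(Nc1ccccc1)c1cccnc1",           # nicotinanilide
  "CC(C)NCC(O)c1ccc(O)c(O)c1",        # catecholamine-like
  "Clc1ccc(cc1)S(=O)(=O)N",           # sulfonamide
  "CCOC(=O)c1ccccc1N",                # benzocaine-like
  "CN(C)CCc1ccccc1",                  # phenethylamine
  "OCC1OC(O)C(O)C(O)C1O",             # sugar
  "CC(N)Cc1ccc(O)cc1",                # tyramine-like
  "O=C1NC(=O)NC(=O)C1",               # barbituric core
  "c1ccc2[nH]ccc2c1",                 # indole
  "CCN(CC)C(=O)c1ccc(N)cc1",          # procainamide-like
  "COc1ccccc1OCCN",                   # guaiacol amine
  "CC(C)(C)NCC(O)c1ccc(O)cc1",        # beta-agonist-like
  "N#Cc1ccc(cc1)C1CCNCC1",            # nitrile piperidine
  "O=C(O)CCc1ccccc1",                 # phenylpropanoate
  "Cc1ccc(cc1)S(=O)(=O)Nc1ncccn1",    # sulfa-pyrimidine
  "OC(c1ccccc1)c1ccccc1",             # benzhydrol
  "CN1CCN(CC1)c1ccccc1",              # phenylpiperazine
  "O=C1CCCCC1Cc1ccccc1",              # benzylcyclohexanone
  "Nc1ccc(cc1)C(=O)O",                # PABA
  "CSc1ccccc1N",                      # thioanisole amine
  "O=C(Cc1ccccc1)Nc1ccccc1",          # phenylacetanilide
  "CCOc1ccc(cc1)NC(=O)C",             # phenacetin
  "Oc1ccc2ccccc2c1",                  # naphthol
  "CC(=O)c1ccc(OC)cc1",               # methoxyacetophenone
  "NCCc1c[nH]c2ccccc12",              # tryptamine
  "OC(=O)C1CCCN1",                    # proline
  "Clc1cccc(Cl)c1N",                  # dichloroaniline
  "CC1CCC(CC1)NC(=O)c1ccco1",         # furan amide (o aromatic)
  "CN(C)c1ccc(cc1)C=O",               # DMAB aldehyde
  "OCCN1CCN(CC1)c1ccc(F)cc1",         # fluorophenylpiperazine
  "CC(C)Oc1ccccc1C(=O)N",             # isopropoxybenzamide
  "Nc1nc2ccccc2s1",                   # aminobenzothiazole
  "O=C(O)c1cccc(c1)C(=O)O",           # isophthalic acid
  "CCCCOc1ccc(cc1)C(=O)OC",           # butoxy ester
  "Cc1ccccc1NC(=O)CN1CCCC1"           # pyrrolidine acetanilide
)

# a handful of field-standard mechanism names head the vocabulary; the rest
# are generic placeholders
moa_vocabulary_names <- function(n) {
  stems <- c(
    "proteasome inhibitor", "HDAC inhibitor", "PLK1 inhibitor",
    "mTOR inhibitor", "tubulin inhibitor", "topoisomerase inhibitor",
    "CDK inhibitor", "HSP90 inhibitor", "survivin inhibitor",
    "p53 activator", "BET inhibitor", "AKT inhibitor", "MEK inhibitor",
    "EGFR inhibitor", "PI3K inhibitor", "aurora kinase inhibitor",
    "BCL2 inhibitor", "PARP inhibitor", "DNA alkylator", "antimetabolite"
  )
  if (n <= length(stems)) return(stems[seq_len(n)])
  c(stems, sprintf("mechanism_%03d", seq_len(n - length(stems))))
}

#' Configuration of a synthetic combination screen
#'
#' Defaults state the emulated screen: 1785 library compounds with 821
#' distinct mechanism annotations, 32 of them active with log10(IC50)
#' uniform between -8.7 and -5.5 (about 2 nM to 3 uM), combinations tested
#' in duplicate.
#'
#' @param n_active Number of active (screened) compounds.
#' @param n_library Total virtual library size.
#' @param n_moas Mechanism vocabulary size.
#' @param log_ic50_range Lower/upper bounds of active-compound log10 IC50.
#' @param n_replicates Combination-screen replicates.
#' @return A `screen_config` list.
#' @export
screen_config <- function(n_active = 32, n_library = 1785, n_moas = 821,
                          log_ic50_range = c(-8.7, -5.5), n_replicates = 2) {
  stopifnot(
    n_active >= 2, n_library >= n_active, n_moas >= 2,
    length(log_ic50_range) == 2, log_ic50_range[1] < log_ic50_range[2],
    n_replicates >= 1
  )
  structure(list(
    n_active = as.integer(n_active), n_library = as.integer(n_library),
    n_moas = as.integer(n_moas), log_ic50_range = log_ic50_range,
    n_replicates = as.integer(n_replicates)
  ), class = "screen_config")
}

#' Mechanism-driven ground truth of the synthetic screen
#'
#' Gamma for a pair is simulated as
#' `baseline + sum(effects over the pair's cross-compound MoA pairs) +
#' pair noise + replicate noise`, clipped to `[0, 2]`. Negative effects push
#' gamma below 1, i.e. towards synergy.
#'
#' @param effects Tibble with columns `moa_1`, `moa_2`, `effect`
#'   (unordered mechanism pairs; may be empty).
#' @param baseline_gamma_mean Gamma of a non-interacting pair, default 1.
#' @param replicate_noise_sd Per-replicate technical noise sd.
#' @param compound_noise_sd Per-pair biological noise sd (shared by both
#'   replicates of a pair; this is what makes replicates correlate less than
#'   perfectly while still agreeing with each other).
#' @param seed Seed used when the truth model itself is sampled.
#' @return A `truth_model` list.
#' @export
truth_model <- function(effects = tibble(moa_1 = character(), moa_2 = character(),
                          effect = numeric()),
                        baseline_gamma_mean = 1.0, replicate_noise_sd = 0.05,
                        compound_noise_sd = 0.08, seed = 1L) {
  effects <- as_tibble(effects)
  stopifnot(
    all(c("moa_1", "moa_2", "effect") %in% names(effects)),
    all(is.finite(effects$effect)),
    replicate_noise_sd >= 0, compound_noise_sd >= 0,
    is.finite(baseline_gamma_mean)
  )
  # canonical unordered mechanism pairs
  m1 <- pmin(effects$moa_1, effects$moa_2)
  m2 <- pmax(effects$moa_1, effects$moa_2)
  effects$moa_1 <- m1
  effects$moa_2 <- m2
  structure(list(
    effects = effects, baseline_gamma_mean = baseline_gamma_mean,
    replicate_noise_sd = replicate_noise_sd,
    compound_noise_sd = compound_noise_sd, seed = as.integer(seed)
  ), class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf(
    "<truth_model> %d MoA-pair effects, baseline %.2f, rep sd %.3f, pair sd %.3f\n",
    nrow(x$effects), x$baseline_gamma_mean, x$replicate_noise_sd, x$compound_noise_sd
  ))
  invisible(x)
}

#' Generate the synthetic compound library
#'
#' Structures are drawn deterministically (seeded) from a bundled list of
#' valid drug-like SMILES, cycled with homologation variants. Each base
#' scaffold carries a primary mechanism drawn from a rank-skewed distribution
#' over the vocabulary (so mechanisms are redundant across the library, as in
#' a real annotated collection, and structure is informative of mechanism);
#' compounds carry 1-2 mechanism labels. Exactly `n_active` compounds --
#' all on distinct scaffolds -- are flagged active with log IC50 uniform in
#' the configured range.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed; identical seed reproduces the library exactly.
#' @return Compound tibble: `id`, `smiles`, `log_ic50`, `moa` (list-column),
#'   `is_active`, `in_training`.
#' @export
generate_library <- function(config = screen_config(), seed = 1L) {
  if (length(BUNDLED_SMILES) == 0) abort("Bundled SMILES list is empty.")
  vocab <- moa_vocabulary_names(config$n_moas)
  nb <- length(BUNDLED_SMILES)
  with_seed(seed, {
    # rank-skewed mechanism frequencies: a few mechanisms recur often
    wts <- 1 / seq_len(config$n_moas)^1.2
    base_primary <- sample(vocab, nb, replace = TRUE, prob = wts)
    i <- seq_len(config$n_library)
    base_idx <- ((i - 1L) %% nb) + 1L
    variant <- (i - 1L) %/% nb
    smiles <- vapply(i, function(k) {
      s <- BUNDLED_SMILES[base_idx[k]]
      v <- variant[k] %% 3L
      if (v > 0 && startsWith(s, "C") && !startsWith(s, "Cl")) {
        s <- paste0(strrep("C", v), s)
      }
      s
    }, character(1))
    primary <- base_primary[base_idx]
    has_secondary <- runif(config$n_library) < 0.5
    secondary <- sample(vocab, config$n_library, replace = TRUE, prob = wts)
    moa <- lapply(i, function(k) {
      if (has_secondary[k] && secondary[k] != primary[k]) {
        c(primary[k], secondary[k])
      } else {
        primary[k]
      }
    })
    # actives sit on distinct scaffolds so their fingerprints are distinct
    present_bases <- unique(base_idx)
    active_bases <- sample(present_bases, min(config$n_active, length(present_bases)))
    active_idx <- integer(0)
    for (bidx in active_bases) {
      cand <- which(base_idx == bidx)
      active_idx <- c(active_idx, cand[sample.int(length(cand), 1)])
    }
    extra_needed <- config$n_active - length(active_idx)
    if (extra_needed > 0) {
      pool <- setdiff(i, active_idx)
      active_idx <- c(active_idx, sample(pool, extra_needed))
    }
    is_active <- i %in% active_idx
    log_ic50 <- runif(
      config$n_library, -5.5, -4.0 # weakly potent background
    )
    log_ic50[is_active] <- runif(
      sum(is_active), config$log_ic50_range[1], config$log_ic50_range[2]
    )
    tibble(
      id = sprintf("CMPD-%04d", i),
      smiles = smiles,
      log_ic50 = log_ic50,
      moa = moa,
      is_active = is_active,
      in_training = is_active
    )
  })
}

# sum of truth effects over the cross-compound MoA pair cross-product
pair_effects <- function(pairs, compounds, truth) {
  moa_sets <- setNames(
    lapply(seq_len(nrow(compounds)), function(i) moa_labels(compounds[i, ])),
    compounds$id
  )
  if (nrow(truth$effects) == 0) return(numeric(nrow(pairs)))
  eff_map <- setNames(
    truth$effects$effect,
    pair_id(truth$effects$moa_1, truth$effects$moa_2)
  )
  vapply(seq_len(nrow(pairs)), function(r) {
    ma <- moa_sets[[pairs$compound_1[r]]]
    mb <- moa_sets[[pairs$compound_2[r]]]
    if (length(ma) == 0 || length(mb) == 0) return(0)
    cross <- expand.grid(ma, mb, stringsAsFactors = FALSE)
    keys <- unique(pair_id(pmin(cross[[1]], cross[[2]]), pmax(cross[[1]], cross[[2]])))
    sum(eff_map[keys], na.rm = TRUE)
  }, numeric(1))
}

#' Simulate the combination screen over the active compounds
#'
#' One synergy record per unordered pair of actives, with per-replicate gamma
#' scores and (optionally) matching duplicate 10x10 dose-response blocks
#' whose excess-Bliss inhibition is proportional to `1 - gamma`.
#'
#' @param actives Compound tibble (all rows treated as screened actives).
#' @param truth A [truth_model()].
#' @param n_replicates Number of replicates (default 2).
#' @param seed Integer seed.
#' @param matrices Also simulate the dose-response blocks (default FALSE;
#'   they are not needed for the score-level pipeline).
#' @param matrix_noise_sd Per-well noise for simulated blocks.
#' @return List with `records` (synergy-record tibble, plus a `gamma_true`
#'   column holding the noise-free mechanism-driven gamma) and `matrices`
#'   (list of [drc_matrix()] or NULL).
#' @export
simulate_screen <- function(actives, truth, n_replicates = 2, seed = 1L,
                            matrices = FALSE, matrix_noise_sd = 0.01) {
  actives <- as_tibble(actives)
  pairs <- enumerate_pairs(actives)
  eff <- pair_effects(pairs, actives, truth)
  gamma_true <- truth$baseline_gamma_mean + eff
  n <- nrow(pairs)
  gam <- with_seed(seed, {
    pair_noise <- rnorm(n, 0, truth$compound_noise_sd)
    g <- matrix(0, n, n_replicates)
    for (r in seq_len(n_replicates)) {
      g[, r] <- gamma_true + pair_noise + rnorm(n, 0, truth$replicate_noise_sd)
    }
    pmin(pmax(g, 0), 2)
  })
  records <- synergy_records(pairs, gam)
  # synergy_records sorts canonically; pairs from enumerate_pairs already are
  records$gamma_true <- pmin(pmax(gamma_true, 0), 2)
  mats <- NULL
  if (matrices) {
    by_id <- setNames(seq_len(nrow(actives)), actives$id)
    mats <- vector("list", n * n_replicates)
    k <- 1L
    for (r in seq_len(n_replicates)) {
      grep_col <- paste0("gamma_rep", r)
      for (p in seq_len(n)) {
        a <- actives[by_id[records$compound_1[p]], ]
        b <- actives[by_id[records$compound_2[p]], ]
        mats[[k]] <- simulate_matrix(
          a, b,
          gamma = records[[grep_col]][p], noise_sd = matrix_noise_sd,
          seed = derive_seed(seed, sprintf("mat-%d-%d", p, r)), replicate = r
        )
        k <- k + 1L
      }
    }
  }
  list(records = records, matrices = mats)
}

#' Default mechanism-driven truth for a set of actives
#'
#' Picks the most frequent cross-compound mechanism pairs among the actives
#' and assigns them synergistic effects, so the simulated screen contains a
#' learnable, recoverable mechanism signal with realistic prevalence
#' (roughly half of pairs synergistic, a minority strongly so).
#'
#' @param actives Active compound tibble.
#' @param n_pairs Number of mechanism pairs given effects.
#' @param effect_range Range of (negative) effects.
#' @param ... Passed through to [truth_model()].
#' @param seed Integer seed.
#' @return A [truth_model()].
#' @export
default_truth_model <- function(actives, n_pairs = 8,
                                effect_range = c(-0.5, -0.2), seed = 1L, ...) {
  counts <- moa_pair_counts(enumerate_pairs(actives), actives)
  counts <- dplyr::arrange(counts, dplyr::desc(.data$n), .data$moa_1, .data$moa_2)
  take <- head(counts, n_pairs)
  effects <- with_seed(derive_seed(seed, "truth"), tibble(
    moa_1 = take$moa_1, moa_2 = take$moa_2,
    effect = runif(nrow(take), effect_range[1], effect_range[2])
  ))
  truth_model(effects, seed = seed, ...)
}

# frequency of cross-compound MoA pairs over a pair table
moa_pair_counts <- function(pairs, compounds) {
  moa_sets <- setNames(
    lapply(seq_len(nrow(compounds)), function(i) moa_labels(compounds[i, ])),
    compounds$id
  )
  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    ma <- moa_sets[[pairs$compound_1[r]]]
    mb <- moa_sets[[pairs$compound_2[r]]]
    if (length(ma) == 0 || length(mb) == 0) return(NULL)
    cross <- expand.grid(ma, mb, stringsAsFactors = FALSE)
    tibble(
      moa_1 = pmin(cross[[1]], cross[[2]]),
      moa_2 = pmax(cross[[1]], cross[[2]])
    ) |> dplyr::distinct()
  })
  dplyr::count(rows, .data$moa_1, .data$moa_2)
}

#' Calibrate replicate noise to a target replicate correlation
#'
#' Adjusts `replicate_noise_sd` by bisection over simulated screens until the
#' replicate-1 vs replicate-2 Pearson correlation of gamma is within
#' tolerance of the target (the emulated assay reproduces at r ~ 0.83).
#'
#' @param actives Active compound tibble.
#' @param truth A [truth_model()].
#' @param target_pearson Target replicate correlation in (0, 1).
#' @param tol Acceptable deviation (default 0.02; the assay statement is
#'   +/- 0.05).
#' @param seed Integer seed for the calibration simulations.
#' @param max_iter Bisection iterations.
#' @return The truth model with `replicate_noise_sd` replaced.
#' @export
calibrate_noise <- function(actives, truth, target_pearson = 0.83,
                            tol = 0.02, seed = 1L, max_iter = 40) {
  stopifnot(target_pearson > 0, target_pearson < 1)
  sim_cor <- function(sd) {
    t2 <- truth
    t2$replicate_noise_sd <- sd
    rec <- simulate_screen(actives, t2, n_replicates = 2, seed = seed)$records
    if (sd(rec$gamma_rep1) < 1e-12 || sd(rec$gamma_rep2) < 1e-12) {
      return(NA_real_)
    }
    cor(rec$gamma_rep1, rec$gamma_rep2)
  }
  r0 <- sim_cor(1e-6)
  if (is.na(r0) || r0 < target_pearson) {
    abort(paste(
      "Target replicate correlation is unattainable:",
      "the screen has (almost) no between-pair gamma variance."
    ), class = "comboscreen_calibration_error")
  }
  lo <- 1e-6
  hi <- 1
  while (!is.na(sim_cor(hi)) && sim_cor(hi) > target_pearson && hi < 32) hi <- hi * 2
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- sim_cor(mid)
    if (is.na(r)) break
    if (abs(r - target_pearson) <= tol / 2) {
      lo <- hi <- mid
      break
    }
    if (r > target_pearson) lo <- mid else hi <- mid
  }
  out <- truth
  out$replicate_noise_sd <- (lo + hi) / 2
  out
}
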