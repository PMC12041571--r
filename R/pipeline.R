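# End-to-end pipeline driver.
#
# simulate -> featurize -> cross-validate -> fit on the full screen -> score
# a virtual candidate pool -> nominate -> evaluate hit rates against the
# synthetic ground truth -> mechanism network analysis. Every stage is a
# plain function call; run_pipeline() wires them together, derives one seed
# per stage from the root seed, writes all artifacts and a manifest.

#' Assemble a pipeline configuration
#'
#' Defaults are desk-scale: a reduced library and candidate pool so the full
#' pipeline runs in minutes on one CPU, with the screen geometry (32 actives,
#' duplicate blocks, potency range) kept at the emulated screen's values.
#'
#' @param screen A [screen_config()].
#' @param truth A [truth_model()] or NULL to derive a default mechanism-driven
#'   truth from the generated actives.
#' @param calibrate_replicate_cor Target replicate Pearson correlation
#'   (NULL skips calibration).
#' @param featurization List: `descriptor`, `composition`, `moa`, `potency`.
#' @param learners Named list of [learner_spec()]s fitted and combined by
#'   average consensus (regression learners pass through
#'   [regression_to_pseudo_probability()]).
#' @param validation List: `scheme` (`"one_compound_out"` or
#'   `"everything_out"`), `n_groups`, `y_randomize` (also run the label-
#'   permuted control).
#' @param n_candidates Size of the virtual candidate pool sampled from the
#'   library (excluding training pairs) for scoring and nomination.
#' @param nomination List: `k`, `per_compound_cap`, `consensus_cutoff`,
#'   `quotas`.
#' @param network List: `gamma_cutoff`, `n_reps` (permutation replicates).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(screen = screen_config(n_library = 160),
                            truth = NULL,
                            calibrate_replicate_cor = 0.83,
                            featurization = list(
                              descriptor = "none", composition = "average",
                              moa = TRUE, potency = TRUE
                            ),
                            learners = list(
                              clf = learner_spec("bagged_trees", "classification"),
                              reg = learner_spec("bagged_trees", "regression")
                            ),
                            validation = list(
                              scheme = "one_compound_out", n_groups = 2,
                              y_randomize = FALSE
                            ),
                            n_candidates = 1500,
                            nomination = list(
                              k = 30, per_compound_cap = 5,
                              consensus_cutoff = 0.7, quotas = c(12, 12, 6)
                            ),
                            network = list(gamma_cutoff = 0.95, n_reps = 200)) {
  stopifnot(inherits(screen, "screen_config"))
  for (l in learners) {
    if (!inherits(l, "learner_spec")) {
      abort("`learners` must be a list of learner_spec objects (field: learners).")
    }
  }
  if (!validation$scheme %in% c("one_compound_out", "everything_out")) {
    abort(sprintf("Unknown validation scheme '%s' (field: validation$scheme).", validation$scheme))
  }
  structure(list(
    screen = screen, truth = truth,
    calibrate_replicate_cor = calibrate_replicate_cor,
    featurization = featurization, learners = learners,
    validation = validation, n_candidates = n_candidates,
    nomination = nomination, network = network
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(config, control = "all"), collapse = "")
  sprintf("%010.0f", hash_string(txt))
}

pipeline_features <- function(pairs, compounds, feat, vocabulary) {
  featurize_pairs(
    pairs, compounds,
    descriptor_name = feat$descriptor %||% "none",
    composition = feat$composition %||% "average",
    moa = isTRUE(feat$moa), potency = isTRUE(feat$potency),
    vocabulary = vocabulary
  )
}

# out-of-fold consensus: average the learners' CV scores, flipping regression
# gamma predictions into pseudo-probabilities first
oof_consensus <- function(cv_list, learners) {
  mat <- do.call(cbind, lapply(names(cv_list), function(nm) {
    s <- cv_list[[nm]]$scores
    if (learners[[nm]]$task == "regression") {
      rng <- range(s, na.rm = TRUE)
      s <- if (diff(rng) > 1e-12) 1 - (s - rng[1]) / diff(rng) else s * 0 + 0.5
    }
    s
  }))
  rowMeans(mat)
}

# fit all configured learners on train rows, emit the average consensus over
# the given test features
consensus_scores <- function(learners, features_train, records_train,
                             features_test, test_pairs, seed) {
  sets <- list()
  for (nm in names(learners)) {
    fit <- fit_predict(
      learners[[nm]], features_train, records_train, features_test,
      test_pairs = test_pairs, seed = derive_seed(seed, nm)
    )
    s <- fit$scores
    if (learners[[nm]]$task == "regression") {
      s <- regression_to_pseudo_probability(s)
    }
    sets[[nm]] <- s
  }
  list(sets = sets, consensus = average_consensus(sets))
}

#' Run the full synthetic-screen analysis pipeline
#'
#' @param config A [pipeline_config()].
#' @param seed Root integer seed; every stage derives its own stream from it.
#' @param out_dir Output directory (created); NULL skips writing files.
#' @param quiet Suppress stage messages.
#' @return (Invisibly) a list with the library, truth model, screen records,
#'   cross-validation results, prediction sets, nomination lists, hit-rate
#'   table, network, edge significance and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL, quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[comboscreen] ", fmt), ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "comboscreen_pipeline_error"
      )
    })
  }

  say("stage simulate: library of %d compounds", config$screen$n_library)
  library_tbl <- stage("simulate", generate_library(config$screen, derive_seed(seed, "library")))
  actives <- library_tbl[library_tbl$is_active, ]
  truth <- config$truth %||% default_truth_model(actives, seed = derive_seed(seed, "truth"))
  if (!is.null(config$calibrate_replicate_cor)) {
    truth <- stage("calibrate", calibrate_noise(
      actives, truth,
      target_pearson = config$calibrate_replicate_cor,
      seed = derive_seed(seed, "calibrate")
    ))
    say("stage calibrate: replicate noise sd %.3f", truth$replicate_noise_sd)
  }
  screen <- stage("screen", simulate_screen(
    actives, truth,
    n_replicates = config$screen$n_replicates, seed = derive_seed(seed, "screen")
  ))
  records <- screen$records
  say("stage screen: %d combinations, %.0f%% synergistic", nrow(records), 100 * mean(records$label))

  vocab <- moa_vocabulary(library_tbl)
  feats <- stage("featurize", pipeline_features(records, actives, config$featurization, vocab))

  say("stage validate: %s", config$validation$scheme)
  folds <- stage("validate", switch(config$validation$scheme,
    one_compound_out = one_compound_out_folds(actives, records),
    everything_out = everything_out_folds(
      actives, records,
      n_groups = config$validation$n_groups, seed = derive_seed(seed, "folds")
    )
  ))
  cv <- stage("validate", lapply(config$learners, function(l) {
    cross_validate(folds, feats, records, l, seed = derive_seed(seed, "cv"))
  }))
  cv_consensus_scores <- oof_consensus(cv, config$learners)
  cv_auc <- roc_auc(cv_consensus_scores, records$label)
  metrics <- confusion_metrics(confusion_counts(records$label, cv_consensus_scores >= 0.5))
  metrics$auc <- cv_auc
  say("stage validate: consensus out-of-fold AUC %.3f", cv_auc)

  yrand <- NULL
  if (isTRUE(config$validation$y_randomize)) {
    rec_y <- y_randomize(records, seed = derive_seed(seed, "yrand"))
    cv_y <- lapply(config$learners, function(l) {
      cross_validate(folds, feats, rec_y, l, seed = derive_seed(seed, "cvy"))
    })
    yrand <- list(auc = roc_auc(oof_consensus(cv_y, config$learners), rec_y$label))
    say("stage validate: y-randomized AUC %.3f", yrand$auc)
  }

  say("stage score: candidate pool")
  candidates <- stage("score", {
    all_cand <- enumerate_pairs(library_tbl, exclude = records)
    if (nrow(all_cand) > config$n_candidates) {
      all_cand[with_seed(
        derive_seed(seed, "candidates"),
        sort(sample.int(nrow(all_cand), config$n_candidates))
      ), ]
    } else {
      all_cand
    }
  })
  cand_feats <- stage("score", pipeline_features(
    candidates, library_tbl, config$featurization, vocab
  ))
  scored <- stage("score", consensus_scores(
    config$learners, feats, records, cand_feats, candidates,
    seed = derive_seed(seed, "fullfit")
  ))

  say("stage nominate")
  moa_table <- synergistic_moa_pairs(records, actives)
  nom <- stage("nominate", list(
    topk = topk_nomination(scored$consensus, k = config$nomination$k),
    tiered = withCallingHandlers(
      tiered_nomination(
        scored$consensus, scored$sets[[1]], library_tbl, moa_table,
        quotas = config$nomination$quotas,
        consensus_cutoff = config$nomination$consensus_cutoff
      ),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    diversity = diversity_capped_topk(
      scored$consensus,
      k = config$nomination$k,
      per_compound_cap = config$nomination$per_compound_cap
    )
  ))

  # hit rates against the generator's mechanism-driven ground truth
  truth_label_for <- function(pairs) {
    g <- truth$baseline_gamma_mean + pair_effects(pairs, library_tbl, truth)
    tibble(
      compound_1 = pairs$compound_1, compound_2 = pairs$compound_2,
      label = label_synergy(pmin(pmax(g, 0), 2))
    )
  }
  hits <- purrr::map_dfr(names(nom), function(nm) {
    if (nrow(nom[[nm]]) == 0) return(NULL)
    dplyr::bind_cols(
      tibble(list = nm),
      hit_rate(nom[[nm]], truth_label_for(nom[[nm]]))
    )
  })
  say("stage evaluate: hit rates %s", paste(sprintf("%s %d%%", hits$list, hits$hit_rate_pct), collapse = ", "))

  say("stage network")
  network <- stage("network", build_network(
    records, actives,
    gamma_cutoff = config$network$gamma_cutoff
  ))
  syn_records <- records[records$gamma_mean < config$network$gamma_cutoff, ]
  edge_sig <- NULL
  if (nrow(syn_records) >= 2) {
    pool_ids <- unique(c(syn_records$compound_1, syn_records$compound_2))
    null <- stage("network", permutation_null(
      actives[actives$id %in% pool_ids, ],
      n_combos = min(nrow(syn_records), length(pool_ids) * (length(pool_ids) - 1) / 2),
      n_reps = config$network$n_reps, seed = derive_seed(seed, "null")
    ))
    edge_sig <- edge_significance(network, null)
  }

  manifest <- c(
    package = "comboscreen",
    version = as.character(utils::packageVersion("comboscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.character(seed),
    config_hash = config_hash(config),
    n_library = as.character(config$screen$n_library),
    n_active = as.character(config$screen$n_active),
    n_records = as.character(nrow(records)),
    replicate_noise_sd = sprintf("%.6f", truth$replicate_noise_sd),
    cv_auc = sprintf("%.6f", cv_auc)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_compounds(library_tbl, file.path(out_dir, "compounds.csv"))
    write_combinations(records, file.path(out_dir, "combinations.csv"))
    write_predictions(scored$consensus, file.path(out_dir, "predictions.csv"))
    for (nm in names(nom)) {
      write_nominations(nom[[nm]], file.path(out_dir, sprintf("nominations_%s.csv", nm)))
    }
    readr::write_csv(format_metrics(metrics), file.path(out_dir, "metrics.csv"))
    readr::write_csv(hits, file.path(out_dir, "hit_rates.csv"))
    write_network(network, file.path(out_dir, "network_edges.tsv"), "tsv")
    if (nrow(network$edges) > 0) {
      write_network(network, file.path(out_dir, "network.graphml"), "graphml")
    }
    if (!is.null(edge_sig)) {
      readr::write_csv(edge_sig, file.path(out_dir, "edge_significance.csv"))
    }
    writeLines(paste(names(manifest), manifest, sep = "="), file.path(out_dir, "manifest.txt"))
    say("artifacts written to %s", out_dir)
  }

  invisible(list(
    library = library_tbl, actives = actives, truth = truth, records = records,
    folds = folds, cv = cv, metrics = metrics, yrand = yrand,
    candidates = candidates, prediction_sets = scored$sets,
    consensus = scored$consensus, moa_table = moa_table,
    nominations = nom, hit_rates = hits, network = network,
    edge_significance = edge_sig, manifest = manifest
  ))
}
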