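# Combination-aware cross-validation and performance metrics.
#
# Pair data leak through shared compounds: a random pair split lets a model
# memorise compounds rather than learn pair behaviour. The two splitters here
# are the field's combination-aware schemes. One-compound-out holds out every
# combination containing one designated compound (validation pairs share one
# compound with training); everything-out partitions compounds into groups
# and validates only on pairs whose both members are unseen.

#' One-compound-out cross-validation folds
#'
#' One fold per compound: the fold's validation set is every combination
#' containing that compound, its training set is everything else. For a
#' complete all-vs-all screen of n compounds this yields n folds of n-1
#' validation pairs, and every pair appears in exactly two validation sets
#' (one per member).
#'
#' @param compounds Compound table (or character vector of ids).
#' @param records Synergy-record tibble.
#' @return Tibble of folds: `fold_id`, `held_out` (id), `train` and
#'   `validation` (list-columns of row indices into `records`).
#' @export
one_compound_out_folds <- function(compounds, records) {
  ids <- if (is.data.frame(compounds)) compounds$id else as.character(compounds)
  bad <- setdiff(unique(c(records$compound_1, records$compound_2)), ids)
  if (length(bad) > 0) {
    abort(sprintf("Records reference compounds not in the list: %s", paste(bad, collapse = ", ")))
  }
  purrr::map_dfr(seq_along(ids), function(i) {
    val <- which(records$compound_1 == ids[i] | records$compound_2 == ids[i])
    tibble(
      fold_id = i, held_out = ids[i],
      train = list(setdiff(seq_len(nrow(records)), val)),
      validation = list(val)
    )
  })
}

#' Everything-out cross-validation folds
#'
#' Compounds are partitioned randomly (seeded) into `n_groups`. Fold g
#' validates on pairs with both compounds inside group g and trains on pairs
#' with both compounds outside it; pairs straddling the boundary are dropped
#' from that fold. No validation pair shares a compound with any training
#' pair.
#'
#' @param compounds Compound table or id vector.
#' @param records Synergy-record tibble.
#' @param n_groups Number of groups (>= 2).
#' @param seed Integer seed for the partition.
#' @return Same shape as [one_compound_out_folds()], with `held_out` a
#'   list-column of ids.
#' @export
everything_out_folds <- function(compounds, records, n_groups = 2, seed = 1L) {
  stopifnot(n_groups >= 2)
  ids <- if (is.data.frame(compounds)) compounds$id else as.character(compounds)
  grp <- with_seed(seed, sample(rep_len(seq_len(n_groups), length(ids))))
  g1 <- grp[match(records$compound_1, ids)]
  g2 <- grp[match(records$compound_2, ids)]
  purrr::map_dfr(seq_len(n_groups), function(g) {
    val <- which(g1 == g & g2 == g)
    trn <- which(g1 != g & g2 != g)
    if (length(val) == 0) {
      warn(sprintf("Everything-out fold %d has an empty validation set.", g))
    }
    tibble(
      fold_id = g, held_out = list(ids[grp == g]),
      train = list(trn), validation = list(val)
    )
  })
}

#' Y-randomization control
#'
#' Permutes the response columns (replicate gammas, mean and label move
#' together) across combinations, preserving the label multiset. Model
#' performance on y-randomized data is the no-signal baseline of a modelling
#' protocol.
#'
#' @param records Synergy-record tibble.
#' @param seed Integer seed.
#' @return The records with responses permuted among keys.
#' @export
y_randomize <- function(records, seed = 1L) {
  stopifnot(nrow(records) >= 2)
  perm <- with_seed(seed, sample.int(nrow(records)))
  resp_cols <- c(
    grep("^gamma_rep", names(records), value = TRUE),
    intersect(c("gamma_mean", "label", "gamma_true"), names(records))
  )
  records[resp_cols] <- records[perm, resp_cols]
  records
}

#' Classification metrics from confusion counts
#'
#' Ratios follow the standard definitions; undefined ratios (zero
#' denominator) are reported as `NA`, never 0. The correct classification
#' rate (CCR) is reported as balanced accuracy, the mean of sensitivity and
#' specificity.
#'
#' @param counts One-row data frame with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]), or a numeric vector with those names.
#' @return A one-row `metric_report` tibble: counts plus `sens`, `spec`,
#'   `ppv`, `npv`, `bacc`, `ccr`.
#' @seealso [format_metrics()] for the 2-decimal table convention.
#' @export
confusion_metrics <- function(counts) {
  if (!is.data.frame(counts)) counts <- as_tibble(as.list(counts))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  if (tp + tn + fp + fn == 0) abort("Empty confusion table.")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  out <- tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sens = sens, spec = spec,
    ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
    bacc = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  )
  out$ccr <- out$bacc
  class(out) <- c("metric_report", class(out))
  out
}

#' Round a metric report to the reporting convention
#'
#' Published combination-screen tables round to 2 decimals, half away from
#' zero.
#'
#' @param metrics A `metric_report` (or any data frame of metrics).
#' @param digits Decimal places.
#' @return The data frame with numeric ratio columns rounded.
#' @export
format_metrics <- function(metrics, digits = 2) {
  num <- intersect(c("sens", "spec", "ppv", "npv", "bacc", "ccr", "auc", "hit_rate"), names(metrics))
  metrics[num] <- lapply(metrics[num], round_half_up, digits = digits)
  metrics
}

#' @export
glance.metric_report <- function(x, ...) as_tibble(x)

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation with tie correction: the probability that a
#' random positive scores above a random negative (ties count 1/2).
#'
#' @param scores Numeric prediction scores, higher = more positive.
#' @param labels Logical (or 0/1) true labels.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Experimental hit rate of a nomination list
#'
#' @param nominated Pair table of nominated combinations.
#' @param truth Synergy-record tibble (or any pair table with a `label`
#'   column) giving the experimental outcome of each nominated pair.
#' @return A one-row tibble: `n_nominated`, `n_hits`, `hit_rate` (fraction)
#'   and `hit_rate_pct` (rounded integer percent).
#' @export
hit_rate <- function(nominated, truth) {
  nominated <- canonicalize_pairs(as_tibble(nominated)[, c("compound_1", "compound_2")],
    quiet = TRUE
  )
  truth <- as_tibble(truth)
  key_n <- pair_id(nominated$compound_1, nominated$compound_2)
  key_t <- pair_id(truth$compound_1, truth$compound_2)
  miss <- !key_n %in% key_t
  if (any(miss)) {
    abort(sprintf(
      "No truth entry for nominated pair(s): %s",
      paste(gsub("\r", " + ", key_n[miss]), collapse = ", ")
    ))
  }
  hits <- sum(truth$label[match(key_n, key_t)])
  tibble(
    n_nominated = nrow(nominated), n_hits = hits,
    hit_rate = hits / nrow(nominated),
    hit_rate_pct = as.integer(round_half_up(100 * hits / nrow(nominated), 0))
  )
}

#' Run cross-validated predictions for a learner over fold specs
#'
#' Fits the learner on each fold's training rows and scores its validation
#' rows; out-of-fold scores for records appearing in several validation sets
#' (as in one-compound-out) are averaged.
#'
#' @param folds Fold tibble from a splitter.
#' @param features Feature matrix, rows aligned with `records`.
#' @param records Synergy-record tibble.
#' @param learner A [learner_spec()].
#' @param seed Integer seed.
#' @return List: `scores` (out-of-fold mean score per record), `auc` (pooled
#'   out-of-fold AUC), `fold_auc` (per-fold AUCs, NA where one-class).
#' @export
cross_validate <- function(folds, features, records, learner, seed = 1L) {
  n <- nrow(records)
  acc <- numeric(n)
  cnt <- numeric(n)
  fold_auc <- rep(NA_real_, nrow(folds))
  for (f in seq_len(nrow(folds))) {
    trn <- folds$train[[f]]
    val <- folds$validation[[f]]
    if (length(val) == 0 || length(trn) == 0) next
    fit <- fit_predict(
      learner,
      train_features = features[trn, , drop = FALSE],
      train_records = records[trn, ],
      test_features = features[val, , drop = FALSE],
      seed = derive_seed(seed, paste0("fold", f))
    )
    sc <- fit$scores$score
    acc[val] <- acc[val] + sc
    cnt[val] <- cnt[val] + 1
    if (length(unique(records$label[val])) == 2) {
      fold_auc[f] <- roc_auc(sc, records$label[val])
    }
  }
  covered <- cnt > 0
  scores <- ifelse(covered, acc / pmax(cnt, 1), NA_real_)
  list(
    scores = scores,
    auc = roc_auc(scores[covered], records$label[covered]),
    fold_auc = fold_auc
  )
}
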