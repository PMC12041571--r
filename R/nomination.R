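# Nomination strategies.
#
# A scored virtual library becomes a short experimental wish-list in one of
# three ways: plain top-k by score; a tiered scheme mixing consensus scores,
# descriptor-only ranks and mechanism-pair knowledge with quota'd tiers; or
# top-k under a per-compound diversity cap.

new_nomination_list <- function(entries, team) {
  entries <- as_tibble(entries)
  if (nrow(entries) > 0) {
    stopifnot(identical(entries$rank, seq_len(nrow(entries))))
    if (anyDuplicated(pair_id(entries$compound_1, entries$compound_2))) {
      abort("Nomination list contains duplicate pairs.")
    }
  }
  attr(entries, "team") <- team
  class(entries) <- c("nomination_list", class(entries))
  entries
}

#' @export
print.nomination_list <- function(x, ...) {
  cat(sprintf("<nomination_list> %s, %d entries\n", attr(x, "team"), nrow(x)))
  NextMethod()
}

#' Aggregate training combinations into a mechanism-pair table
#'
#' Each training drug pair contributes one unordered mechanism pair (the two
#' compounds' primary mechanisms, sorted); pairs are then grouped and the
#' count of representative drug pairs and the mean binary synergy label
#' computed. Mechanism pairs with at least `min_count` representatives and a
#' mean label of at least `min_mean` are flagged as synergistic mechanism
#' pairs.
#'
#' @param records Synergy-record tibble (uses `label`).
#' @param compounds Compound table with `moa` annotations (the first label is
#'   the primary mechanism).
#' @param min_count Minimum representative drug pairs (default 3).
#' @param min_mean Minimum mean label (default 0.66).
#' @return Tibble of class `moa_pair_table`: `moa_1`, `moa_2`, `n`,
#'   `mean_label`, `selected`.
#' @export
synergistic_moa_pairs <- function(records, compounds, min_count = 3,
                                  min_mean = 0.66) {
  compounds <- as_tibble(compounds)
  primary <- setNames(
    vapply(seq_len(nrow(compounds)), function(i) {
      labs <- moa_labels(compounds[i, ])
      if (length(labs) == 0) NA_character_ else labs[1]
    }, character(1)),
    compounds$id
  )
  m1 <- primary[records$compound_1]
  m2 <- primary[records$compound_2]
  if (anyNA(m1) || anyNA(m2)) {
    abort("Every record's compounds must carry MoA labels.")
  }
  tab <- tibble(
    moa_1 = pmin(m1, m2), moa_2 = pmax(m1, m2), label = as.numeric(records$label)
  ) |>
    dplyr::group_by(.data$moa_1, .data$moa_2) |>
    dplyr::summarise(
      n = dplyr::n(), mean_label = mean(.data$label), .groups = "drop"
    ) |>
    dplyr::mutate(selected = .data$n >= min_count & .data$mean_label >= min_mean)
  class(tab) <- c("moa_pair_table", class(tab))
  tab
}

# does a candidate pair's mechanism pair appear among the selected rows?
pair_moa_selected <- function(pairs, compounds, moa_table) {
  sel <- moa_table[moa_table$selected, c("moa_1", "moa_2")]
  sel_keys <- pair_id(sel$moa_1, sel$moa_2)
  primary <- setNames(
    vapply(seq_len(nrow(compounds)), function(i) {
      labs <- moa_labels(compounds[i, ])
      if (length(labs) == 0) NA_character_ else labs[1]
    }, character(1)),
    compounds$id
  )
  m1 <- primary[pairs$compound_1]
  m2 <- primary[pairs$compound_2]
  pair_id(pmin(m1, m2), pmax(m1, m2)) %in% sel_keys
}

#' Top-k nomination by score
#'
#' @param scores A [prediction_set()].
#' @param k Number of nominations (default 30).
#' @return A `nomination_list` (`rank`, pair, `score`, `tier` = `"topk"`),
#'   scores non-increasing; ties broken by canonical key order.
#' @export
topk_nomination <- function(scores, k = 30) {
  if (nrow(scores) < k) {
    abort(sprintf("Only %d scored pairs available for k = %d.", nrow(scores), k))
  }
  ord <- order(-scores$score, scores$compound_1, scores$compound_2)
  take <- as_tibble(scores)[ord[seq_len(k)], ]
  new_nomination_list(tibble(
    rank = seq_len(k),
    compound_1 = take$compound_1, compound_2 = take$compound_2,
    score = take$score, tier = "topk"
  ), team = "topk")
}

#' Tiered nomination
#'
#' Three mutually exclusive tiers with fixed quotas:
#' tier 1 (ranks 1-12): consensus score above `consensus_cutoff`, both
#' compounds active, exactly one in training, mechanism pair selected;
#' tier 2 (ranks 13-24): highest descriptor-only scores with both active,
#' exactly one in training, mechanism pair NOT selected;
#' tier 3 (ranks 25-30): highest consensus scores with both active, neither
#' in training, mechanism pair selected.
#' A tier that cannot be filled is reported short with a warning, never
#' backfilled from another tier.
#'
#' @param consensus,descriptor_only [prediction_set()]s covering the
#'   candidate pool.
#' @param compounds Compound table with `is_active`, `in_training`, `moa`.
#' @param moa_table A [synergistic_moa_pairs()] table.
#' @param quotas Tier sizes, default `c(12, 12, 6)`.
#' @param consensus_cutoff Tier-1 consensus score cutoff (default 0.7).
#' @return A `nomination_list` with `tier` labels `"tier1"`-`"tier3"`.
#' @export
tiered_nomination <- function(consensus, descriptor_only, compounds, moa_table,
                              quotas = c(12, 12, 6), consensus_cutoff = 0.7) {
  compounds <- as_tibble(compounds)
  keys_c <- pair_id(consensus$compound_1, consensus$compound_2)
  keys_d <- pair_id(descriptor_only$compound_1, descriptor_only$compound_2)
  if (!all(keys_c %in% keys_d)) {
    abort("Descriptor-only scores must cover the candidate pool.")
  }
  pool <- as_tibble(consensus)
  pool$descriptor_score <- descriptor_only$score[match(keys_c, keys_d)]
  info <- function(col) {
    v <- setNames(compounds[[col]], compounds$id)
    cbind(v[pool$compound_1], v[pool$compound_2])
  }
  act <- info("is_active")
  trn <- info("in_training")
  if (anyNA(act) || anyNA(trn)) abort("Candidate pool references unknown compounds.")
  both_active <- act[, 1] & act[, 2]
  n_train <- trn[, 1] + trn[, 2]
  moa_sel <- pair_moa_selected(pool, compounds, moa_table)

  q1 <- which(pool$score > consensus_cutoff & both_active & n_train == 1 & moa_sel)
  q1 <- q1[order(-pool$score[q1], pool$compound_1[q1], pool$compound_2[q1])]
  t1 <- head(q1, quotas[1])

  q2 <- which(both_active & n_train == 1 & !moa_sel)
  q2 <- setdiff(q2, t1)
  q2 <- q2[order(-pool$descriptor_score[q2], pool$compound_1[q2], pool$compound_2[q2])]
  t2 <- head(q2, quotas[2])

  q3 <- which(both_active & n_train == 0 & moa_sel)
  q3 <- setdiff(q3, c(t1, t2))
  q3 <- q3[order(-pool$score[q3], pool$compound_1[q3], pool$compound_2[q3])]
  t3 <- head(q3, quotas[3])

  short <- quotas - c(length(t1), length(t2), length(t3))
  if (any(short > 0)) {
    warn(sprintf(
      "Tier shortfall (not backfilled): %s",
      paste(sprintf("tier %d short by %d", which(short > 0), short[short > 0]),
        collapse = "; "
      )
    ))
  }
  idx <- c(t1, t2, t3)
  stopifnot(!anyDuplicated(idx))
  entries <- tibble(
    rank = seq_along(idx),
    compound_1 = pool$compound_1[idx], compound_2 = pool$compound_2[idx],
    score = pool$score[idx],
    tier = rep(c("tier1", "tier2", "tier3"), c(length(t1), length(t2), length(t3)))
  )
  new_nomination_list(entries, team = "tiered")
}

#' Top-k nomination with a per-compound diversity cap
#'
#' Greedy descent through the score-sorted candidates, skipping any pair
#' that would push either compound's appearance count above the cap; by
#' construction no compound appears more than `per_compound_cap` times.
#'
#' @param scores A [prediction_set()].
#' @param k Number of nominations.
#' @param per_compound_cap Maximum appearances per compound (default 5;
#'   `Inf` recovers plain top-k).
#' @return A `nomination_list` with `tier` = `"diversity"`.
#' @export
diversity_capped_topk <- function(scores, k = 30, per_compound_cap = 5) {
  ord <- order(-scores$score, scores$compound_1, scores$compound_2)
  counts <- new.env(parent = emptyenv())
  used <- integer(0)
  for (i in ord) {
    if (length(used) >= k) break
    c1 <- scores$compound_1[i]
    c2 <- scores$compound_2[i]
    n1 <- get0(c1, counts, ifnotfound = 0L)
    n2 <- get0(c2, counts, ifnotfound = 0L)
    if (n1 >= per_compound_cap || n2 >= per_compound_cap) next
    assign(c1, n1 + 1L, counts)
    assign(c2, n2 + 1L, counts)
    used <- c(used, i)
  }
  if (length(used) < k) {
    warn(sprintf(
      "Diversity cap leaves only %d of the requested %d nominations.",
      length(used), k
    ))
  }
  take <- as_tibble(scores)[used, ]
  new_nomination_list(tibble(
    rank = seq_along(used),
    compound_1 = take$compound_1, compound_2 = take$compound_2,
    score = take$score, tier = "diversity"
  ), team = "diversity_capped")
}

#' Pairwise overlap between nomination lists
#'
#' @param lists Named list of `nomination_list`s (>= 2).
#' @return List with `pairwise` (tibble: `team_1`, `team_2`, `shared`) and
#'   `union_size` (distinct pairs across all lists, the de-duplicated
#'   experimental load).
#' @export
overlap_report <- function(lists) {
  stopifnot(length(lists) >= 2)
  nms <- names(lists) %||% paste0("team", seq_along(lists))
  if (is.null(names(lists))) names(lists) <- nms
  keys <- lapply(lists, function(l) pair_id(l$compound_1, l$compound_2))
  combos <- utils::combn(length(lists), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(combos)), function(c) {
    i <- combos[1, c]; j <- combos[2, c]
    tibble(
      team_1 = nms[i], team_2 = nms[j],
      shared = length(intersect(keys[[i]], keys[[j]]))
    )
  })
  list(pairwise = pairwise, union_size = length(unique(unlist(keys))))
}
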