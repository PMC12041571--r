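#' Canonical unordered compound-pair keys
#'
#' Combination screens treat a drug pair as unordered: the pair (A, B) is the
#' same experiment as (B, A). `make_key()` puts every pair into canonical form
#' (lexicographically smaller id first) so that joins, de-duplication and
#' output files are deterministic.
#'
#' @param a,b Character vectors of compound ids (recycled to a common length).
#' @return A tibble with columns `compound_1` and `compound_2`,
#'   `compound_1 < compound_2` row-wise.
#' @examples
#' make_key("X", "A")
#' @export
make_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(a == b)) {
    abort(sprintf(
      "Self-pairs are not valid combinations: %s",
      paste(unique(a[a == b]), collapse = ", ")
    ), class = "comboscreen_self_pair")
  }
  tibble(
    compound_1 = pmin(a, b),
    compound_2 = pmax(a, b)
  )
}

#' Canonicalize the pair columns of a data frame
#'
#' @param df A data frame with `compound_1` and `compound_2` columns.
#' @param quiet Suppress the warning emitted when rows had to be reordered.
#' @return `df` with the two id columns swapped where needed.
#' @export
canonicalize_pairs <- function(df, quiet = FALSE) {
  stopifnot(all(c("compound_1", "compound_2") %in% names(df)))
  flipped <- df$compound_1 > df$compound_2
  if (any(df$compound_1 == df$compound_2)) {
    abort("Self-pairs present in pair table.", class = "comboscreen_self_pair")
  }
  if (any(flipped)) {
    if (!quiet) warn(sprintf("Canonicalized %d non-canonical pair rows.", sum(flipped)))
    tmp <- df$compound_1[flipped]
    df$compound_1[flipped] <- df$compound_2[flipped]
    df$compound_2[flipped] <- tmp
  }
  df
}

# single string per pair, used as a join/map key
pair_id <- function(compound_1, compound_2) {
  paste(compound_1, compound_2, sep = "\r")
}

#' Enumerate all unordered pairs of a compound library
#'
#' All-vs-all combination screens and virtual combination libraries are the
#' C(n, 2) unordered pairs of the library. A 32-compound screen yields 496
#' combinations; a 1785-compound library yields 1,592,220, and excluding the
#' 496 screened pairs leaves 1,591,724 candidates.
#'
#' @param library A data frame of compounds with an `id` column, or a
#'   character vector of ids.
#' @param exclude Optional pair table (columns `compound_1`, `compound_2`)
#'   of pairs to drop, e.g. the training combinations.
#' @return A tibble of canonical pairs in sorted order.
#' @export
enumerate_pairs <- function(library, exclude = NULL) {
  ids <- if (is.data.frame(library)) library$id else as.character(library)
  if (anyDuplicated(ids)) abort("Library ids must be unique.")
  ids <- sort(as.character(ids))
  n <- length(ids)
  if (n < 2) return(tibble(compound_1 = character(), compound_2 = character()))
  # vectorised generation of the upper triangle in sorted order
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  pairs <- tibble(compound_1 = ids[i], compound_2 = ids[j])
  if (!is.null(exclude) && nrow(exclude) > 0) {
    excl <- canonicalize_pairs(exclude[, c("compound_1", "compound_2")], quiet = TRUE)
    pairs <- dplyr::anti_join(pairs, excl, by = c("compound_1", "compound_2"))
  }
  pairs
}

#' Binary synergy call from a mean gamma score
#'
#' The screening platform's gamma score is a response-surface synergy measure
#' on which 1 means no interaction; values below 0.95 are called synergistic
#' and values below 0.5 strongly synergistic. A gamma of exactly 0.95 is
#' non-synergistic.
#'
#' @param gamma_mean Numeric vector of mean gamma scores.
#' @param cutoff Synergy cutoff, default 0.95.
#' @return Logical vector, `TRUE` where synergistic.
#' @seealso [synergy_class()] for the three-level strong/synergistic/none call.
#' @export
label_synergy <- function(gamma_mean, cutoff = 0.95) {
  if (any(!is.finite(gamma_mean))) abort("`gamma_mean` must be finite.")
  gamma_mean < cutoff
}

#' Three-level synergy classification
#'
#' @inheritParams label_synergy
#' @param strong_cutoff Strong-synergy cutoff, default 0.5.
#' @return Factor with levels `"strong"`, `"synergistic"`, `"non-synergistic"`.
#' @export
synergy_class <- function(gamma_mean, cutoff = 0.95, strong_cutoff = 0.5) {
  if (any(!is.finite(gamma_mean))) abort("`gamma_mean` must be finite.")
  factor(
    ifelse(gamma_mean < strong_cutoff, "strong",
      ifelse(gamma_mean < cutoff, "synergistic", "non-synergistic")
    ),
    levels = c("strong", "synergistic", "non-synergistic")
  )
}

#' Assemble a synergy-record table from per-replicate gamma scores
#'
#' One row per unordered combination, carrying the replicate gamma scores,
#' their unweighted arithmetic mean, and the binary synergy label
#' (`gamma_mean < cutoff`). Model training uses the mean gamma.
#'
#' @param pairs Pair table (columns `compound_1`, `compound_2`).
#' @param gamma A numeric matrix with one column per replicate (or a list of
#'   equal-length numeric vectors).
#' @param cutoff Synergy cutoff applied to the mean.
#' @return A tibble with columns `compound_1`, `compound_2`,
#'   `gamma_rep1` ... `gamma_repR`, `gamma_mean`, `label`.
#' @export
synergy_records <- function(pairs, gamma, cutoff = 0.95) {
  pairs <- canonicalize_pairs(as_tibble(pairs)[, c("compound_1", "compound_2")],
    quiet = TRUE
  )
  if (is.list(gamma) && !is.matrix(gamma)) gamma <- do.call(cbind, gamma)
  gamma <- as.matrix(gamma)
  stopifnot(nrow(gamma) == nrow(pairs))
  if (any(!is.finite(gamma))) abort("Gamma scores must be finite.")
  colnames(gamma) <- paste0("gamma_rep", seq_len(ncol(gamma)))
  out <- dplyr::bind_cols(pairs, as_tibble(gamma))
  out$gamma_mean <- rowMeans(gamma)
  out$label <- label_synergy(out$gamma_mean, cutoff)
  key <- pair_id(out$compound_1, out$compound_2)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "Duplicate combination rows: %s",
      paste(unique(gsub("\r", " + ", key[duplicated(key)])), collapse = ", ")
    ), class = "comboscreen_duplicate_pair")
  }
  dplyr::arrange(out, .data$compound_1, .data$compound_2)
}

#' Confusion counts from binary truth and predictions
#'
#' @param truth,pred Logical (or 0/1) vectors of the same length.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.logical(truth)
  pred <- as.logical(pred)
  stopifnot(length(truth) == length(pred), !anyNA(truth), !anyNA(pred))
  tibble(
    tp = sum(pred & truth), tn = sum(!pred & !truth),
    fp = sum(pred & !truth), fn = sum(!pred & truth)
  )
}
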