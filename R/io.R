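# Flat-file interfaces.
#
# compounds.csv: id, smiles, log_ic50, moa (semicolon-joined), is_active,
# in_training. combinations.csv: compound_1, compound_2, per-replicate
# gammas, gamma_mean, label, canonically ordered. Matrices travel as long
# CSV (one well per row). Networks export as TSV edge lists and GraphML.

#' Write / read the compound table
#'
#' @param compounds Compound tibble (`moa` list-column allowed).
#' @param path File path.
#' @return `read_compounds()` returns the compound tibble with `moa` as a
#'   list-column.
#' @export
write_compounds <- function(compounds, path) {
  out <- as_tibble(compounds)
  if (is.list(out$moa)) {
    out$moa <- vapply(out$moa, paste, character(1), collapse = ";")
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_compounds
#' @export
read_compounds <- function(path) {
  tab <- readr::read_csv(path,
    col_types = readr::cols(
      id = readr::col_character(), smiles = readr::col_character(),
      log_ic50 = readr::col_double(), moa = readr::col_character(),
      is_active = readr::col_logical(), in_training = readr::col_logical()
    )
  )
  report_problems(tab, path)
  if (anyDuplicated(tab$id)) abort("Duplicate compound ids in file.")
  tab$moa <- lapply(strsplit(ifelse(is.na(tab$moa), "", tab$moa), ";", fixed = TRUE), trimws)
  tab
}

#' Write / read the combination (synergy record) table
#'
#' Pairs are stored canonically ordered; on read, non-canonical rows are
#' canonicalized with a warning and duplicate pairs are an error listing the
#' offending keys.
#'
#' @param records Synergy-record tibble.
#' @param path File path.
#' @return `read_combinations()` returns the synergy-record tibble.
#' @export
write_combinations <- function(records, path) {
  out <- canonicalize_pairs(as_tibble(records), quiet = TRUE)
  # 17 significant digits round-trip IEEE doubles exactly
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_combinations
#' @export
read_combinations <- function(path) {
  # doubles come in as text and convert through base strtod: vroom's fast
  # float path can be 1 ulp off, which would break bit-identical round-trips
  tab <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE
  )
  report_problems(tab, path)
  for (nm in setdiff(names(tab), c("compound_1", "compound_2", "label"))) {
    tab[[nm]] <- as.numeric(tab[[nm]])
  }
  if ("label" %in% names(tab)) tab$label <- as.logical(tab$label)
  need <- c("compound_1", "compound_2", "gamma_mean", "label")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing column(s) in %s: %s", path, paste(missing_cols, collapse = ", ")))
  }
  tab <- canonicalize_pairs(tab)
  key <- pair_id(tab$compound_1, tab$compound_2)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "Duplicate pair rows in %s: %s", path,
      paste(unique(gsub("\r", " + ", key[duplicated(key)])), collapse = ", ")
    ), class = "comboscreen_duplicate_pair")
  }
  tab
}

report_problems <- function(tab, path) {
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Malformed rows in %s (line %s): %s", path,
      paste(probs$row, collapse = ", "),
      paste(unique(probs$expected), collapse = "; ")
    ), class = "comboscreen_malformed_file")
  }
  invisible(tab)
}

#' Write / read dose-response matrices as long CSV
#'
#' One well per row (`compound_1`, `compound_2`, `replicate`, dose indices,
#' concentrations, `response`).
#'
#' @param matrices List of [drc_matrix()] objects.
#' @param path File path.
#' @return `read_matrices()` returns the list of matrices.
#' @export
write_matrices <- function(matrices, path) {
  readr::write_csv(purrr::map_dfr(matrices, tidy), path)
  invisible(path)
}

#' @rdname write_matrices
#' @export
read_matrices <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  report_problems(tab, path)
  split_keys <- paste(tab$compound_1, tab$compound_2, tab$replicate, sep = "\r")
  lapply(split(seq_len(nrow(tab)), split_keys), function(rows) {
    part <- tab[rows, ]
    part <- part[order(part$dose_index_1, part$dose_index_2), ]
    ni <- max(part$dose_index_1)
    nj <- max(part$dose_index_2)
    resp <- matrix(part$response, ni, nj, byrow = TRUE)
    drc_matrix(
      make_key(part$compound_1[1], part$compound_2[1]),
      conc_a = part$conc_1[match(seq_len(ni), part$dose_index_1)],
      conc_b = part$conc_2[match(seq_len(nj), part$dose_index_2)],
      response = resp, replicate = part$replicate[1]
    )
  })
}

#' Write a prediction set to CSV
#' @param predictions A [prediction_set()].
#' @param path File path.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_csv(tidy(predictions), path)
  invisible(path)
}

#' Write a nomination list to CSV
#' @param nominations A nomination list.
#' @param path File path.
#' @export
write_nominations <- function(nominations, path) {
  out <- as_tibble(nominations)
  out$team <- attr(nominations, "team")
  readr::write_csv(out, path)
  invisible(path)
}

#' Export a mechanism network
#'
#' @param network A [build_network()] result.
#' @param path Output path (`.tsv` for the edge list, `.graphml` for
#'   GraphML).
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(network$edges, path)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}
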