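# Mechanism-of-action co-occurrence network and permutation significance.
#
# Among the synergistic combinations, which mechanism pairings recur? Each
# synergistic drug pair contributes its cross-compound mechanism pairs to an
# edge-frequency map; the significance of an observed edge count is assessed
# against random draws of the same number of combinations from the same
# compound pool.

# per-record cross-compound MoA pairs; mode "cross" uses the full label
# cross-product, "primary" only the first label of each compound
record_moa_pairs <- function(c1, c2, moa_sets, mode = "cross") {
  ma <- moa_sets[[c1]]
  mb <- moa_sets[[c2]]
  if (mode == "primary") {
    ma <- head(ma, 1)
    mb <- head(mb, 1)
  }
  if (length(ma) == 0 || length(mb) == 0) return(character())
  cross <- expand.grid(ma, mb, stringsAsFactors = FALSE)
  pair_id(pmin(cross[[1]], cross[[2]]), pmax(cross[[1]], cross[[2]]))
}

moa_set_map <- function(compounds) {
  compounds <- as_tibble(compounds)
  setNames(
    lapply(seq_len(nrow(compounds)), function(i) moa_labels(compounds[i, ])),
    compounds$id
  )
}

#' Build the mechanism co-occurrence network of synergistic combinations
#'
#' Restricts the records to those with `gamma_mean` below the cutoff; each
#' contributing record adds 1 to every mechanism carried by either compound
#' (node frequency) and 1 to every cross-compound mechanism pair (edge
#' frequency, unordered; self-pairs allowed when both compounds share a
#' mechanism class). Edge mean gamma summarises how synergistic each
#' mechanism pairing is.
#'
#' @param records Synergy-record tibble.
#' @param compounds Compound table with `moa` annotations covering all record
#'   compounds.
#' @param gamma_cutoff Records with `gamma_mean` below this contribute
#'   (default 0.95; use 0.5 for the strong-synergy network).
#' @param moa_mode `"cross"` (full label cross-product) or `"primary"`.
#' @return Object of class `moa_network`: `nodes` (tibble `moa`, `freq`),
#'   `edges` (tibble `moa_1`, `moa_2`, `freq`, `mean_gamma`), plus the
#'   cutoff and record count.
#' @export
build_network <- function(records, compounds, gamma_cutoff = 0.95,
                          moa_mode = c("cross", "primary")) {
  moa_mode <- match.arg(moa_mode)
  moa_sets <- moa_set_map(compounds)
  miss <- setdiff(unique(c(records$compound_1, records$compound_2)), names(moa_sets))
  if (length(miss) > 0) {
    abort(sprintf("Compounds missing from the MoA map: %s", paste(miss, collapse = ", ")))
  }
  syn <- records[records$gamma_mean < gamma_cutoff, ]
  node_env <- new.env(parent = emptyenv())
  edge_freq <- new.env(parent = emptyenv())
  edge_gamma <- new.env(parent = emptyenv())
  bump <- function(env, key, by = 1) {
    assign(key, get0(key, env, ifnotfound = 0) + by, env)
  }
  for (r in seq_len(nrow(syn))) {
    for (m in union(
      if (moa_mode == "primary") head(moa_sets[[syn$compound_1[r]]], 1) else moa_sets[[syn$compound_1[r]]],
      if (moa_mode == "primary") head(moa_sets[[syn$compound_2[r]]], 1) else moa_sets[[syn$compound_2[r]]]
    )) {
      bump(node_env, m)
    }
    for (e in record_moa_pairs(syn$compound_1[r], syn$compound_2[r], moa_sets, moa_mode)) {
      bump(edge_freq, e)
      bump(edge_gamma, e, by = syn$gamma_mean[r])
    }
  }
  nodes <- tibble(
    moa = ls(node_env),
    freq = unname(vapply(ls(node_env), get, numeric(1), envir = node_env))
  ) |> dplyr::arrange(dplyr::desc(.data$freq), .data$moa)
  ekeys <- ls(edge_freq)
  parts <- strsplit(ekeys, "\r", fixed = TRUE)
  ef <- unname(vapply(ekeys, get, numeric(1), envir = edge_freq))
  eg <- unname(vapply(ekeys, get, numeric(1), envir = edge_gamma))
  edges <- tibble(
    moa_1 = vapply(parts, `[`, character(1), 1),
    moa_2 = vapply(parts, `[`, character(1), 2),
    freq = ef,
    mean_gamma = eg / ef
  ) |> dplyr::arrange(dplyr::desc(.data$freq), .data$moa_1, .data$moa_2)
  structure(list(
    nodes = nodes, edges = edges, gamma_cutoff = gamma_cutoff,
    n_records = nrow(syn), moa_mode = moa_mode
  ), class = "moa_network")
}

#' @export
print.moa_network <- function(x, ...) {
  cat(sprintf(
    "<moa_network> %d mechanisms, %d edges from %d synergistic combinations (gamma < %g)\n",
    nrow(x$nodes), nrow(x$edges), x$n_records, x$gamma_cutoff
  ))
  invisible(x)
}

#' @export
tidy.moa_network <- function(x, ...) x$edges

#' Convert the network to an igraph object
#' @param network A `moa_network`.
#' @return An igraph graph with `freq` vertex/edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "moa_network"))
  edges <- network$edges[network$edges$moa_1 != network$edges$moa_2, ]
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = network$nodes[, c("moa", "freq")]
  )
  g
}

#' Plot the mechanism co-occurrence network
#'
#' Node size tracks mechanism frequency, edge width mechanism-pair
#' frequency.
#'
#' @param object A `moa_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.moa_network <- function(object, ...) {
  g <- as_igraph(object)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(
    moa = igraph::V(g)$name, freq = igraph::V(g)$freq,
    x = lay[, 1], y = lay[, 2]
  )
  el <- igraph::as_data_frame(g, what = "edges")
  el$x1 <- nodes$x[match(el$from, nodes$moa)]
  el$y1 <- nodes$y[match(el$from, nodes$moa)]
  el$x2 <- nodes$x[match(el$to, nodes$moa)]
  el$y2 <- nodes$y[match(el$to, nodes$moa)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = el,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2,
        linewidth = .data$freq),
      colour = "grey60", alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$freq),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$moa),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_size_continuous(range = c(2, 10)) +
    ggplot2::scale_linewidth_continuous(range = c(0.3, 3)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "MoA freq", linewidth = "pair freq")
}

#' Permutation null for mechanism-pair counts
#'
#' Per replicate, samples `n_combos` distinct unordered compound pairs
#' uniformly from the pool (without replacement within the replicate) and
#' counts each mechanism pair's occurrences, giving a null distribution of
#' edge counts under random pairing of the same compounds.
#'
#' @param compound_pool Compound table (the compounds appearing in the
#'   observed synergistic combinations).
#' @param n_combos Combinations sampled per replicate.
#' @param n_reps Replicates (default 1000).
#' @param seed Integer seed.
#' @param moa_mode `"cross"` or `"primary"` (must match the observed
#'   network's counting rule).
#' @return Object of class `permutation_null`: `counts` (matrix, n_reps rows,
#'   one column per mechanism pair ever drawn), `n_reps`, `n_combos`, `seed`.
#' @export
permutation_null <- function(compound_pool, n_combos, n_reps = 1000, seed = 1L,
                             moa_mode = c("cross", "primary")) {
  moa_mode <- match.arg(moa_mode)
  compound_pool <- as_tibble(compound_pool)
  n <- nrow(compound_pool)
  stopifnot(n >= 2)
  n_possible <- n * (n - 1) / 2
  if (n_combos > n_possible) {
    abort(sprintf(
      "Cannot draw %d distinct pairs from a pool of %d compounds (max %d).",
      n_combos, n, n_possible
    ))
  }
  moa_sets <- moa_set_map(compound_pool)
  all_pairs <- enumerate_pairs(compound_pool)
  # precompute each possible pair's mechanism-pair keys once
  pair_keys <- lapply(seq_len(nrow(all_pairs)), function(r) {
    record_moa_pairs(all_pairs$compound_1[r], all_pairs$compound_2[r], moa_sets, moa_mode)
  })
  seen <- sort(unique(unlist(pair_keys)))
  counts <- with_seed(seed, {
    m <- matrix(0L, n_reps, length(seen), dimnames = list(NULL, seen))
    for (rep in seq_len(n_reps)) {
      draw <- sample.int(n_possible, n_combos)
      tab <- table(unlist(pair_keys[draw]))
      m[rep, names(tab)] <- as.integer(tab)
    }
    m
  })
  structure(list(
    counts = counts, n_reps = n_reps, n_combos = n_combos, seed = seed,
    moa_mode = moa_mode
  ), class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> %d reps x %d combinations, %d mechanism pairs tracked\n",
    x$n_reps, x$n_combos, ncol(x$counts)
  ))
  invisible(x)
}

#' Null counts for one mechanism pair
#'
#' @param null A [permutation_null()].
#' @param moa_1,moa_2 Mechanism labels of the edge.
#' @return Integer vector of length `n_reps` (zeros when the pair never
#'   occurred in the null).
#' @export
null_counts <- function(null, moa_1, moa_2) {
  key <- pair_id(min(moa_1, moa_2), max(moa_1, moa_2))
  if (key %in% colnames(null$counts)) {
    as.integer(null$counts[, key])
  } else {
    integer(null$n_reps)
  }
}

#' Empirical significance of an observed mechanism-pair count
#'
#' The primary p-value is the add-one-corrected permutation estimate
#' `(1 + #{null >= observed}) / (1 + n_reps)`, whose smallest attainable
#' value is `1/(n_reps+1)`. A normal-tail approximation from the null's mean
#' and standard deviation is also reported (`p_normal`), the form in which
#' screen analyses usually quote significance against a summarised null.
#'
#' @param observed Observed edge count.
#' @param null_counts Integer vector of null counts (see [null_counts()]).
#' @return A one-row tibble of class `perm_test`: `observed`, `null_mean`,
#'   `null_sd`, `p_empirical`, `p_normal`, `n_reps`.
#' @export
empirical_significance <- function(observed, null_counts) {
  stopifnot(length(null_counts) >= 1, is.finite(observed))
  n <- length(null_counts)
  mu <- mean(null_counts)
  sdv <- sd(null_counts)
  out <- tibble(
    observed = observed,
    null_mean = mu,
    null_sd = sdv,
    p_empirical = (1 + sum(null_counts >= observed)) / (1 + n),
    p_normal = if (is.na(sdv) || sdv == 0) NA_real_ else pnorm(observed, mu, sdv, lower.tail = FALSE),
    n_reps = n
  )
  class(out) <- c("perm_test", class(out))
  out
}

#' @export
glance.perm_test <- function(x, ...) as_tibble(x)

#' Significance of every observed network edge
#'
#' @param network A [build_network()] result.
#' @param null A matching [permutation_null()].
#' @return The network's edge table with `null_mean`, `null_sd`,
#'   `p_empirical`, `p_normal` appended.
#' @export
edge_significance <- function(network, null) {
  purrr::map_dfr(seq_len(nrow(network$edges)), function(i) {
    e <- network$edges[i, ]
    s <- empirical_significance(
      e$freq, null_counts(null, e$moa_1, e$moa_2)
    )
    dplyr::bind_cols(e, s[, c("null_mean", "null_sd", "p_empirical", "p_normal")])
  })
}
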