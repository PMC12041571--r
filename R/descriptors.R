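# Pair featurization.
#
# Compounds are turned into fixed-length numeric vectors through a pluggable
# descriptor registry, then pairs are composited by element-wise average or
# sum (order-invariant), optionally augmented with a mechanism-of-action
# presence vector and the two single-agent log IC50 values.

the_registry <- new.env(parent = emptyenv())

#' Register a compound descriptor family
#'
#' The registry makes descriptor families pluggable: external descriptor
#' tables (e.g. expensive commercial descriptors computed elsewhere) can be
#' registered from CSV without touching any caller.
#'
#' @param name Descriptor name, e.g. `"morgan-2048"`.
#' @param fn Function taking a parsed molecule (class `mol`) and the compound
#'   row (one-row data frame), returning a fixed-length numeric vector.
#' @export
register_descriptor <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = the_registry)
  invisible(name)
}

#' @rdname register_descriptor
#' @export
descriptor_names <- function() sort(ls(the_registry))

#' Register an external descriptor family from a CSV table
#'
#' The CSV must have an `id` column plus one numeric column per descriptor
#' dimension; lookups are by compound id, so this supports descriptor
#' families that cannot be computed in-package.
#'
#' @param name Registry name for the family.
#' @param path CSV file path.
#' @export
register_descriptor_csv <- function(name, path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("id" %in% names(tab))
  mat <- as.matrix(tab[, setdiff(names(tab), "id")])
  rownames(mat) <- tab$id
  register_descriptor(name, function(mol, compound) {
    if (!compound$id %in% rownames(mat)) {
      abort(sprintf("No external '%s' descriptor for compound '%s'.", name, compound$id))
    }
    as.numeric(mat[compound$id, ])
  })
}

# --- fingerprint machinery ---------------------------------------------------

# per-atom initial invariant (element, degree, charge, aromatic flag, implicit
# H count), analogous to ECFP atom invariants
atom_invariants <- function(mol) {
  adj <- mol_adjacency(mol)
  degree <- if (nrow(mol$atoms) == 1) 0 else rowSums(adj)
  h <- mol_hydrogens(mol)
  vapply(seq_len(nrow(mol$atoms)), function(i) {
    hash_ints(c(
      ATOMIC_NUMBER[mol$atoms$element[i]], degree[i],
      mol$atoms$charge[i] + 10, as.integer(mol$atoms$aromatic[i]), h[i]
    ))
  }, numeric(1))
}

# circular (Morgan-style) fingerprint: iteratively rehash each atom with its
# sorted (bond order, neighbour hash) environment; every (atom, radius)
# identifier sets one bit
fingerprint_circular <- function(mol, nbits, radius = 2) {
  inv <- atom_invariants(mol)
  nb <- vector("list", nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]; o <- mol$bonds$order[k] * 10
      nb[[a]] <- rbind(nb[[a]], c(o, b))
      nb[[b]] <- rbind(nb[[b]], c(o, a))
    }
  }
  ids <- inv
  all_ids <- inv
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_along(ids), function(i) {
      if (is.null(nb[[i]])) return(hash_ints(c(r, ids[i])))
      env <- nb[[i]]
      pairs <- cbind(env[, 1], ids[env[, 2]])
      ord <- order(pairs[, 1], pairs[, 2])
      hash_ints(c(r, ids[i], t(pairs[ord, , drop = FALSE])))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, new_ids)
  }
  bits <- numeric(nbits)
  bits[(all_ids %% nbits) + 1] <- 1
  bits
}

# linear-path fingerprint (Daylight/Avalon-like shape): all simple paths up to
# `max_len` atoms, canonicalised by taking the smaller of the two direction
# hashes
fingerprint_path <- function(mol, nbits, max_len = 5) {
  n <- nrow(mol$atoms)
  inv <- vapply(seq_len(n), function(i) {
    hash_ints(c(
      ATOMIC_NUMBER[mol$atoms$element[i]],
      as.integer(mol$atoms$aromatic[i]), mol$atoms$charge[i] + 10
    ))
  }, numeric(1))
  nbr <- vector("list", n)
  bond_ord <- list()
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      nbr[[a]] <- c(nbr[[a]], b)
      nbr[[b]] <- c(nbr[[b]], a)
      bond_ord[[paste(a, b)]] <- mol$bonds$order[k]
      bond_ord[[paste(b, a)]] <- mol$bonds$order[k]
    }
  }
  ids <- numeric(0)
  path_hash <- function(path) {
    seq_f <- numeric(0)
    for (i in seq_along(path)) {
      seq_f <- c(seq_f, inv[path[i]])
      if (i < length(path)) seq_f <- c(seq_f, bond_ord[[paste(path[i], path[i + 1])]] * 10)
    }
    min(hash_ints(seq_f), hash_ints(rev(seq_f)))
  }
  walk <- function(path) {
    ids[[length(ids) + 1]] <<- path_hash(path)
    if (length(path) >= max_len) return(invisible())
    for (nx in nbr[[path[length(path)]]]) {
      if (!nx %in% path) walk(c(path, nx))
    }
  }
  for (a in seq_len(n)) walk(a)
  bits <- numeric(nbits)
  bits[(ids %% nbits) + 1] <- 1
  bits
}

PHYSCHEM_NAMES <- c(
  "mol_weight", "n_heavy_atoms", "n_bonds", "n_rings", "n_aromatic_atoms",
  "n_carbon", "n_nitrogen", "n_oxygen", "n_sulfur", "n_halogen",
  "n_hbond_donors", "n_hbond_acceptors", "total_charge", "mean_degree",
  "hetero_fraction", "crude_logp"
)

# small physicochemical battery (counts-based; a stand-in of the same shape as
# a toolkit's descriptor set, names recorded for reproducibility)
physchem_descriptors <- function(mol) {
  el <- mol$atoms$element
  h <- mol_hydrogens(mol)
  n <- length(el)
  nb <- nrow(mol$bonds)
  ncomp <- n_components(mol)
  halo <- el %in% c("F", "Cl", "Br", "I")
  no <- el %in% c("N", "O")
  vals <- c(
    sum(ATOMIC_MASS[el]) + 1.008 * sum(h),
    n, nb,
    nb - n + ncomp, # cyclomatic ring count
    sum(mol$atoms$aromatic),
    sum(el == "C"), sum(el == "N"), sum(el == "O"), sum(el == "S"), sum(halo),
    sum(no & h > 0), sum(no),
    sum(mol$atoms$charge),
    if (n > 0) 2 * nb / n else 0,
    sum(el != "C") / n,
    0.4 * sum(el == "C") + 0.6 * sum(halo) - 0.8 * sum(no)
  )
  setNames(vals, PHYSCHEM_NAMES)
}

n_components <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      ra <- find(mol$bonds$a1[k]); rb <- find(mol$bonds$a2[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# built-in families
local({
  for (nm in c("morgan-1024", "morgan-2048")) {
    nb <- as.integer(sub("morgan-", "", nm))
    local({
      nbits <- nb
      register_descriptor(paste0("morgan-", nbits), function(mol, compound) {
        fingerprint_circular(mol, nbits, radius = 2)
      })
    })
  }
  for (nm in c("avalon-1024", "avalon-2048")) {
    nb <- as.integer(sub("avalon-", "", nm))
    local({
      nbits <- nb
      register_descriptor(paste0("avalon-", nbits), function(mol, compound) {
        fingerprint_path(mol, nbits, max_len = 5)
      })
    })
  }
  register_descriptor("physchem", function(mol, compound) physchem_descriptors(mol))
})

# --- user-facing featurization ----------------------------------------------

#' Compute a descriptor vector for one compound
#'
#' @param compound A one-row data frame with at least `id` and `smiles`.
#' @param descriptor_name Registered descriptor family name
#'   (see [descriptor_names()]).
#' @return Numeric vector with attributes `descriptor` and (for bit vectors)
#'   entries in \{0, 1\}.
#' @export
compound_descriptor <- function(compound, descriptor_name = "morgan-2048") {
  compound <- as_tibble(compound)
  stopifnot(nrow(compound) == 1)
  fn <- get0(descriptor_name, envir = the_registry)
  if (is.null(fn)) {
    abort(sprintf(
      "Unknown descriptor '%s'. Registered: %s", descriptor_name,
      paste(descriptor_names(), collapse = ", ")
    ))
  }
  mol <- tryCatch(parse_smiles(compound$smiles), error = function(e) {
    abort(sprintf(
      "Cannot featurize compound '%s': %s", compound$id, conditionMessage(e)
    ), class = "comboscreen_smiles_error")
  })
  v <- fn(mol, compound)
  structure(as.numeric(v), descriptor = descriptor_name, names = names(v))
}

#' Descriptor matrix for a compound table
#'
#' @param compounds Compound table (columns `id`, `smiles`).
#' @inheritParams compound_descriptor
#' @return Numeric matrix, one row per compound, rownames = ids.
#' @export
featurize_compounds <- function(compounds, descriptor_name = "morgan-2048") {
  compounds <- as_tibble(compounds)
  rows <- lapply(seq_len(nrow(compounds)), function(i) {
    compound_descriptor(compounds[i, ], descriptor_name)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- compounds$id
  mat
}

#' Composite two compound feature vectors into a pair vector
#'
#' @param fa,fb Numeric vectors of identical length (same descriptor family).
#' @param mode `"average"` or `"sum"`; both are order-invariant.
#' @return Numeric vector of the same length.
#' @export
compose_pair <- function(fa, fb, mode = c("average", "sum")) {
  mode <- match.arg(mode)
  if (length(fa) != length(fb)) {
    abort(sprintf("Feature length mismatch: %d vs %d.", length(fa), length(fb)))
  }
  da <- attr(fa, "descriptor"); db <- attr(fb, "descriptor")
  if (!is.null(da) && !is.null(db) && !identical(da, db)) {
    abort(sprintf("Descriptor mismatch: '%s' vs '%s'.", da, db))
  }
  out <- if (mode == "average") (fa + fb) / 2 else fa + fb
  structure(as.numeric(out), descriptor = da, composition = mode, names = names(fa))
}

#' Mechanism-of-action presence vector for a pair
#'
#' Every mechanism in the vocabulary is one position; a position is 1 when
#' either compound of the pair carries that mechanism (presence/absence union
#' encoding: a mechanism shared by both compounds still contributes a single
#' 1). A pair of compounds with two distinct mechanisms therefore has exactly
#' two positions set.
#'
#' @param a,b One-row compound data frames with a `moa` list-column or
#'   semicolon-separated `moa` string column.
#' @param vocabulary Ordered character vector of the library's mechanism
#'   vocabulary.
#' @return Binary numeric vector of length `length(vocabulary)`.
#' @export
moa_pair_vector <- function(a, b, vocabulary) {
  labs <- union(moa_labels(a), moa_labels(b))
  unknown <- setdiff(labs, vocabulary)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown MoA label(s): %s", paste(unknown, collapse = ", ")))
  }
  as.numeric(vocabulary %in% labs)
}

# moa column can be a list-column of character vectors or ";"-joined strings
moa_labels <- function(compound) {
  m <- compound$moa
  if (is.list(m)) m <- m[[1]]
  if (is.null(m) || length(m) == 0 || (length(m) == 1 && (is.na(m) || !nzchar(m)))) {
    return(character())
  }
  if (length(m) == 1 && grepl(";", m)) m <- strsplit(m, ";", fixed = TRUE)[[1]]
  trimws(as.character(m))
}

#' Append the pair's single-agent potencies to a feature vector
#'
#' The two log IC50 values are appended in canonical id order so the result
#' does not depend on argument order.
#'
#' @param f Pair feature vector.
#' @param a,b One-row compound data frames with `id` and `log_ic50`.
#' @return `f` extended by two entries.
#' @export
append_potency <- function(f, a, b) {
  if (!is.finite(a$log_ic50) || !is.finite(b$log_ic50)) {
    abort(sprintf(
      "Missing potency for pair (%s, %s).", a$id, b$id
    ))
  }
  if (a$id > b$id) { tmp <- a; a <- b; b <- tmp }
  structure(
    c(as.numeric(f), a$log_ic50, b$log_ic50),
    descriptor = attr(f, "descriptor"), composition = attr(f, "composition")
  )
}

#' Feature matrix for a table of pairs
#'
#' Convenience wrapper applying [compose_pair()] (and optionally
#' [moa_pair_vector()] and [append_potency()]) across a pair table.
#'
#' @param pairs Pair table (`compound_1`, `compound_2`).
#' @param compounds Compound table covering all pair members.
#' @param descriptor_name Registered descriptor family, or `"moa"` to use the
#'   mechanism vector alone, or `"none"`.
#' @param composition `"average"` or `"sum"`.
#' @param moa Also append the mechanism-of-action pair vector.
#' @param potency Also append the two canonical-ordered log IC50 values.
#' @param vocabulary MoA vocabulary (defaults to all labels seen in
#'   `compounds`, sorted).
#' @return Numeric matrix, one row per pair.
#' @export
featurize_pairs <- function(pairs, compounds, descriptor_name = "morgan-2048",
                            composition = "average", moa = FALSE,
                            potency = FALSE, vocabulary = NULL) {
  pairs <- canonicalize_pairs(as_tibble(pairs), quiet = TRUE)
  compounds <- as_tibble(compounds)
  if (is.null(vocabulary)) vocabulary <- moa_vocabulary(compounds)
  idx <- setNames(seq_len(nrow(compounds)), compounds$id)
  missing <- setdiff(
    unique(c(pairs$compound_1, pairs$compound_2)), compounds$id
  )
  if (length(missing) > 0) {
    abort(sprintf("Pairs reference unknown compounds: %s", paste(missing, collapse = ", ")))
  }
  base <- NULL
  if (!identical(descriptor_name, "none") && !identical(descriptor_name, "moa")) {
    cm <- featurize_compounds(compounds, descriptor_name)
    ia <- idx[pairs$compound_1]; ib <- idx[pairs$compound_2]
    base <- if (composition == "average") {
      (cm[ia, , drop = FALSE] + cm[ib, , drop = FALSE]) / 2
    } else {
      cm[ia, , drop = FALSE] + cm[ib, , drop = FALSE]
    }
  }
  if (moa || identical(descriptor_name, "moa")) {
    moa_sets <- lapply(seq_len(nrow(compounds)), function(i) moa_labels(compounds[i, ]))
    mv <- matrix(0, nrow(pairs), length(vocabulary),
      dimnames = list(NULL, paste0("moa_", seq_along(vocabulary)))
    )
    for (r in seq_len(nrow(pairs))) {
      labs <- union(
        moa_sets[[idx[pairs$compound_1[r]]]],
        moa_sets[[idx[pairs$compound_2[r]]]]
      )
      unknown <- setdiff(labs, vocabulary)
      if (length(unknown) > 0) {
        abort(sprintf("Unknown MoA label(s): %s", paste(unknown, collapse = ", ")))
      }
      mv[r, vocabulary %in% labs] <- 1
    }
    base <- if (is.null(base)) mv else cbind(base, mv)
  }
  if (potency) {
    pa <- compounds$log_ic50[idx[pairs$compound_1]]
    pb <- compounds$log_ic50[idx[pairs$compound_2]]
    if (any(!is.finite(pa)) || any(!is.finite(pb))) abort("Missing potencies.")
    base <- cbind(base, log_ic50_1 = pa, log_ic50_2 = pb)
  }
  if (is.null(base)) abort("No features requested.")
  rownames(base) <- pair_id(pairs$compound_1, pairs$compound_2)
  base
}

#' MoA vocabulary of a compound table
#' @param compounds Compound table with `moa` column.
#' @return Sorted character vector of distinct labels.
#' @export
moa_vocabulary <- function(compounds) {
  compounds <- as_tibble(compounds)
  sort(unique(unlist(lapply(
    seq_len(nrow(compounds)), function(i) moa_labels(compounds[i, ])
  ))))
}

#' Combined mixture graph of a compound pair
#'
#' The pair is represented as the direct sum of the two molecules' adjacency
#' matrices (block diagonal, no inter-molecule edges) with the per-atom
#' feature matrices stacked, the input representation used by graph neural
#' network mixture models.
#'
#' @param a,b One-row compound data frames with `id` and `smiles`.
#' @return Object of class `mixture_graph`: `adjacency`, `node_features`,
#'   `pair` (canonical key), `n_atoms` (per molecule).
#' @export
mixture_graph <- function(a, b) {
  key <- make_key(a$id, b$id)
  if (a$id > b$id) { tmp <- a; a <- b; b <- tmp }
  ma <- tryCatch(parse_smiles(a$smiles), error = function(e) {
    abort(sprintf("Cannot build mixture graph, compound '%s': %s", a$id, conditionMessage(e)))
  })
  mb <- tryCatch(parse_smiles(b$smiles), error = function(e) {
    abort(sprintf("Cannot build mixture graph, compound '%s': %s", b$id, conditionMessage(e)))
  })
  na <- nrow(ma$atoms); nb_ <- nrow(mb$atoms)
  adj <- matrix(0, na + nb_, na + nb_)
  adj[seq_len(na), seq_len(na)] <- mol_adjacency(ma)
  adj[na + seq_len(nb_), na + seq_len(nb_)] <- mol_adjacency(mb)
  structure(list(
    adjacency = adj,
    node_features = rbind(atom_feature_matrix(ma), atom_feature_matrix(mb)),
    pair = key,
    n_atoms = c(na, nb_)
  ), class = "mixture_graph")
}

# element one-hot + degree + aromatic + charge per-atom features
atom_feature_matrix <- function(mol) {
  els <- names(ATOMIC_NUMBER)
  adj <- mol_adjacency(mol)
  deg <- if (nrow(mol$atoms) == 1) 0 else rowSums(adj)
  onehot <- outer(mol$atoms$element, els, `==`) * 1
  colnames(onehot) <- paste0("el_", els)
  cbind(onehot,
    degree = deg, aromatic = as.numeric(mol$atoms$aromatic),
    charge = mol$atoms$charge
  )
}

#' @export
print.mixture_graph <- function(x, ...) {
  cat(sprintf(
    "<mixture_graph> %s + %s  (%d + %d atoms)\n",
    x$pair$compound_1, x$pair$compound_2, x$n_atoms[1], x$n_atoms[2]
  ))
  invisible(x)
}
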