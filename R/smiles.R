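# Minimal SMILES reader.
#
# The screen simulator and the pair featurizers only need a molecular graph:
# atoms (element, aromaticity, charge, implicit hydrogens) and bonds with
# orders. This parser covers the organic subset, bracket atoms, branches,
# ring closures (including %nn), aromatic lower-case atoms and the usual bond
# symbols. Stereo marks (/ \ @) are accepted and ignored. It is deliberately
# strict: anything it cannot interpret is an error, because downstream
# fingerprinting must never run on a half-parsed structure.

SMILES_ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
SMILES_AROMATIC <- c("b", "c", "n", "o", "p", "s")

ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)
ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles A single SMILES string.
#' @return An object of class `mol`: a list with `atoms` (tibble: `element`,
#'   `aromatic`, `charge`, `h_explicit`), `bonds` (tibble: `a1`, `a2`,
#'   `order`; aromatic bonds have order 1.5) and the source string.
#' @examples
#' parse_smiles("c1ccccc1") # benzene: 6 aromatic carbons
#' @export
parse_smiles <- function(smiles) {
  if (length(smiles) != 1 || !is.character(smiles) || is.na(smiles) || !nzchar(smiles)) {
    abort("`smiles` must be a single non-empty string.", class = "comboscreen_smiles_error")
  }
  fail <- function(msg) {
    abort(sprintf("Invalid SMILES '%s': %s", smiles, msg),
      class = "comboscreen_smiles_error"
    )
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  el <- character()
  arom <- logical()
  chg <- integer()
  hexp <- integer()
  b1 <- integer()
  b2 <- integer()
  bord <- numeric()

  prev <- 0L # index of the atom the next atom bonds to; 0 = none
  stack <- integer() # branch stack
  rings <- list() # open ring closures: number -> c(atom, order)
  pending_bond <- NA_real_
  depth <- 0L
  i <- 1L

  add_atom <- function(element, aromatic, charge = 0L, h = NA_integer_) {
    el[[length(el) + 1L]] <<- element
    arom[[length(arom) + 1L]] <<- aromatic
    chg[[length(chg) + 1L]] <<- as.integer(charge)
    hexp[[length(hexp) + 1L]] <<- as.integer(h)
    idx <- length(el)
    if (prev > 0L) {
      ord <- pending_bond
      if (is.na(ord)) ord <- if (aromatic && arom[[prev]]) 1.5 else 1
      b1[[length(b1) + 1L]] <<- prev
      b2[[length(b2) + 1L]] <<- idx
      bord[[length(bord) + 1L]] <<- ord
    }
    pending_bond <<- NA_real_
    prev <<- idx
    invisible(idx)
  }

  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE)
      i <- i + 2L
    } else if (ch %in% SMILES_ORGANIC) {
      add_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% SMILES_AROMATIC) {
      add_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(
        body,
        regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$", body)
      )[[1]]
      if (length(m) == 0) fail(sprintf("cannot read bracket atom [%s]", body))
      sym <- m[3]
      aromatic <- sym %in% SMILES_AROMATIC
      element <- if (aromatic) toupper(sym) else sym
      if (!element %in% names(ATOMIC_NUMBER)) fail(sprintf("unsupported element '%s'", sym))
      htoken <- m[5]
      h <- if (is.na(htoken) || htoken == "") 0L else if (htoken == "H") 1L else as.integer(sub("H", "", htoken))
      ctoken <- m[6]
      charge <- 0L
      if (!is.na(ctoken) && nzchar(ctoken)) {
        if (grepl("^[+-][0-9]+$", ctoken)) {
          charge <- as.integer(ctoken)
        } else {
          charge <- (nchar(ctoken)) * (if (substr(ctoken, 1, 1) == "+") 1L else -1L)
        }
      }
      add_atom(element, aromatic, charge, h)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pending_bond <- switch(ch,
        "-" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1.5, "/" = 1, "\\" = 1
      )
      i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) fail("branch with no preceding atom")
      stack <- c(stack, prev)
      depth <- depth + 1L
      i <- i + 1L
    } else if (ch == ")") {
      if (depth == 0L) fail("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      depth <- depth - 1L
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) fail("truncated %nn ring closure")
        num <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
        if (!grepl("^[0-9]{2}$", num)) fail("malformed %nn ring closure")
        i <- i + 3L
      } else {
        num <- ch
        i <- i + 1L
      }
      if (prev == 0L) fail("ring closure with no preceding atom")
      if (!is.null(rings[[num]])) {
        open <- rings[[num]]
        if (open[1] == prev) fail("ring closure to self")
        ord <- pending_bond
        if (is.na(ord)) ord <- open[2]
        if (is.na(ord)) ord <- if (arom[[prev]] && arom[[open[1]]]) 1.5 else 1
        b1[[length(b1) + 1L]] <- open[1]
        b2[[length(b2) + 1L]] <- prev
        bord[[length(bord) + 1L]] <- ord
        rings[[num]] <- NULL
        pending_bond <- NA_real_
      } else {
        rings[[num]] <- c(prev, pending_bond)
        pending_bond <- NA_real_
      }
    } else if (ch == ".") {
      prev <- 0L
      pending_bond <- NA_real_
      i <- i + 1L
    } else {
      fail(sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (depth > 0L) fail("unclosed '('")
  if (length(rings) > 0L) fail("unmatched ring closure(s)")
  if (!is.na(pending_bond)) fail("dangling bond symbol")
  if (length(el) == 0L) fail("no atoms")

  atoms <- tibble(
    element = el, aromatic = arom, charge = chg, h_explicit = hexp
  )
  bonds <- tibble(a1 = b1, a2 = b2, order = bord)
  structure(list(atoms = atoms, bonds = bonds, smiles = smiles), class = "mol")
}

#' @export
print.mol <- function(x, ...) {
  cat(sprintf(
    "<mol> %s  (%d heavy atoms, %d bonds)\n",
    x$smiles, nrow(x$atoms), nrow(x$bonds)
  ))
  invisible(x)
}

# symmetric heavy-atom adjacency matrix (1 where bonded)
mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- matrix(0, n, n)
  if (nrow(mol$bonds) > 0) {
    adj[cbind(mol$bonds$a1, mol$bonds$a2)] <- 1
    adj[cbind(mol$bonds$a2, mol$bonds$a1)] <- 1
  }
  adj
}

# implicit hydrogens from default valences (organic-subset convention);
# bracket atoms use their explicit H count
mol_hydrogens <- function(mol) {
  n <- nrow(mol$atoms)
  bond_sum <- numeric(n)
  if (nrow(mol$bonds) > 0) {
    ord <- ifelse(mol$bonds$order == 1.5, 1, mol$bonds$order)
    # an aromatic atom participates in a delocalised system; count ring bonds
    # as single and add one to the valence consumed
    for (k in seq_len(nrow(mol$bonds))) {
      bond_sum[mol$bonds$a1[k]] <- bond_sum[mol$bonds$a1[k]] + ord[k]
      bond_sum[mol$bonds$a2[k]] <- bond_sum[mol$bonds$a2[k]] + ord[k]
    }
  }
  h <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(mol$atoms$h_explicit[i])) {
      h[i] <- mol$atoms$h_explicit[i]
    } else {
      val <- DEFAULT_VALENCE[mol$atoms$element[i]]
      used <- bond_sum[i] + abs(mol$atoms$charge[i]) + if (mol$atoms$aromatic[i]) 1 else 0
      h[i] <- max(0, if (is.na(val)) 0 else val - used)
    }
  }
  h
}
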