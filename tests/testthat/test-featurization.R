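test_that("fingerprints meet their bit-vector contract and are reproducible", {
  bz <- tibble::tibble(id = "benzene", smiles = "c1ccccc1")
  fp <- compound_descriptor(bz, "morgan-2048")
  expect_length(fp, 2048)
  expect_true(all(fp %in% c(0, 1)))
  expect_identical(fp, compound_descriptor(bz, "morgan-2048"))
  expect_length(compound_descriptor(bz, "avalon-1024"), 1024)
  pc <- compound_descriptor(bz, "physchem")
  expect_equal(unname(pc[c("n_heavy_atoms", "n_rings", "n_aromatic_atoms")]), c(6, 1, 6))
  err <- tryCatch(
    compound_descriptor(tibble::tibble(id = "bad1", smiles = "C("), "morgan-1024"),
    error = function(e) conditionMessage(e)
  )
  expect_match(err, "bad1") # error names the compound
  expect_error(compound_descriptor(bz, "no-such-descriptor"), "Unknown descriptor")
})

test_that("external descriptor families plug in through the registry", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = c("a", "b"), d1 = c(1, 2), d2 = c(3, 4)), path)
  register_descriptor_csv("external-test", path)
  v <- compound_descriptor(tibble::tibble(id = "b", smiles = "CC"), "external-test")
  expect_equal(as.numeric(v), c(2, 4))
  expect_error(
    compound_descriptor(tibble::tibble(id = "zz", smiles = "CC"), "external-test"),
    "zz"
  )
})

test_that("pair composition is element-wise, order-invariant and idempotent", {
  expect_equal(as.numeric(compose_pair(c(0, 1, 1), c(1, 1, 0), "average")), c(0.5, 1, 0.5))
  expect_equal(as.numeric(compose_pair(c(0, 1), c(1, 1), "sum")), c(1, 2))
  expect_error(compose_pair(1:3, 1:4), "mismatch")
  set.seed(4)
  for (i in 1:20) {
    a <- runif(16)
    b <- runif(16)
    expect_equal(
      as.numeric(compose_pair(a, b, "average")),
      as.numeric(compose_pair(b, a, "average"))
    )
    expect_equal(as.numeric(compose_pair(a, a, "average")), a)
  }
})

test_that("mechanism pair vectors use presence/absence union semantics", {
  vocab <- c("m1", "m2", "m3", "m4")
  a <- moa_compounds("A", list("m1"))
  b <- moa_compounds("B", list("m3"))
  v <- moa_pair_vector(a, b, vocab)
  expect_equal(v, c(1, 0, 1, 0)) # two distinct mechanisms -> exactly two 1s
  shared <- moa_pair_vector(moa_compounds("C", list("m2")), moa_compounds("D", list("m2")), vocab)
  expect_equal(sum(shared), 1) # shared mechanism -> one 1
  none <- moa_pair_vector(moa_compounds("E", list(character())), moa_compounds("F", list(character())), vocab)
  expect_equal(sum(none), 0)
  expect_error(moa_pair_vector(a, moa_compounds("G", list("weird")), vocab), "weird")
  # sums equal union sizes for random label sets
  set.seed(9)
  for (i in 1:20) {
    la <- sample(vocab, sample(0:3, 1))
    lb <- sample(vocab, sample(0:3, 1))
    v <- moa_pair_vector(
      moa_compounds("X", list(la)), moa_compounds("Y", list(lb)), vocab
    )
    expect_equal(sum(v), length(union(la, lb)))
  }
})

test_that("potency appending is canonical in compound order", {
  a <- tibble::tibble(id = "B", log_ic50 = -6)
  b <- tibble::tibble(id = "A", log_ic50 = -8)
  f <- runif(8)
  out <- append_potency(f, a, b)
  expect_length(out, 10)
  expect_equal(unname(tail(out, 2)), c(-8, -6)) # ordered by id A < B
  expect_identical(unname(append_potency(f, a, b)), unname(append_potency(f, b, a)))
  expect_error(append_potency(f, a, tibble::tibble(id = "C", log_ic50 = NA_real_)), "potency")
})

test_that("mixture graphs are block-diagonal direct sums", {
  a <- tibble::tibble(id = "ethane", smiles = "CC")
  b <- tibble::tibble(id = "methane", smiles = "C")
  g <- mixture_graph(a, b)
  expect_equal(dim(g$adjacency), c(3, 3))
  expect_equal(g$adjacency, t(g$adjacency))
  expect_equal(nrow(g$node_features), 3)
  # no inter-molecule edges: off-diagonal blocks all zero
  expect_true(all(g$adjacency[1:2, 3] == 0))
  aspirin <- tibble::tibble(id = "asa", smiles = "CC(=O)Oc1ccccc1C(=O)O")
  g2 <- mixture_graph(aspirin, a)
  na <- nrow(parse_smiles(aspirin$smiles)$atoms)
  expect_equal(nrow(g2$node_features), na + 2)
  expect_true(all(g2$adjacency[seq_len(na), na + 1:2] == 0))
  expect_error(mixture_graph(tibble::tibble(id = "bad", smiles = "C("), a), "bad")
})

test_that("pair featurization is invariant to argument order", {
  scr <- small_screen(seed = 13, n_library = 30, n_active = 8)
  pairs <- enumerate_pairs(scr$actives)[1:10, ]
  flipped <- tibble::tibble(
    compound_1 = pairs$compound_2, compound_2 = pairs$compound_1
  )
  f1 <- suppressWarnings(featurize_pairs(pairs, scr$actives, "morgan-1024", moa = TRUE, potency = TRUE))
  f2 <- suppressWarnings(featurize_pairs(flipped, scr$actives, "morgan-1024", moa = TRUE, potency = TRUE))
  expect_equal(unname(f1), unname(f2))
})
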