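test_that("mechanism-pair aggregation applies both thresholds", {
  comps <- moa_compounds(
    c("a1", "a2", "a3", "b1", "b2", "b3", "c1"),
    list("mA", "mA", "mA", "mB", "mB", "mB", "mC")
  )
  rec <- tibble::tibble(
    compound_1 = c("a1", "a2", "a3", "a1", "a2", "b1"),
    compound_2 = c("b1", "b2", "b3", "c1", "c1", "c1"),
    label = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
  tab <- synergistic_moa_pairs(rec, comps)
  ab <- tab[tab$moa_1 == "mA" & tab$moa_2 == "mB", ]
  expect_equal(ab$n, 3)
  expect_equal(ab$mean_label, 2 / 3, tolerance = 1e-9)
  expect_true(ab$selected) # 0.667 >= 0.66 with 3 representatives
  ac <- tab[tab$moa_1 == "mA" & tab$moa_2 == "mC", ]
  expect_false(ac$selected) # only 2 representatives despite mean 1
})

test_that("a mechanism-pair effect in the generator is recovered by the table", {
  act <- moa_compounds(
    c("P1", "P2", "P3", "H1", "H2", "H3", "X1", "X2"),
    list("mechP", "mechP", "mechP", "mechH", "mechH", "mechH", "mechX", "mechX")
  )
  truth <- truth_model(
    effects = tibble::tibble(moa_1 = "mechH", moa_2 = "mechP", effect = -0.4),
    replicate_noise_sd = 0, compound_noise_sd = 0
  )
  rec <- simulate_screen(act, truth, seed = 1)$records
  tab <- synergistic_moa_pairs(rec, act)
  hp <- tab[tab$moa_1 == "mechH" & tab$moa_2 == "mechP", ]
  expect_equal(hp$n, 9)
  expect_true(hp$selected)
  expect_false(any(tab$selected[!(tab$moa_1 == "mechH" & tab$moa_2 == "mechP")]))
})

test_that("top-k nomination sorts, caps and breaks ties canonically", {
  set.seed(61)
  pairs <- enumerate_pairs(sprintf("c%02d", 1:15))
  ps <- prediction_set(pairs, round(runif(nrow(pairs)), 2))
  nom <- topk_nomination(ps, k = 30)
  expect_equal(nrow(nom), 30)
  expect_equal(nom$rank, 1:30)
  expect_true(all(diff(nom$score) <= 0))
  full <- topk_nomination(ps, k = nrow(ps))
  expect_equal(nrow(full), nrow(ps))
  expect_error(topk_nomination(ps, k = nrow(ps) + 1), "available")
  # tie at the cut goes to the lexicographically earlier key
  tie <- prediction_set(pairs[1:3, ], c(1, 0.5, 0.5))
  nom2 <- topk_nomination(tie, k = 2)
  ordered_keys <- paste(tie$compound_1, tie$compound_2)[2:3]
  expect_equal(paste(nom2$compound_1[2], nom2$compound_2[2]), min(ordered_keys))
})

test_that("tiered nomination fills exact quotas from an engineered pool", {
  # training actives t1..t6 carry mechA; the selected mechanism pair is
  # (mechA, mechB), established by three all-synergistic training pairs
  train <- moa_compounds(sprintf("t%d", 1:6),
    as.list(rep(c("mechA", "mechB"), 3)), in_training = TRUE)
  newA <- moa_compounds(sprintf("na%02d", 1:8), as.list(rep("mechA", 8)))
  newB <- moa_compounds(sprintf("nb%02d", 1:8), as.list(rep("mechB", 8)))
  newC <- moa_compounds(sprintf("nc%02d", 1:8), as.list(rep("mechC", 8)))
  comps <- dplyr::bind_rows(train, newA, newB, newC)
  train_rec <- tibble::tibble(
    compound_1 = c("t1", "t3", "t5"), compound_2 = c("t2", "t4", "t6"),
    label = TRUE
  )
  moa_tab <- synergistic_moa_pairs(train_rec, comps)
  expect_true(moa_tab$selected[moa_tab$moa_1 == "mechA" & moa_tab$moa_2 == "mechB"])

  pool <- dplyr::bind_rows(
    # tier-1 pool: one compound in training, mechanism pair (mechA, mechB)
    make_key(rep(c("t2", "t4", "t6"), each = 8), rep(newA$id, 3))[1:16, ],
    # tier-2 pool: one in training, (mechA, mechC) never selected
    make_key(rep(c("t1", "t3", "t5"), each = 8), rep(newC$id, 3))[1:16, ],
    # tier-3 pool: nothing in training, mechanism pair selected
    make_key(rep(newA$id[1:4], each = 4), rep(newB$id[1:4], 4))
  )
  set.seed(3)
  cons <- prediction_set(pool, runif(nrow(pool), 0.75, 0.99))
  desc <- prediction_set(pool, runif(nrow(pool)))
  nom <- tiered_nomination(cons, desc, comps, moa_tab)
  expect_equal(nrow(nom), 30)
  expect_equal(as.vector(table(nom$tier)[c("tier1", "tier2", "tier3")]), c(12L, 12L, 6L))
  expect_equal(nom$rank, 1:30)
  expect_false(anyDuplicated(paste(nom$compound_1, nom$compound_2)) > 0)
  # tier membership is exclusive and honours the filters
  t1_keys <- nom[nom$tier == "tier1", c("compound_1", "compound_2")]
  expect_true(all(t1_keys$compound_1 %in% c(train$id, newA$id) |
    t1_keys$compound_2 %in% train$id))

  # empty mechanism table: tiers 1 and 3 empty, tier 2 full
  empty_tab <- moa_tab
  empty_tab$selected <- FALSE
  expect_warning(nom2 <- tiered_nomination(cons, desc, comps, empty_tab), "shortfall")
  expect_equal(sum(nom2$tier == "tier1"), 0)
  expect_equal(sum(nom2$tier == "tier3"), 0)
  expect_equal(sum(nom2$tier == "tier2"), 12)
})

test_that("diversity cap limits per-compound appearances", {
  # one compound dominating the top of the ranking appears exactly cap times
  others <- sprintf("z%02d", 1:40)
  rest <- enumerate_pairs(others)
  pairs <- dplyr::bind_rows(make_key(rep("hub", 40), others), rest)
  scores <- c(seq(1, 0.61, length.out = 40), seq(0.6, 0.01, length.out = nrow(rest)))
  ps <- prediction_set(pairs, scores)
  nom <- diversity_capped_topk(ps, k = 30, per_compound_cap = 5)
  expect_equal(nrow(nom), 30)
  expect_equal(sum(nom$compound_1 == "hub" | nom$compound_2 == "hub"), 5)
  # infinite cap degenerates to plain top-k
  expect_equal(
    diversity_capped_topk(ps, k = 30, per_compound_cap = Inf)$score,
    topk_nomination(ps, k = 30)$score
  )
})

test_that("overlap reports count shared pairs and the union", {
  mk <- function(prefix) {
    new_pairs <- make_key(paste0(prefix, 1:30), paste0(prefix, "x", 1:30))
    prediction_set(new_pairs, seq(1, 0.5, length.out = 30))
  }
  l1 <- topk_nomination(mk("a"), 30)
  l2 <- topk_nomination(mk("b"), 30)
  l3 <- topk_nomination(mk("c"), 30)
  rep1 <- overlap_report(list(A = l1, B = l2, C = l3))
  expect_equal(rep1$union_size, 90)
  expect_true(all(rep1$pairwise$shared == 0))
  # one shared pair between two teams
  l2b <- l2
  l2b$compound_1[1] <- l1$compound_1[1]
  l2b$compound_2[1] <- l1$compound_2[1]
  rep2 <- overlap_report(list(A = l1, B = l2b, C = l3))
  expect_equal(rep2$union_size, 89)
  expect_equal(rep2$pairwise$shared[rep2$pairwise$team_1 == "A" & rep2$pairwise$team_2 == "B"], 1)
  rep3 <- overlap_report(list(A = l1, B = l1))
  expect_equal(rep3$union_size, 30)
})
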