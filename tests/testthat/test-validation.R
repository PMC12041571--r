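test_that("one-compound-out folds have the defining exclusion structure", {
  scr <- small_screen(seed = 5, n_library = 60, n_active = 12)
  rec <- scr$records
  folds <- one_compound_out_folds(scr$actives, rec)
  expect_equal(nrow(folds), 12)
  appearances <- integer(nrow(rec))
  for (f in seq_len(nrow(folds))) {
    val <- folds$validation[[f]]
    trn <- folds$train[[f]]
    held <- folds$held_out[f]
    expect_equal(length(val), 11) # n-1 pairs contain the held-out compound
    # brute-force leakage oracle
    expect_true(all(rec$compound_1[val] == held | rec$compound_2[val] == held))
    expect_false(any(rec$compound_1[trn] == held | rec$compound_2[trn] == held))
    expect_length(intersect(val, trn), 0)
    appearances[val] <- appearances[val] + 1L
  }
  expect_true(all(appearances == 2L)) # each pair has two members
  expect_error(one_compound_out_folds(scr$actives$id[-1], rec), "not in the list")
})

test_that("everything-out folds never share compounds between train and validation", {
  scr <- small_screen(seed = 6, n_library = 80, n_active = 32)
  rec <- scr$records
  folds <- everything_out_folds(scr$actives, rec, n_groups = 2, seed = 2)
  expect_equal(nrow(folds), 2)
  for (f in 1:2) {
    val <- folds$validation[[f]]
    trn <- folds$train[[f]]
    expect_equal(length(val), choose(16, 2)) # 16/16 split of a complete screen
    val_ids <- unique(c(rec$compound_1[val], rec$compound_2[val]))
    trn_ids <- unique(c(rec$compound_1[trn], rec$compound_2[trn]))
    expect_length(intersect(val_ids, trn_ids), 0)
  }
  expect_identical(
    everything_out_folds(scr$actives, rec, n_groups = 3, seed = 7),
    everything_out_folds(scr$actives, rec, n_groups = 3, seed = 7)
  )
})

test_that("y-randomization permutes responses while preserving their multiset", {
  scr <- small_screen(seed = 8, n_library = 40, n_active = 10)
  shuf <- y_randomize(scr$records, seed = 3)
  expect_equal(sort(shuf$gamma_mean), sort(scr$records$gamma_mean))
  expect_equal(sum(shuf$label), sum(scr$records$label))
  expect_identical(shuf, y_randomize(scr$records, seed = 3))
  expect_identical(shuf$compound_1, scr$records$compound_1) # keys untouched
})

test_that("confusion metrics agree with a brute-force recomputation", {
  set.seed(14)
  scores <- runif(200)
  labels <- runif(200) < scores # correlated labels
  pred <- scores >= 0.5
  m <- confusion_metrics(confusion_counts(labels, pred))
  # independent recomputation from raw lists
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  expect_equal(m$sens, tp / (tp + fn))
  expect_equal(m$spec, tn / (tn + fp))
  expect_equal(m$ppv, tp / (tp + fp))
  expect_equal(m$npv, tn / (tn + fn))
  expect_equal(m$bacc, (m$sens + m$spec) / 2)
  expect_equal(m$ccr, m$bacc)
})

test_that("undefined metric ratios are missing values, not zeros", {
  m <- confusion_metrics(tibble::tibble(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(m$sens)) # 0/0
  expect_true(is.na(m$ppv))
  expect_equal(m$spec, 1)
  # tn=0 with fn=1 is 0/1: defined, equals 0
  m2 <- confusion_metrics(tibble::tibble(tp = 50, tn = 0, fp = 37, fn = 1))
  expect_equal(m2$npv, 0)
  expect_error(confusion_metrics(tibble::tibble(tp = 0, tn = 0, fp = 0, fn = 0)))
})

test_that("roc_auc matches pair enumeration and handles edge cases", {
  # hand case: enumerate positive-negative pairs
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_true(is.na(roc_auc(runif(5), rep(TRUE, 5))))
  set.seed(2)
  scores <- runif(4000)
  labels <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)
  # agreement with explicit Mann-Whitney enumeration on a small case
  s <- c(0.1, 0.5, 0.5, 0.9, 0.3)
  l <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  pairs <- expand.grid(p = which(l), n = which(!l))
  brute <- mean(ifelse(s[pairs$p] > s[pairs$n], 1, ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(s, l), brute)
})

test_that("hit_rate counts confirmed nominations and demands full truth coverage", {
  nom <- make_key(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10))
  truth <- dplyr::bind_cols(nom, tibble::tibble(label = rep(c(TRUE, FALSE), 5)))
  hr <- hit_rate(nom, truth)
  expect_equal(hr$hit_rate, 0.5)
  expect_equal(hr$hit_rate_pct, 50L)
  expect_error(hit_rate(nom, truth[-1, ]), "No truth entry")
})
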