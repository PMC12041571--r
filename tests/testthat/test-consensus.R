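toy_sets <- function(scores_list) {
  pairs <- make_key(sprintf("B%02d", seq_along(scores_list[[1]])),
    sprintf("A%02d", seq_along(scores_list[[1]])))
  lapply(seq_along(scores_list), function(i) {
    prediction_set(pairs, scores_list[[i]], model_id = paste0("m", i),
      kind = "classifier_probability")
  })
}

test_that("regression pseudo-probabilities invert the gamma ranking exactly", {
  pairs <- make_key(c("b", "c", "d"), c("a", "a", "a"))
  ps <- prediction_set(pairs, c(0.5, 1.0, 1.5), kind = "regression_raw")
  out <- regression_to_pseudo_probability(ps)
  expect_equal(out$score, c(1.0, 0.5, 0.0))
  expect_equal(attr(out, "kind"), "regression_pseudo_probability")
  set.seed(31)
  g <- runif(50, 0.3, 1.7)
  ps2 <- prediction_set(make_key(sprintf("x%02d", 1:50), rep("a", 50)), g,
    kind = "regression_raw")
  out2 <- regression_to_pseudo_probability(ps2)
  expect_equal(cor(out2$score, g, method = "spearman"), -1)
  flat <- prediction_set(pairs, rep(0.7, 3), kind = "regression_raw")
  expect_error(regression_to_pseudo_probability(flat),
    class = "comboscreen_degenerate_scale")
})

test_that("average consensus is the per-key mean and permutation-invariant", {
  sets <- toy_sets(list(c(0.2, 0.6), c(0.8, 0.6)))
  avg <- average_consensus(sets)
  expect_equal(avg$score, c(0.5, 0.6))
  expect_equal(average_consensus(rev(sets))$score, avg$score)
  expect_equal(average_consensus(sets[c(1, 1)])$score, sets[[1]]$score)
  bad <- toy_sets(list(c(0.2, 0.6)))[[1]]
  bad$compound_2[1] <- "ZZ"
  expect_error(average_consensus(list(sets[[1]], bad)), "identical pair keys")
})

test_that("majority vote follows the documented tie-break", {
  three <- toy_sets(list(c(0.9, 0.1), c(0.8, 0.2), c(0.1, 0.3)))
  v <- majority_vote(three)
  expect_equal(v$label, c(TRUE, FALSE))
  two <- toy_sets(list(c(0.9), c(0.1)))
  expect_true(majority_vote(two)$label) # even split -> synergistic
  expect_false(all(majority_vote(toy_sets(list(c(0.1), c(0.2), c(0.3))))$label))
})

test_that("bliss residual scoring matches the reference-model identities", {
  expect_equal(bliss_residual_score(0.75, 0.5, 0.5), 0)
  expect_equal(bliss_residual_score(1, 0, 0), 1)
  expect_equal(bliss_residual_score(0, 1, 1), -1)
  expect_error(bliss_residual_score(1.2, 0.5, 0.5))
  set.seed(41)
  c_ab <- runif(200); s_a <- runif(200); s_b <- runif(200)
  sc <- bliss_residual_score(c_ab, s_a, s_b)
  expect_true(all(sc >= -1 & sc <= 1))
  # cross-module consistency: zero residual exactly on Bliss-composed surfaces
  expect_equal(bliss_residual_score(bliss_expected(s_a, s_b), s_a, s_b), rep(0, 200))
})

test_that("learners separate a separable toy problem and are seed-deterministic", {
  set.seed(51)
  n <- 120
  X <- cbind(matrix(runif(n * 6), n), noise = runif(n))
  y <- as.numeric(X[, 1] + X[, 2] > 1)
  gam <- 1.2 - 0.5 * y + rnorm(n, 0, 0.02)
  rec <- tibble::tibble(
    compound_1 = sprintf("a%03d", 1:n), compound_2 = sprintf("b%03d", 1:n),
    gamma_mean = gam, label = y == 1
  )
  pairs <- rec[, 1:2]
  for (alg in c("bagged_trees", "boosted_trees")) {
    spec <- learner_spec(alg, "classification")
    fit <- fit_predict(spec, X, rec, X, test_pairs = pairs, seed = 1)
    expect_gt(roc_auc(fit$scores$score, rec$label), 0.95)
    fit2 <- fit_predict(spec, X, rec, X, test_pairs = pairs, seed = 1)
    expect_identical(fit$scores$score, fit2$scores$score)
  }
  net <- learner_spec("feedforward_net", "classification",
    list(hidden = c(16, 8), epochs = 60, learning_rate = 0.01))
  fitn <- fit_predict(net, X, rec, X, test_pairs = pairs, seed = 2)
  expect_gt(roc_auc(fitn$scores$score, rec$label), 0.95)
  # regression mode emits raw gamma-scale predictions
  rfit <- fit_predict(learner_spec("bagged_trees", "regression"), X, rec, X,
    test_pairs = pairs, seed = 1)
  expect_lt(mean(abs(rfit$scores$score - rec$gamma_mean)), 0.2)
  expect_equal(attr(rfit$scores, "kind"), "regression_raw")
  # degenerate one-class training rejected for classifiers
  rec1 <- rec; rec1$label <- TRUE
  expect_error(
    fit_predict(learner_spec("bagged_trees", "classification"), X, rec1, X,
      test_pairs = pairs, seed = 1),
    class = "comboscreen_degenerate_training"
  )
  # constant features carry no signal
  Xc <- matrix(1, n, 3)
  cfit <- fit_predict(learner_spec("bagged_trees", "classification"), Xc, rec, Xc,
    test_pairs = pairs, seed = 1)
  expect_equal(roc_auc(cfit$scores$score, rec$label), 0.5)
})

test_that("the surrogate model is centred at zero residual on a null screen and deterministic", {
  act <- generate_library(screen_config(n_active = 10, n_library = 10, n_moas = 8), seed = 2)
  null_truth <- truth_model(replicate_noise_sd = 0, compound_noise_sd = 0)
  rec <- simulate_screen(act, null_truth, seed = 1)$records
  m <- surrogate_combo_model(act, rec, epochs = 250, seed = 3)
  pr <- predict(m, rec, act)
  expect_lt(abs(mean(pr$score)), 0.05)
  expect_true(all(pr$c_ab >= 0 & pr$c_ab <= 1))
  m2 <- surrogate_combo_model(act, rec, epochs = 250, seed = 3)
  expect_identical(predict(m2, rec, act)$score, pr$score)
  expect_error(surrogate_combo_model(act, rec[0, ], seed = 1), "No combination")
})
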