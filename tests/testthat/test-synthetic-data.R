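test_that("library generation honours the configuration and is deterministic", {
  cfg <- screen_config(n_active = 5, n_library = 5, n_moas = 10)
  lib <- generate_library(cfg, seed = 1)
  expect_equal(nrow(lib), 5)
  expect_true(all(lib$is_active))

  cfg2 <- screen_config(n_active = 12, n_library = 90, n_moas = 40)
  lib_a <- generate_library(cfg2, seed = 42)
  lib_b <- generate_library(cfg2, seed = 42)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_compounds(lib_a, p1)
  write_compounds(lib_b, p2)
  expect_identical(readLines(p1), readLines(p2)) # byte-identical output
  expect_equal(sum(lib_a$is_active), 12)
  expect_true(all(is.finite(lib_a$log_ic50[lib_a$is_active])))
  rng <- range(lib_a$log_ic50[lib_a$is_active])
  expect_gte(rng[1], -8.7)
  expect_lte(rng[2], -5.5)
  # every structure parses and ids are unique
  expect_false(anyDuplicated(lib_a$id) > 0)
  for (s in unique(lib_a$smiles)) expect_s3_class(parse_smiles(s), "mol")
})

test_that("additive null screen has gamma 1 everywhere and no synergy calls", {
  act <- moa_compounds(sprintf("C%d", 1:6), as.list(sprintf("m%d", 1:6)))
  null_truth <- truth_model(replicate_noise_sd = 0, compound_noise_sd = 0)
  rec <- simulate_screen(act, null_truth, seed = 1)$records
  expect_equal(nrow(rec), 15)
  expect_true(all(rec$gamma_mean == 1))
  expect_false(any(rec$label))
})

test_that("a forced mechanism-pair effect propagates exactly at zero noise", {
  act <- moa_compounds(
    c("P1", "P2", "H1", "H2", "X1"),
    list("mechP", "mechP", "mechH", "mechH", "mechX")
  )
  truth <- truth_model(
    effects = tibble::tibble(moa_1 = "mechH", moa_2 = "mechP", effect = -0.4),
    replicate_noise_sd = 0, compound_noise_sd = 0
  )
  rec <- simulate_screen(act, truth, seed = 1)$records
  carrier <- (rec$compound_1 %in% c("P1", "P2") & rec$compound_2 %in% c("H1", "H2")) |
    (rec$compound_1 %in% c("H1", "H2") & rec$compound_2 %in% c("P1", "P2"))
  expect_true(all(rec$gamma_mean[carrier] == 0.6))
  expect_true(all(rec$label[carrier]))
  expect_true(all(rec$gamma_mean[!carrier] == 1))
  # ground-truth recoverability: labels equal the mechanism rule for every pair
  expect_equal(rec$label, label_synergy(rec$gamma_true))
})

test_that("simulated gammas are clipped and the null screen is centred on baseline", {
  act <- moa_compounds(sprintf("C%d", 1:10), as.list(sprintf("m%d", 1:10)))
  truth <- truth_model(replicate_noise_sd = 0.3, compound_noise_sd = 0.3)
  rec <- simulate_screen(act, truth, seed = 5)$records
  g <- c(rec$gamma_rep1, rec$gamma_rep2)
  expect_true(all(g >= 0 & g <= 2))
  se <- sd(rec$gamma_mean) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$gamma_mean) - 1), 3 * se + 0.02) # clip bias margin
  # seeded determinism
  rec2 <- simulate_screen(act, truth, seed = 5)$records
  expect_identical(rec, rec2)
})

test_that("noise calibration reaches the target replicate correlation", {
  scr <- small_screen(seed = 7)
  truth <- calibrate_noise(scr$actives, scr$truth, target_pearson = 0.83, seed = 7)
  rec <- simulate_screen(scr$actives, truth, seed = 8)$records
  r <- cor(rec$gamma_rep1, rec$gamma_rep2)
  expect_lt(abs(r - 0.83), 0.05)
  # zero replicate noise gives perfect agreement
  t0 <- scr$truth
  t0$replicate_noise_sd <- 0
  rec0 <- simulate_screen(scr$actives, t0, seed = 8)$records
  expect_equal(cor(rec0$gamma_rep1, rec0$gamma_rep2), 1.0)
  # a variance-free screen cannot reach any correlation target
  flat <- truth_model(replicate_noise_sd = 0, compound_noise_sd = 0)
  expect_error(
    calibrate_noise(scr$actives, flat, target_pearson = 0.99, seed = 1),
    class = "comboscreen_calibration_error"
  )
})
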