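test_that("compound and combination tables round-trip through CSV", {
  scr <- small_screen(seed = 19, n_library = 30, n_active = 8)
  d <- withr::local_tempdir()
  cp <- file.path(d, "compounds.csv")
  write_compounds(scr$library, cp)
  lib2 <- read_compounds(cp)
  expect_equal(lib2$id, scr$library$id)
  expect_equal(lib2$log_ic50, scr$library$log_ic50)
  expect_equal(lib2$moa, scr$library$moa)
  expect_error(
    read_compounds({
      p <- file.path(d, "dup.csv")
      write_compounds(dplyr::bind_rows(scr$library, scr$library[1, ]), p)
      p
    }),
    "Duplicate"
  )
})

test_that("combination reader canonicalizes and rejects duplicate pairs", {
  scr <- small_screen(seed = 23, n_library = 30, n_active = 6)
  d <- withr::local_tempdir()
  rec <- scr$records
  # write with flipped pair order
  flipped <- rec
  flipped$compound_1 <- rec$compound_2
  flipped$compound_2 <- rec$compound_1
  p <- file.path(d, "flip.csv")
  readr::write_csv(flipped, p)
  expect_warning(back <- read_combinations(p), "Canonicalized")
  expect_equal(back$compound_1, rec$compound_1)
  p2 <- file.path(d, "dup.csv")
  readr::write_csv(dplyr::bind_rows(rec, rec[3, ]), p2)
  expect_error(read_combinations(p2), class = "comboscreen_duplicate_pair")
})

test_that("dose-response matrices round-trip through long CSV", {
  a <- tibble::tibble(id = "A", log_ic50 = -6.5)
  b <- tibble::tibble(id = "B", log_ic50 = -6)
  mats <- list(
    simulate_matrix(a, b, gamma = 0.7, noise_sd = 0.01, seed = 1, replicate = 1),
    simulate_matrix(a, b, gamma = 0.7, noise_sd = 0.01, seed = 2, replicate = 2)
  )
  p <- withr::local_tempfile(fileext = ".csv")
  write_matrices(mats, p)
  back <- read_matrices(p)
  expect_length(back, 2)
  reps <- vapply(back, function(m) m$replicate, integer(1))
  orig <- mats[order(vapply(mats, function(m) m$replicate, integer(1)))]
  for (i in seq_along(back)) {
    m <- back[[order(reps)[i]]]
    expect_equal(m$response, orig[[i]]$response)
    expect_equal(m$conc_a, orig[[i]]$conc_a)
  }
})

test_that("the end-to-end pipeline runs, writes artifacts and is deterministic", {
  cfg <- pipeline_config(
    screen = screen_config(n_active = 10, n_library = 60, n_moas = 25),
    learners = list(clf = learner_spec("bagged_trees", "classification",
      list(n_trees = 15, max_depth = 4))),
    n_candidates = 150,
    network = list(gamma_cutoff = 0.95, n_reps = 50)
  )
  d <- withr::local_tempdir()
  res <- suppressMessages(run_pipeline(cfg, seed = 5, out_dir = d))
  expect_true(file.exists(file.path(d, "manifest.txt")))
  for (f in c("compounds.csv", "combinations.csv", "predictions.csv",
    "metrics.csv", "hit_rates.csv", "network_edges.tsv")) {
    expect_true(file.exists(file.path(d, f)), label = f)
  }
  expect_true(file.exists(file.path(d, "network.graphml")))
  g <- igraph::read_graph(file.path(d, "network.graphml"), format = "graphml")
  expect_gt(igraph::vcount(g), 0)
  manifest <- readLines(file.path(d, "manifest.txt"))
  expect_true(any(grepl("^seed=5$", manifest)))
  expect_true(any(grepl("^config_hash=", manifest)))
  # rerun with the same config and seed reproduces the metric report
  res2 <- suppressMessages(run_pipeline(cfg, seed = 5))
  expect_equal(res2$metrics, res$metrics)
  expect_identical(res2$consensus$score, res$consensus$score)
})

test_that("configuration errors name the offending field", {
  expect_error(
    pipeline_config(learners = list(clf = "random_forest")),
    "learners"
  )
  expect_error(
    pipeline_config(validation = list(scheme = "leave_none_out")),
    "validation\\$scheme"
  )
})
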