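# shared fixtures, all generated in code

# small annotated library + screen used across module tests
small_screen <- function(seed = 11, n_library = 120, n_active = 16,
                         n_moas = 30, calibrate = FALSE) {
  cfg <- screen_config(
    n_active = n_active, n_library = n_library, n_moas = n_moas
  )
  lib <- generate_library(cfg, seed = seed)
  act <- lib[lib$is_active, ]
  truth <- default_truth_model(act, seed = seed)
  if (calibrate) truth <- calibrate_noise(act, truth, 0.83, seed = seed)
  screen <- simulate_screen(act, truth, seed = seed)
  list(config = cfg, library = lib, actives = act, truth = truth,
    records = screen$records)
}

# tiny hand-built compound table with controlled MoA labels
moa_compounds <- function(ids, moas, in_training = FALSE, is_active = TRUE,
                          log_ic50 = -7) {
  tibble::tibble(
    id = ids,
    smiles = rep_len(c("c1ccccc1", "CCO", "CCN", "CCC"), length(ids)),
    log_ic50 = rep_len(log_ic50, length(ids)),
    moa = as.list(moas),
    is_active = rep_len(is_active, length(ids)),
    in_training = rep_len(in_training, length(ids))
  )
}
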