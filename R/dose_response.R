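# Dose-response matrices and reference-model synergy surfaces.
#
# The screen geometry is the 10x10 combination block: for each compound, a
# vehicle well (zero dose) plus nine 1:2 serial dilutions placed so the
# compound's IC50 falls in the middle of the nine-dose range. Synergy is read
# off the block by comparing observed fractional inhibition to a
# no-interaction reference surface (Bliss independence or highest single
# agent) built from the margins.

#' Serial-dilution concentration grid for one compound
#'
#' Element 1 is the vehicle (zero dose); elements 2..n_points form a
#' geometric series with the given dilution ratio, positioned so the IC50
#' sits between the 5th and 6th nonzero dose (geometric midpoint of the
#' nine-dose range).
#'
#' @param log_ic50 log10 molar IC50 of the compound.
#' @param n_points Total grid points including vehicle (default 10).
#' @param dilution Dilution ratio between adjacent doses (default 2, i.e.
#'   1:2 serial dilutions). Must exceed 1.
#' @return Numeric vector of length `n_points`, molar.
#' @export
concentration_grid <- function(log_ic50, n_points = 10, dilution = 2) {
  if (!is.finite(log_ic50)) abort("`log_ic50` must be finite.")
  if (!is.finite(dilution) || dilution <= 1) abort("`dilution` must be > 1.")
  ndose <- n_points - 1L
  ic50 <- 10^log_ic50
  # doses d_k = d_1 * dilution^(k-1); IC50 = geometric mean of d_5 and d_6
  mid <- (ndose + 2) / 2 # 5.5 for nine doses
  doses <- ic50 * dilution^(seq_len(ndose) - mid)
  c(0, doses)
}

#' Hill dose-response curve
#'
#' Standard sigmoidal fractional-inhibition model:
#' `e_max * conc^slope / (conc^slope + ic50^slope)`.
#'
#' @param conc Concentration(s), molar, >= 0.
#' @param ic50 Half-maximal concentration, molar, > 0.
#' @param slope Hill slope, > 0.
#' @param e_max Maximal inhibition fraction in (0, 1].
#' @return Fractional inhibition in `[0, e_max]`.
#' @export
hill_response <- function(conc, ic50, slope = 1, e_max = 1) {
  stopifnot(all(conc >= 0), ic50 > 0, slope > 0, e_max > 0, e_max <= 1)
  e_max * conc^slope / (conc^slope + ic50^slope)
}

#' Bliss independence expected combination response
#'
#' Probabilistic non-interaction reference: two independently acting agents
#' with single-agent inhibitions `s_a` and `s_b` combine to
#' `s_a + s_b - s_a * s_b`.
#'
#' @param s_a,s_b Single-agent fractional inhibitions in `[0, 1]`.
#' @return Expected combined inhibition in `[0, 1]`.
#' @export
bliss_expected <- function(s_a, s_b) {
  check_fraction(s_a, "s_a")
  check_fraction(s_b, "s_b")
  s_a + s_b - s_a * s_b
}

#' Highest-single-agent expected combination response
#'
#' @inheritParams bliss_expected
#' @return `max(s_a, s_b)` element-wise.
#' @export
hsa_expected <- function(s_a, s_b) {
  check_fraction(s_a, "s_a")
  check_fraction(s_b, "s_b")
  pmax(s_a, s_b)
}

#' Construct a dose-response matrix object
#'
#' @param key One-row pair table (see [make_key()]).
#' @param conc_a,conc_b Concentration vectors (index 1 = vehicle).
#' @param response Matrix of fractional inhibition, rows indexed by `conc_a`.
#' @param replicate Replicate number.
#' @return Object of class `drc_matrix`.
#' @export
drc_matrix <- function(key, conc_a, conc_b, response, replicate = 1L) {
  response <- as.matrix(response)
  stopifnot(
    nrow(response) == length(conc_a), ncol(response) == length(conc_b),
    all(is.finite(response)), conc_a[1] == 0, conc_b[1] == 0
  )
  if (any(diff(conc_a[-1]) <= 0) || any(diff(conc_b[-1]) <= 0)) {
    abort("Concentration vectors must be strictly increasing after the vehicle well.")
  }
  if (abs(response[1, 1]) > 0.05) {
    abort("Vehicle well response[1,1] must be ~0.")
  }
  structure(list(
    key = key, conc_a = conc_a, conc_b = conc_b,
    response = response, replicate = as.integer(replicate)
  ), class = "drc_matrix")
}

#' @export
print.drc_matrix <- function(x, ...) {
  cat(sprintf(
    "<drc_matrix> %s + %s, replicate %d, %dx%d grid, mean inhibition %.3f\n",
    x$key$compound_1, x$key$compound_2, x$replicate,
    nrow(x$response), ncol(x$response), mean(x$response)
  ))
  invisible(x)
}

#' Tidy a dose-response matrix into long format
#' @param x A `drc_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per well.
#' @export
tidy.drc_matrix <- function(x, ...) {
  grid <- tidyr::expand_grid(
    i = seq_along(x$conc_a), j = seq_along(x$conc_b)
  )
  tibble(
    compound_1 = x$key$compound_1, compound_2 = x$key$compound_2,
    replicate = x$replicate,
    dose_index_1 = grid$i, dose_index_2 = grid$j,
    conc_1 = x$conc_a[grid$i], conc_2 = x$conc_b[grid$j],
    response = as.numeric(x$response[cbind(grid$i, grid$j)])
  )
}

#' Excess-over-reference synergy surface of a combination block
#'
#' Builds the cell-wise expected surface from the chosen reference model over
#' the single-agent margins, subtracts it from the observed block, and
#' summarises the excess as the mean over the nonzero-dose cells. Positive
#' summaries indicate more inhibition than the non-interaction expectation
#' (synergy).
#'
#' @param matrix A [drc_matrix()].
#' @param model `"bliss"` or `"hsa"`.
#' @param single_agent_responses Optional list of two vectors of marginal
#'   responses aligned to `conc_a`/`conc_b`; defaults to the block's own
#'   margin rows/columns.
#' @return Object of class `synergy_surface` with `expected`, `excess`,
#'   `summary`.
#' @export
excess_surface <- function(matrix, model = c("bliss", "hsa"),
                           single_agent_responses = NULL) {
  model <- match.arg(model)
  obs <- matrix$response
  if (is.null(single_agent_responses)) {
    s_a <- obs[, 1] # margin of compound A: B at vehicle
    s_b <- obs[1, ]
  } else {
    s_a <- single_agent_responses[[1]]
    s_b <- single_agent_responses[[2]]
    stopifnot(length(s_a) == nrow(obs), length(s_b) == ncol(obs))
  }
  ref_fun <- if (model == "bliss") bliss_expected else hsa_expected
  expected <- outer(s_a, s_b, ref_fun)
  excess <- obs - expected
  nz <- excess[-1, -1, drop = FALSE] # 81 nonzero-dose cells of a 10x10 block
  structure(list(
    model = model, expected = expected, excess = excess,
    summary = mean(nz), key = matrix$key, replicate = matrix$replicate
  ), class = "synergy_surface")
}

#' @export
print.synergy_surface <- function(x, ...) {
  cat(sprintf(
    "<synergy_surface> %s + %s, model %s, mean excess %.4f\n",
    x$key$compound_1, x$key$compound_2, x$model, x$summary
  ))
  invisible(x)
}

#' @export
glance.synergy_surface <- function(x, ...) {
  tibble(
    compound_1 = x$key$compound_1, compound_2 = x$key$compound_2,
    model = x$model, replicate = x$replicate, mean_excess = x$summary
  )
}

#' Simulate one combination dose-response block
#'
#' Margins follow Hill curves for the two compounds; interior cells are the
#' Bliss expectation of the margins plus a synergy shift
#' `kappa * (1 - gamma)` on nonzero-dose cells (so gamma = 1 is additive,
#' gamma < 1 produces excess inhibition) plus optional well noise, clipped to
#' `[0, 1]`.
#'
#' @param a,b One-row compound data frames with `id` and `log_ic50`.
#' @param gamma Simulated gamma score in `[0, 2]`.
#' @param noise_sd Per-well Gaussian noise sd.
#' @param seed Integer seed (well noise only).
#' @param kappa Excess-inhibition scale per unit of (1 - gamma), default 0.25.
#' @param slope,e_max Hill parameters of both margins.
#' @param replicate Replicate number stored on the block.
#' @return A [drc_matrix()].
#' @export
simulate_matrix <- function(a, b, gamma, noise_sd = 0, seed = 1,
                            kappa = 0.25, slope = 1, e_max = 0.7,
                            replicate = 1L) {
  stopifnot(gamma >= 0, gamma <= 2)
  key <- make_key(a$id, b$id)
  conc_a <- concentration_grid(a$log_ic50)
  conc_b <- concentration_grid(b$log_ic50)
  s_a <- c(0, hill_response(conc_a[-1], 10^a$log_ic50, slope, e_max))
  s_b <- c(0, hill_response(conc_b[-1], 10^b$log_ic50, slope, e_max))
  resp <- outer(s_a, s_b, bliss_expected)
  shift <- matrix(0, length(conc_a), length(conc_b))
  shift[-1, -1] <- kappa * (1 - gamma)
  resp <- resp + shift
  if (noise_sd > 0) {
    resp <- resp + with_seed(seed, matrix(
      rnorm(length(resp), 0, noise_sd), nrow(resp)
    ))
    resp[1, 1] <- 0 # vehicle well is the normalisation anchor
  }
  resp <- pmin(pmax(resp, 0), 1)
  drc_matrix(key, conc_a, conc_b, resp, replicate)
}

#' Heatmap of a dose-response block
#' @param object A `drc_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drc_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$dose_index_2), y = factor(.data$dose_index_1),
    fill = .data$response
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "inhibition") +
    ggplot2::labs(
      x = object$key$compound_2, y = object$key$compound_1,
      title = sprintf("Combination block, replicate %d", object$replicate)
    ) +
    ggplot2::theme_minimal()
}
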