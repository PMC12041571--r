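# Score combination and consensus.
#
# Every base learner emits a prediction set: one synergy score per canonical
# pair, on a [0, 1] scale where higher means more synergistic. Classifier
# probabilities are used as-is; regression gamma predictions are flipped into
# pseudo-probabilities; the multi-task surrogate model emits a Bliss-residual
# score rescaled to the same orientation. Consensus is the per-pair mean, or
# a majority vote on thresholded labels.

#' Construct a prediction set
#'
#' @param pairs Pair table (`compound_1`, `compound_2`).
#' @param score Numeric scores aligned with `pairs`.
#' @param model_id Identifier of the producing model.
#' @param kind One of `"classifier_probability"`,
#'   `"regression_pseudo_probability"`, `"regression_raw"`,
#'   `"bliss_residual_rescaled"`, `"consensus"`.
#' @return A tibble of class `prediction_set` with columns `compound_1`,
#'   `compound_2`, `score`; attributes `model_id` and `kind`.
#' @export
prediction_set <- function(pairs, score, model_id = "model",
                           kind = c(
                             "classifier_probability",
                             "regression_pseudo_probability",
                             "regression_raw",
                             "bliss_residual_rescaled", "consensus"
                           )) {
  kind <- match.arg(kind)
  pairs <- canonicalize_pairs(as_tibble(pairs)[, c("compound_1", "compound_2")],
    quiet = TRUE
  )
  if (any(!is.finite(score))) abort("Prediction scores must be finite.")
  stopifnot(length(score) == nrow(pairs))
  out <- dplyr::bind_cols(pairs, tibble(score = as.numeric(score)))
  attr(out, "model_id") <- model_id
  attr(out, "kind") <- kind
  class(out) <- c("prediction_set", class(out))
  out
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf(
    "<prediction_set> %s (%s), %d pairs\n",
    attr(x, "model_id"), attr(x, "kind"), nrow(x)
  ))
  NextMethod()
}

# shared-key check used by the consensus operations
assert_same_keys <- function(sets) {
  keys <- lapply(sets, function(s) pair_id(s$compound_1, s$compound_2))
  ref <- sort(keys[[1]])
  for (k in keys[-1]) {
    if (!identical(sort(k), ref)) {
      abort("Prediction sets do not share identical pair keys.")
    }
  }
  keys
}

#' Convert regression gamma predictions to pseudo-probabilities
#'
#' Min-max scales the predicted gammas of the batch to `[0, 1]` and subtracts
#' from 1, so the lowest predicted gamma (strongest synergy) maps to 1 and
#' the highest to 0. Scaling is computed over the prediction batch being
#' converted; the scope is recorded in the result's attributes.
#'
#' @param predictions A `prediction_set` of kind `"regression_raw"` (or any
#'   pair table with a `score` column of predicted gammas).
#' @return A `prediction_set` of kind `"regression_pseudo_probability"`.
#' @export
regression_to_pseudo_probability <- function(predictions) {
  g <- predictions$score
  rng <- range(g)
  if (diff(rng) < 1e-12) {
    abort("All predicted gammas are equal; min-max scale undefined.",
      class = "comboscreen_degenerate_scale"
    )
  }
  out <- prediction_set(
    predictions, 1 - (g - rng[1]) / diff(rng),
    model_id = paste0(attr(predictions, "model_id") %||% "regression", "_pseudo"),
    kind = "regression_pseudo_probability"
  )
  attr(out, "scale_range") <- rng
  attr(out, "scale_scope") <- "prediction_batch"
  out
}

#' Average-probability consensus
#'
#' @param sets List of `prediction_set`s over identical pair keys.
#' @return A `prediction_set` of kind `"consensus"` (per-pair arithmetic
#'   mean).
#' @export
average_consensus <- function(sets) {
  stopifnot(length(sets) >= 1)
  keys <- assert_same_keys(sets)
  ref <- sets[[1]]
  mat <- vapply(seq_along(sets), function(i) {
    sets[[i]]$score[match(keys[[1]], keys[[i]])]
  }, numeric(nrow(ref)))
  if (nrow(ref) == 1) mat <- matrix(mat, nrow = 1)
  prediction_set(ref, rowMeans(mat),
    model_id = paste0("consensus(", paste(
      vapply(sets, function(s) attr(s, "model_id") %||% "?", character(1)),
      collapse = "+"
    ), ")"),
    kind = "consensus"
  )
}

#' Majority-vote consensus
#'
#' Each model votes synergistic where its score meets the threshold; the
#' pair label is the majority. An even split is called synergistic (the
#' documented tie-break, erring towards nomination).
#'
#' @param sets List of `prediction_set`s over identical keys (odd count
#'   recommended).
#' @param threshold Score threshold for a positive vote.
#' @return Tibble with `compound_1`, `compound_2`, `votes`, `label`.
#' @export
majority_vote <- function(sets, threshold = 0.5) {
  stopifnot(length(sets) >= 1)
  keys <- assert_same_keys(sets)
  ref <- sets[[1]]
  vmat <- vapply(seq_along(sets), function(i) {
    as.numeric(sets[[i]]$score[match(keys[[1]], keys[[i]])] >= threshold)
  }, numeric(nrow(ref)))
  if (!is.matrix(vmat)) vmat <- matrix(vmat, nrow = 1)
  votes <- rowSums(vmat)
  tibble(
    compound_1 = ref$compound_1, compound_2 = ref$compound_2,
    votes = as.integer(votes),
    label = votes >= length(sets) / 2
  )
}

#' Bliss-residual synergy score
#'
#' The combination's observed (or predicted) inhibition minus its Bliss
#' expectation from the single agents:
#' `c_ab - (s_a + s_b - s_a * s_b)`, in `[-1, 1]`, higher = more
#' synergistic.
#'
#' @param c_ab Combination inhibition in `[0, 1]`.
#' @param s_a,s_b Single-agent inhibitions in `[0, 1]`.
#' @return Numeric score(s) in `[-1, 1]`.
#' @export
bliss_residual_score <- function(c_ab, s_a, s_b) {
  check_fraction(c_ab, "c_ab")
  c_ab - bliss_expected(s_a, s_b)
}

# --- multi-task Bliss-residual surrogate ------------------------------------

# fixed-weight message-passing embedding: a seeded random graph convolution
# stack (2 rounds, sum pooling) over the mixture/compound graph; the
# trainable part of the surrogate sits on top of it
graph_conv_embedding <- function(mol, dim = 64, rounds = 2, seed = 7L) {
  Xf <- atom_feature_matrix(mol)
  A <- mol_adjacency(mol) + diag(nrow(Xf))
  W <- with_seed(seed, lapply(seq_len(rounds), function(r) {
    matrix(rnorm((if (r == 1) ncol(Xf) else dim) * dim, 0, 1 / sqrt(dim)),
      ncol = dim
    )
  }))
  H <- Xf
  for (r in seq_len(rounds)) H <- tanh(A %*% H %*% W[[r]])
  colSums(H)
}

surrogate_encode <- function(compounds, encoder, descriptor, seed) {
  if (encoder == "fingerprint_mlp") {
    featurize_compounds(compounds, descriptor)
  } else {
    t(vapply(
      seq_len(nrow(compounds)),
      function(i) graph_conv_embedding(parse_smiles(compounds$smiles[i]), seed = seed),
      numeric(64)
    ))
  }
}

#' Multi-task surrogate model of combination inhibition
#'
#' A small shared-encoder network in the style of structure-based
#' combination models: each compound is encoded (fingerprint MLP by default,
#' or a fixed seeded graph-convolution embedding), a single-agent head
#' predicts the compound's inhibition `s`, and a combination head predicts
#' the pair's inhibition `c(AB)` from the summed embeddings. The synergy
#' score of a pair is the Bliss residual `c(AB) - (s(A)+s(B)-s(A)s(B))`,
#' higher = more synergistic. All outputs pass through a sigmoid so they stay
#' in `[0, 1]`. Optional auxiliary screens (extra synergy-record tables, e.g.
#' simulated sister cell lines) are trained through additional combination
#' heads sharing the encoder, emulating multi-task pretraining at desk scale.
#'
#' @param compounds Compound tibble of the screened actives (`id`, `smiles`,
#'   `log_ic50`).
#' @param records Synergy-record tibble (uses `gamma_mean`).
#' @param encoder `"fingerprint_mlp"` or `"graph_conv"`.
#' @param descriptor Fingerprint family for the fingerprint encoder.
#' @param hidden_encoder,hidden_head Layer widths.
#' @param epochs,learning_rate Adam training schedule (full batch).
#' @param kappa Scale tying gamma to excess inhibition (matches
#'   [simulate_matrix()]).
#' @param aux_records Optional list of extra synergy-record tables for
#'   auxiliary combination tasks.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return Object of class `combo_surrogate`.
#' @export
surrogate_combo_model <- function(compounds, records,
                                  encoder = c("fingerprint_mlp", "graph_conv"),
                                  descriptor = "morgan-1024",
                                  hidden_encoder = 48, hidden_head = 32,
                                  epochs = 400, learning_rate = 0.02,
                                  kappa = 0.25, aux_records = NULL, seed = 1L) {
  encoder <- match.arg(encoder)
  compounds <- as_tibble(compounds)
  if (nrow(records) == 0) abort("No combination training data.")
  X <- surrogate_encode(compounds, encoder, descriptor, seed)
  ids <- compounds$id
  # single-agent target: inhibition at a fixed reference dose from the
  # compound's Hill curve (anchors the single-agent head)
  c_ref <- 10^-6.5
  s_target <- hill_response(c_ref, 10^compounds$log_ic50, slope = 1, e_max = 0.7)
  tasks <- c(list(records), if (!is.null(aux_records)) aux_records)
  task_data <- lapply(tasks, function(rec) {
    ia <- match(rec$compound_1, ids)
    ib <- match(rec$compound_2, ids)
    if (anyNA(ia) || anyNA(ib)) abort("Records reference compounds not in `compounds`.")
    s_a <- s_target[ia]
    s_b <- s_target[ib]
    c_obs <- pmin(pmax(bliss_expected(s_a, s_b) + kappa * (1 - rec$gamma_mean), 0), 1)
    list(ia = ia, ib = ib, c_obs = c_obs)
  })

  d <- ncol(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  n_tasks <- length(task_data)
  par <- with_seed(seed, list(
    W1 = matrix(rnorm(d * hidden_encoder, 0, sqrt(1 / d)), d, hidden_encoder),
    b1 = rep(0, hidden_encoder),
    u = rnorm(hidden_encoder, 0, sqrt(1 / hidden_encoder)), bs = 0,
    W2 = lapply(seq_len(n_tasks), function(t) {
      matrix(
        rnorm(hidden_encoder * hidden_head, 0, sqrt(2 / hidden_encoder)),
        hidden_encoder, hidden_head
      )
    }),
    b2 = lapply(seq_len(n_tasks), function(t) rep(0, hidden_head)),
    v = lapply(seq_len(n_tasks), function(t) rnorm(hidden_head, 0, sqrt(1 / hidden_head))),
    bc = lapply(seq_len(n_tasks), function(t) 0)
  ))
  mstate <- rapply(par, function(x) x * 0, how = "replace")
  vstate <- rapply(par, function(x) x * 0, how = "replace")
  b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8
  sigmoid <- function(z) 1 / (1 + exp(-z))
  loss_trace <- numeric(epochs)

  upd <- function(name, idx = NULL, grad) {
    # Adam step on one parameter (optionally a list element)
    get_p <- function(lst) if (is.null(idx)) lst[[name]] else lst[[name]][[idx]]
    set_p <- function(lst, val) {
      if (is.null(idx)) lst[[name]] <- val else lst[[name]][[idx]] <- val
      lst
    }
    m <- b1a * get_p(mstate) + (1 - b1a) * grad
    v <- b2a * get_p(vstate) + (1 - b2a) * grad^2
    mstate <<- set_p(mstate, m)
    vstate <<- set_p(vstate, v)
    mh <- m / (1 - b1a^step)
    vh <- v / (1 - b2a^step)
    par <<- set_p(par, get_p(par) - learning_rate * mh / (sqrt(vh) + epsa))
  }
  step <- 0
  for (ep in seq_len(epochs)) {
    step <- step + 1
    Z1 <- sweep(Xs %*% par$W1, 2, par$b1, `+`)
    H <- tanh(Z1)
    s_hat <- sigmoid(as.numeric(H %*% par$u) + par$bs)
    dH <- matrix(0, nrow(H), ncol(H))
    total <- 0
    # single-agent task
    ds_pre <- 2 * (s_hat - s_target) / length(s_target) * s_hat * (1 - s_hat)
    total <- total + mean((s_hat - s_target)^2)
    g_u <- as.numeric(crossprod(H, ds_pre))
    g_bs <- sum(ds_pre)
    dH <- dH + outer(ds_pre, par$u)
    g_W2 <- list(); g_b2 <- list(); g_v <- list(); g_bc <- list()
    for (t in seq_len(n_tasks)) {
      td <- task_data[[t]]
      P <- H[td$ia, , drop = FALSE] + H[td$ib, , drop = FALSE]
      Zh <- sweep(P %*% par$W2[[t]], 2, par$b2[[t]], `+`)
      Ah <- pmax(Zh, 0)
      c_hat <- sigmoid(as.numeric(Ah %*% par$v[[t]]) + par$bc[[t]])
      m <- length(td$c_obs)
      total <- total + mean((c_hat - td$c_obs)^2)
      dc_pre <- 2 * (c_hat - td$c_obs) / m * c_hat * (1 - c_hat)
      g_v[[t]] <- as.numeric(crossprod(Ah, dc_pre))
      g_bc[[t]] <- sum(dc_pre)
      dAh <- outer(dc_pre, par$v[[t]]) * (Zh > 0)
      g_W2[[t]] <- crossprod(P, dAh)
      g_b2[[t]] <- colSums(dAh)
      dP <- dAh %*% t(par$W2[[t]])
      agg <- rowsum(rbind(dP, dP), group = c(td$ia, td$ib))
      dH[as.integer(rownames(agg)), ] <- dH[as.integer(rownames(agg)), ] + agg
    }
    dZ1 <- dH * (1 - H^2)
    g_W1 <- crossprod(Xs, dZ1)
    g_b1 <- colSums(dZ1)
    upd("W1", grad = g_W1); upd("b1", grad = g_b1)
    upd("u", grad = g_u); upd("bs", grad = g_bs)
    for (t in seq_len(n_tasks)) {
      upd("W2", t, g_W2[[t]]); upd("b2", t, g_b2[[t]])
      upd("v", t, g_v[[t]]); upd("bc", t, g_bc[[t]])
    }
    loss_trace[ep] <- total
  }
  structure(list(
    par = par, mu = mu, sd = sdv, encoder = encoder, descriptor = descriptor,
    kappa = kappa, loss_trace = loss_trace, n_tasks = n_tasks, seed = seed,
    train_ids = ids
  ), class = "combo_surrogate")
}

#' Predict synergy scores with the surrogate model
#'
#' @param object A `combo_surrogate`.
#' @param pairs Pair table to score.
#' @param compounds Compound table covering the pairs (`id`, `smiles`).
#' @param ... Unused.
#' @return Tibble with `compound_1`, `compound_2`, `s_a`, `s_b`, `c_ab` and
#'   `score` (the Bliss residual, higher = more synergistic).
#' @export
predict.combo_surrogate <- function(object, pairs, compounds, ...) {
  pairs <- canonicalize_pairs(as_tibble(pairs), quiet = TRUE)
  compounds <- as_tibble(compounds)
  X <- surrogate_encode(compounds, object$encoder, object$descriptor, object$seed)
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, `/`)
  H <- tanh(sweep(Xs %*% object$par$W1, 2, object$par$b1, `+`))
  sig <- function(z) 1 / (1 + exp(-z))
  s_hat <- sig(as.numeric(H %*% object$par$u) + object$par$bs)
  ia <- match(pairs$compound_1, compounds$id)
  ib <- match(pairs$compound_2, compounds$id)
  if (anyNA(ia) || anyNA(ib)) abort("Pairs reference compounds not provided.")
  P <- H[ia, , drop = FALSE] + H[ib, , drop = FALSE]
  Ah <- pmax(sweep(P %*% object$par$W2[[1]], 2, object$par$b2[[1]], `+`), 0)
  c_hat <- sig(as.numeric(Ah %*% object$par$v[[1]]) + object$par$bc[[1]])
  tibble(
    compound_1 = pairs$compound_1, compound_2 = pairs$compound_2,
    s_a = s_hat[ia], s_b = s_hat[ib], c_ab = c_hat,
    score = bliss_residual_score(c_hat, s_hat[ia], s_hat[ib])
  )
}

#' Surrogate scores as a prediction set
#'
#' Rescales the Bliss residual from `[-1, 1]` to `[0, 1]` so it can be
#' averaged with probability-scale prediction sets.
#'
#' @inheritParams predict.combo_surrogate
#' @return A [prediction_set()] of kind `"bliss_residual_rescaled"`.
#' @export
surrogate_prediction_set <- function(object, pairs, compounds) {
  pr <- predict(object, pairs, compounds)
  prediction_set(pr, (pr$score + 1) / 2,
    model_id = paste0("surrogate_", object$encoder),
    kind = "bliss_residual_rescaled"
  )
}

#' @export
print.combo_surrogate <- function(x, ...) {
  cat(sprintf(
    "<combo_surrogate> encoder %s, %d task(s), final loss %.4f\n",
    x$encoder, x$n_tasks, tail(x$loss_trace, 1)
  ))
  invisible(x)
}

#' @export
glance.combo_surrogate <- function(x, ...) {
  tibble(
    encoder = x$encoder, n_tasks = x$n_tasks,
    epochs = length(x$loss_trace),
    final_loss = tail(x$loss_trace, 1),
    n_compounds = length(x$train_ids)
  )
}

#' @export
tidy.prediction_set <- function(x, ...) {
  out <- as_tibble(x)
  out$model_id <- attr(x, "model_id")
  out$kind <- attr(x, "kind")
  out
}
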