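# Base learners.
#
# The environment provides no tree-ensemble or neural-network package, so the
# three learner families used for synergy classification/regression are
# implemented here directly: bagged CART-style trees, gradient-boosted trees
# (Newton leaf values, logistic loss for classification), and a dense
# feed-forward network trained with Adam. Split search is vectorised across
# all candidate (feature, threshold) columns at once, which keeps pure-R tree
# induction fast on fingerprint/mechanism bit matrices.

#' Specify a base learner
#'
#' @param algorithm One of `"bagged_trees"`, `"boosted_trees"`,
#'   `"feedforward_net"`.
#' @param task `"classification"` (emit probability of synergy) or
#'   `"regression"` (emit predicted gamma).
#' @param hyperparameters Named list overriding the defaults. Boosted trees
#'   default to learning rate 0.01; the feed-forward net defaults to hidden
#'   layers 700/500/300, Adam, learning rate 1e-4, batch 128, 70 epochs.
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(algorithm = c("bagged_trees", "boosted_trees", "feedforward_net"),
                         task = c("classification", "regression"),
                         hyperparameters = list()) {
  algorithm <- match.arg(algorithm)
  task <- match.arg(task)
  defaults <- switch(algorithm,
    bagged_trees = list(
      n_trees = 50, max_depth = 8, min_node = 3, subsample = 1, mtry = "sqrt"
    ),
    boosted_trees = list(
      n_rounds = 150, learning_rate = 0.01, max_depth = 2, min_node = 5,
      lambda = 1
    ),
    feedforward_net = list(
      hidden = c(700, 500, 300), learning_rate = 1e-4, batch_size = 128,
      epochs = 70, l2 = 1e-4
    )
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(algorithm = algorithm, task = task, hyperparameters = hp),
    class = "learner_spec"
  )
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("<learner_spec> %s (%s)\n", x$algorithm, x$task))
  invisible(x)
}

# --- binning: map features to a binary "x <= threshold is FALSE" design ------

# candidate split columns: binary features give one column, continuous
# features up to `max_cuts` quantile thresholds
make_binner <- function(X, max_cuts = 7) {
  cuts <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- unique(X[, j])
    if (length(v) <= 1) {
      cuts[[j]] <- numeric(0)
    } else if (length(v) <= max_cuts + 1) {
      s <- sort(v)
      cuts[[j]] <- (s[-1] + s[-length(s)]) / 2
    } else {
      q <- unique(quantile(X[, j], probs = seq_len(max_cuts) / (max_cuts + 1)))
      cuts[[j]] <- q
    }
  }
  structure(list(cuts = cuts, p = ncol(X)), class = "binner")
}

# indicator matrix: column k is 1 where x_j > cut (the "right" side)
bin_apply <- function(binner, X) {
  cols <- list()
  feat <- integer(0)
  for (j in seq_len(binner$p)) {
    for (cut in binner$cuts[[j]]) {
      cols[[length(cols) + 1]] <- as.numeric(X[, j] > cut)
      feat[[length(feat) + 1]] <- j
    }
  }
  if (length(cols) == 0) {
    return(structure(matrix(0, nrow(X), 0), feature = integer(0)))
  }
  structure(do.call(cbind, cols), feature = feat)
}

# --- single tree on the binned design ---------------------------------------

# CART via the xgboost-style gain G^2/H: with grad = y, hess = 1 this is
# exact variance-reduction splitting with mean leaves; boosting supplies
# logistic grad/hess. `mtry` (a count) samples a random column subset per
# node, decorrelating bagged trees in the random-forest manner.
fit_tree <- function(B, grad, hess, rows, depth, max_depth, min_node, lambda = 0,
                     mtry = NULL) {
  G <- sum(grad[rows])
  H <- sum(hess[rows])
  leaf <- list(leaf = TRUE, value = G / (H + lambda))
  if (depth >= max_depth || length(rows) < 2 * min_node) return(leaf)
  cols <- if (!is.null(mtry) && mtry < ncol(B)) sample.int(ncol(B), mtry) else seq_len(ncol(B))
  Bs <- B[rows, cols, drop = FALSE]
  GR <- as.numeric(crossprod(Bs, grad[rows])) # sums on the "right" (x > cut)
  HR <- as.numeric(crossprod(Bs, hess[rows]))
  nR <- as.numeric(colSums(Bs))
  GL <- G - GR
  HL <- H - HR
  nL <- length(rows) - nR
  ok <- nL >= min_node & nR >= min_node
  if (!any(ok)) return(leaf)
  gain <- GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - G^2 / (H + lambda)
  gain[!ok] <- -Inf
  best <- which.max(gain)
  if (!is.finite(gain[best]) || gain[best] <= 1e-10) return(leaf)
  right <- rows[Bs[, best] == 1]
  left <- setdiff(rows, right)
  list(
    leaf = FALSE, col = cols[best],
    left = fit_tree(B, grad, hess, left, depth + 1, max_depth, min_node, lambda, mtry),
    right = fit_tree(B, grad, hess, right, depth + 1, max_depth, min_node, lambda, mtry)
  )
}

predict_tree <- function(tree, B, rows = seq_len(nrow(B))) {
  out <- numeric(nrow(B))
  recurse <- function(node, rows) {
    if (length(rows) == 0) return(invisible())
    if (node$leaf) {
      out[rows] <<- node$value
      return(invisible())
    }
    right <- rows[B[rows, node$col] == 1]
    recurse(node$right, right)
    recurse(node$left, setdiff(rows, right))
  }
  recurse(tree, rows)
  out
}

fit_bagged_trees <- function(X, y, hp, seed) {
  binner <- make_binner(X)
  B <- bin_apply(binner, X)
  n <- nrow(X)
  mtry <- hp$mtry
  if (identical(mtry, "sqrt")) mtry <- max(1L, floor(sqrt(ncol(B))))
  trees <- with_seed(seed, lapply(seq_len(hp$n_trees), function(t) {
    rows <- sample.int(n, size = ceiling(hp$subsample * n), replace = TRUE)
    fit_tree(B, grad = y, hess = rep(1, n), rows = rows, depth = 0,
      max_depth = hp$max_depth, min_node = hp$min_node, mtry = mtry)
  }))
  structure(list(binner = binner, trees = trees), class = "bagged_trees_model")
}

predict_bagged_trees <- function(model, X) {
  B <- bin_apply(model$binner, X)
  preds <- vapply(model$trees, predict_tree, numeric(nrow(X)), B = B)
  if (nrow(X) == 1) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

fit_boosted_trees <- function(X, y, hp, seed, task) {
  binner <- make_binner(X)
  B <- bin_apply(binner, X)
  n <- nrow(X)
  if (task == "classification") {
    p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
    f <- rep(log(p0 / (1 - p0)), n)
    base <- f[1]
  } else {
    base <- mean(y)
    f <- rep(base, n)
  }
  trees <- vector("list", hp$n_rounds)
  with_seed(seed, for (t in seq_len(hp$n_rounds)) {
    if (task == "classification") {
      p <- 1 / (1 + exp(-f))
      grad <- y - p
      hess <- pmax(p * (1 - p), 1e-6)
    } else {
      grad <- y - f
      hess <- rep(1, n)
    }
    tr <- fit_tree(B, grad, hess, seq_len(n), 0, hp$max_depth, hp$min_node, hp$lambda)
    trees[[t]] <- tr
    f <- f + hp$learning_rate * predict_tree(tr, B)
  })
  structure(list(
    binner = binner, trees = trees, base = base,
    learning_rate = hp$learning_rate, task = task
  ), class = "boosted_trees_model")
}

predict_boosted_trees <- function(model, X) {
  B <- bin_apply(model$binner, X)
  f <- rep(model$base, nrow(X))
  for (tr in model$trees) f <- f + model$learning_rate * predict_tree(tr, B)
  if (model$task == "classification") 1 / (1 + exp(-f)) else f
}

# --- dense feed-forward network with Adam -----------------------------------

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    W <- list()
    b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      W[[l]] <- matrix(
        rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
        sizes[l], sizes[l + 1]
      )
      b[[l]] <- rep(0, sizes[l + 1])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(params, X) {
  L <- length(params$W)
  A <- list(X)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], `+`)
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z # relu hidden, linear output
  }
  A
}

fit_feedforward_net <- function(X, y, hp, seed, task) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  sizes <- c(ncol(X), hp$hidden, 1)
  params <- mlp_init(sizes, seed)
  L <- length(params$W)
  mW <- lapply(params$W, function(w) w * 0); vW <- mW
  mb <- lapply(params$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(Xs)
  step <- 0
  with_seed(derive_seed(seed, "batches"), for (ep in seq_len(hp$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = hp$batch_size)) {
      idx <- ord[start:min(start + hp$batch_size - 1, n)]
      A <- mlp_forward(params, Xs[idx, , drop = FALSE])
      out <- A[[L + 1]][, 1]
      if (task == "classification") {
        p <- 1 / (1 + exp(-out))
        delta <- matrix((p - y[idx]) / length(idx), ncol = 1)
      } else {
        delta <- matrix(2 * (out - y[idx]) / length(idx), ncol = 1)
      }
      step <- step + 1
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + hp$l2 * params$W[[l]]
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(params$W[[l]])) * (A[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        params$W[[l]] <- params$W[[l]] - hp$learning_rate * mhW / (sqrt(vhW) + eps)
        params$b[[l]] <- params$b[[l]] - hp$learning_rate * mhb / (sqrt(vhb) + eps)
      }
    }
  })
  structure(list(params = params, mu = mu, sd = sdv, task = task),
    class = "feedforward_net_model"
  )
}

predict_feedforward_net <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, `/`)
  out <- mlp_forward(model$params, Xs)[[length(model$params$W) + 1]][, 1]
  if (model$task == "classification") 1 / (1 + exp(-out)) else out
}

# --- fit/predict front end ---------------------------------------------------

#' Fit a learner and score a test set
#'
#' Classification learners emit the probability of the synergy class;
#' regression learners emit raw predicted gamma (convert with
#' [regression_to_pseudo_probability()] before averaging with classifier
#' probabilities).
#'
#' @param spec A [learner_spec()].
#' @param train_features,test_features Numeric feature matrices with equal
#'   column counts.
#' @param train_records Synergy-record tibble aligned with `train_features`
#'   (`label` used for classification, `gamma_mean` for regression).
#' @param test_pairs Optional pair table aligned with `test_features`; when
#'   omitted, pair ids are recovered from `rownames(test_features)`.
#' @param seed Integer seed.
#' @return List with `model` and `scores` (a [prediction_set()]).
#' @export
fit_predict <- function(spec, train_features, train_records, test_features,
                        test_pairs = NULL, seed = 1L) {
  stopifnot(inherits(spec, "learner_spec"))
  if (ncol(train_features) != ncol(test_features)) {
    abort("Train/test feature width mismatch.")
  }
  y <- if (spec$task == "classification") {
    lab <- as.numeric(train_records$label)
    if (length(unique(lab)) < 2) {
      abort("Training labels contain a single class; cannot fit a classifier.",
        class = "comboscreen_degenerate_training"
      )
    }
    lab
  } else {
    train_records$gamma_mean
  }
  hp <- spec$hyperparameters
  model <- switch(spec$algorithm,
    bagged_trees = fit_bagged_trees(train_features, y, hp, seed),
    boosted_trees = fit_boosted_trees(train_features, y, hp, seed, spec$task),
    feedforward_net = fit_feedforward_net(train_features, y, hp, seed, spec$task)
  )
  raw <- switch(spec$algorithm,
    bagged_trees = predict_bagged_trees(model, test_features),
    boosted_trees = predict_boosted_trees(model, test_features),
    feedforward_net = predict_feedforward_net(model, test_features)
  )
  if (is.null(test_pairs)) test_pairs <- pairs_from_rownames(test_features)
  kind <- if (spec$task == "classification") "classifier_probability" else "regression_raw"
  scores <- prediction_set(
    test_pairs, raw,
    model_id = paste0(spec$algorithm, "_", substr(spec$task, 1, 3)),
    kind = kind
  )
  list(model = model, scores = scores)
}

pairs_from_rownames <- function(features) {
  rn <- rownames(features)
  if (is.null(rn)) abort("No `test_pairs` given and feature matrix has no pair rownames.")
  parts <- strsplit(rn, "\r", fixed = TRUE)
  tibble(
    compound_1 = vapply(parts, `[`, character(1), 1),
    compound_2 = vapply(parts, `[`, character(1), 2)
  )
}
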