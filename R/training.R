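# Losses and training loops.
#
# The ordinal models are trained with the CORAL loss: the K-class problem is
# decomposed into K-1 binary threshold tasks ("is the label above threshold
# k?") sharing one weight vector with per-threshold biases. The binary
# target for threshold k is 1[y > k] so that the derived continuous score
# (the sum of threshold probabilities) increases with severity.

#' CORAL binary threshold targets
#'
#' For a label `y` in `0 .. K-1` the target vector has `K - 1` entries with
#' entry `k` (zero-based) equal to `1` exactly when `y > k`. The vector is
#' therefore a run of ones followed by zeros and sums to `y`.
#'
#' @param y integer label(s) in `0 .. K-1`.
#' @param K number of classes.
#' @return numeric vector (scalar `y`) or matrix with one row per label.
#' @export
coral_targets <- function(y, K) {
  K <- as.integer(K)
  if (any(y < 0 | y > K - 1) || any(y != floor(y)))
    stop("labels must be integers in 0 .. K-1", call. = FALSE)
  m <- outer(as.numeric(y), 0:(K - 2L), `>`) * 1
  if (length(y) == 1L) as.numeric(m[1, ]) else m
}

#' CORAL ordinal loss
#'
#' Sum over the `K - 1` threshold tasks of the binary cross-entropy between
#' the sigmoid-transformed logits and the targets of [coral_targets()],
#' averaged over samples. Because a label error of `|y - c|` classes flips
#' `|y - c|` of the binary targets, larger ordinal mistakes incur strictly
#' larger loss.
#'
#' @param logits numeric vector of `K - 1` logits, or a matrix with one row
#'   per sample.
#' @param y integer label(s).
#' @param K number of classes.
#' @return mean per-sample loss (nonnegative scalar).
#' @export
coral_loss <- function(logits, y, K) {
  if (!all(is.finite(logits)))
    stop("logits must be finite", call. = FALSE)
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  stopifnot(ncol(logits) == K - 1L, nrow(logits) == length(y))
  targ <- coral_targets(y, K)
  if (is.null(dim(targ))) targ <- matrix(targ, nrow = 1L)
  # numerically stable BCE-with-logits: max(x,0) - x*t + log1p(exp(-|x|))
  x <- logits
  per <- pmax(x, 0) - x * targ + log1p(exp(-abs(x)))
  mean(rowSums(per))
}

#' Contrastive loss for twin pairs
#'
#' `mean(same * d^2 + (1 - same) * max(margin - d, 0)^2)` over pairs with
#' embedding distance `d` and binary same-class indicator `same`.
#'
#' @param d nonnegative distances.
#' @param same 0/1 same-class indicators.
#' @param margin margin for different-class pairs.
#' @return nonnegative scalar.
#' @export
contrastive_loss <- function(d, same, margin = 2) {
  stopifnot(length(d) == length(same), all(d >= 0),
            all(same %in% c(0, 1)))
  mean(same * d^2 + (1 - same) * pmax(margin - d, 0)^2)
}

#' Training configuration
#'
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed master seed controlling shuffling, pair sampling, dropout
#'   masks and weight initialization downstream.
#' @param class_balancing draw training examples with inverse class
#'   frequency weights (with replacement).
#' @param margin contrastive-loss margin (twin models).
#' @param pairs_per_epoch twin pairs sampled per epoch (default: training
#'   set size).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 8L, batch_size = 32L,
                         learning_rate = 1e-3, seed = 1L,
                         class_balancing = FALSE, margin = 2,
                         pairs_per_epoch = NULL) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 class_balancing = isTRUE(class_balancing),
                 margin = margin, pairs_per_epoch = pairs_per_epoch),
            class = "train_config")
}

# loss + gradients for one non-twin batch; returns loss, head grads, dG
head_loss_grads <- function(model, G, y) {
  cfg <- model$config
  p <- model$params
  N <- nrow(G)
  switch(cfg$model_type,
    multiclass = {
      logits <- G %*% p$head_W + matrix(p$head_b, N, cfg$K, byrow = TRUE)
      z <- exp(logits - apply(logits, 1, max))
      P <- z / rowSums(z)
      Y <- matrix(0, N, cfg$K); Y[cbind(seq_len(N), y + 1L)] <- 1
      loss <- -mean(log(pmax(P[cbind(seq_len(N), y + 1L)], 1e-12)))
      dlog <- (P - Y) / N
      list(loss = loss,
           grads = list(head_W = crossprod(G, dlog),
                        head_b = colSums(dlog)),
           dG = dlog %*% t(p$head_W))
    },
    ordinal = {
      z <- as.vector(G %*% p$head_w)
      logits <- outer(z, rep(1, cfg$K - 1L)) +
        matrix(p$head_b, N, cfg$K - 1L, byrow = TRUE)
      loss <- coral_loss(logits, y, cfg$K)
      targ <- coral_targets(y, cfg$K)
      if (is.null(dim(targ))) targ <- matrix(targ, nrow = 1L)
      delta <- (sigmoid(logits) - targ) / N
      dz <- rowSums(delta)
      list(loss = loss,
           grads = list(head_w = crossprod(G, matrix(dz)),
                        head_b = colSums(delta)),
           dG = matrix(dz) %*% t(p$head_w))
    },
    regression = {
      r <- as.vector(G %*% p$head_W) + p$head_b
      loss <- mean((r - y)^2)
      dr <- 2 * (r - y) / N
      list(loss = loss,
           grads = list(head_W = crossprod(G, matrix(dr)),
                        head_b = sum(dr)),
           dG = matrix(dr) %*% t(p$head_W))
    },
    stop("twin batches are handled separately"))
}

twin_loss_grads <- function(model, G, same, margin) {
  p <- model$params
  E <- G %*% p$head_W +
    matrix(p$head_b, nrow(G), model$config$embedding_dim, byrow = TRUE)
  P <- nrow(E) / 2L
  ea <- E[seq_len(P), , drop = FALSE]
  eb <- E[P + seq_len(P), , drop = FALSE]
  diff <- ea - eb
  d <- sqrt(rowSums(diff^2))
  loss <- contrastive_loss(d, same, margin)
  dd <- (2 * d * same - 2 * (1 - same) * pmax(margin - d, 0)) / P
  unit <- diff / pmax(d, 1e-12)
  unit[d == 0, ] <- 0
  dea <- unit * dd
  dE <- rbind(dea, -dea)
  list(loss = loss,
       grads = list(head_W = crossprod(G, dE), head_b = colSums(dE)),
       dG = dE %*% t(p$head_W))
}

sample_twin_pairs <- function(y, n_pairs) {
  classes <- unique(y)
  by_class <- split(seq_along(y), y)
  n_same <- n_pairs %/% 2L
  ia <- integer(n_pairs); ib <- integer(n_pairs); same <- numeric(n_pairs)
  eligible <- names(by_class)[vapply(by_class, length, 1L) >= 2L]
  for (j in seq_len(n_pairs)) {
    if (j <= n_same && length(eligible) > 0) {
      cls <- sample(eligible, 1L)
      pick <- sample(by_class[[cls]], 2L)
      ia[j] <- pick[1]; ib[j] <- pick[2]; same[j] <- 1
    } else {
      cls <- sample(names(by_class), 2L)
      ia[j] <- sample_one(by_class[[cls[1]]])
      ib[j] <- sample_one(by_class[[cls[2]]])
      same[j] <- 0
    }
  }
  list(ia = ia, ib = ib, same = same)
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# deterministic evaluation loss on a split (dropout off)
eval_loss <- function(model, x, y, margin = 2, twin_pairs = NULL) {
  cfg <- model$config
  if (cfg$model_type == "twin") {
    xx <- array(c(x[, , twin_pairs$ia], x[, , twin_pairs$ib]),
                dim = c(dim(x)[1:2], 2L * length(twin_pairs$ia)))
    bb <- backbone_fwd(model$params, xx, cfg$channels)
    E <- head_fwd(model, bb$features)
    P <- length(twin_pairs$ia)
    d <- sqrt(rowSums((E[seq_len(P), , drop = FALSE] -
                         E[P + seq_len(P), , drop = FALSE])^2))
    return(list(loss = contrastive_loss(d, twin_pairs$same, margin),
                metric = NA_real_))
  }
  bb <- backbone_fwd(model$params, x, cfg$channels)
  G <- bb$features
  out <- head_fwd(model, G)
  switch(cfg$model_type,
    multiclass = {
      loss <- -mean(log(pmax(out[cbind(seq_along(y), y + 1L)], 1e-12)))
      list(loss = loss, metric = mean(max.col(out) - 1L == y))
    },
    ordinal = {
      b <- sort(model$params$head_b, decreasing = TRUE)
      z <- as.vector(G %*% model$params$head_w)
      logits <- outer(z, rep(1, cfg$K - 1L)) +
        matrix(b, length(z), cfg$K - 1L, byrow = TRUE)
      list(loss = coral_loss(logits, y, cfg$K),
           metric = mean(rowSums(out > 0.5) == y))
    },
    regression = list(loss = mean((out - y)^2),
                      metric = sqrt(mean((out - y)^2))))
}

#' Train a severity model on a synthetic dataset
#'
#' Minibatch Adam training with per-epoch logging of training and
#' validation loss and validation-based model selection (the returned model
#' carries the parameters of the epoch with the lowest validation loss).
#' Multi-class models use cross-entropy, ordinal models the CORAL loss,
#' regression models squared error against the integer labels, and twin
#' models a contrastive loss over sampled same/different-class image pairs.
#' MC models train with their spatial dropout active. Deterministic given
#' `config$seed`.
#'
#' @param model a `sev_model` from [build_model()].
#' @param dataset a `sev_dataset` with `train` and `val` splits.
#' @param config a [train_config()].
#' @return a list of class `train_result` with `model` (best checkpoint),
#'   `log` (data.frame epoch/train_loss/val_loss/val_metric), and
#'   `best_epoch`.
#' @export
train_model <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "sev_model"), inherits(dataset, "sev_dataset"),
            inherits(config, "train_config"))
  if (is.null(dataset$images))
    stop("dataset has no rendered images", call. = FALSE)
  tr <- dataset_split(dataset, "train")
  va <- dataset_split(dataset, "val")
  if (nrow(tr$manifest) == 0 || nrow(va$manifest) == 0)
    stop("dataset needs non-empty train and val splits", call. = FALSE)
  xtr <- tr$images; ytr <- tr$manifest$label
  xva <- va$images; yva <- va$manifest$label
  cfg <- model$config
  if (cfg$model_type != "twin" &&
      length(unique(ytr)) < cfg$K && config$class_balancing)
    stop("class balancing requires every class in the training split",
         call. = FALSE)

  with_seed(config$seed, {
    opt <- adam_init(model$params)
    n <- length(ytr)
    n_pairs <- config$pairs_per_epoch %||% n
    val_pairs <- if (cfg$model_type == "twin")
      sample_twin_pairs(yva, max(16L, length(yva)))
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric(), val_metric = numeric())
    best <- list(loss = Inf, params = model$params, epoch = 0L)

    for (ep in seq_len(config$epochs)) {
      if (cfg$model_type == "twin") {
        pairs <- sample_twin_pairs(ytr, n_pairs)
        order_idx <- seq_len(n_pairs)
        nb <- ceiling(n_pairs / config$batch_size)
      } else if (config$class_balancing) {
        w <- 1 / table(ytr)[as.character(ytr)]
        order_idx <- sample.int(n, n, replace = TRUE, prob = w)
        nb <- ceiling(n / config$batch_size)
      } else {
        order_idx <- sample.int(n)
        nb <- ceiling(n / config$batch_size)
      }
      ep_loss <- 0; ep_n <- 0
      for (b in seq_len(nb)) {
        take <- order_idx[(((b - 1L) * config$batch_size + 1L)):
                            min(b * config$batch_size, length(order_idx))]
        if (cfg$model_type == "twin") {
          ia <- pairs$ia[take]; ib <- pairs$ib[take]
          xb <- array(c(xtr[, , ia], xtr[, , ib]),
                      dim = c(dim(xtr)[1:2], 2L * length(take)))
          bb <- backbone_fwd(model$params, xb, cfg$channels,
                             dropout_rate = cfg$dropout_rate,
                             dropout_active = cfg$mc_dropout,
                             keep_cache = TRUE)
          hl <- twin_loss_grads(model, bb$features, pairs$same[take],
                                config$margin)
        } else {
          xb <- xtr[, , take, drop = FALSE]
          bb <- backbone_fwd(model$params, xb, cfg$channels,
                             dropout_rate = cfg$dropout_rate,
                             dropout_active = cfg$mc_dropout,
                             keep_cache = TRUE)
          hl <- head_loss_grads(model, bb$features, ytr[take])
        }
        bg <- backbone_bwd(model$params, hl$dG, bb$cache, cfg$channels)
        step <- adam_step(model$params, c(bg, hl$grads), opt,
                          lr = config$learning_rate)
        model$params <- step$params
        opt <- step$state
        ep_loss <- ep_loss + hl$loss * length(take)
        ep_n <- ep_n + length(take)
      }
      ev <- eval_loss(model, xva, yva, config$margin, val_pairs)
      log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                   val_loss = ev$loss,
                                   val_metric = ev$metric))
      if (ev$loss < best$loss)
        best <- list(loss = ev$loss, params = model$params, epoch = ep)
    }
    model$params <- best$params
    structure(list(model = model, log = log, best_epoch = best$epoch,
                   config = config),
              class = "train_result")
  })
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %s, best epoch %d (val loss %.4f)\n",
              x$model$config$model_type, x$best_epoch,
              min(x$log$val_loss)))
  print(x$log, row.names = FALSE)
  invisible(x)
}
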