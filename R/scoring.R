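# Conversion of model outputs into continuous severity scores, Monte Carlo
# dropout inference, and affine rescaling to the 1-9 expert rating scale.

#' Continuous score from multi-class softmax output
#'
#' The expected class index under the softmax distribution:
#' `sum_i p_i * (i - 1)` for classes `1..K`, giving a score in
#' `[0, K - 1]`.
#'
#' @param p probability vector of length `K` (or matrix, one row per image).
#' @param K number of classes.
#' @param tol tolerance on `sum(p) == 1`.
#' @return numeric score(s) in `[0, K - 1]`.
#' @export
multiclass_score <- function(p, K, tol = 1e-6) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  stopifnot(ncol(p) == K)
  if (any(p < -tol) || any(abs(rowSums(p) - 1) > tol))
    stop("p must be a probability vector summing to 1", call. = FALSE)
  as.vector(p %*% (0:(K - 1L)))
}

#' Continuous score from ordinal threshold probabilities
#'
#' The sum of the `K - 1` sigmoid threshold probabilities ("how many class
#' thresholds has this image passed?"), giving a score in `[0, K - 1]`.
#'
#' @param q sigmoid vector of length `K - 1` (or matrix, one row per image).
#' @return numeric score(s).
#' @export
ordinal_score <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  if (any(q < 0 | q > 1))
    stop("q entries must lie in [0, 1]", call. = FALSE)
  rowSums(q)
}

#' Continuous score from a regression output
#'
#' The raw regression output is already continuous; optional clipping to
#' `[0, K - 1]` makes it comparable with the bounded scores for rescaled
#' error metrics.
#'
#' @param r numeric output(s).
#' @param K number of classes.
#' @param clip clamp to `[0, K - 1]`.
#' @return numeric score(s).
#' @export
regression_score <- function(r, K, clip = FALSE) {
  stopifnot(all(is.finite(r)))
  if (clip) clamp(r, 0, K - 1) else r
}

#' Continuous score from twin embedding distances
#'
#' The median Euclidean distance between the target embedding and the
#' anchor-pool embeddings (an even pool size yields the mean of the two
#' central order statistics). Larger distances from the healthy (class 0)
#' anchors mean higher severity.
#'
#' @param target_embedding numeric embedding vector (or matrix, one row per
#'   image).
#' @param pool an [select_anchors()] pool, or a plain embedding matrix with
#'   one row per anchor.
#' @return nonnegative score(s).
#' @export
twin_score <- function(target_embedding, pool) {
  emb <- if (inherits(pool, "anchor_pool")) pool$embeddings else pool
  if (is.null(dim(target_embedding)))
    target_embedding <- matrix(target_embedding, nrow = 1L)
  if (ncol(emb) != ncol(target_embedding))
    stop("embedding dimensions do not match", call. = FALSE)
  apply(target_embedding, 1, function(t)
    median(sqrt(colSums((t(emb) - t)^2))))
}

#' Select an anchor pool of lowest-class images
#'
#' Picks `n` class-0 images from the training split to serve as the twin
#' model's healthy reference pool. With an auxiliary multi-class model the
#' `n` images with the highest class-0 softmax confidence are taken
#' ("confidence" strategy); without one, a seeded uniform sample
#' ("random" strategy).
#'
#' @param dataset a `sev_dataset`.
#' @param model optional auxiliary multi-class `sev_model`.
#' @param twin_model twin model used to cache anchor embeddings (optional).
#' @param n pool size (default 10).
#' @param seed seed for the random strategy.
#' @param split source split (default `"train"`).
#' @return an `anchor_pool`: images, manifest rows, strategy label, and
#'   (when `twin_model` is given) cached embeddings.
#' @export
select_anchors <- function(dataset, model = NULL, twin_model = NULL,
                           n = 10L, seed = 1L, split = "train") {
  sp <- dataset_split(dataset, split)
  cls0 <- which(sp$manifest$label == 0L)
  if (length(cls0) < n)
    stop(sprintf("need at least %d class-0 images in the %s split", n,
                 split), call. = FALSE)
  if (!is.null(model)) {
    stopifnot(model$config$model_type == "multiclass")
    conf <- predict_output(model, sp$images[, , cls0, drop = FALSE])$p[, 1]
    pick <- cls0[order(-conf, cls0)][seq_len(n)]
    strategy <- "confidence"
  } else {
    pick <- with_seed(seed, sort(sample(cls0, n)))
    strategy <- "random"
  }
  images <- sp$images[, , pick, drop = FALSE]
  structure(list(images = images,
                 manifest = sp$manifest[pick, , drop = FALSE],
                 strategy = strategy,
                 embeddings = if (!is.null(twin_model))
                   twin_embed(twin_model, images)),
            class = "anchor_pool")
}

#' Monte Carlo dropout inference
#'
#' Runs `n_passes` stochastic forward passes with spatial dropout active
#' and averages the per-pass outputs elementwise (softmax vectors, sigmoid
#' vectors, or regression scalars); for twin models the per-pass median
#' anchor distances are averaged instead, since embeddings carry no
#' canonical mean scale. The per-pass standard deviation is returned as an
#' epistemic uncertainty estimate. Deterministic given `seed`: one master
#' seed drives all per-pass dropout masks.
#'
#' @param model an MC `sev_model` (built with `mc_dropout = TRUE`).
#' @param x image matrix or array.
#' @param n_passes number of stochastic passes (default 50).
#' @param seed master seed.
#' @param anchors an `anchor_pool` (twin models only).
#' @return an `mc_output` list: `mean` (averaged probability output, same
#'   shape as a single pass; for twin, averaged distances), `sd` (per-pass
#'   standard deviation, same shape), `model_type`, `n_passes`.
#' @export
mc_predict <- function(model, x, n_passes = 50L, seed = 1L,
                       anchors = NULL) {
  stopifnot(inherits(model, "sev_model"), n_passes >= 1L)
  if (!model$config$mc_dropout)
    stop("mc_predict requires a model built with mc_dropout = TRUE",
         call. = FALSE)
  type <- model$config$model_type
  if (type == "twin" && is.null(anchors))
    stop("twin MC prediction needs an anchor pool", call. = FALSE)
  x <- as_image_array(x)
  with_seed(seed, {
    passes <- vector("list", n_passes)
    for (i in seq_len(n_passes)) {
      if (type == "twin") {
        e_t <- twin_embed(model, x, dropout_active = TRUE)
        e_a <- twin_embed(model, anchors$images, dropout_active = TRUE)
        passes[[i]] <- twin_score(e_t, e_a)
      } else {
        out <- predict_output(model, x, dropout_active = TRUE)
        passes[[i]] <- out$p %||% out$q %||% out$r
      }
    }
    stack <- simplify2array(passes)   # dims of one pass x n_passes
    nd <- length(dim(stack))
    if (nd <= 1L) stack <- matrix(stack, ncol = n_passes)
    m <- if (length(dim(stack)) == 3L) apply(stack, 1:2, mean)
         else rowMeans(stack)
    s <- if (n_passes == 1L) {
      if (length(dim(stack)) == 3L) m * 0 else m * 0
    } else if (length(dim(stack)) == 3L) apply(stack, 1:2, sd)
    else apply(stack, 1, sd)
    structure(list(mean = m, sd = s, model_type = type,
                   n_passes = as.integer(n_passes)),
              class = "mc_output")
  })
}

#' Score model outputs on the model scale
#'
#' Dispatches to the model family's score: expected class index
#' (multi-class), threshold-probability sum (ordinal), raw output
#' (regression), or median anchor distance (twin).
#'
#' @param output a `probability_output`, an `mc_output`, or a raw
#'   probability matrix/vector.
#' @param K number of classes.
#' @param model_type required when `output` is a bare matrix.
#' @param anchors `anchor_pool` with cached embeddings (plain twin scoring).
#' @param clip clip regression scores to `[0, K - 1]`.
#' @return numeric vector of model-scale scores.
#' @export
score_output <- function(output, K, model_type = NULL, anchors = NULL,
                         clip = FALSE) {
  if (inherits(output, "mc_output")) {
    if (output$model_type == "twin") return(as.vector(output$mean))
    return(score_output(output$mean, K, output$model_type, clip = clip))
  }
  if (inherits(output, "probability_output")) {
    mt <- output$model_type
    val <- output$p %||% output$q %||% output$r %||% output$e
    if (mt == "twin") {
      if (is.null(anchors) || is.null(anchors$embeddings))
        stop("twin scoring needs an anchor pool with embeddings",
             call. = FALSE)
      return(twin_score(val, anchors))
    }
    return(score_output(val, K, mt, clip = clip))
  }
  switch(model_type,
         multiclass = multiclass_score(output, K),
         ordinal = ordinal_score(output),
         regression = regression_score(output, K, clip = clip),
         stop("unknown model_type", call. = FALSE))
}

#' Rescale a model-scale score to the 1-9 expert rating scale
#'
#' Classification, ordinal, and regression scores on `[0, K - 1]` are
#' mapped affinely. The `"paper"` mapping is `score * 3 + 1` (for K = 3 it
#' spans 1-7); the `"full_range"` mapping `score * 8 / (K - 1) + 1` spans
#' the full 1-9 scale for any K. Twin scores, which are unbounded, are
#' shifted by `+1` and clipped. All outputs are clipped to `[1, 9]`.
#'
#' @param score model-scale score(s).
#' @param model_type model family of the score.
#' @param K number of classes.
#' @param mapping `"paper"` or `"full_range"`.
#' @return rescaled score(s) in `[1, 9]`.
#' @export
rescale_score <- function(score, model_type, K = 3L,
                          mapping = c("paper", "full_range")) {
  mapping <- match.arg(mapping)
  out <- if (model_type == "twin") {
    score + 1
  } else if (mapping == "paper") {
    score * 3 + 1
  } else {
    score * 8 / (K - 1) + 1
  }
  clamp(out, 1, 9)
}

#' Score a dataset split with a model
#'
#' Convenience wrapper producing a predictions table: one row per image
#' with the model-scale score, the rescaled score, and (for MC models) the
#' per-pass uncertainty.
#'
#' @param model a `sev_model`.
#' @param dataset a `sev_dataset`.
#' @param split split to score.
#' @param mc number of MC passes (0 = plain deterministic forward pass).
#' @param seed seed for MC dropout masks.
#' @param anchors `anchor_pool` (twin models; embeddings cached if absent).
#' @param mapping rescale mapping.
#' @return data.frame: manifest columns + `score`, `score_rescaled`,
#'   `mc_sd`.
#' @export
score_dataset <- function(model, dataset, split = "test", mc = 0L,
                          seed = 1L, anchors = NULL,
                          mapping = "paper") {
  sp <- dataset_split(dataset, split)
  K <- model$config$K
  type <- model$config$model_type
  if (type == "twin" && is.null(anchors))
    stop("twin scoring needs an anchor pool", call. = FALSE)
  if (type == "twin" && is.null(anchors$embeddings))
    anchors$embeddings <- twin_embed(model, anchors$images)
  if (mc > 0L) {
    out <- mc_predict(model, sp$images, n_passes = mc, seed = seed,
                      anchors = anchors)
    score <- score_output(out, K)
    mc_sd <- if (type == "twin") as.vector(out$sd) else {
      # uncertainty of the score: sd of per-pass scores is not retained
      # per-element; summarize output sd through the score weights
      if (is.matrix(out$sd)) rowMeans(out$sd) else as.vector(out$sd)
    }
  } else {
    out <- predict_output(model, sp$images)
    score <- score_output(out, K, anchors = anchors)
    mc_sd <- NA_real_
  }
  res <- sp$manifest
  res$model_type <- type
  res$mc <- mc > 0L
  res$n_passes <- if (mc > 0L) as.integer(mc) else NA_integer_
  res$score <- score
  res$score_rescaled <- rescale_score(score, type, K, mapping)
  res$mc_sd <- mc_sd
  res
}
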