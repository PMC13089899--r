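# Model construction and forward passes for the four model families:
# multi-class softmax, CORAL ordinal, regression, and twin (siamese)
# embedding networks, all sharing the same small CNN backbone.

#' Configure a severity model
#'
#' @param model_type one of `"multiclass"`, `"ordinal"`, `"regression"`,
#'   `"twin"`.
#' @param K number of ordinal classes (>= 2).
#' @param backbone backbone identifier; `"cnn3"` (3-block CNN) is the
#'   default, with channel widths set by `channels`.
#' @param mc_dropout insert spatial (channel-wise) dropout after every
#'   backbone block and keep it active at inference (Monte Carlo dropout).
#' @param dropout_rate dropout probability in \[0,1); only meaningful with
#'   `mc_dropout = TRUE`.
#' @param embedding_dim embedding width for twin models.
#' @param channels channel widths of the backbone blocks.
#' @return a `model_config` list.
#' @export
model_config <- function(model_type = c("multiclass", "ordinal",
                                        "regression", "twin"),
                         K = 3L, backbone = "cnn3", mc_dropout = FALSE,
                         dropout_rate = if (mc_dropout) 0.2 else 0,
                         embedding_dim = 32L,
                         channels = c(8L, 16L, 32L)) {
  model_type <- match.arg(model_type)
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (mc_dropout) {
    stopifnot_scalar_prob(dropout_rate, "dropout_rate")
  } else if (dropout_rate != 0) {
    stop("dropout_rate is only used with mc_dropout = TRUE", call. = FALSE)
  }
  structure(list(model_type = model_type, K = K, backbone = backbone,
                 mc_dropout = isTRUE(mc_dropout),
                 dropout_rate = dropout_rate,
                 embedding_dim = as.integer(embedding_dim),
                 channels = as.integer(channels)),
            class = "model_config")
}

#' Build a severity model
#'
#' Initializes backbone and head parameters. The multi-class head has `K`
#' outputs through a softmax; the ordinal head follows the CORAL
#' construction — a single shared weight vector with `K - 1` independent
#' bias terms feeding `K - 1` sigmoids, which forces the predicted
#' threshold probabilities to be rank-monotone once the biases are sorted;
#' the regression head is one linear output; the twin model exposes an
#' embedding applied identically (shared weights) to both inputs.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @param side input image side length (must match the data).
#' @return an object of class `sev_model`.
#' @export
build_model <- function(config, seed = 1L, side = 64L) {
  stopifnot(inherits(config, "model_config"))
  params <- backbone_init(config$channels, in_ch = 1L, seed = seed)
  C <- config$channels[length(config$channels)]
  K <- config$K
  hp <- with_seed(mix_seed(seed, 202L), {
    switch(config$model_type,
      multiclass = list(
        head_W = matrix(rnorm(C * K, 0, sqrt(2 / C)), C, K),
        head_b = numeric(K)),
      ordinal = list(
        head_w = matrix(rnorm(C, 0, sqrt(2 / C)), C, 1L),
        # ordered initialization: high threshold -> low bias
        head_b = seq(1, -1, length.out = K - 1L)),
      regression = list(
        head_W = matrix(rnorm(C, 0, sqrt(2 / C)), C, 1L),
        head_b = 0),
      twin = list(
        head_W = matrix(rnorm(C * config$embedding_dim, 0, sqrt(2 / C)),
                        C, config$embedding_dim),
        head_b = numeric(config$embedding_dim)))
  })
  structure(list(config = config, params = c(params, hp), side = side),
            class = "sev_model")
}

#' @export
print.sev_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<sev_model> %s, K = %d, backbone %s (%s), %s%d parameters\n",
              x$config$model_type, x$config$K, x$config$backbone,
              paste(x$config$channels, collapse = "-"),
              if (x$config$mc_dropout)
                sprintf("MC dropout %.2g, ", x$config$dropout_rate) else "",
              npar))
  invisible(x)
}

as_image_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

# Head forward on GAP features G (N x C). For ordinal prediction the biases
# are sorted in decreasing order so that the K-1 sigmoid outputs are
# non-increasing in the threshold index (CORAL rank-monotonicity).
head_fwd <- function(model, G, sort_biases = TRUE) {
  cfg <- model$config
  p <- model$params
  switch(cfg$model_type,
    multiclass = {
      logits <- G %*% p$head_W +
        matrix(p$head_b, nrow(G), cfg$K, byrow = TRUE)
      z <- exp(logits - apply(logits, 1, max))
      z / rowSums(z)
    },
    ordinal = {
      b <- if (sort_biases) sort(p$head_b, decreasing = TRUE) else p$head_b
      z <- as.vector(G %*% p$head_w)
      sigmoid(outer(z, rep(1, cfg$K - 1L)) +
                matrix(b, length(z), cfg$K - 1L, byrow = TRUE))
    },
    regression = as.vector(G %*% p$head_W) + p$head_b,
    twin = G %*% p$head_W +
      matrix(p$head_b, nrow(G), cfg$embedding_dim, byrow = TRUE))
}

#' Forward pass: model outputs for a batch of images
#'
#' Returns the model family's native probabilistic output: a softmax matrix
#' (`n x K`) for multi-class, a sigmoid matrix (`n x (K-1)`) of threshold
#' probabilities for ordinal (rank-monotone across columns), a numeric
#' vector for regression, and an embedding matrix for twin models. With
#' `dropout_active = TRUE` (MC models only) spatial dropout masks are drawn
#' from the current RNG stream, so wrap calls in a seeded context for
#' reproducibility; [mc_predict()] does this for you.
#'
#' @param model a `sev_model`.
#' @param x image matrix (`side x side`) or array (`side x side x n`).
#' @param dropout_active keep spatial dropout active (stochastic pass).
#' @return a `probability_output` list with elements `model_type` and one of
#'   `p`, `q`, `r`, `e`.
#' @export
predict_output <- function(model, x, dropout_active = FALSE) {
  stopifnot(inherits(model, "sev_model"))
  if (dropout_active && !model$config$mc_dropout)
    stop("dropout_active requires a model built with mc_dropout = TRUE",
         call. = FALSE)
  x <- as_image_array(x)
  bb <- backbone_fwd(model$params, x, model$config$channels,
                     dropout_rate = model$config$dropout_rate,
                     dropout_active = dropout_active)
  out <- head_fwd(model, bb$features)
  structure(list(model_type = model$config$model_type,
                 p = if (model$config$model_type == "multiclass") out,
                 q = if (model$config$model_type == "ordinal") out,
                 r = if (model$config$model_type == "regression") out,
                 e = if (model$config$model_type == "twin") out),
            class = "probability_output")
}

#' Twin forward pass: embedding distance between two images
#'
#' Runs both images through the shared-weight embedding branch and returns
#' the Euclidean distance between their embeddings. Symmetric in its
#' arguments; zero for identical inputs when dropout is inactive.
#'
#' @param model a twin `sev_model`.
#' @param image_a,image_b images of identical shape.
#' @param dropout_active stochastic pass (MC models).
#' @return nonnegative scalar distance.
#' @export
twin_forward <- function(model, image_a, image_b, dropout_active = FALSE) {
  stopifnot(inherits(model, "sev_model"),
            model$config$model_type == "twin")
  if (!identical(dim(image_a), dim(image_b)))
    stop("images must have the same shape", call. = FALSE)
  x <- array(c(image_a, image_b), dim = c(dim(image_a)[1:2], 2L))
  e <- predict_output(model, x, dropout_active = dropout_active)$e
  sqrt(sum((e[1, ] - e[2, ])^2))
}

#' Embed images with a twin model
#'
#' @param model a twin `sev_model`.
#' @param x image matrix or array.
#' @param dropout_active stochastic pass.
#' @return embedding matrix (`n x embedding_dim`).
#' @export
twin_embed <- function(model, x, dropout_active = FALSE) {
  stopifnot(model$config$model_type == "twin")
  predict_output(model, x, dropout_active = dropout_active)$e
}

#' Save / load a model as plain JSON
#'
#' Parameters are serialized as nested numeric arrays so checkpoints are
#' text files that survive any transport.
#'
#' @param model a `sev_model`.
#' @param path file path.
#' @return `path` (save) or the restored `sev_model` (load).
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config), side = model$side,
              params = lapply(model$params, function(p)
                list(dim = dim(p) %||% length(p), data = as.vector(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[c("model_type", "K", "backbone",
                                            "mc_dropout", "dropout_rate",
                                            "embedding_dim", "channels")])
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) > 1L) array(p$data, dim = p$dim) else p$data
  })
  structure(list(config = cfg, params = params, side = obj$side),
            class = "sev_model")
}
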