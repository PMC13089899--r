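# Shared fixtures: everything is generated in code at test time.

# small, fast dataset for unit tests (32 px images)
tiny_dataset <- function(n = 60, seed = 42, side = 32L, ...) {
  generate_dataset(n, ordinal_scheme(3), seed = seed, side = side, ...)
}

# quickly trained model on a tiny dataset
quick_fit <- function(model_type = "ordinal", dataset = tiny_dataset(),
                      epochs = 2L, seed = 7L, mc = FALSE) {
  cfg <- model_config(model_type, K = dataset$params$K, mc_dropout = mc)
  model <- build_model(cfg, seed = seed, side = dataset$params$side)
  train_model(model, dataset, train_config(epochs = epochs, seed = seed))
}

# random probability vector (softmax of random logits)
random_simplex <- function(K) {
  z <- exp(rnorm(K))
  z / sum(z)
}

# brute-force Spearman: average-tie ranks then Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# brute-force AUROC: O(n^2) pairwise concordance with 0.5 for ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
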