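test_that("Spearman correlation matches hand values and the rank oracle", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  expect_equal(spearman_rho(1:5, c(1, 3, 2, 5, 4)), 0.8)
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "variance")

  set.seed(20)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE) + runif(n, 0, 0.01)  # near-ties
    y <- round(runif(n, 0, 5))                               # real ties
    if (sd(y) == 0) next
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normalized-rank MSE matches hand values and is rank-invariant", {
  expect_equal(normalized_rank_mse(c(0.1, 0.5, 0.9), 1:3), 0)
  expect_equal(normalized_rank_mse(c(5, 1), 1:2), 0.25)
  expect_equal(normalized_rank_mse(c(1, 3, 2, 4), 1:4), 0.03125)
  expect_error(normalized_rank_mse(1:3, c(1, 1, 2)), "permutation")

  set.seed(21)
  scores <- rnorm(40)
  truth <- sample(40)
  base <- normalized_rank_mse(scores, truth)
  expect_equal(normalized_rank_mse(exp(scores), truth), base)
  expect_equal(normalized_rank_mse(rank(scores), truth), base)
})

test_that("AUROC matches hand values, the O(n^2) oracle, and pROC", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "one class")

  set.seed(22)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    scores <- sample(1:10, n, replace = TRUE)  # plenty of ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  # independent reference implementation
  set.seed(23)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("rating MSE matches hand values", {
  expect_equal(rating_mse(c(1, 6), c(1, 6)), 0)
  expect_equal(rating_mse(c(2, 4), c(1, 6)), 2.5)
  expect_equal(rating_mse(c(5, 5), c(1, 9)), 16)
  expect_error(rating_mse(c(2, 4), c(NA, 6)), "missing")
})

test_that("temporal-change MSE differs changes and ignores offsets", {
  tab <- data.frame(subject_id = c("a", "b"),
                    score_t1 = c(0, 1), score_t2 = c(1, 0),
                    ref_t1 = c(0, 1), ref_t2 = c(2, 1))
  # deltas: pred (1, -1) vs ref (2, 0) -> mean((−1)^2, (−1)^2) = 1
  expect_equal(temporal_change_mse(tab), 1)
  ident <- data.frame(subject_id = "a", score_t1 = 1, score_t2 = 3,
                      ref_t1 = 5, ref_t2 = 7)
  expect_equal(temporal_change_mse(ident), 0)
  # per-subject additive offsets on both timepoints cancel
  off <- tab
  off$score_t1 <- off$score_t1 + c(10, -4)
  off$score_t2 <- off$score_t2 + c(10, -4)
  expect_equal(temporal_change_mse(off), temporal_change_mse(tab))
  expect_error(temporal_change_mse(tab[, 1:3]), "lacks")
})

test_that("pair tables join the two timepoints of each subject", {
  pred <- data.frame(subject_id = c("a", "b", "a", "c"),
                     timepoint = c(0L, 0L, 1L, 0L),
                     score_rescaled = c(1, 2, 3, 4),
                     rating_1to9 = c(2L, 3L, 5L, 4L))
  tab <- make_pair_table(pred)
  expect_equal(tab$subject_id, "a")
  expect_equal(tab$score_t2 - tab$score_t1, 2)
  expect_equal(tab$ref_t2 - tab$ref_t1, 3)
})

test_that("bootstrap is deterministic with sane intervals", {
  set.seed(30)
  dat <- data.frame(score = rnorm(100))
  dat$rank <- rank(dat$score + rnorm(100, 0, 0.2))
  met <- function(d) spearman_rho(d$score, d$rank)

  a <- bootstrap_metric(met, dat, B = 200, seed = 3, name = "spearman")
  b <- bootstrap_metric(met, dat, B = 200, seed = 3, name = "spearman")
  expect_identical(a$samples, b$samples)
  expect_true(a$ci[1] <= a$mean && a$mean <= a$ci[2])
  # resampling consistency: bootstrap mean near the point estimate
  expect_equal(a$mean, met(dat), tolerance = 0.05)

  # constant metric: zero-width interval
  const <- bootstrap_metric(function(d) 1, dat, B = 50, seed = 1)
  expect_equal(unname(diff(const$ci)), 0)
})

test_that("degenerate resamples are redrawn, excessive degeneracy errors", {
  dat <- data.frame(score = c(1, 2, 3, 4), label = c(0, 1, 1, 1))
  res <- bootstrap_metric(function(d) auroc(d$score, d$label), dat,
                          B = 50, seed = 2, name = "auroc")
  expect_true(all(is.finite(res$samples)))
  # a metric that always fails cannot be bootstrapped
  expect_error(bootstrap_metric(function(d) stop("nope"), dat, B = 10,
                                seed = 1), "undefined")
})

test_that("model comparison t-tests behave across regimes", {
  mk <- function(samples, name = "m") {
    structure(list(name = name, samples = samples, mean = mean(samples),
                   ci = quantile(samples, c(0.025, 0.975)), B = length(samples),
                   seed = 1L, n_redraws = 0L), class = "bootstrap_result")
  }
  same <- compare_models(mk(rep(0.7, 100)), mk(rep(0.7, 100)))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  sep <- compare_models(mk(rep(0.9, 100)), mk(rep(0.5, 100)))
  expect_lt(sep$p_value, 0.05)
  expect_true(sep$significant)

  set.seed(31)
  close_sep <- compare_models(mk(rnorm(500, 0.9, 0.01)),
                              mk(rnorm(500, 0.89, 0.01)))
  expect_true(close_sep$significant)

  expect_error(compare_models(mk(1:5, "a"), mk(1:5, "b")), "different")
})

test_that("pairwise comparison tables cover every model pair", {
  set.seed(32)
  mk <- function(mu) {
    s <- rnorm(100, mu, 0.02)
    structure(list(name = "spearman", samples = s, mean = mean(s),
                   ci = quantile(s, c(0.025, 0.975)), B = 100L, seed = 1L,
                   n_redraws = 0L), class = "bootstrap_result")
  }
  results <- list(a = mk(0.9), b = mk(0.8), c = mk(0.7), d = mk(0.6))
  tab <- pairwise_comparisons(results)
  expect_equal(nrow(tab), choose(4, 2))
  expect_setequal(paste(tab$model_a, tab$model_b),
                  apply(utils::combn(letters[1:4], 2), 2, paste,
                        collapse = " "))
})
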