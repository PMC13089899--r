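test_that("multiclass score is the expected class index", {
  expect_equal(multiclass_score(c(1, 0, 0), 3), 0)
  expect_equal(multiclass_score(c(0, 0, 1), 3), 2)
  expect_equal(multiclass_score(c(0.2, 0.5, 0.3), 3), 1.1)
  expect_error(multiclass_score(c(0.5, 0.2, 0.1), 3), "summing")
})

test_that("ordinal score sums the threshold probabilities", {
  expect_equal(ordinal_score(c(0, 0)), 0)
  expect_equal(ordinal_score(c(1, 1)), 2)
  expect_equal(ordinal_score(c(0.9, 0.4)), 1.3)
  expect_error(ordinal_score(c(1.2, 0)), "\\[0, 1\\]")
})

test_that("regression score passes through with optional clipping", {
  expect_equal(regression_score(1.37, 3), 1.37)
  expect_equal(regression_score(-0.4, 3, clip = TRUE), 0)
  expect_equal(regression_score(2.8, 3, clip = TRUE), 2)
})

test_that("scores stay in [0, K-1] over random probability vectors", {
  set.seed(12)
  for (i in 1:200) {
    K <- sample(2:6, 1)
    expect_true(multiclass_score(random_simplex(K), K) >= 0)
    expect_true(multiclass_score(random_simplex(K), K) <= K - 1)
    q <- runif(K - 1)
    expect_true(ordinal_score(q) >= 0 && ordinal_score(q) <= K - 1)
    # strict monotonicity in any coordinate
    j <- sample(K - 1, 1)
    q2 <- q; q2[j] <- min(1, q[j] + 0.1)
    if (q2[j] > q[j]) expect_gt(ordinal_score(q2), ordinal_score(q))
  }
})

test_that("twin score is the median anchor distance", {
  # 1-D embeddings: target 3 vs ten anchors at 0
  expect_equal(twin_score(matrix(3), matrix(rep(0, 10))), 3)
  # distances 1..10 -> even-size median 5.5
  expect_equal(twin_score(matrix(0), matrix(1:10)), 5.5)
  # identical target and anchors
  expect_equal(twin_score(matrix(c(1, 2), 1), matrix(c(1, 2), 10, 2,
                                                     byrow = TRUE)), 0)
  expect_error(twin_score(matrix(1), matrix(1, 2, 3)), "dimension")
  # invariant under anchor permutation
  set.seed(3)
  emb <- matrix(rnorm(20), 10, 2)
  tgt <- matrix(rnorm(2), 1)
  expect_equal(twin_score(tgt, emb), twin_score(tgt, emb[sample(10), ]))
})

test_that("anchor selection takes class-0 images, deterministically", {
  ds <- tiny_dataset(n = 80, seed = 51)
  pool <- select_anchors(ds, n = 5, seed = 9)
  expect_equal(nrow(pool$manifest), 5L)
  expect_true(all(pool$manifest$label == 0L))
  expect_identical(select_anchors(ds, n = 5, seed = 9)$manifest$path,
                   pool$manifest$path)

  # confidence strategy: the selected images maximize class-0 softmax
  aux <- quick_fit("multiclass", ds, epochs = 2, seed = 3)$model
  pc <- select_anchors(ds, model = aux, n = 5)
  expect_equal(pc$strategy, "confidence")
  tr <- dataset_split(ds, "train")
  cls0 <- which(tr$manifest$label == 0L)
  conf <- predict_output(aux, tr$images[, , cls0, drop = FALSE])$p[, 1]
  top <- sort(conf, decreasing = TRUE)[5]
  sel <- conf[match(pc$manifest$path, tr$manifest$path[cls0])]
  expect_true(all(sel >= top - 1e-12))

  expect_error(select_anchors(ds, n = 10000), "class-0")
})

test_that("MC inference with zero dropout is deterministic with zero sd", {
  m <- build_model(model_config("ordinal", K = 3, mc_dropout = TRUE,
                                dropout_rate = 0), seed = 1, side = 32)
  x <- tiny_dataset(n = 12, seed = 3)$images[, , 1:3]
  out <- mc_predict(m, x, n_passes = 5, seed = 2)
  expect_equal(max(out$sd), 0)
  expect_equal(out$mean, predict_output(m, x)$q, tolerance = 1e-12)
})

test_that("MC inference is seed-deterministic; one pass equals one draw", {
  m <- build_model(model_config("ordinal", K = 3, mc_dropout = TRUE,
                                dropout_rate = 0.3), seed = 1, side = 32)
  x <- tiny_dataset(n = 12, seed = 3)$images[, , 1:3]
  a <- mc_predict(m, x, n_passes = 10, seed = 7)
  b <- mc_predict(m, x, n_passes = 10, seed = 7)
  expect_identical(a$mean, b$mean)
  expect_gt(max(a$sd), 0)

  one <- mc_predict(m, x, n_passes = 1, seed = 7)
  manual <- sevscore:::with_seed(7, predict_output(m, x,
                                                   dropout_active = TRUE))
  expect_equal(one$mean, manual$q, tolerance = 1e-12)

  plain <- build_model(model_config("ordinal", K = 3), seed = 1, side = 32)
  expect_error(mc_predict(plain, x), "mc_dropout")
})

test_that("averaging commutes with scoring for linear score maps", {
  x <- tiny_dataset(n = 25, seed = 13)$images[, , 1:20]
  for (mt in c("multiclass", "ordinal", "regression")) {
    m <- build_model(model_config(mt, K = 3, mc_dropout = TRUE,
                                  dropout_rate = 0.25), seed = 2, side = 32)
    avg <- mc_predict(m, x, n_passes = 8, seed = 5)
    score_of_mean <- score_output(avg, K = 3)
    per_pass <- sevscore:::with_seed(5, {
      sapply(1:8, function(i) {
        out <- predict_output(m, x, dropout_active = TRUE)
        score_output(out, K = 3)
      })
    })
    expect_equal(score_of_mean, rowMeans(per_pass), tolerance = 1e-10)
  }
})

test_that("rescaling follows the printed affine maps and clips to [1, 9]", {
  expect_equal(rescale_score(0, "ordinal"), 1)
  expect_equal(rescale_score(2, "ordinal", K = 3), 7)     # x3 + 1
  expect_equal(rescale_score(0, "twin"), 1)
  expect_equal(rescale_score(9.5, "twin"), 9)             # shift and clip
  expect_equal(rescale_score(2, "ordinal", K = 3, mapping = "full_range"), 9)
  expect_equal(rescale_score(3, "multiclass", K = 4, mapping = "full_range"),
               9)
  expect_equal(rescale_score(1.1, "multiclass", K = 3), 4.3)
})
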