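# Rank-agreement and calibration metric suite with bootstrap confidence
# intervals and pairwise model comparison.

#' Spearman rank correlation
#'
#' Pearson correlation of the average-tie rank vectors. Signals an explicit
#' error when either input has zero rank variance (the coefficient is
#' undefined there).
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("Spearman correlation undefined: zero rank variance",
         call. = FALSE)
  cor(rx, ry)
}

#' Normalized-rank mean squared error
#'
#' Ranks the predicted scores (average ties), divides both the predicted
#' and the reference rank vector by `n` (the maximum rank), and returns the
#' mean squared difference. Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param scores numeric predictions.
#' @param true_ranks reference ranks, a permutation of `1..n`.
#' @return nonnegative error.
#' @export
normalized_rank_mse <- function(scores, true_ranks) {
  n <- length(scores)
  if (length(true_ranks) != n)
    stop("scores and true_ranks differ in length", call. = FALSE)
  if (!setequal(true_ranks, seq_len(n)))
    stop("true_ranks must be a permutation of 1..n", call. = FALSE)
  mean((rank(scores) / n - true_ranks / n)^2)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive case receives a higher score than
#' a random negative case, with ties counted as 1/2. Computed from the
#' rank-sum statistic.
#'
#' @param scores numeric predictions.
#' @param binary_labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, binary_labels) {
  stopifnot(length(scores) == length(binary_labels),
            all(binary_labels %in% c(0, 1)))
  npos <- sum(binary_labels == 1)
  nneg <- sum(binary_labels == 0)
  if (npos == 0 || nneg == 0)
    stop("AUROC undefined: only one class present", call. = FALSE)
  r <- rank(scores)
  (sum(r[binary_labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Group ordinal classes into a clinically relevant binary label
#'
#' Classes `<= cut` become negative (0), classes `> cut` positive (1) —
#' e.g. normal/pre-plus vs plus with `cut = 1` on a 3-class scheme.
#'
#' @param labels integer ordinal labels in `0..K-1`.
#' @param cut integer in `0..K-2`.
#' @return 0/1 vector.
#' @export
binary_grouping <- function(labels, cut) {
  stopifnot(cut >= 0, all(labels >= 0))
  as.integer(labels > cut)
}

#' Mean squared error against 9-point median expert ratings
#'
#' @param rescaled_scores predictions on the 1-9 scale.
#' @param ratings_1to9 median expert ratings in 1..9.
#' @return nonnegative error.
#' @export
rating_mse <- function(rescaled_scores, ratings_1to9) {
  if (anyNA(ratings_1to9) || length(ratings_1to9) == 0)
    stop("ratings are missing", call. = FALSE)
  stopifnot(length(rescaled_scores) == length(ratings_1to9),
            all(rescaled_scores >= 1 & rescaled_scores <= 9))
  mean((rescaled_scores - ratings_1to9)^2)
}

#' Temporal-change mean squared error
#'
#' For each subject with two timepoints, the predicted severity change
#' `score(t2) - score(t1)` is compared with the reference change
#' `rating(t2) - rating(t1)`; the result is the mean squared difference.
#' Per-subject additive offsets applied to both timepoints cancel out.
#'
#' @param pair_table data.frame with columns `subject_id`, `score_t1`,
#'   `score_t2`, `ref_t1`, `ref_t2` — see [make_pair_table()].
#' @return nonnegative error.
#' @export
temporal_change_mse <- function(pair_table) {
  need <- c("score_t1", "score_t2", "ref_t1", "ref_t2")
  if (!all(need %in% names(pair_table)))
    stop("pair_table lacks columns: ",
         paste(setdiff(need, names(pair_table)), collapse = ", "),
         call. = FALSE)
  if (anyNA(pair_table[need]))
    stop("pair_table contains unpaired or unrated subjects", call. = FALSE)
  dpred <- pair_table$score_t2 - pair_table$score_t1
  dref <- pair_table$ref_t2 - pair_table$ref_t1
  mean((dpred - dref)^2)
}

#' Build a longitudinal pair table from a predictions table
#'
#' Joins the two timepoints of every subject that has both, pairing the
#' prediction column with a reference column.
#'
#' @param predictions data.frame with `subject_id`, `timepoint`, a score
#'   column and a reference column.
#' @param score_col,ref_col column names.
#' @return data.frame with one row per paired subject.
#' @export
make_pair_table <- function(predictions, score_col = "score_rescaled",
                            ref_col = "rating_1to9") {
  t0 <- predictions[predictions$timepoint == 0L, ]
  t1 <- predictions[predictions$timepoint == 1L, ]
  common <- intersect(t0$subject_id, t1$subject_id)
  i0 <- match(common, t0$subject_id)
  i1 <- match(common, t1$subject_id)
  data.frame(subject_id = common,
             score_t1 = t0[[score_col]][i0],
             score_t2 = t1[[score_col]][i1],
             ref_t1 = t0[[ref_col]][i0],
             ref_t2 = t1[[ref_col]][i1],
             stringsAsFactors = FALSE)
}

#' Bootstrap a metric
#'
#' Resamples the evaluation units (rows) with replacement `B` times and
#' re-evaluates the metric on every resample. Resamples on which the metric
#' is undefined (e.g. a single-class AUROC draw) are redrawn; the redraw
#' count is recorded, and more than 50% degenerate draws is an error.
#'
#' @param metric a function taking the resampled `data` rows and returning
#'   a scalar.
#' @param data data.frame of evaluation units (one row per image or per
#'   subject pair).
#' @param B number of bootstrap iterations (default 500).
#' @param seed seed.
#' @param name metric name carried into the result.
#' @return a `bootstrap_result`: `samples` (length B), `mean`, `ci` (2.5
#'   and 97.5 percentiles), `B`, `seed`, `n_redraws`, `name`.
#' @export
bootstrap_metric <- function(metric, data, B = 500L, seed = 1L,
                             name = deparse(substitute(metric))) {
  stopifnot(is.function(metric), B >= 2L, nrow(data) >= 2L)
  with_seed(seed, {
    n <- nrow(data)
    samples <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        val <- tryCatch(metric(data[sample.int(n, n, replace = TRUE), ,
                                    drop = FALSE]),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        redraws <- redraws + 1L
        if (redraws > B) # > 50% degenerate on average
          stop("metric undefined on most bootstrap resamples",
               call. = FALSE)
      }
      samples[b] <- val
    }
    structure(list(name = name, samples = samples, mean = mean(samples),
                   ci = unname(quantile(samples, c(0.025, 0.975))),
                   B = as.integer(B), seed = as.integer(seed),
                   n_redraws = redraws),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s: %.4f [%.4f, %.4f] (B = %d)\n",
              x$name, x$mean, x$ci[1], x$ci[2], x$B))
  invisible(x)
}

#' Compare two models on a bootstrapped metric
#'
#' Two-sided t-test on the two bootstrap sample vectors; a p-value below
#' 0.05 flags the models as statistically different. Degenerate
#' (zero-variance) sample vectors are handled explicitly: identical
#' constants give p = 1, separated constants p = 0.
#'
#' @param resultA,resultB `bootstrap_result`s of the same metric with the
#'   same `B`.
#' @param alpha significance level (default 0.05).
#' @return list: `p_value`, `significant`, `mean_diff`, `metric`.
#' @export
compare_models <- function(resultA, resultB, alpha = 0.05) {
  stopifnot(inherits(resultA, "bootstrap_result"),
            inherits(resultB, "bootstrap_result"))
  if (!identical(resultA$name, resultB$name))
    stop("cannot compare different metrics: ", resultA$name, " vs ",
         resultB$name, call. = FALSE)
  if (resultA$B != resultB$B)
    stop("bootstrap sizes differ", call. = FALSE)
  a <- resultA$samples; b <- resultB$samples
  if (sd(a) == 0 && sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  } else {
    p <- t.test(a, b, alternative = "two.sided")$p.value
  }
  list(p_value = p, significant = p < alpha,
       mean_diff = mean(a) - mean(b), metric = resultA$name)
}

#' Evaluate a predictions table against its fine-grained references
#'
#' Computes the cross-sectional metric suite (Spearman, normalized-rank
#' MSE, clinically relevant AUROC, 9-point rating MSE) with bootstrap CIs
#' on the ranked baseline test images, plus the temporal-change MSE on
#' longitudinal pairs when present.
#'
#' @param predictions a [score_dataset()] table for the test split.
#' @param cut binary grouping cut for the AUROC (classes `<= cut` negative).
#' @param B bootstrap iterations.
#' @param seed seed.
#' @return named list of `bootstrap_result`s (and `n_ranked`).
#' @export
evaluate_predictions <- function(predictions, cut = 1L, B = 500L,
                                 seed = 1L) {
  ranked <- predictions[!is.na(predictions$rank) &
                          predictions$timepoint == 0L, ]
  if (nrow(ranked) < 5L)
    stop("need at least 5 ranked baseline test images", call. = FALSE)
  out <- list(
    spearman = bootstrap_metric(
      function(d) spearman_rho(d$score, d$rank), ranked, B = B,
      seed = mix_seed(seed, 1L), name = "spearman"),
    rank_mse = bootstrap_metric(
      function(d) mean((rank(d$score) / nrow(d) - rank(d$rank) / nrow(d))^2),
      ranked, B = B, seed = mix_seed(seed, 2L), name = "rank_mse"),
    auroc = bootstrap_metric(
      function(d) auroc(d$score, binary_grouping(d$label, cut)), ranked,
      B = B, seed = mix_seed(seed, 3L), name = "auroc"),
    rating_mse = bootstrap_metric(
      function(d) rating_mse(d$score_rescaled, d$rating_1to9), ranked,
      B = B, seed = mix_seed(seed, 4L), name = "rating_mse"))
  pairs <- make_pair_table(predictions)
  if (nrow(pairs) >= 2L) {
    out$temporal_mse <- bootstrap_metric(
      temporal_change_mse, pairs, B = B, seed = mix_seed(seed, 5L),
      name = "temporal_mse")
  }
  out$n_ranked <- nrow(ranked)
  out
}

#' Pairwise comparison matrix across models
#'
#' All `choose(m, 2)` pairwise bootstrap t-tests for one metric across `m`
#' models.
#'
#' @param results named list of `bootstrap_result`s for the same metric.
#' @param alpha significance level.
#' @return data.frame with one row per model pair: `model_a`, `model_b`,
#'   `p_value`, `significant`, `mean_diff`.
#' @export
pairwise_comparisons <- function(results, alpha = 0.05) {
  m <- length(results)
  stopifnot(m >= 2L, !is.null(names(results)))
  pairs <- utils::combn(names(results), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    cmp <- compare_models(results[[pairs[1, j]]], results[[pairs[2, j]]],
                          alpha = alpha)
    data.frame(model_a = pairs[1, j], model_b = pairs[2, j],
               p_value = cmp$p_value, significant = cmp$significant,
               mean_diff = cmp$mean_diff, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
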