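# End-to-end experiment runner: generate synthetic data, train the model
# variants (4 families x {plain, MC}), score the test split, and run the
# evaluation suite with pairwise model comparison. The exec/sevscore script
# exposes these as shell subcommands (synth / train / score / evaluate /
# run-all).

#' Default experiment configuration
#'
#' @param n subjects in the synthetic dataset.
#' @param K ordinal classes.
#' @param side image side length.
#' @param seed master seed; model training, MC inference and bootstrap
#'   seeds are derived from it.
#' @param epochs training epochs per model.
#' @param mc_passes MC dropout passes at inference.
#' @param B bootstrap iterations.
#' @param cut AUROC binary grouping cut.
#' @param model_types model families to train.
#' @param mc_variants train an MC twin of every family.
#' @param dropout_rate spatial dropout rate for MC variants.
#' @return a named list.
#' @export
experiment_config <- function(n = 800L, K = 3L, side = 64L, seed = 1L,
                              epochs = 8L, mc_passes = 50L, B = 500L,
                              cut = 1L,
                              model_types = c("multiclass", "ordinal",
                                              "regression", "twin"),
                              mc_variants = TRUE, dropout_rate = 0.2) {
  list(n = as.integer(n), K = as.integer(K), side = as.integer(side),
       seed = as.integer(seed), epochs = as.integer(epochs),
       mc_passes = as.integer(mc_passes), B = as.integer(B),
       cut = as.integer(cut), model_types = model_types,
       mc_variants = isTRUE(mc_variants), dropout_rate = dropout_rate)
}

#' Run a full severity-scoring experiment on synthetic data
#'
#' Generates a dataset, trains every requested model variant, scores the
#' test split (plain or MC), evaluates all variants against the
#' fine-grained references, and produces pairwise bootstrap comparisons
#' per metric.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, predictions, metric
#'   reports and comparison matrices are written as CSV/JSON.
#' @param quiet suppress progress messages.
#' @return list with `dataset`, `fits`, `predictions` (named list of
#'   tables), `metrics` (named list of metric lists), `comparisons` (named
#'   list of pairwise tables per metric).
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  scheme <- ordinal_scheme(config$K)
  say("generating %d-subject synthetic dataset (K = %d, side = %d)",
      config$n, config$K, config$side)
  dataset <- generate_dataset(config$n, scheme, seed = config$seed,
                              side = config$side)

  variants <- list()
  for (mt in config$model_types) {
    variants[[mt]] <- list(model_type = mt, mc = FALSE)
    if (config$mc_variants)
      variants[[paste0("mc_", mt)]] <- list(model_type = mt, mc = TRUE)
  }

  fits <- list(); predictions <- list()
  anchors_plain <- NULL
  for (nm in names(variants)) {
    v <- variants[[nm]]
    say("training %s", nm)
    cfg <- model_config(v$model_type, K = config$K, mc_dropout = v$mc,
                        dropout_rate = if (v$mc) config$dropout_rate else 0)
    model <- build_model(cfg, seed = mix_seed(config$seed, nm),
                         side = config$side)
    fit <- train_model(model, dataset,
                       train_config(epochs = config$epochs,
                                    seed = mix_seed(config$seed, nm, 2L)))
    fits[[nm]] <- fit
    anchors <- if (v$model_type == "twin")
      select_anchors(dataset, twin_model = fit$model,
                     seed = mix_seed(config$seed, 3L))
    predictions[[nm]] <- score_dataset(
      fit$model, dataset, split = "test",
      mc = if (v$mc) config$mc_passes else 0L,
      seed = mix_seed(config$seed, nm, 4L), anchors = anchors)
  }

  say("evaluating %d variants", length(predictions))
  metrics <- lapply(seq_along(predictions), function(i)
    evaluate_predictions(predictions[[i]], cut = config$cut, B = config$B,
                         seed = mix_seed(config$seed, 5L, i)))
  names(metrics) <- names(predictions)

  comparisons <- NULL
  if (length(metrics) >= 2L) {
    metric_names <- setdiff(names(metrics[[1]]), "n_ranked")
    comparisons <- lapply(setNames(metric_names, metric_names),
                          function(mn) {
      per_model <- lapply(metrics, `[[`, mn)
      per_model <- per_model[!vapply(per_model, is.null, TRUE)]
      if (length(per_model) >= 2L) pairwise_comparisons(per_model)
    })
  }

  result <- list(dataset = dataset, fits = fits,
                 predictions = predictions, metrics = metrics,
                 comparisons = comparisons, config = config)
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  invisible(result)
}

#' Write experiment outputs to disk
#'
#' @param result a [run_experiment()] result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$predictions)) {
    write.csv(result$predictions[[nm]],
              file.path(out_dir, paste0("predictions_", nm, ".csv")),
              row.names = FALSE)
  }
  report <- do.call(rbind, lapply(names(result$metrics), function(nm) {
    ms <- result$metrics[[nm]]
    ms <- ms[vapply(ms, inherits, TRUE, "bootstrap_result")]
    do.call(rbind, lapply(ms, function(m)
      data.frame(model = nm, metric = m$name, mean = m$mean,
                 ci_lower = m$ci[1], ci_upper = m$ci[2], B = m$B,
                 seed = m$seed, stringsAsFactors = FALSE)))
  }))
  write.csv(report, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(result$metrics, function(ms)
      lapply(ms[vapply(ms, inherits, TRUE, "bootstrap_result")],
             function(m) list(mean = m$mean, ci = m$ci, B = m$B))),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$comparisons)) {
    for (mn in names(result$comparisons)) {
      if (!is.null(result$comparisons[[mn]]))
        write.csv(result$comparisons[[mn]],
                  file.path(out_dir, paste0("comparisons_", mn, ".csv")),
                  row.names = FALSE)
    }
  }
  for (nm in names(result$fits)) {
    write.csv(result$fits[[nm]]$log,
              file.path(out_dir, paste0("trainlog_", nm, ".csv")),
              row.names = FALSE)
  }
  invisible(out_dir)
}

# ---- CLI subcommand implementations --------------------------------------

#' CLI: generate a synthetic dataset on disk
#'
#' @param out output directory.
#' @param n,K,side,seed dataset parameters.
#' @param force overwrite a non-empty directory.
#' @return the dataset, invisibly.
#' @export
cmd_synth <- function(out, n = 200L, K = 3L, side = 64L, seed = 1L,
                      force = FALSE) {
  ds <- generate_dataset(n, ordinal_scheme(K), seed = seed, side = side)
  write_dataset(ds, out, force = force)
  invisible(ds)
}

#' CLI: train one model on a dataset directory
#'
#' @param data_dir dataset directory from [cmd_synth()].
#' @param out output directory for checkpoint + training log.
#' @param model_type model family.
#' @param mc train the MC dropout variant.
#' @param epochs,seed training parameters.
#' @return the `train_result`, invisibly.
#' @export
cmd_train <- function(data_dir, out, model_type = "ordinal", mc = FALSE,
                      epochs = 8L, seed = 1L) {
  ds <- read_dataset(data_dir)
  cfg <- model_config(model_type, K = ds$params$K, mc_dropout = mc)
  model <- build_model(cfg, seed = seed, side = ds$params$side)
  fit <- train_model(model, ds, train_config(epochs = epochs, seed = seed))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  save_model(fit$model, file.path(out, "checkpoint.json"))
  write.csv(fit$log, file.path(out, "trainlog.csv"), row.names = FALSE)
  jsonlite::write_json(c(unclass(cfg), list(epochs = epochs, seed = seed)),
                       file.path(out, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(fit)
}

#' CLI: score a dataset split with a trained checkpoint
#'
#' @param checkpoint checkpoint JSON from [cmd_train()].
#' @param data_dir dataset directory.
#' @param out predictions CSV path.
#' @param split split to score.
#' @param mc MC passes (0 = plain).
#' @param seed MC seed.
#' @return the predictions table, invisibly.
#' @export
cmd_score <- function(checkpoint, data_dir, out, split = "test", mc = 0L,
                      seed = 1L) {
  model <- load_model(checkpoint)
  ds <- read_dataset(data_dir)
  anchors <- if (model$config$model_type == "twin")
    select_anchors(ds, twin_model = model, seed = seed)
  pred <- score_dataset(model, ds, split = split, mc = mc, seed = seed,
                        anchors = anchors)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write.csv(pred, out, row.names = FALSE)
  invisible(pred)
}

#' CLI: evaluate one or more prediction tables
#'
#' @param prediction_files character vector of [cmd_score()] CSVs; names
#'   become model names.
#' @param out output directory.
#' @param cut,B,seed evaluation parameters.
#' @return list with `metrics` and `comparisons`, invisibly.
#' @export
cmd_evaluate <- function(prediction_files, out, cut = 1L, B = 500L,
                         seed = 1L) {
  if (is.null(names(prediction_files)))
    names(prediction_files) <-
      sub("\\.csv$", "", basename(prediction_files))
  preds <- lapply(prediction_files, read.csv, stringsAsFactors = FALSE)
  metrics <- lapply(seq_along(preds), function(i)
    evaluate_predictions(preds[[i]], cut = cut, B = B,
                         seed = mix_seed(seed, i)))
  names(metrics) <- names(preds)
  comparisons <- NULL
  if (length(metrics) >= 2L) {
    metric_names <- setdiff(names(metrics[[1]]), "n_ranked")
    comparisons <- lapply(setNames(metric_names, metric_names),
                          function(mn) {
      per_model <- lapply(metrics, `[[`, mn)
      per_model <- per_model[!vapply(per_model, is.null, TRUE)]
      if (length(per_model) >= 2L) pairwise_comparisons(per_model)
    })
  }
  res <- list(metrics = metrics, comparisons = comparisons)
  write_experiment(list(predictions = list(), metrics = metrics,
                        comparisons = comparisons, fits = list()), out)
  invisible(res)
}
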