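#' Fit one model on a split and score its test predictions
#'
#' Trains on the plan's training samples only, predicts the held-out test
#' samples, and computes per-output-feature Spearman correlations against
#' the test truth in the model's output-transform space (the statistic is
#' rank-based, so any strictly monotone per-feature representation gives
#' the same value).
#'
#' @param paired A `paired_omics`.
#' @param plan A `split_plan`.
#' @param model Model kind: `"elastic_net"`, `"random_forest"`, `"mlp"` or
#'   `"autoencoder"`.
#' @param ... Passed to the model's fit function.
#' @return List: `scores` (tibble `feature`, `score`, `flagged`),
#'   `predictions` (tibble over test samples), `model`.
#' @export
evaluate_split <- function(paired, plan, model = "elastic_net", ...) {
  train <- training_slice(paired, plan, "train")
  test <- training_slice(paired, plan, "test")
  fit <- switch(model,
    elastic_net = fit_elastic_net(train, ...),
    random_forest = fit_random_forest(train, ...),
    mlp = fit_mlp(train, ...),
    autoencoder = fit_autoencoder(train, ...),
    stop("unknown model kind: ", model, call. = FALSE))
  pred <- predict(fit, test$input)
  truth <- apply_transform(fit$ft_out, abund_matrix(test$output)[, fit$output_features, drop = FALSE])
  list(scores = per_feature_spearman(pred, truth), predictions = pred, model = fit)
}

#' Run the cross-omics prediction benchmark
#'
#' For every requested model and every split plan: fit on the training
#' samples, predict the test samples, score per output feature; then
#' aggregate per-feature scores across splits ([score_features()]).
#' Optionally writes a results directory
#' (`<out>/<combo>/<model>/<seed>/{predictions,scores}.tsv`, aggregates
#' under `<combo>/summary/`, and a manifest tying files to the
#' configuration hash).
#'
#' @param paired A `paired_omics`.
#' @param plans List of `split_plan`s (see [make_splits()]).
#' @param models Character vector of model kinds.
#' @param top_k Top-feature count for the reported summary.
#' @param out_dir Optional output directory.
#' @param model_args Named list: per-model extra arguments.
#' @return A `benchmark_result`: `scores` (long tibble `model`, `split`,
#'   `feature`, `score`), `feature_scores` (named list per model),
#'   `predictions` (per model, per split), `plans`, `combo`.
#' @export
run_benchmark <- function(paired, plans, models = "elastic_net", top_k = 50,
                          out_dir = NULL, model_args = list()) {
  stopifnot(inherits(paired, "paired_omics"))
  bad <- setdiff(models, c("elastic_net", "random_forest", "mlp", "autoencoder"))
  if (length(bad)) stop("unknown model kinds: ", paste(bad, collapse = ", "), call. = FALSE)
  top_k <- min(top_k, length(feature_ids(paired$output)))
  scores_long <- list()
  predictions <- list()
  for (model in models) {
    preds <- list()
    for (plan in plans) {
      args <- c(list(paired = paired, plan = plan, model = model),
                model_args[[model]] %||% list())
      res <- do.call(evaluate_split, args)
      scores_long[[length(scores_long) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(model = model, split = plan$seed), res$scores)
      preds[[as.character(plan$seed)]] <- res$predictions
    }
    predictions[[model]] <- preds
  }
  scores_long <- dplyr::bind_rows(scores_long)
  fscores <- lapply(stats::setNames(models, models), function(m) {
    score_features(dplyr::filter(scores_long, .data$model == m), top_k = top_k)
  })
  result <- structure(list(scores = scores_long, feature_scores = fscores,
                           predictions = predictions, plans = plans,
                           combo = paired$combo, top_k = top_k),
                      class = "benchmark_result")
  if (!is.null(out_dir)) write_benchmark(result, out_dir)
  result
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s, %d splits\n", x$combo, length(x$plans)))
  for (m in names(x$feature_scores)) {
    s <- attr(x$feature_scores[[m]], "summary")
    cat(sprintf("  %-14s top-%d mean Spearman %.3f +/- %.3f\n", m, s$top_k, s$score, s$error))
  }
  invisible(x)
}

write_benchmark <- function(result, out_dir) {
  combo_dir <- file.path(out_dir, gsub("[^A-Za-z0-9+_-]", "_", result$combo))
  manifest <- list()
  for (m in names(result$predictions)) {
    for (seed in names(result$predictions[[m]])) {
      d <- file.path(combo_dir, m, seed)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      readr::write_tsv(result$predictions[[m]][[seed]],
                       file.path(d, "predictions.tsv"), progress = FALSE)
      sc <- dplyr::filter(result$scores, .data$model == m, .data$split == as.integer(seed))
      readr::write_tsv(sc, file.path(d, "scores.tsv"), progress = FALSE)
      manifest[[length(manifest) + 1L]] <- list(
        step = paste("predict+score", m, "seed", seed),
        files = file.path(m, seed, c("predictions.tsv", "scores.tsv")))
    }
  }
  sm <- file.path(combo_dir, "summary")
  dir.create(sm, recursive = TRUE, showWarnings = FALSE)
  for (m in names(result$feature_scores)) {
    readr::write_tsv(tibble::as_tibble(result$feature_scores[[m]]),
                     file.path(sm, paste0(m, "_feature_scores.tsv")), progress = FALSE)
  }
  summaries <- lapply(result$feature_scores, function(fs) attr(fs, "summary"))
  jsonlite::write_json(
    list(combo = result$combo, top_k = result$top_k,
         seeds = vapply(result$plans, `[[`, integer(1), "seed"),
         summary = summaries,
         config_hash = rlang::hash(list(result$combo, result$top_k,
                                        vapply(result$plans, `[[`, integer(1), "seed"))),
         manifest = manifest),
    file.path(sm, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(combo_dir)
}
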