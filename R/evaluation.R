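#' Spearman rank correlation
#'
#' Pearson correlation of the rank-transformed vectors, average ranks for
#' ties — the standard statistic for comparing a predicted feature vector
#' with its ground truth. Returns `NA` when either vector is constant
#' (undefined correlation); scoring code records such features as 0 with a
#' flag.
#'
#' @param pred,truth Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`, or `NA` for a constant input.
#' @export
spearman_cor <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("length mismatch: ", length(pred), " vs ", length(truth), call. = FALSE)
  }
  if (length(pred) < 2L) stop("need at least 2 observations", call. = FALSE)
  rp <- rank(pred, ties.method = "average")
  rt <- rank(truth, ties.method = "average")
  sp <- stats::sd(rp); st <- stats::sd(rt)
  if (sp == 0 || st == 0) return(NA_real_)
  sum((rp - mean(rp)) * (rt - mean(rt))) / ((length(rp) - 1) * sp * st)
}

# per-feature Spearman between a prediction tibble and a truth matrix
per_feature_spearman <- function(pred, truth) {
  feats <- colnames(truth)
  tibble::tibble(
    feature = feats,
    score = vapply(feats, function(j) {
      r <- spearman_cor(pred[[j]], truth[, j])
      if (is.na(r)) 0 else r
    }, numeric(1)),
    flagged = vapply(feats, function(j) is.na(spearman_cor(pred[[j]], truth[, j])), logical(1)))
}

#' Aggregate per-split feature correlations
#'
#' Given per-feature Spearman correlations from repeated train/test splits,
#' computes each feature's mean and SD across splits and the reported
#' summary: the mean over the `top_k` features by per-feature mean
#' correlation (descending, ties broken by feature id), with the error
#' defined as the mean per-feature SD over those same features.
#'
#' @param scores Tibble with columns `split`, `feature`, `score` (and
#'   optionally `flagged`).
#' @param top_k How many top features enter the summary (default 50).
#' @return A `feature_scores` tibble (`feature`, `mean`, `sd`, `n_splits`,
#'   `flagged`) ordered by descending mean; `summary(x)` or
#'   `attr(x, "summary")` holds `score`, `error`, `top_k`, `top_features`.
#' @export
score_features <- function(scores, top_k = 50) {
  stopifnot(all(c("split", "feature", "score") %in% names(scores)))
  counts <- scores |> dplyr::count(.data$feature)
  if (length(unique(counts$n)) != 1L) {
    bad <- counts$feature[counts$n < max(counts$n)]
    stop("features missing from some splits: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  per_feat <- scores |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      mean = mean(.data$score),
      sd = if (dplyr::n() > 1) stats::sd(.data$score) else 0,
      n_splits = dplyr::n(),
      flagged = if ("flagged" %in% names(scores)) any(.data$flagged) else FALSE,
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean), .data$feature)
  if (top_k > nrow(per_feat)) {
    stop(sprintf("top_k = %d exceeds the %d scored features", top_k, nrow(per_feat)),
         call. = FALSE)
  }
  top <- per_feat[seq_len(top_k), ]
  structure(per_feat,
            class = c("feature_scores", class(per_feat)),
            per_split = scores,
            summary = list(score = mean(top$mean), error = mean(top$sd),
                           top_k = top_k, top_features = top$feature))
}

#' @export
print.feature_scores <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<feature_scores> %d features, %d splits; top-%d mean Spearman %.3f +/- %.3f\n",
              nrow(x), max(x$n_splits), s$top_k, s$score, s$error))
  NextMethod()
}

#' Top features of a score set
#' @param x A `feature_scores` (or tibble with `feature` and `mean`).
#' @param k Number of features, or `fraction` of all features.
#' @param fraction Fraction in (0, 1] used when `k` is missing.
#' @return Character vector of feature ids.
#' @export
top_features <- function(x, k = NULL, fraction = NULL) {
  ord <- x[order(-x$mean, x$feature), ]
  if (is.null(k)) {
    stopifnot(!is.null(fraction), fraction > 0, fraction <= 1)
    k <- round(fraction * nrow(ord))
    if (k < 1) stop("fraction keeps no features", call. = FALSE)
  }
  utils::head(ord$feature, k)
}

#' Correlation-shift comparison between input and predicted features
#'
#' For every feature id shared between the input and output layers (e.g.
#' the same enzyme measured as gene and as transcript), compares
#' `spearman(input feature, truth feature)` with
#' `spearman(predicted feature, truth feature)`. A one-sided Mann-Whitney
#' test asks whether predictions sit closer to the truth than the raw input
#' does.
#'
#' @param input,predicted,truth Tables (`abund_tbl`, tibble with
#'   `sample_id`, or matrix) over the same samples.
#' @param features Optional feature subset (e.g. the top-50 set).
#' @return Tibble (`feature`, `input_vs_truth`, `predicted_vs_truth`);
#'   `attr(, "test")` holds the Mann-Whitney comparison.
#' @export
correlation_shift_densities <- function(input, predicted, truth, features = NULL) {
  as_mat <- function(x) if (is.matrix(x)) x else abund_matrix(abund_coerce(x))
  mi <- as_mat(input); mp <- as_mat(predicted); mt <- as_mat(truth)
  shared <- intersect(colnames(mi), colnames(mt))
  if (!is.null(features)) shared <- intersect(shared, features)
  if (length(shared) == 0L) stop("no shared feature ids between input and truth", call. = FALSE)
  res <- tibble::tibble(
    feature = shared,
    input_vs_truth = vapply(shared, function(j) {
      r <- spearman_cor(mi[, j], mt[, j]); if (is.na(r)) 0 else r
    }, numeric(1), USE.NAMES = FALSE),
    predicted_vs_truth = vapply(shared, function(j) {
      if (!j %in% colnames(mp)) return(NA_real_)
      r <- spearman_cor(mp[, j], mt[, j]); if (is.na(r)) 0 else r
    }, numeric(1), USE.NAMES = FALSE))
  ok <- !is.na(res$predicted_vs_truth)
  test <- stats::wilcox.test(res$predicted_vs_truth[ok], res$input_vs_truth[ok],
                             alternative = "greater", exact = FALSE, correct = TRUE)
  attr(res, "test") <- list(statistic = unname(test$statistic), p_value = test$p.value,
                            alternative = "predicted closer to truth than input")
  res
}

abund_coerce <- function(x) {
  if (inherits(x, "abund_tbl")) return(x)
  if (is.data.frame(x) && "sample_id" %in% names(x)) {
    return(abundance_table(x, modality = "concat", scale = "relative"))
  }
  stop("expected an abundance table, tibble with sample_id, or matrix", call. = FALSE)
}

#' Core well-predicted feature analysis
#'
#' Takes two or more per-feature score sets (one per train/test partition
#' or per input type), extracts each set's top fraction by mean score, and
#' reports the pairwise Jaccard similarity matrix, the all-way intersection
#' (the "core set") and the union.
#'
#' @param score_sets Named list of `feature_scores` (or tibbles with
#'   `feature` and `mean`).
#' @param top_fraction Fraction of features per top set (default 0.25).
#' @return A `core_set_report`: `$sets`, `$jaccard`, `$core`, `$union`,
#'   `$core_fraction`.
#' @export
core_feature_analysis <- function(score_sets, top_fraction = 0.25) {
  stopifnot(length(score_sets) >= 2)
  if (is.null(names(score_sets))) names(score_sets) <- paste0("set", seq_along(score_sets))
  sets <- lapply(score_sets, top_features, fraction = top_fraction)
  if (any(lengths(sets) == 0L)) stop("top_fraction yields an empty set", call. = FALSE)
  nm <- names(sets)
  J <- matrix(1, length(sets), length(sets), dimnames = list(nm, nm))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    J[i, j] <- jaccard(sets[[i]], sets[[j]])
  }
  core <- Reduce(intersect, sets)
  un <- Reduce(union, sets)
  structure(list(sets = sets, jaccard = J, core = core, union = un,
                 core_fraction = length(core) / length(un),
                 top_fraction = top_fraction),
            class = "core_set_report")
}

#' Jaccard similarity of two id sets
#' @param a,b Character vectors.
#' @return `|a ∩ b| / |a ∪ b|`; 1 for two empty sets.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' @export
print.core_set_report <- function(x, ...) {
  cat(sprintf("<core_set_report> %d sets (top %.0f%%); core %d / union %d (%.1f%%)\n",
              length(x$sets), 100 * x$top_fraction, length(x$core), length(x$union),
              100 * x$core_fraction))
  invisible(x)
}

#' Feature variance versus prediction quality
#'
#' Computes each output feature's variance on the test-set truth values
#' (averaged across partitions) and tests its rank association with the
#' feature's mean prediction quality.
#'
#' @param truth_tables List of truth matrices/tables, one per partition
#'   (test samples x features), or a single table.
#' @param scores A `feature_scores`.
#' @return Tibble (`feature`, `variance`, `mean_score`, `flagged`);
#'   `attr(, "association")` holds the Spearman statistic and two-sided
#'   p-value.
#' @export
variance_vs_quality <- function(truth_tables, scores) {
  if (!is.list(truth_tables) || is.data.frame(truth_tables)) truth_tables <- list(truth_tables)
  mats <- lapply(truth_tables, function(x) if (is.matrix(x)) x else abund_matrix(abund_coerce(x)))
  feats <- scores$feature
  vars <- sapply(mats, function(m) {
    stopifnot(all(feats %in% colnames(m)))
    apply(m[, feats, drop = FALSE], 2, stats::var)
  })
  res <- tibble::tibble(feature = feats,
                        variance = unname(rowMeans(as.matrix(vars))),
                        mean_score = scores$mean,
                        flagged = scores$flagged)
  ct <- suppressWarnings(stats::cor.test(res$variance, res$mean_score,
                                         method = "spearman", exact = FALSE))
  attr(res, "association") <- list(rho = unname(ct$estimate), p_value = ct$p.value)
  res
}

#' Enzyme-class enrichment of well-predicted features
#'
#' Labels features by their first Enzyme Commission digit (classes 1-7) and
#' asks, for each requested top fraction, whether any class is over- or
#' under-represented among the best-predicted features relative to the
#' background of all predicted features, by Fisher's exact test (two-sided)
#' on the 2x2 membership table.
#'
#' @param scores A `feature_scores` (background = all its features).
#' @param fractions Top fractions to test (default 0.10, 0.25, 0.50).
#' @param classes Optional named vector mapping feature id to class; by
#'   default the leading EC digit is parsed from the feature id.
#' @return Tibble (`fraction`, `class`, `in_top`, `out_top`, `class_size`,
#'   `odds_ratio`, `p_value`).
#' @export
ec_class_enrichment <- function(scores, fractions = c(0.10, 0.25, 0.50),
                                classes = NULL) {
  background <- scores$feature
  if (is.null(classes)) {
    classes <- stats::setNames(ec_class_of(background), background)
  }
  cls <- classes[background]
  known <- !is.na(cls)
  rows <- list()
  for (f in fractions) {
    top <- top_features(scores, fraction = f)
    for (cl in sort(unique(cls[known]))) {
      in_class <- background[known][cls[known] == cl]
      a <- length(intersect(top, in_class))
      b <- length(setdiff(top, in_class))
      cc <- length(setdiff(in_class, top))
      d <- length(background[known]) - a - b - cc
      if (b + d == 0 || cc + d == 0) {  # degenerate: top set = background
        or <- 1; p <- 1
      } else {
        p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
        or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fraction = f, class = cl, in_top = a, out_top = cc,
        class_size = length(in_class), odds_ratio = or, p_value = p)
    }
  }
  dplyr::bind_rows(rows)
}

#' First-digit Enzyme Commission class of feature ids
#' @param ids Feature ids such as `"1.4.1.3"` (an optional modality prefix
#'   before the last `_` is ignored).
#' @return Character class labels (`"1"`-`"7"`), `NA` where unparseable.
#' @export
ec_class_of <- function(ids) {
  stripped <- stringr::str_remove(ids, "^.*_")
  m <- stringr::str_match(stripped, "^([1-7])\\.")[, 2]
  m
}

# two-sided rank-sum with a p = 1 convention when every pooled value ties
rank_sum_test <- function(a, b) {
  if (all(c(a, b) == c(a, b)[1])) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  exact <- length(a) < 50 && length(b) < 50 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Mann-Whitney comparison of two models' feature correlations
#'
#' Two-sided rank-sum test on the per-feature mean correlations of two
#' models scored over the same feature universe. Exact when both samples
#' are below 50 and tie-free; normal approximation with tie correction
#' otherwise.
#'
#' @param scores_a,scores_b Numeric vectors of per-feature correlations, or
#'   `feature_scores` objects.
#' @return Tibble with `statistic` (U for the first sample), `p_value`,
#'   `n_a`, `n_b`.
#' @export
compare_models <- function(scores_a, scores_b) {
  va <- if (is.data.frame(scores_a)) scores_a$mean else scores_a
  vb <- if (is.data.frame(scores_b)) scores_b$mean else scores_b
  if (length(va) < 2 || length(vb) < 2) stop("need at least 2 features per model", call. = FALSE)
  rs <- rank_sum_test(va, vb)
  tibble::tibble(statistic = rs$statistic, p_value = rs$p_value,
                 n_a = length(va), n_b = length(vb))
}
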