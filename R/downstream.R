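#' Binary IBD labels from sample metadata
#'
#' Collapses UC and CD to a single IBD label for the binary disease
#' classification task.
#'
#' @param metadata Sample metadata (see [check_metadata()]).
#' @return Factor with levels `HC`, `IBD`, named by sample id.
#' @export
ibd_labels <- function(metadata) {
  metadata <- check_metadata(metadata)
  stats::setNames(factor(ifelse(metadata$diagnosis == "HC", "HC", "IBD"),
                         levels = c("HC", "IBD")),
                  metadata$sample_id)
}

#' Fairness-controlled downsampling across data sources
#'
#' Classifiers trained on different data sources (input features, predicted
#' features, ground-truth features) are only comparable when they see the
#' same amount of data. For one split plan, every source's training set is
#' downsampled to the size of the smallest source, then further subsampled
#' so the IBD and HC counts are exactly equal; test sets are restricted to
#' the samples all sources share. Subsampling is deterministic under the
#' plan's seed.
#'
#' @param sources Named list of tables (`abund_tbl`, tibble with
#'   `sample_id`, or matrix with sample rownames).
#' @param metadata Sample metadata.
#' @param plan A `split_plan`.
#' @return List with `train_ids` and `test_ids` (shared by all sources) and
#'   `labels`; training ids are exactly class-balanced.
#' @export
downsample_for_fairness <- function(sources, metadata, plan) {
  sources <- lapply(sources, sample_matrix)
  labels <- ibd_labels(metadata)
  ids_of <- function(x) {
    if (is.matrix(x)) rownames(x) else x$sample_id
  }
  train_sets <- lapply(sources, function(x) intersect(plan$train_samples, ids_of(x)))
  test_sets <- lapply(sources, function(x) intersect(plan$test_samples, ids_of(x)))
  n_target <- min(lengths(train_sets))
  set.seed(plan$seed + 500009L)
  # common training pool: the intersection, downsampled to the smallest source
  train_pool <- Reduce(intersect, train_sets)
  if (length(train_pool) > n_target) train_pool <- sort(sample(sort(train_pool), n_target))
  by_class <- split(train_pool, droplevels(labels[train_pool]))
  if (length(by_class) < 2L || any(lengths(by_class) == 0L)) {
    stop("downsampling emptied a class: ",
         paste(sprintf("%s=%d", names(by_class), lengths(by_class)), collapse = ", "),
         call. = FALSE)
  }
  n_per_class <- min(lengths(by_class))
  train_ids <- sort(unlist(lapply(by_class, function(ids) {
    if (length(ids) > n_per_class) sort(sample(sort(ids), n_per_class)) else ids
  }), use.names = FALSE))
  test_ids <- sort(Reduce(intersect, test_sets))
  if (length(test_ids) == 0L) stop("no shared test samples across sources", call. = FALSE)
  list(train_ids = train_ids, test_ids = test_ids, labels = labels)
}

# any samples-by-features table as a plain matrix (classifier features need
# not be compositions: predicted tables live in transformed space)
sample_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)))
    return(x)
  }
  if (is.data.frame(x) && "sample_id" %in% names(x)) {
    m <- as.matrix(as.data.frame(x)[setdiff(names(x), "sample_id")])
    rownames(m) <- as.character(x[["sample_id"]])
    return(m)
  }
  stop("expected a matrix with sample rownames or a data frame with sample_id", call. = FALSE)
}

# declared random-search grid for the disease classifier
classifier_grid <- function() {
  list(num_trees = seq(100, 1000, by = 100),
       max_depth = c(0, seq(4, 32, by = 4)),  # 0 = unlimited
       min_node = 1:8,
       mtry_rule = c("sqrt", "log2", "frac0.3"))
}

mtry_from_rule <- function(rule, p) {
  m <- switch(rule,
    sqrt = floor(sqrt(p)),
    log2 = floor(log2(p)),
    frac0.3 = floor(0.3 * p))
  max(1L, min(p, m))
}

#' Train the IBD random-forest classifier with random-search CV
#'
#' Hyperparameters (trees, depth, minimum node size, feature subsampling
#' rule) are chosen by `n_iter` iterations of random search maximizing mean
#' balanced accuracy over `k` patient-level stratified folds inside the
#' training set, then the forest is refitted on the full (class-balanced)
#' training set.
#'
#' @param x Training table (`abund_tbl`, tibble with `sample_id`, or matrix
#'   with rownames).
#' @param labels Factor of labels named by sample id (see [ibd_labels()]).
#' @param metadata Sample metadata (patient ids for the inner folds).
#' @param n_iter Random-search iterations (default 50).
#' @param k Inner folds (default 5).
#' @param seed Random state for search and forest.
#' @return An `ibd_classifier`: ranger fit, chosen hyperparameters, classes.
#' @export
train_classifier <- function(x, labels, metadata, n_iter = 50, k = 5, seed = 0) {
  m <- sample_matrix(x)
  y <- droplevels(labels[rownames(m)])
  if (nlevels(y) < 2L) stop("training data contains a single class", call. = FALSE)
  metadata <- check_metadata(metadata)
  pat <- stats::setNames(metadata$patient_id, metadata$sample_id)[rownames(m)]
  dx <- as.data.frame(m)
  names(dx) <- paste0("x", seq_len(ncol(dx)))
  grid <- classifier_grid()
  # patient-level stratified folds on the (already balanced) training set
  pat_dx <- tibble::tibble(patient_id = pat, y = y) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  set.seed(seed)
  fold_of <- stats::setNames(rep(NA_integer_, nrow(pat_dx)), pat_dx$patient_id)
  for (cl in levels(y)) {
    ids <- sample(sort(pat_dx$patient_id[pat_dx$y == cl]))
    fold_of[ids] <- rep(seq_len(k), length.out = length(ids))
  }
  foldid <- unname(fold_of[pat])
  draws <- tibble::tibble(
    num_trees = sample(grid$num_trees, n_iter, replace = TRUE),
    max_depth = sample(grid$max_depth, n_iter, replace = TRUE),
    min_node = sample(grid$min_node, n_iter, replace = TRUE),
    mtry_rule = sample(grid$mtry_rule, n_iter, replace = TRUE))
  cv_score <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    accs <- vapply(seq_len(k), function(f) {
      tr <- foldid != f
      if (nlevels(droplevels(y[tr])) < 2L || !any(!tr)) return(NA_real_)
      fit <- ranger::ranger(x = dx[tr, , drop = FALSE], y = y[tr],
                            num.trees = draws$num_trees[i],
                            max.depth = draws$max_depth[i],
                            min.node.size = draws$min_node[i],
                            mtry = mtry_from_rule(draws$mtry_rule[i], ncol(dx)),
                            seed = ranger_seed(seed), num.threads = 1)
      pred <- stats::predict(fit, data = dx[!tr, , drop = FALSE], num.threads = 1)$predictions
      balanced_accuracy(pred, y[!tr])
    }, numeric(1))
    cv_score[i] <- mean(accs, na.rm = TRUE)
  }
  best <- which.max(cv_score)
  final <- ranger::ranger(x = dx, y = y,
                          num.trees = draws$num_trees[best],
                          max.depth = draws$max_depth[best],
                          min.node.size = draws$min_node[best],
                          mtry = mtry_from_rule(draws$mtry_rule[best], ncol(dx)),
                          probability = TRUE, seed = ranger_seed(seed), num.threads = 1)
  structure(list(fit = final, params = as.list(draws[best, ]),
                 cv_score = cv_score[best], classes = levels(y),
                 feature_names = names(dx), orig_features = colnames(m),
                 seed = seed),
            class = "ibd_classifier")
}

#' Balanced accuracy (mean of per-class recalls)
#' @param pred,truth Factors over the same samples.
#' @export
balanced_accuracy <- function(pred, truth) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  mean(vapply(levels(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

# rank-statistic AUC of scores for the positive class
roc_auc <- function(scores, truth, positive) {
  pos <- truth == positive
  if (!any(pos) || all(pos)) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Evaluate an IBD classifier on held-out samples
#'
#' @param clf An `ibd_classifier` from [train_classifier()].
#' @param x Test table with the training features.
#' @param labels Factor of labels named by sample id.
#' @return One-row tibble: balanced accuracy, ROC-AUC (NA with a flag when
#'   the test set has a single class), and precision/recall/F1 for the IBD
#'   class.
#' @export
evaluate_classifier <- function(clf, x, labels) {
  m <- sample_matrix(x)
  stopifnot(identical(colnames(m), clf$orig_features))
  dx <- as.data.frame(m)
  names(dx) <- clf$feature_names
  y <- factor(labels[rownames(m)], levels = clf$classes)
  prob <- stats::predict(clf$fit, data = dx, num.threads = 1)$predictions
  p_ibd <- prob[, "IBD"]
  pred <- factor(ifelse(p_ibd >= 0.5, "IBD", "HC"), levels = clf$classes)
  classification_metrics(pred, y, scores = p_ibd)
}

classification_metrics <- function(pred, y, scores = NULL) {
  tp <- sum(pred == "IBD" & y == "IBD")
  fp <- sum(pred == "IBD" & y == "HC")
  fn <- sum(pred == "HC" & y == "IBD")
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  auc <- if (is.null(scores)) NA_real_ else roc_auc(scores, y, "IBD")
  tibble::tibble(
    balanced_accuracy = balanced_accuracy(pred, y),
    roc_auc = auc,
    auc_undefined = is.na(auc),
    precision = precision, recall = recall, f1 = f1,
    n_test = length(y))
}

#' Stratified dummy baseline
#'
#' Predicts test labels by sampling from the training class distribution;
#' its expected balanced accuracy is 0.5 regardless of class imbalance.
#'
#' @param train_labels,test_labels Factors of labels.
#' @param seed Sampling seed.
#' @return One-row metrics tibble as in [evaluate_classifier()].
#' @export
dummy_baseline <- function(train_labels, test_labels, seed = 0) {
  set.seed(seed)
  lv <- levels(factor(train_labels))
  probs <- prop.table(table(factor(train_labels)))
  pred <- factor(sample(lv, length(test_labels), replace = TRUE, prob = as.numeric(probs)),
                 levels = lv)
  scores <- as.numeric(pred == "IBD")
  classification_metrics(pred, factor(test_labels, levels = lv), scores = scores)
}

#' Run the downstream IBD classification benchmark
#'
#' For every split plan: fairness-downsample the sources, train one
#' classifier per source on the balanced training set, evaluate on the
#' shared test samples, and add the stratified dummy baseline.
#'
#' @param sources Named list of tables (e.g. `input`, `predicted`,
#'   `ground_truth`); see [downsample_for_fairness()].
#' @param metadata Sample metadata.
#' @param plans List of `split_plan`s.
#' @param n_iter Random-search iterations per classifier.
#' @return Tibble of per-(source, split) metrics, plus per-split training
#'   sizes (identical across sources by construction).
#' @export
run_ibd_classification <- function(sources, metadata, plans, n_iter = 50) {
  rows <- list()
  for (plan in plans) {
    ds <- downsample_for_fairness(sources, metadata, plan)
    tr_y <- ds$labels[ds$train_ids]
    te_y <- ds$labels[ds$test_ids]
    for (nm in names(sources)) {
      m <- sources[[nm]]
      m <- sample_matrix(m)
      clf <- train_classifier(m[ds$train_ids, , drop = FALSE], ds$labels, metadata,
                              n_iter = n_iter, seed = plan$seed)
      res <- evaluate_classifier(clf, m[ds$test_ids, , drop = FALSE], ds$labels)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(source = nm, split = plan$seed,
                       n_train = length(ds$train_ids),
                       n_train_ibd = sum(tr_y == "IBD"),
                       n_train_hc = sum(tr_y == "HC")), res)
    }
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(source = "dummy", split = plan$seed,
                     n_train = length(ds$train_ids),
                     n_train_ibd = sum(tr_y == "IBD"),
                     n_train_hc = sum(tr_y == "HC")),
      dummy_baseline(tr_y, te_y, seed = plan$seed))
  }
  dplyr::bind_rows(rows)
}

#' Pairwise Mann-Whitney comparison of classifiers across splits
#'
#' @param runs Tibble from [run_ibd_classification()] (columns `source`,
#'   `split`, `balanced_accuracy`).
#' @return Tibble of two-sided rank-sum tests for every source pair.
#' @export
compare_classifiers <- function(runs) {
  cov <- runs |> dplyr::count(.data$source)
  if (length(unique(cov$n)) != 1L) {
    stop("sources cover different numbers of splits: ",
         paste(sprintf("%s=%d", cov$source, cov$n), collapse = ", "), call. = FALSE)
  }
  srcs <- sort(unique(runs$source))
  pairs <- utils::combn(srcs, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(p) {
    a <- runs$balanced_accuracy[runs$source == p[1]]
    b <- runs$balanced_accuracy[runs$source == p[2]]
    rs <- rank_sum_test(a, b)
    tibble::tibble(source_a = p[1], source_b = p[2],
                   statistic = rs$statistic, p_value = rs$p_value)
  }))
}

# ranger interprets seed 0 as "unseeded" (draws from the ambient RNG), so
# all forest seeds are shifted by one to keep seed-0 runs reproducible
ranger_seed <- function(seed) as.integer(seed) + 1L
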