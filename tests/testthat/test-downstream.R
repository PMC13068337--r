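# a tiny cohort with a strong, linearly separable class signal
separable_cohort <- function(n_pat = 16, visits = 2, p = 10, shift = 3, seed = 20) {
  set.seed(seed)
  md <- tiny_metadata(rep(c("HC", "CD"), each = n_pat / 2), visits = visits)
  n <- nrow(md)
  m <- matrix(rexp(n * p), n, p, dimnames = list(md$sample_id, sprintf("f%02d", 1:p)))
  m[md$diagnosis == "CD", 1:3] <- m[md$diagnosis == "CD", 1:3] * exp(shift)
  list(table = tiny_table(m / rowSums(m), "mBx"), metadata = md)
}

test_that("fairness downsampling applies the min rule and exact class balance", {
  co <- separable_cohort(n_pat = 20, visits = 3)
  md <- co$metadata
  plan <- make_splits(md, n_splits = 1)[[1]]
  m <- abund_matrix(co$table)
  sources <- list(input = m,
                  predicted = m[1:50, ],      # smaller source
                  ground_truth = m)
  ds <- downsample_for_fairness(sources, md, plan)
  labels <- ds$labels[ds$train_ids]
  expect_equal(sum(labels == "IBD"), sum(labels == "HC"))
  avail <- length(intersect(plan$train_samples, rownames(m)[1:50]))
  expect_lte(length(ds$train_ids), avail)    # min rule caps at the smallest source
  expect_true(all(ds$train_ids %in% plan$train_samples))
  expect_true(all(ds$test_ids %in% plan$test_samples))

  ds2 <- downsample_for_fairness(sources, md, plan)
  expect_identical(ds, ds2)                  # deterministic under the plan seed
})

test_that("training 60/20 imbalance is balanced down to 20/20", {
  md <- tiny_metadata(rep(c("CD", "HC"), times = c(30, 10)), visits = 2)
  plan <- list(seed = 1L, train_patients = unique(md$patient_id),
               test_patients = character(0),
               train_samples = md$sample_id[1:80], test_samples = md$sample_id[77:80])
  class(plan) <- "split_plan"
  m <- matrix(runif(80 * 4), 80, 4, dimnames = list(md$sample_id, paste0("f", 1:4)))
  ds <- downsample_for_fairness(list(a = m), md, plan)
  labels <- table(ds$labels[ds$train_ids])
  expect_equal(as.integer(labels[c("HC", "IBD")]), c(20L, 20L))
})

test_that("classification metrics reproduce confusion-matrix arithmetic", {
  truth <- factor(c(rep("IBD", 10), rep("HC", 10)), levels = c("HC", "IBD"))
  pred <- factor(c(rep("IBD", 8), rep("HC", 2), "IBD", rep("HC", 9)),
                 levels = c("HC", "IBD"))  # TP=8 FN=2 FP=1 TN=9
  res <- crossomics:::classification_metrics(pred, truth)
  expect_equal(res$precision, 8 / 9)
  expect_equal(res$recall, 0.8)
  expect_equal(res$balanced_accuracy, 0.85)
  expect_equal(res$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))

  perfect <- crossomics:::classification_metrics(truth, truth,
                                                 scores = as.numeric(truth == "IBD"))
  expect_true(all(unlist(perfect[c("balanced_accuracy", "roc_auc", "precision",
                                   "recall", "f1")]) == 1))

  all_ibd <- factor(rep("IBD", 20), levels = c("HC", "IBD"))
  expect_equal(crossomics:::classification_metrics(all_ibd, truth)$balanced_accuracy, 0.5)
})

test_that("rank-based AUC matches the probability interpretation", {
  truth <- factor(c("HC", "HC", "IBD", "IBD"), levels = c("HC", "IBD"))
  expect_equal(crossomics:::roc_auc(c(0.1, 0.2, 0.8, 0.9), truth, "IBD"), 1)
  expect_equal(crossomics:::roc_auc(c(0.9, 0.8, 0.2, 0.1), truth, "IBD"), 0)
  expect_equal(crossomics:::roc_auc(c(0.1, 0.8, 0.2, 0.9), truth, "IBD"), 0.75)
  expect_true(is.na(crossomics:::roc_auc(runif(3), factor(rep("IBD", 3)), "IBD")))
})

test_that("the classifier separates a linearly separable cohort and is deterministic", {
  co <- separable_cohort()
  md <- co$metadata
  labels <- ibd_labels(md)
  m <- abund_matrix(co$table)
  clf <- train_classifier(m, labels, md, n_iter = 5, seed = 1)
  train_metrics <- evaluate_classifier(clf, m, labels)
  expect_equal(train_metrics$balanced_accuracy, 1.0)
  clf2 <- train_classifier(m, labels, md, n_iter = 5, seed = 1)
  expect_identical(clf$params, clf2$params)

  one_class <- labels
  one_class[] <- "IBD"
  expect_error(train_classifier(m, one_class, md, n_iter = 2), "single class")
})

test_that("label permutation drives test accuracy to chance", {
  co <- separable_cohort(n_pat = 20, visits = 2)
  md <- co$metadata
  m <- abund_matrix(co$table)
  plan <- make_splits(md, n_splits = 1)[[1]]
  true_labels <- ibd_labels(md)
  accs <- vapply(1:10, function(s) {
    set.seed(s + 300)
    # permute training labels at the patient level; evaluate on true labels
    perm_md <- md
    pat <- unique(md$patient_id)
    perm_dx <- sample(dplyr::distinct(md, .data$patient_id, .data$diagnosis)$diagnosis)
    perm_md$diagnosis <- perm_dx[match(md$patient_id, pat)]
    labels <- ibd_labels(perm_md)
    clf <- train_classifier(m[plan$train_samples, ], labels, perm_md, n_iter = 3, seed = s)
    evaluate_classifier(clf, m[plan$test_samples, ], true_labels)$balanced_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("the stratified dummy baseline hovers at chance", {
  train <- factor(rep(c("HC", "IBD"), each = 30), levels = c("HC", "IBD"))
  test <- factor(rep(c("HC", "IBD"), each = 500), levels = c("HC", "IBD"))
  one <- dummy_baseline(train, test, seed = 1)
  expect_lt(abs(one$balanced_accuracy - 0.5), 0.05)
  expect_identical(dummy_baseline(train, test, seed = 9),
                   dummy_baseline(train, test, seed = 9))
  means <- vapply(1:100, function(s) dummy_baseline(train, test, s)$balanced_accuracy,
                  numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.02)
})

test_that("classifier comparison requires equal coverage and detects separation", {
  runs <- tibble::tibble(
    source = rep(c("a", "b"), each = 10),
    split = rep(1:10, 2),
    balanced_accuracy = c(seq(0.8, 0.9, length.out = 10), seq(0.4, 0.5, length.out = 10)))
  res <- compare_classifiers(runs)
  expect_lt(res$p_value, 1e-4)
  shuffled <- runs[sample(nrow(runs)), ]
  expect_equal(compare_classifiers(shuffled)$p_value, res$p_value)

  same <- tibble::tibble(source = rep(c("a", "b"), each = 10), split = rep(1:10, 2),
                         balanced_accuracy = rep(0.7, 20))
  expect_gt(compare_classifiers(same)$p_value, 0.99)

  expect_error(compare_classifiers(runs[-1, ]), "different numbers of splits")
})
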