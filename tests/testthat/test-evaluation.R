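test_that("spearman correlation matches a brute-force rank-then-Pearson oracle", {
  expect_equal(spearman_cor(1:10, 1:10), 1.0)
  expect_equal(spearman_cor(1:10, 10:1), -1.0)
  set.seed(14)
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20)
    if (i %% 3 == 0) { x <- round(x); y <- round(y) }  # exercise ties
    # oracle: Pearson moment formula on average ranks
    rx <- rank(x); ry <- rank(y)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(spearman_cor(x, y), oracle, tolerance = 1e-12)
    expect_equal(spearman_cor(x, y), cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  expect_true(is.na(spearman_cor(rep(1, 5), rnorm(5))))
  expect_error(spearman_cor(1:3, 1:4), "length mismatch")
})

test_that("score aggregation reproduces hand-computed top-k summaries", {
  scores <- tibble::tibble(
    split = rep(1:2, each = 3),
    feature = rep(c("a", "b", "c"), 2),
    score = c(0.9, 0.5, 0.1, 0.7, 0.7, 0.3))
  fs <- score_features(scores, top_k = 2)
  expect_equal(fs$feature, c("a", "b", "c"))
  expect_equal(fs$mean, c(0.8, 0.6, 0.2))
  expect_equal(fs$sd, c(sd(c(0.9, 0.7)), sd(c(0.5, 0.7)), sd(c(0.1, 0.3))))
  s <- summary(fs)
  expect_equal(s$score, mean(c(0.8, 0.6)))
  expect_equal(s$error, mean(c(sd(c(0.9, 0.7)), sd(c(0.5, 0.7)))))
  expect_equal(s$top_features, c("a", "b"))

  expect_error(score_features(scores, top_k = 5), "exceeds")
  expect_error(score_features(scores[-1, ], top_k = 2), "missing from some splits")

  # identical correlations across splits collapse the error to zero
  const <- tibble::tibble(split = rep(1:3, each = 2),
                          feature = rep(c("a", "b"), 3),
                          score = rep(c(0.6, 0.4), 3))
  expect_equal(summary(score_features(const, top_k = 2))$error, 0)
})

test_that("score aggregation is permutation-equivariant and tie-breaks by feature id", {
  set.seed(15)
  scores <- tidyr::expand_grid(split = 1:4, feature = sprintf("f%02d", 1:12))
  scores$score <- round(runif(nrow(scores)), 2)
  fs1 <- score_features(scores, top_k = 5)
  fs2 <- score_features(scores[sample(nrow(scores)), ], top_k = 5)
  strip <- function(fs) tibble::tibble(feature = fs$feature, mean = fs$mean, sd = fs$sd)
  expect_equal(strip(fs1), strip(fs2))
  expect_equal(summary(fs1), summary(fs2))
  tied <- tibble::tibble(split = 1, feature = c("z", "a", "m"), score = 0.5)
  expect_equal(score_features(tied, top_k = 2)$feature, c("a", "m", "z"))
})

test_that("top-k summary is monotone in any single feature's correlations", {
  base <- tidyr::expand_grid(split = 1:3, feature = c("a", "b", "c"))
  base$score <- c(0.2, 0.4, 0.6, 0.2, 0.4, 0.6, 0.2, 0.4, 0.6)
  s0 <- summary(score_features(base, top_k = 2))$score
  bumped <- base
  bumped$score[bumped$feature == "a"] <- bumped$score[bumped$feature == "a"] + 0.3
  expect_gte(summary(score_features(bumped, top_k = 2))$score, s0)
})

test_that("jaccard and core-set analysis match set arithmetic", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(character(0), character(0)), 1)

  mk_scores <- function(feats, vals) {
    score_features(tibble::tibble(split = 1, feature = feats, score = vals),
                   top_k = length(feats))
  }
  s1 <- mk_scores(letters[1:8], c(8:1) / 10)
  s2 <- mk_scores(letters[1:8], c(8:1) / 10)
  same <- core_feature_analysis(list(x = s1, y = s2), top_fraction = 0.25)
  expect_true(all(same$jaccard == 1))
  expect_equal(length(same$core), 2)          # top 25% of 8
  expect_equal(same$core_fraction, 1)

  s3 <- mk_scores(letters[1:8], c(1:8) / 10)  # reversed ranking -> disjoint top sets
  disj <- core_feature_analysis(list(x = s1, y = s3), top_fraction = 0.25)
  expect_equal(disj$jaccard["x", "y"], 0)
  expect_length(disj$core, 0)
  expect_true(all(diag(disj$jaccard) == 1))

  # three hand-built sets against hand-computed pairwise Jaccard
  h1 <- mk_scores(c("a", "b", "c", "d"), c(0.9, 0.8, 0.2, 0.1))
  h2 <- mk_scores(c("a", "b", "c", "d"), c(0.9, 0.1, 0.8, 0.2))
  h3 <- mk_scores(c("a", "b", "c", "d"), c(0.1, 0.2, 0.9, 0.8))
  rep3 <- core_feature_analysis(list(p = h1, q = h2, r = h3), top_fraction = 0.5)
  expect_equal(rep3$jaccard["p", "q"], 1 / 3)   # {a,b} vs {a,c}
  expect_equal(rep3$jaccard["p", "r"], 0)       # {a,b} vs {c,d}
  expect_equal(rep3$jaccard["q", "r"], 1 / 3)   # {a,c} vs {c,d}
})

test_that("variance-versus-quality pairs are scale-aware but rank-invariant", {
  set.seed(16)
  m <- matrix(runif(60), 10, 6, dimnames = list(sprintf("s%d", 1:10), sprintf("f%d", 1:6)))
  scores <- score_features(tibble::tibble(split = 1, feature = colnames(m),
                                          score = runif(6)), top_k = 3)
  v1 <- variance_vs_quality(m, scores)
  expect_equal(v1$variance, unname(apply(m[, v1$feature], 2, var)))
  v2 <- variance_vs_quality(m * 2, scores)
  expect_equal(v2$variance, 4 * v1$variance)
  expect_equal(attr(v2, "association")$rho, attr(v1, "association")$rho)

  mc <- m; mc[, 1] <- 0.3
  flagged_scores <- score_features(tibble::tibble(split = 1, feature = colnames(m),
                                                  score = c(0, runif(5)),
                                                  flagged = c(TRUE, rep(FALSE, 5))),
                                   top_k = 3)
  vc <- variance_vs_quality(mc, flagged_scores)
  expect_equal(vc$variance[vc$feature == "f1"], 0)
  expect_true(vc$flagged[vc$feature == "f1"])
})

test_that("variance-quality association p-values are calibrated under the null", {
  set.seed(17)
  pvals <- replicate(100, {
    sc <- score_features(tibble::tibble(split = 1, feature = sprintf("f%02d", 1:30),
                                        score = runif(30)), top_k = 5)
    m <- matrix(rnorm(20 * 30, sd = rep(runif(30, 0.5, 2), each = 20)), 20, 30,
                dimnames = list(NULL, sprintf("f%02d", 1:30)))
    attr(variance_vs_quality(m, sc), "association")$p_value
  })
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.05)
})

test_that("enrichment odds ratios and p-values match hypergeometric enumeration", {
  # 2x2 table (8,2 / 10,80): top set of 10, background 100, class of 18
  feats <- sprintf("%d.1.1.%d", c(rep(1, 18), rep(2, 82)), 1:100)
  scores <- score_features(tibble::tibble(
    split = 1, feature = feats,
    score = c(rep(0.9, 8), rep(0.1, 10), rep(0.9, 2), rep(0.1, 80))), top_k = 10)
  res <- ec_class_enrichment(scores, fractions = 0.10)
  row1 <- res[res$class == "1", ]
  expect_equal(row1$in_top, 8)
  expect_equal(row1$odds_ratio, 32)
  # closed-form two-sided Fisher p by hypergeometric enumeration
  probs <- dhyper(0:10, 18, 82, 10)
  p_oracle <- sum(probs[probs <= dhyper(8, 18, 82, 10) * (1 + 1e-7)])
  expect_equal(row1$p_value, p_oracle, tolerance = 1e-10)
})

test_that("uniformly drawn top sets give approximately uniform enrichment p-values", {
  set.seed(18)
  feats <- sprintf("%d.2.3.%d", rep(1:4, each = 25), 1:100)
  pvals <- replicate(200, {
    sc <- score_features(tibble::tibble(split = 1, feature = feats,
                                        score = runif(100)), top_k = 10)
    min(ec_class_enrichment(sc, fractions = 0.25)$p_value)
  })
  # smallest of 4 class tests: conservative, but must not pile up near 0
  expect_gt(mean(pvals > 0.05), 0.5)
})

test_that("the degenerate full-background top set returns the convention values", {
  feats <- sprintf("%d.1.1.%d", rep(1:2, each = 5), 1:10)
  sc <- score_features(tibble::tibble(split = 1, feature = feats,
                                      score = runif(10)), top_k = 5)
  res <- ec_class_enrichment(sc, fractions = 1.0)
  expect_true(all(res$odds_ratio == 1))
  expect_true(all(res$p_value == 1))
})

test_that("model comparison reproduces exact rank-sum enumeration", {
  res <- compare_models(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)    # 2 * 1/choose(6,3)... enumerated exactly
  # oracle by full enumeration of C(6,3) arrangements
  pool <- c(1, 2, 3, 4, 5, 6)
  combos <- combn(6, 3)
  u_obs <- 0
  u_all <- apply(combos, 2, function(idx) {
    a <- pool[idx]; b <- pool[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  p_exact <- mean(u_all <= u_obs) + mean(u_all >= (9 - u_obs))
  expect_equal(res$p_value, p_exact)

  same <- compare_models(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.3, 0.4))
  expect_gt(same$p_value, 0.99)

  a <- runif(10); b <- runif(10)
  expect_equal(compare_models(a, b)$p_value, compare_models(exp(a), exp(b))$p_value)
  expect_error(compare_models(1, 1:3), "at least 2")
})

test_that("correlation-shift densities separate input echo from prediction quality", {
  set.seed(19)
  n <- 40
  truth <- matrix(runif(n * 6), n, 6, dimnames = list(sprintf("s%d", 1:n), sprintf("1.1.1.%d", 1:6)))
  predicted <- truth
  input <- matrix(runif(n * 6), n, 6, dimnames = dimnames(truth))
  res <- correlation_shift_densities(input, predicted, truth)
  expect_equal(res$predicted_vs_truth, rep(1, 6), tolerance = 1e-12)
  expect_lt(max(abs(res$input_vs_truth)), 0.5)   # independent input stays near 0
  expect_lt(attr(res, "test")$p_value, 0.01)

  sub <- correlation_shift_densities(input, predicted, truth,
                                     features = colnames(truth)[1:3])
  expect_true(all(sub$feature %in% res$feature))
  expect_equal(nrow(sub), 3)
  expect_error(correlation_shift_densities(input[, 0], predicted, truth), "no shared")
})
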