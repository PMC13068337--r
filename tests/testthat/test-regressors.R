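test_that("elastic net recovers a noiseless linear map exactly on held-out samples", {
  paired <- noiseless_linear_paired()
  md <- paired$metadata
  plan <- make_splits(md, n_splits = 1)[[1]]
  train <- training_slice(paired, plan, "train")
  test <- training_slice(paired, plan, "test")
  fit <- fit_elastic_net(train)
  pred <- predict(fit, test$input)
  truth <- apply_transform(fit$ft_out, abund_matrix(test$output))
  for (j in colnames(truth)) {
    expect_equal(spearman_cor(pred[[j]], truth[, j]), 1.0, tolerance = 1e-6)
  }
})

test_that("an infinite penalty shrinks every coefficient to zero", {
  paired <- noiseless_linear_paired(n = 40, p = 8, q = 3)
  fit <- fit_elastic_net(paired, lambda_grid = c(1e6, 9e5), nfolds = 5)
  expect_true(all(fit$fits[-1, ] == 0))
  pred <- predict(fit, paired$input)
  expect_true(all(apply(as.matrix(pred[-1]), 2, stats::sd) == 0))
})

test_that("predictions reproduce the linear algebra X beta + intercept", {
  paired <- noiseless_linear_paired(n = 40, p = 8, q = 3)
  fit <- fit_elastic_net(paired)
  ids <- sample_ids(paired$input)[1:3]
  sub <- abund_matrix(paired$input)[ids, , drop = FALSE]
  pred <- predict(fit, sub)
  X <- apply_transform(fit$ft_in, sub)
  manual <- sweep(X %*% fit$fits[-1, , drop = FALSE], 2, fit$fits[1, ], `+`)
  expect_equal(unname(as.matrix(pred[-1])), unname(manual), tolerance = 1e-12)
  expect_equal(pred$sample_id, ids)
})

test_that("predict validates the feature universe", {
  paired <- noiseless_linear_paired(n = 30, p = 6, q = 2)
  fit <- fit_elastic_net(paired)
  m <- abund_matrix(paired$input)
  expect_error(predict(fit, m[, -1]), "missing: g01")
  m2 <- cbind(m, extra = 1)
  expect_error(predict(fit, m2), "unexpected: extra")
})

test_that("regressor fits are invariant to output column order", {
  paired <- noiseless_linear_paired(n = 40, p = 8, q = 4)
  rev_out <- paired
  m <- abund_matrix(paired$output)[, 4:1]
  rev_out$output <- abundance_table(
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                     tibble::as_tibble(as.data.frame(m))), "mBx")
  f1 <- fit_elastic_net(paired)
  f2 <- fit_elastic_net(rev_out)
  expect_equal(f1$fits[, colnames(f2$fits)], f2$fits, tolerance = 1e-10)
})

test_that("elastic net with mixing 1 and vanishing penalty approaches least squares", {
  # well-conditioned (non-compositional) design via identity transforms
  set.seed(21)
  n <- 100; p <- 4
  U <- matrix(runif(n * p, 0.5, 2), n, p,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("g%02d", 1:p)))
  beta <- c(1, 0.5, 0.25, 0.8)
  y <- drop(U %*% beta) + rnorm(n, sd = 0.02)
  md <- tibble::tibble(sample_id = rownames(U), patient_id = rownames(U),
                       diagnosis = "HC", visit = 1)
  out <- matrix(y, n, 1, dimnames = list(rownames(U), "b1"))
  paired <- make_paired(tiny_table(U, "mGx"), tiny_table(out, "mBx"), md)
  ols <- unname(stats::coef(stats::lm(y ~ U)))
  fit <- fit_elastic_net(paired, alpha = 1, lambda_grid = c(1e-5, 1e-6), nfolds = 5,
                         transforms = c(input = "identity", output = "identity"))
  expect_equal(unname(fit$fits[, 1]), ols, tolerance = 0.02)
})

test_that("random forest baseline is deterministic and honours constant outputs", {
  sim <- small_sim(seed = 7)
  paired <- paired_from_sim(sim)
  plan <- make_splits(sim$metadata, n_splits = 1)[[1]]
  train <- training_slice(paired, plan, "train")
  f1 <- fit_random_forest(train, num_trees = 50)
  f2 <- fit_random_forest(train, num_trees = 50)
  test <- training_slice(paired, plan, "test")
  expect_equal(predict(f1, test$input), predict(f2, test$input))

  # constant output feature -> constant prediction, flagged
  const <- train
  m <- abund_matrix(const$output)
  m[, 1] <- 0.5
  const$output <- tiny_table(m, "mBx")
  fc <- fit_random_forest(const, num_trees = 20, transforms = c(input = "clr", output = "identity"))
  expect_true(colnames(m)[1] %in% fc$constant_outputs)
  pr <- predict(fc, test$input)
  expect_true(all(pr[[colnames(m)[1]]] == 0.5))
})

test_that("random forest ranks planted signal features above noise features", {
  sim <- simulate_multiomics(sim_config(
    n_patients = 20, samples_per_patient = 4,
    n_features = c(mGx = 40, mBx = 20),
    sparsity = c(mGx = 0.2, mBx = 0.1),
    n_signal_outputs = 5, signal_support = 3, signal_strength = 10,
    n_class_features = c(mGx = 4, mBx = 4), seed = 8))
  paired <- paired_from_sim(sim)
  plan <- make_splits(sim$metadata, n_splits = 1)[[1]]
  res <- evaluate_split(paired, plan, "random_forest", num_trees = 200)
  sig <- sim$truth$signal_output_ids
  m_sig <- mean(res$scores$score[res$scores$feature %in% sig])
  m_noise <- mean(res$scores$score[!res$scores$feature %in% sig])
  expect_gt(m_sig, m_noise + 0.2)
})

test_that("network augmentation expands the training set as declared", {
  sim <- small_sim(seed = 9)
  paired <- paired_from_sim(sim)
  n <- nrow(paired$input)
  f1 <- fit_mlp(paired, hidden = c(8), epochs = 5, augmentation_factor = 1, seed = 1)
  expect_equal(f1$train_rows, n)
  f3 <- fit_mlp(paired, hidden = c(8), epochs = 5, augmentation_factor = 3, seed = 1)
  expect_equal(f3$train_rows, 3 * n)
  expect_error(fit_mlp(paired, augmentation_factor = 0.5), "augmentation_factor")
})

test_that("network training is deterministic under a fixed seed", {
  sim <- small_sim(seed = 10)
  paired <- paired_from_sim(sim)
  f1 <- fit_mlp(paired, hidden = c(16, 8), epochs = 30, seed = 5)
  f2 <- fit_mlp(paired, hidden = c(16, 8), epochs = 30, seed = 5)
  expect_identical(f1$fits, f2$fits)
  pred <- predict(f1, paired$input)
  expect_identical(pred, predict(f2, paired$input))
  expect_equal(pred$sample_id, sample_ids(paired$input))
})

test_that("a linear network matches the elastic net on the noiseless fixture", {
  paired <- noiseless_linear_paired(n = 80, p = 10, q = 4)
  plan <- make_splits(paired$metadata, n_splits = 1)[[1]]
  en <- evaluate_split(paired, plan, "elastic_net")
  nn <- evaluate_split(paired, plan, "mlp", hidden = integer(0), epochs = 400,
                       lr = 0.05, dropout = 0, validation_fraction = 0,
                       transforms = c(input = "clr", output = "clr"), seed = 2)
  expect_gte(mean(nn$scores$score), mean(en$scores$score) - 0.05)
})

test_that("autoencoder training reduces reconstruction error and stays reproducible", {
  sim <- simulate_multiomics(sim_config(
    n_patients = 10, samples_per_patient = 3,
    n_features = c(mGx = 20, mTx = 10, mBx = 10),
    sparsity = c(mGx = 0.1, mTx = 0.1, mBx = 0),
    n_signal_outputs = 3, signal_support = 3,
    n_class_features = c(mGx = 2, mBx = 2), seed = 12))
  paired <- paired_from_sim(sim)   # concatenated mGx + mTx input
  expect_equal(modality(paired$input), "concat")
  f1 <- fit_autoencoder(paired, latent_dim = 8, lambda = 0, epochs = 150, nfolds = 5, seed = 3)
  rec <- f1$ae$recon_loss
  checkpoints <- rec[seq(10, length(rec), by = 20)]
  expect_true(all(diff(checkpoints) < 0))
  f2 <- fit_autoencoder(paired, latent_dim = 8, lambda = 0, epochs = 150, nfolds = 5, seed = 3)
  expect_identical(f1$fits, f2$fits)
  expect_error(fit_autoencoder(paired, latent_dim = 500), "latent dimension")
  single <- make_paired(sim$tables$mGx, sim$tables$mBx, sim$metadata)
  expect_error(fit_autoencoder(single, latent_dim = 4), "modalities")
})

test_that("autoencoder latents feed the elastic net nearly as well as raw concatenation", {
  paired <- noiseless_linear_paired(n = 80, p = 12, q = 3)
  paired$input <- abundance_table(tibble::as_tibble(as.data.frame(paired$input)),
                                  modality = "concat", scale = "relative")
  plan <- make_splits(paired$metadata, n_splits = 1)[[1]]
  direct <- evaluate_split(paired, plan, "elastic_net")
  latent <- evaluate_split(paired, plan, "autoencoder", latent_dim = 11,
                           lambda = 1, epochs = 600, nfolds = 5, seed = 4)
  expect_gte(mean(latent$scores$score), mean(direct$scores$score) - 0.1)
})

test_that("feature-selection pre-training averages fold scores exactly and ranks all features", {
  sim <- small_sim(seed = 13)
  paired <- paired_from_sim(sim)
  plan <- make_splits(sim$metadata, n_splits = 1)[[1]]
  train <- training_slice(paired, plan, "train")
  sel <- pretrain_feature_selection(train, k_folds = 4, keep_fraction = 1.0,
                                    num_trees = 30, seed = 1)
  expect_setequal(sel$feature, feature_ids(paired$output))
  expect_true(all(sel$selected))
  # averaging oracle: reported mean equals brute-force mean of fold scores
  fold_scores <- attr(sel, "fold_scores")
  expect_equal(sel$mean_score,
               unname(colMeans(fold_scores)[sel$feature]), tolerance = 1e-12)
  # ranking is by descending mean with id tie-break
  expect_true(all(diff(sel$mean_score) <= 1e-15))

  expect_error(pretrain_feature_selection(train, keep_fraction = 0.001),
               "keeps none")
})
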