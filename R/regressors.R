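#' Cross-omics multi-output regressors
#'
#' Four model families predict one omics layer from another on a paired
#' dataset restricted to training samples:
#'
#' * [fit_elastic_net()] — one elastic-net linear model per output feature
#'   (coordinate descent via glmnet), penalty chosen by internal
#'   cross-validation grouped by patient. The strongest model in practice
#'   and the reference predictor for downstream analyses.
#' * [fit_random_forest()] — a random-forest regression baseline, one
#'   forest per output feature under a shared seed (default 42).
#' * [fit_mlp()] — a feed-forward multi-output network with optional
#'   training-set augmentation by Gaussian jitter.
#' * [fit_autoencoder()] — a joint-loss autoencoder over concatenated
#'   multi-omics input; the elastic net is then fitted on frozen latent
#'   features.
#'
#' All fits see only the rows they are given: restrict the paired dataset
#' to training samples first (see [training_slice()]).
#'
#' @name cross_omics_regressors
NULL

# shared preamble: fit input/output transforms on the given (training) rows
prep_xy <- function(paired, transforms) {
  X <- abund_matrix(paired$input)
  Y <- abund_matrix(paired$output)
  ft_in <- fit_transform(X, transforms[["input"]])
  ft_out <- fit_transform(Y, transforms[["output"]])
  list(X = apply_transform(ft_in, X), Y = apply_transform(ft_out, Y),
       ft_in = ft_in, ft_out = ft_out)
}

new_cross_omics_model <- function(kind, paired, prep, fits, extra = list()) {
  structure(c(list(
    kind = kind,
    ft_in = prep$ft_in, ft_out = prep$ft_out,
    input_features = feature_ids(paired$input),
    output_features = colnames(prep$Y),
    combo = paired$combo,
    fits = fits), extra),
    class = "cross_omics_model")
}

#' Restrict a paired dataset to a split plan's training (or test) samples
#' @param paired A `paired_omics`.
#' @param plan A `split_plan`.
#' @param side `"train"` or `"test"`.
#' @return A `paired_omics` restricted to that side's samples.
#' @export
training_slice <- function(paired, plan, side = c("train", "test")) {
  side <- match.arg(side)
  ids <- intersect(sample_ids(paired$input),
                   if (side == "train") plan$train_samples else plan$test_samples)
  slice_paired(paired, ids)
}

# patient-grouped fold ids for glmnet's internal CV
patient_foldid <- function(patient_ids, nfolds, seed) {
  pats <- sort(unique(patient_ids))
  nfolds <- min(nfolds, length(pats))
  set.seed(seed)
  fold_of <- stats::setNames(rep(seq_len(nfolds), length.out = length(pats)),
                             sample(pats))
  list(foldid = as.integer(fold_of[patient_ids]), nfolds = nfolds)
}

#' Per-output-feature elastic net (MelonnPan-style predictor)
#'
#' Fits an independent elastic-net linear model for every output feature on
#' the transformed inputs. The penalty strength is selected per feature by
#' internal cross-validation over `lambda_grid`, with folds grouped by
#' patient so repeated samples never straddle a fold boundary; the mixing
#' parameter `alpha` is fixed. Constant transformed output features get a
#' constant predictor and are flagged.
#'
#' @param paired A `paired_omics` restricted to training samples.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param lambda_grid Penalty grid (default 13 log-spaced points in
#'   `10^[-4, 1]`).
#' @param nfolds Internal CV folds (default 10, grouped by patient).
#' @param transforms Named pair `c(input=, output=)` of transform kinds;
#'   default centered log-ratio for both.
#' @param seed Seed for fold assignment.
#' @return A `cross_omics_model`.
#' @export
fit_elastic_net <- function(paired, alpha = 0.5,
                            lambda_grid = 10^seq(1, -4, length.out = 13),
                            nfolds = 10,
                            transforms = default_transforms("elastic_net"),
                            seed = 0) {
  stopifnot(alpha >= 0, alpha <= 1)
  prep <- prep_xy(paired, transforms)
  fid <- patient_foldid(paired$metadata$patient_id, nfolds, seed)
  q <- ncol(prep$Y)
  coefs <- matrix(0, ncol(prep$X) + 1L, q,
                  dimnames = list(c("(Intercept)", colnames(prep$X)), colnames(prep$Y)))
  lambda_sel <- rep(NA_real_, q)
  constant <- logical(q)
  for (k in seq_len(q)) {
    y <- prep$Y[, k]
    if (stats::sd(y) == 0) {
      constant[k] <- TRUE
      coefs[1, k] <- y[1]
      next
    }
    cvfit <- glmnet::cv.glmnet(prep$X, y, alpha = alpha, lambda = lambda_grid,
                               foldid = fid$foldid, standardize = TRUE)
    lambda_sel[k] <- cvfit$lambda.min
    coefs[, k] <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  }
  new_cross_omics_model("elastic_net", paired, prep, fits = coefs,
                        extra = list(alpha = alpha, lambda = lambda_sel,
                                     constant_outputs = colnames(prep$Y)[constant],
                                     seed = seed))
}

#' Random-forest regression baseline
#'
#' One forest per output feature on the transformed inputs, all built under
#' the same seed (default 42).
#'
#' @inheritParams fit_elastic_net
#' @param num_trees Trees per forest (default 100).
#' @param seed Forest seed.
#' @return A `cross_omics_model`.
#' @export
fit_random_forest <- function(paired, num_trees = 100,
                              transforms = default_transforms("random_forest"),
                              seed = 42) {
  prep <- prep_xy(paired, transforms)
  dx <- as.data.frame(prep$X)
  names(dx) <- paste0("x", seq_len(ncol(dx)))
  q <- ncol(prep$Y)
  constant <- logical(q)
  fits <- vector("list", q)
  for (k in seq_len(q)) {
    y <- prep$Y[, k]
    if (stats::sd(y) == 0) {
      constant[k] <- TRUE
      fits[[k]] <- y[1]
      next
    }
    fits[[k]] <- ranger::ranger(x = dx, y = y, num.trees = num_trees, seed = ranger_seed(seed),
                                num.threads = 1)
  }
  names(fits) <- colnames(prep$Y)
  new_cross_omics_model("random_forest", paired, prep, fits = fits,
                        extra = list(constant_outputs = colnames(prep$Y)[constant],
                                     seed = seed))
}

#' Feed-forward network regressor with optional augmentation
#'
#' A multi-output dense network (default two hidden layers, 512 and 256
#' units, ReLU, dropout 0.1) trained full-batch with Adam on
#' mean-squared-error loss. By default it trains for a fixed number of
#' epochs; setting `validation_fraction > 0` enables early stopping on a
#' patient-level validation slice instead. With many unlearnable output
#' features, early stopping on the total validation loss halts before the
#' learnable outputs are fit, so fixed-epoch training with dropout is the
#' default. When `augmentation_factor = n > 1` the training set is
#' expanded to `n` times its size by adding jittered copies: Gaussian noise
#' in transformed input space with per-feature SD equal to
#' `jitter_sd_scale` times the feature's training SD.
#'
#' @inheritParams fit_elastic_net
#' @param hidden Hidden layer widths; `integer(0)` gives a linear model.
#' @param epochs,lr,dropout,patience Optimizer settings.
#' @param augmentation_factor Final training size as a multiple of the
#'   original (1 = no augmentation).
#' @param jitter_sd_scale Jitter SD as a fraction of each feature's SD.
#' @param validation_fraction Fraction of training patients held out for
#'   early stopping.
#' @param output_features Optional subset of output features to train on
#'   (used after feature-selection pre-training).
#' @return A `cross_omics_model`.
#' @export
fit_mlp <- function(paired, hidden = c(512, 256), epochs = 1000, lr = 5e-3,
                    dropout = 0.1, augmentation_factor = 1, jitter_sd_scale = 0.1,
                    validation_fraction = 0, patience = 30,
                    transforms = default_transforms("mlp"),
                    output_features = NULL, seed = 0) {
  stopifnot(augmentation_factor >= 1)
  if (!is.null(output_features)) {
    missing <- setdiff(output_features, feature_ids(paired$output))
    if (length(missing)) stop("unknown output features: ", paste(missing, collapse = ", "), call. = FALSE)
    paired$output <- rebuild_abund(paired$output,
                                   abund_matrix(paired$output)[, output_features, drop = FALSE],
                                   normalized = FALSE)
  }
  prep <- prep_xy(paired, transforms)
  Y <- prep$Y
  X <- prep$X
  n0 <- nrow(X)
  # validation patients for early stopping
  set.seed(seed + 7L)
  pats <- sort(unique(paired$metadata$patient_id))
  n_val <- floor(validation_fraction * length(pats))
  val_idx <- NULL
  if (n_val >= 1) {
    val_pats <- sample(pats, n_val)
    val_idx <- which(paired$metadata$patient_id %in% val_pats)
  }
  if (augmentation_factor > 1) {
    n_extra <- round((augmentation_factor - 1) * n0)
    sds <- apply(X, 2, stats::sd)
    set.seed(seed + 11L)
    pick <- sample.int(n0, n_extra, replace = TRUE)
    # keep validation rows out of the augmentation pool
    if (length(val_idx)) pick <- sample(setdiff(seq_len(n0), val_idx), n_extra, replace = TRUE)
    jitter <- matrix(stats::rnorm(n_extra * ncol(X)), n_extra) %*% diag(jitter_sd_scale * sds, ncol(X))
    X <- rbind(X, X[pick, , drop = FALSE] + jitter)
    Y <- rbind(Y, Y[pick, , drop = FALSE])
  }
  fit <- nn_train(X, Y, hidden = hidden, epochs = epochs, lr = lr,
                  dropout = dropout, seed = seed, val_idx = val_idx,
                  patience = patience)
  prep$Y <- Y[seq_len(min(nrow(Y), n0)), , drop = FALSE]
  model <- new_cross_omics_model("mlp", paired, prep, fits = fit$params,
                                 extra = list(history = fit$history,
                                              train_rows = nrow(X),
                                              seed = seed))
  model$output_features <- colnames(Y)
  model
}

#' Autoencoder with joint reconstruction/regression loss, then elastic net
#'
#' Encodes the concatenated multi-omics input into a latent space trained
#' with loss `MSE(reconstruction) + lambda * MSE(regression toward the
#' outputs)`; the elastic-net regressor is then fitted on the frozen latent
#' features. Requires a concatenated (multi-modality) input.
#'
#' @inheritParams fit_elastic_net
#' @param latent_dim Latent dimension; must be below the input dimension.
#' @param lambda Weight of the regression term in the joint loss.
#' @param epochs,lr Optimizer settings.
#' @param allow_single_modality Permit a single-modality input (testing).
#' @return A `cross_omics_model`; `$ae$recon_loss` holds the recorded
#'   reconstruction-loss curve.
#' @export
fit_autoencoder <- function(paired, latent_dim = 32, lambda = 1, epochs = 500,
                            lr = 1e-2, alpha = 0.5,
                            lambda_grid = 10^seq(1, -4, length.out = 13),
                            nfolds = 10,
                            transforms = default_transforms("autoencoder"),
                            seed = 0, allow_single_modality = FALSE) {
  if (!allow_single_modality && modality(paired$input) != "concat") {
    stop("autoencoder regressor expects >= 2 concatenated input modalities", call. = FALSE)
  }
  prep <- prep_xy(paired, transforms)
  ae <- ae_train(prep$X, prep$Y, latent_dim = latent_dim, lambda = lambda,
                 epochs = epochs, lr = lr, seed = seed)
  Z <- ae_encode(ae, prep$X)
  colnames(Z) <- paste0("latent_", seq_len(ncol(Z)))
  fid <- patient_foldid(paired$metadata$patient_id, nfolds, seed)
  q <- ncol(prep$Y)
  coefs <- matrix(0, ncol(Z) + 1L, q,
                  dimnames = list(c("(Intercept)", colnames(Z)), colnames(prep$Y)))
  constant <- logical(q)
  for (k in seq_len(q)) {
    y <- prep$Y[, k]
    if (stats::sd(y) == 0) {
      constant[k] <- TRUE
      coefs[1, k] <- y[1]
      next
    }
    cvfit <- glmnet::cv.glmnet(Z, y, alpha = alpha, lambda = lambda_grid,
                               foldid = fid$foldid, standardize = TRUE)
    coefs[, k] <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  }
  new_cross_omics_model("autoencoder", paired, prep, fits = coefs,
                        extra = list(ae = ae, latent_dim = latent_dim,
                                     joint_lambda = lambda,
                                     constant_outputs = colnames(prep$Y)[constant],
                                     seed = seed))
}

#' Predict output features for unseen samples
#'
#' @param object A `cross_omics_model`.
#' @param newdata An `abund_tbl` (or samples x features matrix) whose
#'   feature ids exactly match the model's training input features.
#' @param ... Unused.
#' @return Tibble with `sample_id` and one column per trained output
#'   feature, in the model's output-transform space.
#' @export
predict.cross_omics_model <- function(object, newdata, ...) {
  m <- if (is.matrix(newdata)) newdata else abund_matrix(newdata)
  missing <- setdiff(object$input_features, colnames(m))
  extra <- setdiff(colnames(m), object$input_features)
  if (length(missing) || length(extra)) {
    stop("input features do not match training features",
         if (length(missing)) paste0("; missing: ", paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  m <- m[, object$input_features, drop = FALSE]
  X <- apply_transform(object$ft_in, m)
  pred <- switch(object$kind,
    elastic_net = cbind(1, X) %*% object$fits,
    autoencoder = {
      Z <- ae_encode(object$ae, X)
      cbind(1, Z) %*% object$fits
    },
    random_forest = {
      dx <- as.data.frame(X)
      names(dx) <- paste0("x", seq_len(ncol(dx)))
      vapply(object$fits, function(f) {
        if (is.numeric(f) && length(f) == 1L) rep(f, nrow(dx))
        else stats::predict(f, data = dx, num.threads = 1)$predictions
      }, numeric(nrow(X)))
    },
    mlp = {
      out <- nn_predict_mat(object$fits, X)
      colnames(out) <- object$output_features
      out
    })
  colnames(pred) <- object$output_features
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(as.data.frame(pred), .name_repair = "minimal"))
}

#' @export
print.cross_omics_model <- function(x, ...) {
  cat(sprintf("<cross_omics_model %s> %s: %d -> %d features (%s/%s transforms)\n",
              x$kind, x$combo, length(x$input_features), length(x$output_features),
              x$ft_in$kind, x$ft_out$kind))
  invisible(x)
}

#' Feature-selection pre-training
#'
#' Ranks output features by how predictable they look inside the training
#' partition: `k_folds` patient-level folds, a random-forest regressor per
#' fold, per-feature Spearman correlation on each fold's held-out part,
#' averaged across folds. The top `keep_fraction` of features (descending
#' mean score, ties broken by feature id) is retained for subsequent model
#' training.
#'
#' @param paired A `paired_omics` restricted to training samples.
#' @param k_folds Folds (default 10).
#' @param keep_fraction Fraction of output features to keep.
#' @param num_trees Trees per fold model.
#' @param transforms Transform pairing for the fold models.
#' @param seed Fold-assignment and forest seed.
#' @return Tibble (`feature`, `mean_score`, `rank`, `selected`), ordered by
#'   rank; selected ids in `attr(, "selected")`.
#' @export
pretrain_feature_selection <- function(paired, k_folds = 10, keep_fraction = 0.25,
                                       num_trees = 100,
                                       transforms = default_transforms("random_forest"),
                                       seed = 0) {
  q <- length(feature_ids(paired$output))
  n_keep <- round(keep_fraction * q)
  if (n_keep < 1) {
    stop(sprintf("keep_fraction %.3f of %d features keeps none", keep_fraction, q), call. = FALSE)
  }
  fid <- patient_foldid(paired$metadata$patient_id, k_folds, seed)
  scores <- matrix(NA_real_, fid$nfolds, q,
                   dimnames = list(NULL, feature_ids(paired$output)))
  for (f in seq_len(fid$nfolds)) {
    tr_ids <- paired$metadata$sample_id[fid$foldid != f]
    va_ids <- paired$metadata$sample_id[fid$foldid == f]
    fold_fit <- fit_random_forest(slice_paired(paired, tr_ids),
                                  num_trees = num_trees, transforms = transforms,
                                  seed = seed)
    va <- slice_paired(paired, va_ids)
    pred <- predict(fold_fit, va$input)
    truth <- apply_transform(fold_fit$ft_out, abund_matrix(va$output))
    scores[f, ] <- vapply(colnames(truth), function(j) {
      r <- spearman_cor(pred[[j]], truth[, j])
      if (is.na(r)) 0 else r
    }, numeric(1))
  }
  mean_score <- colMeans(scores)
  ord <- order(-mean_score, names(mean_score))
  res <- tibble::tibble(feature = names(mean_score)[ord],
                        mean_score = unname(mean_score[ord]),
                        rank = seq_along(ord),
                        selected = seq_along(ord) <= n_keep)
  attr(res, "selected") <- res$feature[res$selected]
  attr(res, "fold_scores") <- scores
  res
}

#' Serialize a fitted linear cross-omics model to JSON
#'
#' Stores the coefficient matrix, the fitted input/output transforms, the
#' training feature ids and (for the autoencoder family) the encoder
#' weights, so predictions can be reproduced exactly without the training
#' data. Forest and network models hold structures that do not round-trip
#' through JSON and are rejected.
#'
#' @param model A `cross_omics_model` of kind `elastic_net` or
#'   `autoencoder`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "cross_omics_model"))
  if (!model$kind %in% c("elastic_net", "autoencoder")) {
    stop("only the linear model families serialize to JSON (got ", model$kind, ")",
         call. = FALSE)
  }
  payload <- list(
    kind = model$kind,
    combo = model$combo,
    input_features = model$input_features,
    output_features = model$output_features,
    coefficients = as.data.frame(model$fits),
    coef_rows = rownames(model$fits),
    ft_in = jsonlite::fromJSON(transform_to_json(model$ft_in), simplifyVector = TRUE),
    ft_out = jsonlite::fromJSON(transform_to_json(model$ft_out), simplifyVector = TRUE))
  if (model$kind == "autoencoder") {
    payload$encoder <- list(We = model$ae$params$We, be = model$ae$params$be)
  }
  js <- jsonlite::toJSON(payload, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_to_json
#' @param json JSON string or file produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  fits <- as.matrix(x$coefficients)
  rownames(fits) <- x$coef_rows
  colnames(fits) <- x$output_features
  rebuild_ft <- function(ft) {
    state <- if (is.null(ft$state) || length(ft$state) == 0) NULL else lapply(ft$state, as.numeric)
    structure(list(kind = ft$kind, state = state, features = ft$features),
              class = "fitted_transform")
  }
  model <- structure(list(
    kind = x$kind, combo = x$combo,
    input_features = x$input_features, output_features = x$output_features,
    ft_in = rebuild_ft(x$ft_in), ft_out = rebuild_ft(x$ft_out),
    fits = fits), class = "cross_omics_model")
  if (identical(x$kind, "autoencoder")) {
    model$ae <- list(params = list(We = as.matrix(x$encoder$We),
                                   be = as.numeric(x$encoder$be)))
  }
  model
}
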