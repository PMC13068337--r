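#' Configuration for the paired multi-omics simulator
#'
#' Describes a longitudinal cohort in which samples are nested within
#' patients, every patient carries one diagnosis (UC, CD or HC), abundance
#' tables are compositional and zero-inflated, and a planted sparse linear
#' map in log space ties a subset of output features to the input layer.
#'
#' Defaults describe a cohort of 40 patients with 5 visits each (200
#' samples), a 100-feature gene-family input layer and a 50-feature
#' metabolite-like output layer, 10 signal outputs each driven by 5 input
#' features at signal-to-noise ratio 5, 30% structural zeros in the input
#' layer and 10% in the denser output layer, and a log-scale disease shift
#' of 1.0 on 10 features of each layer (UC and CD versus HC).
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Visits per patient; a single count or a
#'   `c(min, max)` range sampled per patient.
#' @param n_features Named vector, features per modality; the last entry is
#'   the output layer unless `output_modality` says otherwise.
#' @param output_modality Which modality is predicted.
#' @param sparsity Named vector in `[0, 1)`: per-modality fraction of
#'   structural zeros.
#' @param n_signal_outputs Output features with a planted dependency.
#' @param signal_support Nonzero coefficients per signal output.
#' @param signal_strength Ratio of planted-signal variance to noise variance.
#' @param class_proportions Named fractions for UC, CD, HC; must sum to 1.
#' @param n_class_features Named vector: per-modality count of features
#'   carrying the disease shift.
#' @param class_effect_size Additive log-scale shift for UC/CD samples.
#' @param patient_sd SD of the per-(patient, feature) log-scale intercept.
#' @param noise_sd SD of per-sample log-scale noise in the input layer.
#' @param seed Integer seed; one stream per component (labels, intensity,
#'   presence, noise) is derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 40,
                       samples_per_patient = 5,
                       n_features = c(mGx = 100, mBx = 50),
                       output_modality = NULL,
                       sparsity = c(mGx = 0.30, mBx = 0.10),
                       n_signal_outputs = 10,
                       signal_support = 5,
                       signal_strength = 5,
                       class_proportions = c(UC = 0.25, CD = 0.35, HC = 0.40),
                       n_class_features = c(mGx = 10, mBx = 10),
                       class_effect_size = 1.0,
                       patient_sd = 0.5,
                       noise_sd = 1.0,
                       seed = 0) {
  if (is.null(output_modality)) output_modality <- names(n_features)[length(n_features)]
  cfg <- list(n_patients = n_patients, samples_per_patient = samples_per_patient,
              n_features = n_features, output_modality = output_modality,
              sparsity = sparsity, n_signal_outputs = n_signal_outputs,
              signal_support = signal_support, signal_strength = signal_strength,
              class_proportions = class_proportions,
              n_class_features = n_class_features,
              class_effect_size = class_effect_size,
              patient_sd = patient_sd, noise_sd = noise_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 2, length(cfg$n_features) >= 2,
            !is.null(names(cfg$n_features)))
  if (!cfg$output_modality %in% names(cfg$n_features)) {
    stop("output_modality '", cfg$output_modality, "' not in n_features", call. = FALSE)
  }
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (got ", sum(cfg$class_proportions), ")", call. = FALSE)
  }
  if (!all(sort(names(cfg$class_proportions)) == c("CD", "HC", "UC"))) {
    stop("class_proportions must be named UC, CD, HC", call. = FALSE)
  }
  if (any(cfg$sparsity < 0 | cfg$sparsity >= 1)) {
    stop("sparsity must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$n_signal_outputs > cfg$n_features[[cfg$output_modality]]) {
    stop("n_signal_outputs exceeds the number of output features", call. = FALSE)
  }
  for (mod in names(cfg$n_class_features)) {
    if (!mod %in% names(cfg$n_features)) {
      stop("n_class_features names a modality absent from n_features: ", mod, call. = FALSE)
    }
    if (cfg$n_class_features[[mod]] > cfg$n_features[[mod]]) {
      stop("n_class_features exceeds feature count for ", mod, call. = FALSE)
    }
  }
  n_in_total <- sum(cfg$n_features[setdiff(names(cfg$n_features), cfg$output_modality)])
  if (cfg$signal_support > n_in_total) {
    stop("signal_support exceeds the total number of input features", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# independent named substreams derived from one master seed
sim_streams <- function(seed) {
  set.seed(seed)
  s <- sample.int(2147483646L, 4L)
  stats::setNames(as.list(s), c("labels", "intensity", "presence", "noise"))
}

#' Generate a paired multi-omics cohort with known ground truth
#'
#' Input-layer features are log-normal latent intensities with a
#' per-(patient, feature) random intercept, masked by structural zeros to
#' the configured per-feature sparsity, then closed to sum 1 per sample.
#' Each signal output feature is a sparse linear combination of the
#' log-scale input intensities plus Gaussian noise scaled so that
#' signal-to-noise equals `signal_strength`; the remaining outputs are
#' independent noise with the same patient structure. Disease-affected
#' features receive an additive log-scale shift for UC/CD samples.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list: `tables` (named list of `abund_tbl`, one per
#'   modality), `metadata` (see [check_metadata()]), `truth` (planted
#'   coefficients and index sets) and `config`.
#' @export
simulate_multiomics <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  streams <- sim_streams(config$seed)
  out_mod <- config$output_modality
  in_mods <- setdiff(names(config$n_features), out_mod)

  # --- labels stream: cohort layout and diagnoses -------------------------
  set.seed(streams$labels)
  n_pat <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n_pat))
  counts <- largest_remainder(config$class_proportions[c("UC", "CD", "HC")], n_pat)
  diagnoses <- sample(rep(names(counts), counts))
  spp <- config$samples_per_patient
  visits <- if (length(spp) == 2L) sample(spp[1]:spp[2], n_pat, replace = TRUE) else rep(spp, n_pat)
  meta <- tibble::tibble(
    patient_id = rep(patients, visits),
    diagnosis = rep(diagnoses, visits),
    visit = unlist(lapply(visits, seq_len), use.names = FALSE))
  meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
  meta <- meta[c("sample_id", "patient_id", "diagnosis", "visit")]
  n <- nrow(meta)
  pat_idx <- match(meta$patient_id, patients)
  is_ibd <- meta$diagnosis %in% c("UC", "CD")

  feat_ids <- lapply(names(config$n_features), function(mod) {
    sprintf("%s_f%03d", mod, seq_len(config$n_features[[mod]]))
  })
  names(feat_ids) <- names(config$n_features)

  # --- intensity stream: latents, planted map, class feature choice -------
  set.seed(streams$intensity)
  z_in <- list()
  for (mod in in_mods) {
    d <- config$n_features[[mod]]
    mu <- stats::rnorm(d)
    u <- matrix(stats::rnorm(n_pat * d, sd = config$patient_sd), n_pat, d)
    e <- matrix(stats::rnorm(n * d, sd = config$noise_sd), n, d)
    z <- sweep(e + u[pat_idx, , drop = FALSE], 2, mu, `+`)
    colnames(z) <- feat_ids[[mod]]
    z_in[[mod]] <- z
  }
  z_all <- do.call(cbind, z_in)
  d_in <- ncol(z_all)
  d_out <- config$n_features[[out_mod]]

  n_sig <- config$n_signal_outputs
  signal_outputs <- if (n_sig > 0) sort(sample.int(d_out, n_sig)) else integer(0)
  coef <- matrix(0, d_out, d_in, dimnames = list(feat_ids[[out_mod]], colnames(z_all)))
  for (k in signal_outputs) {
    support <- sample.int(d_in, config$signal_support)
    coef[k, support] <- sample(c(-1, 1), config$signal_support, replace = TRUE) *
      stats::runif(config$signal_support, 0.5, 1.5)
  }

  # disease-affected features: input-layer class features are taken from the
  # planted coefficient support (first come, in column order) so that the
  # class signal propagates into predictable outputs; output-layer class
  # features prefer the non-signal outputs, where the shift is not masked by
  # the much larger planted-signal variance nor entangled with the
  # input-mediated class effect
  class_feats <- list()
  for (mod in names(config$n_class_features)) {
    k <- config$n_class_features[[mod]]
    if (k == 0) next
    if (mod == out_mod) {
      pool <- c(setdiff(seq_len(d_out), signal_outputs), signal_outputs)
      class_feats[[mod]] <- feat_ids[[mod]][sort(pool[seq_len(k)])]
    } else {
      offset <- match(paste0(mod, "_f001"), colnames(z_all)) - 1L
      local_cols <- seq_len(config$n_features[[mod]]) + offset
      in_support <- local_cols[colSums(coef[, local_cols, drop = FALSE] != 0) > 0]
      pool <- c(in_support, setdiff(local_cols, in_support))
      class_feats[[mod]] <- feat_ids[[mod]][sort(pool[seq_len(k)] - offset)]
    }
  }

  # apply input-layer class shifts before forming outputs so signal outputs
  # inherit the disease signal through the planted map
  for (mod in in_mods) {
    cf <- intersect(class_feats[[mod]] %||% character(0), colnames(z_in[[mod]]))
    if (length(cf)) {
      z_in[[mod]][is_ibd, cf] <- z_in[[mod]][is_ibd, cf] + config$class_effect_size
      z_all[is_ibd, intersect(cf, colnames(z_all))] <-
        z_all[is_ibd, intersect(cf, colnames(z_all))] + config$class_effect_size
    }
  }

  # --- noise stream: output layer ----------------------------------------
  set.seed(streams$noise)
  lat_var <- config$patient_sd^2 + config$noise_sd^2
  mu_out <- stats::rnorm(d_out)
  u_out <- matrix(stats::rnorm(n_pat * d_out, sd = config$patient_sd), n_pat, d_out)
  e_out <- matrix(stats::rnorm(n * d_out), n, d_out)
  y <- matrix(0, n, d_out, dimnames = list(meta$sample_id, feat_ids[[out_mod]]))
  for (k in seq_len(d_out)) {
    if (k %in% signal_outputs) {
      sig_var <- sum(coef[k, ]^2) * lat_var
      noise_sd_k <- sqrt(sig_var / config$signal_strength)
      y[, k] <- mu_out[k] + drop(z_all %*% coef[k, ]) + noise_sd_k * e_out[, k]
    } else {
      y[, k] <- mu_out[k] + u_out[pat_idx, k] + config$noise_sd * e_out[, k]
    }
  }
  cf_out <- class_feats[[out_mod]] %||% character(0)
  if (length(cf_out)) y[is_ibd, cf_out] <- y[is_ibd, cf_out] + config$class_effect_size

  # --- presence stream: structural zeros, then closure --------------------
  # Planted dependencies are only identifiable on prevalent features: a
  # signal routed through a mostly-absent input cannot be recovered by any
  # method, and zeroed signal outputs corrupt the truth ranks. As in real
  # cohorts, where the predictable core consists of prevalent features,
  # the signal support and signal outputs stay dense and each modality's
  # zero mass is spread over its remaining features (exact per-feature
  # counts, capped at 95% zeros per feature).
  set.seed(streams$presence)
  latents <- c(lapply(z_in, identity), stats::setNames(list(y), out_mod))
  # planted signal and class features stay dense: a dependency routed
  # through a mostly-absent feature, or a class marker mostly zeroed out,
  # would not be the effect the analysis studies
  exempt <- list()
  exempt[[out_mod]] <- union(signal_outputs,
                             match(class_feats[[out_mod]] %||% character(0),
                                   feat_ids[[out_mod]]))
  for (mod in in_mods) {
    cols <- grep(paste0("^", mod, "_"), colnames(z_all))
    exempt[[mod]] <- union(which(colSums(coef[, cols, drop = FALSE] != 0) > 0),
                           match(class_feats[[mod]] %||% character(0),
                                 feat_ids[[mod]]))
  }
  tables <- list()
  feat_sparsity <- list()
  for (mod in names(config$n_features)) {
    s <- config$sparsity[[mod]] %||% 0
    m <- exp(latents[[mod]])
    d <- ncol(m)
    zeros_per_feat <- rep(0L, d)
    if (s > 0) {
      free <- setdiff(seq_len(d), exempt[[mod]])
      if (length(free) == 0L) {
        stop(sprintf("no features left to carry sparsity %.2f in %s", s, mod), call. = FALSE)
      }
      per_feat <- round(s * n * d / length(free))
      cap <- floor(0.95 * n)
      if (per_feat >= n) {
        stop(sprintf(paste0("sparsity %.2f for %s needs %d zeros in each of %d ",
                            "maskable features but samples number only %d"),
                     s, mod, per_feat, length(free), n), call. = FALSE)
      }
      zeros_per_feat[free] <- min(per_feat, cap)
      for (j in free) m[sample.int(n, zeros_per_feat[j]), j] <- 0
      empty <- rowSums(m) == 0
      if (any(empty)) {
        stop(sprintf("sparsity %.2f for %s left %d sample(s) all-zero (e.g. %s); lower it",
                     s, mod, sum(empty), meta$sample_id[which(empty)[1]]), call. = FALSE)
      }
    }
    feat_sparsity[[mod]] <- stats::setNames(zeros_per_feat / n, feat_ids[[mod]])
    rownames(m) <- meta$sample_id
    tables[[mod]] <- abund_from_matrix(m / rowSums(m), modality = mod_tag(mod),
                                       scale = "relative", normalized = TRUE)
  }

  truth <- structure(list(
    coefficients = coef,
    signal_output_ids = feat_ids[[out_mod]][signal_outputs],
    class_feature_ids = class_feats,
    patient_assignments = stats::setNames(diagnoses, patients),
    feature_sparsity = feat_sparsity,
    output_modality = out_mod
  ), class = "synthetic_truth")

  structure(list(tables = tables, metadata = meta, truth = truth, config = config),
            class = "sim_cohort")
}

# integer apportionment of proportions (largest remainder)
largest_remainder <- function(props, total) {
  raw <- props * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

mod_tag <- function(mod) if (mod %in% c("mGx", "mTx", "mPx", "mBx")) mod else "concat"

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d samples / %d patients; modalities: %s (output: %s); %d signal outputs\n",
              nrow(x$metadata), x$config$n_patients,
              paste(names(x$tables), collapse = ", "), x$truth$output_modality,
              length(x$truth$signal_output_ids)))
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' One TSV per modality, a metadata TSV, and a `truth.json` holding the
#' planted coefficients and index sets.
#'
#' @param sim A `sim_cohort` from [simulate_multiomics()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mod in names(sim$tables)) {
    write_abundance(sim$tables[[mod]], file.path(dir, paste0(mod, ".tsv")))
  }
  readr::write_tsv(sim$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  cf <- sim$truth$coefficients
  nz <- which(cf != 0, arr.ind = TRUE)
  truth <- list(
    coefficients = data.frame(output = rownames(cf)[nz[, 1]],
                              input = colnames(cf)[nz[, 2]],
                              beta = cf[nz]),
    signal_output_ids = sim$truth$signal_output_ids,
    class_feature_ids = sim$truth$class_feature_ids,
    patient_assignments = as.list(sim$truth$patient_assignments),
    output_modality = sim$truth$output_modality)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Paired dataset straight from a simulated cohort
#'
#' Convenience wrapper: zero-imputes and re-closes every modality table,
#' then pairs the requested inputs with the cohort's output layer.
#'
#' @param sim A `sim_cohort`.
#' @param inputs Input modality names; default all non-output modalities.
#' @param impute Zero-impute tables before pairing (default TRUE).
#' @return A `paired_omics` object.
#' @export
paired_from_sim <- function(sim, inputs = NULL, impute = TRUE) {
  out_mod <- sim$truth$output_modality
  if (is.null(inputs)) inputs <- setdiff(names(sim$tables), out_mod)
  prep <- function(tbl) if (impute) impute_zeros(tbl) else tbl
  make_paired(lapply(sim$tables[inputs], prep), prep(sim$tables[[out_mod]]),
              sim$metadata)
}
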