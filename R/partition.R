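#' Patient-level, class-stratified train/test split plans
#'
#' Longitudinal cohorts repeat samples within patients, so splitting at the
#' sample level leaks patient identity into the test set. Each plan here
#' groups patients by diagnosis, shuffles each group deterministically under
#' its seed, and assigns roughly `test_fraction` of every class to the test
#' side (ceiling, so no class ever has an empty test set). Sample lists are
#' derived by patient membership.
#'
#' @param metadata Sample metadata (see [check_metadata()]).
#' @param n_splits Number of plans (default 10).
#' @param test_fraction Fraction of patients per class in the test side.
#' @param seeds Integer seeds, one per plan; default `0:(n_splits - 1)`.
#' @return A list of `split_plan` objects, each with `seed`,
#'   `train_patients`, `test_patients`, `train_samples`, `test_samples`.
#' @export
make_splits <- function(metadata, n_splits = 10, test_fraction = 0.2, seeds = NULL) {
  metadata <- check_metadata(metadata)
  if (is.null(seeds)) seeds <- seq_len(n_splits) - 1L
  if (length(seeds) != n_splits) stop("need one seed per split", call. = FALSE)
  pat <- dplyr::distinct(metadata, .data$patient_id, .data$diagnosis)
  small <- pat |> dplyr::count(.data$diagnosis) |> dplyr::filter(.data$n < 2L)
  if (nrow(small)) {
    stop("cannot stratify: classes with < 2 patients: ",
         paste(small$diagnosis, collapse = ", "), call. = FALSE)
  }
  lapply(seeds, function(seed) {
    set.seed(seed)
    test_patients <- character(0)
    for (dx in sort(unique(pat$diagnosis))) {
      ids <- sort(pat$patient_id[pat$diagnosis == dx])
      ids <- sample(ids)
      n_test <- ceiling(test_fraction * length(ids))
      test_patients <- c(test_patients, ids[seq_len(n_test)])
    }
    train_patients <- setdiff(pat$patient_id, test_patients)
    structure(list(
      seed = as.integer(seed),
      train_patients = sort(train_patients),
      test_patients = sort(test_patients),
      train_samples = metadata$sample_id[metadata$patient_id %in% train_patients],
      test_samples = metadata$sample_id[metadata$patient_id %in% test_patients]
    ), class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan seed=%d> %d train / %d test patients (%d / %d samples)\n",
              x$seed, length(x$train_patients), length(x$test_patients),
              length(x$train_samples), length(x$test_samples)))
  invisible(x)
}

#' Inner cross-validation folds over training patients
#'
#' Partitions the training patients of a split plan into `k` folds,
#' stratified by diagnosis, for hyperparameter selection that never sees
#' test patients. Deterministic under the plan's seed.
#'
#' @param plan A `split_plan` from [make_splits()].
#' @param metadata Sample metadata.
#' @param k Number of folds (default 5).
#' @return A list of `k` character vectors of patient ids (pairwise
#'   disjoint, union = training patients).
#' @export
inner_cv_folds <- function(plan, metadata, k = 5) {
  metadata <- check_metadata(metadata)
  pat <- dplyr::distinct(metadata, .data$patient_id, .data$diagnosis) |>
    dplyr::filter(.data$patient_id %in% plan$train_patients)
  low <- pat |> dplyr::count(.data$diagnosis) |> dplyr::filter(.data$n < k)
  if (nrow(low)) {
    stop("cannot build ", k, " stratified folds: ",
         paste(sprintf("%s has %d training patients", low$diagnosis, low$n), collapse = "; "),
         call. = FALSE)
  }
  set.seed(plan$seed + 100003L)
  folds <- rep(list(character(0)), k)
  for (dx in sort(unique(pat$diagnosis))) {
    ids <- sample(sort(pat$patient_id[pat$diagnosis == dx]))
    assign_to <- rep(seq_len(k), length.out = length(ids))
    for (i in seq_along(ids)) {
      folds[[assign_to[i]]] <- c(folds[[assign_to[i]]], ids[i])
    }
  }
  lapply(folds, sort)
}

#' Serialize split plans to JSON
#' @param plans List of `split_plan` objects.
#' @param path Optional output file.
#' @export
splits_to_json <- function(plans, path = NULL) {
  js <- jsonlite::toJSON(lapply(plans, unclass), auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname splits_to_json
#' @param json JSON string or file from [splits_to_json()].
#' @export
splits_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(x, function(p) {
    p$seed <- as.integer(p$seed[[1]])
    p[c("train_patients", "test_patients", "train_samples", "test_samples")] <-
      lapply(p[c("train_patients", "test_patients", "train_samples", "test_samples")],
             function(v) as.character(unlist(v)))
    structure(p, class = "split_plan")
  })
}
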