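#' Total-sum scaling
#'
#' Divides each sample row by its total so rows sum to 1 (closure). Zeros are
#' preserved. Standard first step for compositional microbiome profiles.
#'
#' @param x An `abund_tbl`.
#' @return A relative-scale `abund_tbl` with rows summing to 1.
#' @export
tss_normalize <- function(x) {
  m <- abund_matrix(x)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("all-zero sample rows: ", paste(rownames(m)[rs == 0], collapse = ", "),
         call. = FALSE)
  }
  rebuild_abund(x, m / rs, scale = "relative", normalized = TRUE)
}

#' Impute zeros before log-ratio transformation
#'
#' Relative-abundance tables get a small constant `eps` (default 1e-7, below
#' typical nonzero values) added to every entry; count tables get a
#' pseudocount of 1. Relative tables are re-closed to sum 1 afterwards so the
#' centered log-ratio transform still operates on a composition.
#'
#' @param x An `abund_tbl` with a declared scale.
#' @param eps Constant added to relative abundances.
#' @param pseudocount Constant added to counts.
#' @param renormalize Re-close relative tables after imputation (default TRUE).
#' @return A strictly positive `abund_tbl`.
#' @export
impute_zeros <- function(x, eps = 1e-7, pseudocount = 1, renormalize = TRUE) {
  m <- abund_matrix(x)
  if (abund_scale(x) == "relative") {
    m <- m + eps
    if (renormalize) {
      m <- m / rowSums(m)
      return(rebuild_abund(x, m, scale = "relative", normalized = TRUE))
    }
    return(rebuild_abund(x, m, scale = "relative", normalized = FALSE))
  }
  rebuild_abund(x, m + pseudocount, scale = "count", normalized = FALSE)
}

#' Prevalence/abundance feature filtering
#'
#' Two modes used for sparse microbiome features, applied to a normalized
#' (relative) table:
#'
#' * `lenient`: keep feature j iff the fraction of samples with abundance
#'   >= 5e-5 (0.005%) exceeds 0.10, and the fraction of zeros is <= 0.95.
#' * `strict`: keep j iff the fraction with abundance >= 1e-4 (0.01%)
#'   exceeds 0.10, the fraction of samples with abundance below 1e-6
#'   (0.0001%) does not exceed 0.10, and the fraction of zeros is <= 0.95.
#'
#' "More than 10% of samples" is a strict inequality: a feature at exactly
#' 10% prevalence fails. Lenient always retains a superset of strict.
#'
#' @param x A normalized relative-scale `abund_tbl`.
#' @param mode `"lenient"` or `"strict"`.
#' @param min_abundance Abundance threshold; defaults to 5e-5 (lenient) or
#'   1e-4 (strict).
#' @param prevalence Required fraction of samples at or above
#'   `min_abundance` (strictly exceeded), default 0.10.
#' @param max_zero_fraction Maximum tolerated fraction of zeros, default 0.95.
#' @param strict_low_abundance_cut Strict mode only: drop features whose
#'   abundance is below this value in more than `prevalence` of samples.
#' @return The filtered `abund_tbl`; dropped features and reasons are
#'   attached as a tibble retrievable with [filter_report()].
#' @export
filter_features <- function(x, mode = c("lenient", "strict"),
                            min_abundance = NULL, prevalence = 0.10,
                            max_zero_fraction = 0.95,
                            strict_low_abundance_cut = 1e-6) {
  mode <- match.arg(mode)
  if (abund_scale(x) != "relative") {
    stop("filter_features expects a relative-abundance table; normalize first", call. = FALSE)
  }
  if (is.null(min_abundance)) min_abundance <- if (mode == "strict") 1e-4 else 5e-5
  stopifnot(min_abundance > 0, min_abundance < 1, prevalence > 0, prevalence < 1,
            max_zero_fraction > 0, max_zero_fraction < 1)
  m <- abund_matrix(x)
  n <- nrow(m)
  frac_at <- colMeans(m >= min_abundance)
  frac_zero <- colMeans(m == 0)
  keep <- frac_at > prevalence & frac_zero <= max_zero_fraction
  reason <- dplyr::case_when(
    frac_zero > max_zero_fraction ~ sprintf("%.0f%% zeros", 100 * frac_zero),
    frac_at <= prevalence ~ sprintf("abundance >= %g in only %.0f%% of samples", min_abundance, 100 * frac_at),
    TRUE ~ NA_character_
  )
  if (mode == "strict") {
    frac_low <- colMeans(m < strict_low_abundance_cut)
    low_fail <- frac_low > prevalence
    reason[keep & low_fail] <- sprintf("abundance < %g in %.0f%% of samples",
                                       strict_low_abundance_cut, 100 * frac_low[keep & low_fail])
    keep <- keep & !low_fail
  }
  if (!any(keep)) {
    stop(sprintf("all %d features dropped under %s filtering of %d samples",
                 ncol(m), mode, n), call. = FALSE)
  }
  out <- rebuild_abund(x, m[, keep, drop = FALSE], normalized = FALSE)
  attr(out, "normalized") <- FALSE  # closure broken by dropping columns
  attr(out, "filter_report") <- tibble::tibble(
    feature = colnames(m)[!keep], reason = reason[!keep], mode = mode)
  out
}

#' Report of features dropped by the last [filter_features()] call
#' @param x A filtered `abund_tbl`.
#' @return Tibble with columns `feature`, `reason`, `mode`.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report") %||% tibble::tibble(feature = character(), reason = character(), mode = character())
}

#' Collapse taxon-stratified enzyme features
#'
#' Functional profilers report Enzyme Commission (EC) features both in total
#' and stratified per contributing taxon, as `"EC|taxon"`. Summing the
#' stratified columns per EC id reduces dimensionality and sparsity while
#' conserving each sample's total. Unstratified columns pass through.
#'
#' @param x An `abund_tbl` whose feature ids optionally carry a taxon suffix.
#' @param delim Delimiter between EC id and taxon (default `"|"`).
#' @return An `abund_tbl` with one column per EC id.
#' @export
destratify_ec <- function(x, delim = "|") {
  feats <- feature_ids(x)
  base <- vapply(strsplit(feats, delim, fixed = TRUE), function(p) {
    if (length(p) == 0L || !nzchar(p[1])) stop("unparseable feature id", call. = FALSE)
    p[1]
  }, character(1))
  if (identical(base, feats)) return(x)
  m <- abund_matrix(x)
  groups <- factor(base, levels = unique(base))
  summed <- t(rowsum(t(m), group = groups))
  colnames(summed) <- levels(groups)
  rebuild_abund(x, summed)
}

#' Assemble a paired input/output dataset
#'
#' Restricts one or more input tables and an output table to their common
#' samples (in the order of the first input), column-concatenating multiple
#' inputs with modality-prefixed feature ids so names stay unique.
#'
#' @param inputs An `abund_tbl` or (possibly named) list of them.
#' @param output The output-modality `abund_tbl`.
#' @param metadata Sample metadata (see [check_metadata()]).
#' @return A `paired_omics` object: `$input`, `$output`, `$metadata`, `$combo`.
#' @export
make_paired <- function(inputs, output, metadata) {
  if (inherits(inputs, "abund_tbl")) inputs <- list(inputs)
  metadata <- check_metadata(metadata)
  mods <- vapply(inputs, modality, character(1))
  common <- Reduce(intersect, c(lapply(inputs, sample_ids),
                                list(sample_ids(output), metadata$sample_id)))
  if (length(common) == 0L) {
    counts <- paste(sprintf("%s=%d", c(mods, modality(output), "metadata"),
                            c(vapply(inputs, nrow, integer(1)), nrow(output), nrow(metadata))),
                    collapse = ", ")
    stop("no samples shared across tables (", counts, ")", call. = FALSE)
  }
  common <- sample_ids(inputs[[1]])[sample_ids(inputs[[1]]) %in% common]
  take <- function(tbl) {
    m <- abund_matrix(tbl)[common, , drop = FALSE]
    rebuild_abund(tbl, m)
  }
  in_mats <- lapply(inputs, function(tbl) abund_matrix(tbl)[common, , drop = FALSE])
  if (length(inputs) > 1L) {
    for (i in seq_along(in_mats)) {
      colnames(in_mats[[i]]) <- paste0(mods[i], "_", colnames(in_mats[[i]]))
    }
    in_mat <- do.call(cbind, in_mats)
    input <- abund_from_matrix(in_mat, modality = "concat",
                               scale = abund_scale(inputs[[1]]))
  } else {
    input <- rebuild_abund(inputs[[1]], in_mats[[1]])
  }
  structure(list(
    input = input,
    output = take(output),
    metadata = metadata[match(common, metadata$sample_id), ],
    combo = paste0(paste(mods, collapse = "+"), "->", modality(output))
  ), class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("<paired_omics> %s: %d samples, %d input features, %d output features\n",
              x$combo, nrow(x$input), length(feature_ids(x$input)),
              length(feature_ids(x$output))))
  invisible(x)
}

# restrict a paired dataset to a sample id subset, preserving given order
slice_paired <- function(paired, ids) {
  stopifnot(all(ids %in% sample_ids(paired$input)))
  structure(list(
    input = rebuild_abund(paired$input, abund_matrix(paired$input)[ids, , drop = FALSE]),
    output = rebuild_abund(paired$output, abund_matrix(paired$output)[ids, , drop = FALSE]),
    metadata = paired$metadata[match(ids, paired$metadata$sample_id), ],
    combo = paired$combo
  ), class = "paired_omics")
}
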