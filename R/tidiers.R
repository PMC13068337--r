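#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted cross-omics model
#'
#' For the linear families (elastic net, autoencoder head) returns the
#' nonzero coefficients in long form; for the forest and network families
#' returns the per-output-feature fit summary.
#'
#' @param x A `cross_omics_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cross_omics_model <- function(x, ...) {
  if (x$kind %in% c("elastic_net", "autoencoder")) {
    co <- x$fits
    nz <- which(co != 0, arr.ind = TRUE)
    return(tibble::tibble(
      output_feature = colnames(co)[nz[, 2]],
      term = rownames(co)[nz[, 1]],
      estimate = co[nz]) |>
      dplyr::arrange(.data$output_feature, .data$term))
  }
  tibble::tibble(output_feature = x$output_features,
                 constant = x$output_features %in% (x$constant_outputs %||% character(0)))
}

#' @export
glance.cross_omics_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, combo = x$combo,
                 n_input_features = length(x$input_features),
                 n_output_features = length(x$output_features),
                 input_transform = x$ft_in$kind, output_transform = x$ft_out$kind,
                 n_constant_outputs = length(x$constant_outputs %||% character(0)))
}

#' @export
tidy.feature_scores <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.feature_scores <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(score = s$score, error = s$error, top_k = s$top_k,
                 n_features = nrow(x), n_splits = max(x$n_splits))
}

#' @export
tidy.core_set_report <- function(x, ...) {
  J <- x$jaccard
  tibble::tibble(set_a = rep(rownames(J), each = ncol(J)),
                 set_b = rep(colnames(J), nrow(J)),
                 jaccard = as.numeric(t(J)))
}

#' @export
glance.core_set_report <- function(x, ...) {
  tibble::tibble(n_sets = length(x$sets), top_fraction = x$top_fraction,
                 core_size = length(x$core), union_size = length(x$union),
                 core_fraction = x$core_fraction)
}

#' @export
tidy.ibd_classifier <- function(x, ...) {
  tibble::tibble(parameter = names(x$params), value = as.character(unlist(x$params)))
}

#' @export
glance.ibd_classifier <- function(x, ...) {
  tibble::tibble(cv_balanced_accuracy = x$cv_score,
                 n_features = length(x$feature_names), seed = x$seed)
}

#' @importFrom rlang .data
NULL
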