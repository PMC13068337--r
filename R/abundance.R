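#' Construct an abundance table
#'
#' An abundance table is a tibble with one row per sample: a `sample_id`
#' character column followed by one numeric column per feature. Rows hold
#' relative abundances (unitless, optionally closed to sum 1) or raw counts.
#' The omics layer (`modality`) and measurement scale travel with the table
#' as attributes so downstream steps can pick the right imputation rule.
#'
#' @param df Data frame with a `sample_id` column and numeric feature columns.
#' @param modality One of `"mGx"`, `"mTx"`, `"mPx"`, `"mBx"`, `"concat"`.
#' @param scale `"relative"` or `"count"`.
#' @param normalized Logical; `TRUE` asserts each row sums to 1 (checked).
#' @return A tibble of class `abund_tbl`.
#' @export
abundance_table <- function(df, modality = c("mGx", "mTx", "mPx", "mBx", "concat"),
                            scale = c("relative", "count"), normalized = FALSE) {
  modality <- match.arg(modality)
  scale <- match.arg(scale)
  df <- tibble::as_tibble(df)
  if (!"sample_id" %in% names(df)) {
    stop("abundance table needs a 'sample_id' column", call. = FALSE)
  }
  df <- dplyr::relocate(df, "sample_id")
  df$sample_id <- as.character(df$sample_id)
  feats <- setdiff(names(df), "sample_id")
  if (length(feats) == 0L) stop("abundance table has no feature columns", call. = FALSE)
  bad <- feats[!vapply(df[feats], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric feature columns: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup_s)) stop("duplicated sample ids: ", paste(unique(dup_s), collapse = ", "), call. = FALSE)
  dup_f <- feats[duplicated(feats)]
  if (length(dup_f)) stop("duplicated feature ids: ", paste(unique(dup_f), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[feats])
  if (anyNA(m)) stop("abundance table contains missing values", call. = FALSE)
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', feature '%s'",
                 df$sample_id[ij[1]], feats[ij[2]]), call. = FALSE)
  }
  if (normalized) {
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("table marked normalized but row sums deviate from 1 (max |1 - sum| = ",
           format(max(abs(rs - 1))), ")", call. = FALSE)
    }
  }
  structure(df,
            class = c("abund_tbl", class(tibble::tibble())),
            modality = modality, scale = scale, normalized = normalized)
}

#' @export
feature_ids <- function(x) setdiff(names(x), "sample_id")

#' @export
sample_ids <- function(x) x$sample_id

#' Omics layer tag of an abundance table
#' @param x An `abund_tbl`.
#' @export
modality <- function(x) attr(x, "modality") %||% "concat"

abund_scale <- function(x) attr(x, "scale") %||% "relative"
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Numeric matrix view of an abundance table (samples x features)
#' @param x An `abund_tbl` or compatible data frame.
#' @export
abund_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[feature_ids(x)])
  rownames(m) <- x$sample_id
  m
}

abund_from_matrix <- function(m, modality, scale = "relative", normalized = FALSE) {
  df <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), df)
  abundance_table(df, modality = modality, scale = scale, normalized = normalized)
}

# rebuild an abund_tbl after a value-only change, preserving tags
rebuild_abund <- function(x, m, scale = abund_scale(x), normalized = is_normalized(x)) {
  abund_from_matrix(m, modality = modality(x), scale = scale, normalized = normalized)
}

#' Validate a sample metadata table
#'
#' Metadata carries one row per sample: `sample_id`, `patient_id`,
#' `diagnosis` (one of UC, CD, HC) and an integer `visit` index. Every
#' patient must have a single diagnosis across all of their samples.
#'
#' @param metadata Data frame with the four columns above.
#' @return The validated metadata as a tibble.
#' @export
check_metadata <- function(metadata) {
  metadata <- tibble::as_tibble(metadata)
  need <- c("sample_id", "patient_id", "diagnosis")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"visit" %in% names(metadata)) metadata$visit <- 1L
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$patient_id <- as.character(metadata$patient_id)
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup)) stop("duplicated sample ids in metadata: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(metadata$diagnosis), c("UC", "CD", "HC"))
  if (length(bad)) stop("unknown diagnosis labels: ", paste(bad, collapse = ", "), call. = FALSE)
  conflict <- metadata |>
    dplyr::distinct(.data$patient_id, .data$diagnosis) |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflict)) {
    stop("patients with conflicting diagnoses: ",
         paste(conflict$patient_id, collapse = ", "), call. = FALSE)
  }
  metadata
}

#' Read an abundance table from TSV
#'
#' Expects a header row of feature ids and a first column of sample ids.
#' Files written features-in-rows must be declared via `transposed = TRUE`;
#' orientation is never guessed.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams abundance_table
#' @param transposed If `TRUE` the file stores features in rows.
#' @return An `abund_tbl`.
#' @export
read_abundance <- function(path, modality, scale = "relative", transposed = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         name_repair = "minimal")
  if (ncol(raw) < 2L) stop("expected an id column plus at least one feature column", call. = FALSE)
  names(raw)[1] <- "sample_id"
  if (transposed) {
    ids <- as.character(raw[[1]])
    m <- t(as.matrix(raw[-1]))
    colnames(m) <- ids
    raw <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                            tibble::as_tibble(as.data.frame(m), .name_repair = "minimal"))
  }
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      v <- suppressWarnings(as.numeric(vals[[j]]))
      if (anyNA(v) && !anyNA(vals[[j]])) {
        bad_row <- which(is.na(v))[1]
        stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                     vals[[j]][bad_row], names(vals)[j], bad_row, path), call. = FALSE)
      }
      vals[[j]] <- v
    }
  }
  abundance_table(dplyr::bind_cols(raw[1], vals), modality = modality, scale = scale)
}

#' Write an abundance table to TSV
#' @param x An `abund_tbl`.
#' @param path Output path.
#' @export
write_abundance <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(path)
}
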