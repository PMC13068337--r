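#' Feature transforms for compositional abundance data
#'
#' Transforms are fitted on training samples only and applied to unseen
#' samples with the frozen state:
#'
#' * `clr` — centered log-ratio, `log(x_i / g(x))` with `g` the row geometric
#'   mean; requires strictly positive, closed rows (impute zeros first).
#'   Stateless. Output rows sum to 0.
#' * `arcsin` — `asin(sqrt(x_i))` for proportions in `[0, 1]`; works on
#'   non-imputed data, zeros map to 0. Stateless.
#' * `quantile` — per-feature empirical quantile map to standard-normal
#'   quantiles, learned on the training values with `(rank - 0.5)/n`
#'   plotting positions and linear interpolation for unseen values; test
#'   values outside the training range are clamped to the training min/max.
#' * `identity` — passthrough.
#'
#' @param train Numeric matrix (samples x features) of training values.
#' @param kind One of `"clr"`, `"arcsin"`, `"quantile"`, `"identity"`.
#' @return A `fitted_transform` to use with [apply_transform()].
#' @export
fit_transform <- function(train, kind = c("clr", "arcsin", "quantile", "identity")) {
  kind <- match.arg(kind)
  state <- NULL
  if (kind == "quantile") {
    state <- apply(train, 2, function(v) sort(v), simplify = FALSE)
    const <- vapply(state, function(s) s[length(s)] - s[1] == 0, logical(1))
    if (any(const)) {
      warning("constant training features mapped to zero: ",
              paste(utils::head(names(state)[const], 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(kind = kind, state = state, features = colnames(train)),
            class = "fitted_transform")
}

#' Apply a fitted transform to a matrix of samples
#' @param ft A `fitted_transform` from [fit_transform()].
#' @param m Numeric matrix (samples x features) with the training features.
#' @return Transformed numeric matrix of the same shape.
#' @export
apply_transform <- function(ft, m) {
  stopifnot(inherits(ft, "fitted_transform"))
  if (!is.null(ft$features) && !identical(colnames(m), ft$features)) {
    stop("feature columns do not match the transform's training features", call. = FALSE)
  }
  switch(ft$kind,
    identity = m,
    clr = clr_matrix(m),
    arcsin = arcsin_sqrt_matrix(m),
    quantile = {
      out <- m
      for (j in seq_len(ncol(m))) {
        out[, j] <- quantile_to_normal_one(ft$state[[j]], m[, j])
      }
      out
    })
}

clr_matrix <- function(m) {
  if (any(m <= 0)) {
    ij <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("non-positive entry at row %d, column %d; ",
                        "centered log-ratio needs strictly positive values ",
                        "(run impute_zeros first)"), ij[1], ij[2]), call. = FALSE)
  }
  lg <- log(m)
  sweep(lg, 1, rowMeans(lg))
}

arcsin_sqrt_matrix <- function(m) {
  if (any(m < 0 | m > 1)) {
    stop("arcsin square root needs values in [0, 1]", call. = FALSE)
  }
  asin(sqrt(m))
}

# map new values through the frozen per-feature empirical CDF -> qnorm
quantile_to_normal_one <- function(sorted_train, v) {
  n <- length(sorted_train)
  if (sorted_train[n] - sorted_train[1] == 0) return(rep(0, length(v)))
  pp <- (seq_len(n) - 0.5) / n
  v <- pmin(pmax(v, sorted_train[1]), sorted_train[n])
  # linear interpolation on the training quantile curve; ties collapse to
  # their mean plotting position via approx's ties handling
  p <- stats::approx(x = sorted_train, y = pp, xout = v, ties = mean, rule = 2)$y
  stats::qnorm(pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n)))
}

#' Centered log-ratio transform of a normalized table
#'
#' Convenience wrapper returning a tibble; see [fit_transform()] for the
#' definition. Each output row sums to 0.
#'
#' @param x A strictly positive, normalized `abund_tbl` (or matrix).
#' @return Tibble with `sample_id` and transformed feature columns.
#' @export
clr <- function(x) {
  m <- if (is.matrix(x)) x else abund_matrix(x)
  out <- clr_matrix(m)
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(out) %||% as.character(seq_len(nrow(out)))),
                   tibble::as_tibble(as.data.frame(out), .name_repair = "minimal"))
}

#' Arcsin square root transform of a proportion table
#' @param x A normalized `abund_tbl` (or matrix) with entries in `[0, 1]`.
#' @return Tibble with `sample_id` and transformed feature columns in
#'   `[0, pi/2]`.
#' @export
arcsin_sqrt <- function(x) {
  m <- if (is.matrix(x)) x else abund_matrix(x)
  out <- arcsin_sqrt_matrix(m)
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(out) %||% as.character(seq_len(nrow(out)))),
                   tibble::as_tibble(as.data.frame(out), .name_repair = "minimal"))
}

# default transform pairing per regressor family
default_transforms <- function(kind) {
  switch(kind,
    elastic_net = c(input = "clr", output = "clr"),
    random_forest = c(input = "clr", output = "clr"),
    mlp = c(input = "quantile", output = "quantile"),
    autoencoder = c(input = "clr", output = "clr"),
    c(input = "identity", output = "identity"))
}

#' Serialize a fitted transform to JSON
#' @param ft A `fitted_transform`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @export
transform_to_json <- function(ft, path = NULL) {
  js <- jsonlite::toJSON(list(kind = ft$kind, features = ft$features,
                              state = ft$state), digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname transform_to_json
#' @param json JSON string or file path produced by [transform_to_json()].
#' @export
transform_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  state <- if (is.null(x$state) || length(x$state) == 0) NULL else lapply(x$state, as.numeric)
  structure(list(kind = x$kind, state = state, features = x$features),
            class = "fitted_transform")
}
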