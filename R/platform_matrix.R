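#' Platform matrix container
#'
#' A `platform_matrix` holds one platform's measurements as a samples x
#' features numeric matrix together with an explicit observation mask. The
#' mask (not `NA` scanning) is the single source of truth for missingness:
#' `values` is `NA` exactly where `observed_mask` is `FALSE`.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   `NA` entries are taken as missing when `observed_mask` is not given.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: rownames of `values`).
#' @param feature_ids character vector of unique feature identifiers
#'   (default: colnames of `values`).
#' @param platform single string tagging the platform of origin
#'   (e.g. `"input"`, `"target"`, `"NPC"`, `"Metabolon"`).
#' @param observed_mask logical matrix of the same shape as `values`;
#'   `TRUE` where a value was measured.
#'
#' @return An object of class `platform_matrix`: a list with elements
#'   `values`, `observed_mask`, `sample_ids`, `feature_ids`, `platform`.
#' @export
platform_matrix <- function(values, sample_ids = rownames(values),
                            feature_ids = colnames(values),
                            platform = "unknown", observed_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values))
    stop("id lengths must match matrix dimensions")
  if (is.null(observed_mask)) observed_mask <- !is.na(values)
  observed_mask <- as.matrix(observed_mask)
  if (!identical(dim(observed_mask), dim(values)))
    stop("observed_mask must have the same shape as values")
  if (any(observed_mask & is.na(values)))
    stop("NA value at a position marked observed")
  values[!observed_mask] <- NA_real_
  dimnames(values) <- list(sample_ids, feature_ids)
  dimnames(observed_mask) <- dimnames(values)
  structure(list(values = values, observed_mask = observed_mask,
                 sample_ids = sample_ids, feature_ids = feature_ids,
                 platform = as.character(platform)[1]),
            class = "platform_matrix")
}

#' @export
print.platform_matrix <- function(x, ...) {
  miss <- 1 - mean(x$observed_mask)
  cat(sprintf("platform_matrix '%s': %d samples x %d features (%.1f%% missing)\n",
              x$platform, length(x$sample_ids), length(x$feature_ids),
              100 * miss))
  invisible(x)
}

#' @export
dim.platform_matrix <- function(x) dim(x$values)

#' Subset a platform matrix by samples and/or features
#'
#' @param x a [platform_matrix()].
#' @param samples sample ids (character) or indices to keep; `NULL` keeps all.
#' @param features feature ids (character) or indices to keep; `NULL` keeps all.
#' @return a `platform_matrix` restricted to the requested rows/columns.
#' @export
pm_subset <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "platform_matrix"))
  ri <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  }
  ci <- if (is.null(features)) seq_along(x$feature_ids) else {
    if (is.character(features)) match(features, x$feature_ids) else features
  }
  if (anyNA(ri)) stop("unknown sample id(s)")
  if (anyNA(ci)) stop("unknown feature id(s)")
  platform_matrix(x$values[ri, ci, drop = FALSE],
                  sample_ids = x$sample_ids[ri],
                  feature_ids = x$feature_ids[ci],
                  platform = x$platform,
                  observed_mask = x$observed_mask[ri, ci, drop = FALSE])
}

# values with missing entries replaced by per-feature observed means
# (used only where a complete matrix is required: LOF distances, embedding)
pm_mean_complete <- function(x) {
  v <- x$values
  for (j in seq_len(ncol(v))) {
    nas <- !x$observed_mask[, j]
    if (any(nas)) {
      mu <- mean(v[!nas, j])
      if (!is.finite(mu)) mu <- 0
      v[nas, j] <- mu
    }
  }
  v
}
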