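#' Filter invariant and high-missingness features
#'
#' Removes features that are invariant (zero variance over their observed
#' entries) or whose missingness fraction strictly exceeds
#' `max_missing_frac`. This is the standard metabolomics panel QC (e.g. a
#' 1148-metabolite Metabolon panel reduced to 915 after the 25% rule).
#'
#' @param matrix a [platform_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction (default 0.25).
#' @return list with `matrix` (the filtered [platform_matrix()]) and
#'   `removed` (data.frame: feature_id, reason, missing_frac).
#' @export
filter_features <- function(matrix, max_missing_frac = 0.25) {
  stopifnot(inherits(matrix, "platform_matrix"))
  miss <- 1 - colMeans(matrix$observed_mask)
  vr <- apply(matrix$values, 2, function(x) stats::var(x[!is.na(x)]))
  invariant <- is.na(vr) | vr == 0
  too_missing <- miss > max_missing_frac
  drop <- invariant | too_missing
  reason <- ifelse(invariant & too_missing, "invariant+missing",
                   ifelse(invariant, "invariant", "missing"))
  removed <- data.frame(feature_id = matrix$feature_ids[drop],
                        reason = reason[drop],
                        missing_frac = unname(miss[drop]),
                        stringsAsFactors = FALSE)
  if (all(drop)) stop("all features removed by filtering")
  list(matrix = pm_subset(matrix, features = which(!drop)),
       removed = removed)
}

#' Detect outlier samples with the local outlier factor
#'
#' Computes the local outlier factor (LOF) of every sample over the
#' mean-completed feature matrix and flags samples whose LOF exceeds
#' `threshold`. `n_neighbors = 20` and threshold 1.5 reproduce the cited
#' method's default settings. Ties at the decision boundary are kept
#' (not flagged).
#'
#' @param matrix a [platform_matrix()].
#' @param n_neighbors neighbourhood size k (default 20).
#' @param threshold LOF decision threshold (default 1.5).
#' @return character vector of flagged sample ids (possibly empty), with
#'   the full LOF scores in attribute `"lof"`.
#' @export
detect_outlier_samples <- function(matrix, n_neighbors = 20,
                                   threshold = 1.5) {
  stopifnot(inherits(matrix, "platform_matrix"))
  n <- length(matrix$sample_ids)
  if (n <= n_neighbors)
    stop("n_samples must exceed n_neighbors for LOF")
  x <- pm_mean_complete(matrix)
  lof <- local_outlier_factor(x, k = n_neighbors)
  flagged <- matrix$sample_ids[lof > threshold]
  attr(flagged, "lof") <- stats::setNames(lof, matrix$sample_ids)
  flagged
}

#' Local outlier factor scores
#'
#' Direct implementation of the density-based LOF score: for each point,
#' the ratio of the average local reachability density of its k nearest
#' neighbours to its own. Scores near 1 indicate inliers; scores well
#' above 1 indicate points in regions sparser than their neighbours'.
#' Neighbourhoods include all points tied at the k-distance.
#'
#' @param x numeric matrix, observations in rows.
#' @param k neighbourhood size.
#' @return numeric vector of LOF scores, one per row of `x`.
#' @export
local_outlier_factor <- function(x, k = 20) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be < number of observations")
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  # k-distance and neighbourhood (with ties at the k-distance included)
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    kd <- sort(di, partial = k)[k]
    kdist[i] <- kd
    nbrs[[i]] <- which(di <= kd)
  }
  # reachability distance reach(i <- o) = max(kdist(o), d(i, o))
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    o <- nbrs[[i]]
    reach <- pmax(kdist[o], d[i, o])
    lrd[i] <- 1 / (mean(reach) + 1e-300)
  }
  sapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i])
}

#' Split samples into training / validation / test sets
#'
#' Random permutation by seed, contiguous assignment, with set sizes fixed
#' by floor-then-largest-remainder rounding of `fractions * n` (remainder
#' ties broken in order train, validation, test).
#'
#' @param sample_ids character vector of sample ids.
#' @param fractions length-3 numeric summing to 1 (default `c(0.7, 0.1,
#'   0.2)`).
#' @param seed integer seed.
#' @return An object of class `sample_split`: list with `train_ids`,
#'   `val_ids`, `test_ids`, `fractions`, `seed`.
#' @export
split_samples <- function(sample_ids, fractions = c(0.7, 0.1, 0.2),
                          seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be length 3 and sum to 1")
  n <- length(sample_ids)
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- raw - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    # largest remainders win; ties resolved by set order (train, val, test)
    ord <- order(-rem, seq_along(rem))
    sizes[ord[seq_len(short)]] <- sizes[ord[seq_len(short)]] + 1
  }
  set.seed(seed)
  perm <- sample(sample_ids)
  structure(list(
    train_ids = perm[seq_len(sizes[1])],
    val_ids = perm[sizes[1] + seq_len(sizes[2])],
    test_ids = perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
    fractions = fractions, seed = as.integer(seed)),
    class = "sample_split")
}

#' @export
print.sample_split <- function(x, ...) {
  cat(sprintf("sample_split: %d train / %d val / %d test (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Fit a per-feature scaler on training samples only
#'
#' The primary method (`"minmax"`) maps each feature affinely into
#' [-1, 1] using the training-set minimum and maximum (centre = mid-range,
#' half_range = half the range). The alternative (`"zscore"`) standardises
#' by training mean and SD, then relies on clipping; it exists because the
#' source description of the scaling is ambiguous between the two. Both
#' clip transformed values to [-1, 1], so validation/test values outside
#' the training range saturate.
#'
#' @param matrix a [platform_matrix()].
#' @param train_ids sample ids the scaler may see; statistics use observed
#'   entries of these rows only.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return object of class `scaler_params`: list with `center`,
#'   `half_range` (named per feature), `method`, `clip_bounds`, `fitted_on`.
#' @export
fit_scaler <- function(matrix, train_ids = matrix$sample_ids,
                       method = c("minmax", "zscore")) {
  stopifnot(inherits(matrix, "platform_matrix"))
  method <- match.arg(method)
  tr <- pm_subset(matrix, samples = train_ids)
  center <- numeric(ncol(tr$values))
  half <- numeric(ncol(tr$values))
  for (j in seq_len(ncol(tr$values))) {
    x <- tr$values[, j][tr$observed_mask[, j]]
    if (length(x) == 0) stop("feature with no observed training values: ",
                             tr$feature_ids[j])
    if (method == "minmax") {
      center[j] <- (max(x) + min(x)) / 2
      half[j] <- (max(x) - min(x)) / 2
    } else {
      center[j] <- mean(x)
      half[j] <- stats::sd(x)
    }
    if (!is.finite(half[j]) || half[j] <= 0)
      stop("zero half_range for feature ", tr$feature_ids[j],
           " (should have been filtered)")
  }
  structure(list(center = stats::setNames(center, tr$feature_ids),
                 half_range = stats::setNames(half, tr$feature_ids),
                 method = method, clip_bounds = c(-1, 1),
                 fitted_on = train_ids),
            class = "scaler_params")
}

#' Transform a platform matrix to the scaled [-1, 1] space
#'
#' @param matrix a [platform_matrix()] whose features all appear in
#'   `params`.
#' @param params a [fit_scaler()] result.
#' @return a `platform_matrix` with scaled, clipped values (mask
#'   unchanged).
#' @export
scaler_transform <- function(matrix, params) {
  stopifnot(inherits(matrix, "platform_matrix"),
            inherits(params, "scaler_params"))
  idx <- match(matrix$feature_ids, names(params$center))
  if (anyNA(idx)) stop("feature(s) missing from scaler params")
  v <- sweep(matrix$values, 2, params$center[idx], "-")
  v <- sweep(v, 2, params$half_range[idx], "/")
  v <- pmin(pmax(v, params$clip_bounds[1]), params$clip_bounds[2])
  out <- matrix
  out$values <- v
  dimnames(out$values) <- dimnames(matrix$values)
  out
}

#' Invert the scaler back to original units
#'
#' Exact inverse for values within the clip bounds; clipped values map to
#' the training-range endpoint.
#'
#' @param matrix scaled `platform_matrix` (or a bare numeric matrix with
#'   feature ids as colnames).
#' @param params the [fit_scaler()] result used to scale.
#' @return object of the same type with values in original units.
#' @export
scaler_inverse_transform <- function(matrix, params) {
  stopifnot(inherits(params, "scaler_params"))
  if (inherits(matrix, "platform_matrix")) {
    vals <- matrix$values
    fids <- matrix$feature_ids
  } else {
    vals <- as.matrix(matrix)
    fids <- colnames(vals)
  }
  idx <- match(fids, names(params$center))
  if (anyNA(idx)) stop("feature(s) missing from scaler params")
  v <- sweep(vals, 2, params$half_range[idx], "*")
  v <- sweep(v, 2, params$center[idx], "+")
  if (inherits(matrix, "platform_matrix")) {
    matrix$values <- v
    dimnames(matrix$values) <- list(matrix$sample_ids, matrix$feature_ids)
    matrix
  } else {
    dimnames(v) <- dimnames(vals)
    v
  }
}
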