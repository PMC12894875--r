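#' Embedding parameters for feature clustering
#'
#' The clustering stage embeds features (not samples) into 2-D using their
#' value vectors across shared samples under a cosine-distance geometry.
#' The reference pipeline's parameterisation (cosine metric, 2 components,
#' 35 neighbours, min_dist 0.3) is kept as the interface; the embedding
#' backend is pluggable — any method producing features x 2 coordinates
#' from a cosine-similarity neighbourhood satisfies the contract. The
#' default backend (`method = "knn_mds"`) builds the `n_neighbors`-nearest-
#' neighbour graph under cosine distance, finds its connected components,
#' lays each component out by classical MDS of its internal cosine
#' distances (normalised to unit RMS radius) and places component centres
#' far apart — mirroring how neighbourhood-embedding methods render
#' disconnected manifolds as compact, well-separated islands. With a fully
#' connected graph it reduces to global classical MDS, which is also
#' available directly as `method = "cmds"`. Both backends are
#' deterministic; `min_dist` is carried for interface compatibility only.
#'
#' @param metric distance name; only `"cosine"` is implemented.
#' @param n_components embedding dimension (2).
#' @param n_neighbors neighbourhood size (35).
#' @param min_dist minimum embedded distance parameter (0.3).
#' @param method embedding backend: `"knn_mds"` (default) or `"cmds"`.
#' @param seed integer seed recorded with the embedding.
#' @return object of class `embedding_params`.
#' @export
embedding_params <- function(metric = "cosine", n_components = 2L,
                             n_neighbors = 35L, min_dist = 0.3,
                             method = c("knn_mds", "cmds"), seed = 1L) {
  method <- match.arg(method)
  if (n_components < 2) stop("n_components must be >= 2")
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  if (min_dist < 0) stop("min_dist must be >= 0")
  if (metric != "cosine") stop("only cosine metric is implemented")
  structure(list(metric = metric, n_components = as.integer(n_components),
                 n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist, method = method,
                 seed = as.integer(seed)),
            class = "embedding_params")
}

# pairwise cosine distance between columns of a samples x features matrix
cosine_distance <- function(x) {
  nrm <- sqrt(colSums(x^2))
  nrm[nrm == 0] <- 1
  s <- crossprod(x) / outer(nrm, nrm)
  d <- 1 - s
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Embed features of both platforms jointly into 2-D
#'
#' Stacks the two platforms feature-wise (every feature becomes one point),
#' mean-completes residual missing entries for the embedding only, and
#' embeds under cosine distance.
#'
#' @param input_matrix,target_matrix [platform_matrix()] objects over the
#'   same samples (target may be `NULL` to embed one platform).
#' @param params an [embedding_params()].
#' @param sample_ids optionally restrict to these samples (e.g. training +
#'   validation only, to keep test rows out of model selection).
#' @return numeric matrix (features x 2) with feature ids as rownames.
#' @export
embed_features <- function(input_matrix, target_matrix = NULL,
                           params = embedding_params(),
                           sample_ids = NULL) {
  stopifnot(inherits(input_matrix, "platform_matrix"))
  if (!is.null(sample_ids)) {
    input_matrix <- pm_subset(input_matrix, samples = sample_ids)
    if (!is.null(target_matrix))
      target_matrix <- pm_subset(target_matrix, samples = sample_ids)
  }
  x <- pm_mean_complete(input_matrix)
  if (!is.null(target_matrix)) {
    stopifnot(identical(input_matrix$sample_ids, target_matrix$sample_ids))
    x <- cbind(x, pm_mean_complete(target_matrix))
  }
  if (ncol(x) <= params$n_neighbors)
    stop("fewer features than n_neighbors")
  x <- scale(x, center = TRUE, scale = FALSE)  # cosine of centred profiles
  d <- cosine_distance(x)
  set.seed(params$seed)
  coords <- if (params$method == "knn_mds")
    .knn_component_layout(d, params$n_neighbors, params$n_components)
  else .cmds_pad(d, params$n_components)
  rownames(coords) <- colnames(x)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}

# classical MDS padded with zero columns if the distance geometry is
# lower-dimensional than requested
.cmds_pad <- function(d, k) {
  co <- stats::cmdscale(stats::as.dist(d), k = k)
  if (ncol(co) < k) co <- cbind(co, matrix(0, nrow(co), k - ncol(co)))
  co
}

# kNN-graph component layout: per-component classical MDS islands
.knn_component_layout <- function(d, n_neighbors, k = 2L,
                                  center_radius = 10) {
  n <- ncol(d)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    adj[i, order(d[i, ])[2:(n_neighbors + 1)]] <- TRUE
  adj <- adj | t(adj)
  comp <- integer(n); cc <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cc <- cc + 1L
    q <- i
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      if (comp[v] == 0) {
        comp[v] <- cc
        q <- c(q, which(adj[v, ] & comp == 0))
      }
    }
  }
  if (cc == 1L) return(.cmds_pad(d, k))
  ang <- 2 * pi * seq_len(cc) / cc
  centers <- center_radius * cbind(cos(ang), sin(ang))
  if (k > 2) centers <- cbind(centers, matrix(0, cc, k - 2))
  coords <- matrix(0, n, k)
  for (c0 in seq_len(cc)) {
    idx <- which(comp == c0)
    if (length(idx) == 1) { coords[idx, ] <- centers[c0, ]; next }
    sub <- .cmds_pad(d[idx, idx, drop = FALSE], k)
    sub <- scale(sub, scale = FALSE)
    rms <- sqrt(mean(rowSums(sub^2)))
    if (rms > 0) sub <- sub / rms
    coords[idx, ] <- sweep(sub, 2, centers[c0, ], "+")
  }
  coords
}

# mean silhouette width for a labelled partition given a distance matrix
mean_silhouette <- function(d, labels) {
  n <- length(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { s[i] <- 0; next }
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(ks[ks != labels[i]],
                    function(k) mean(d[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the number of clusters by silhouette with an elbow tie-break
#'
#' For each candidate k, k-means (10 restarts, fixed seed) is run on the
#' 2-D coordinates and the mean silhouette width recorded. The k with the
#' maximal silhouette wins; near-ties (within `tie_tol`) are broken toward
#' the elbow of the within-cluster sum-of-squares curve (largest second
#' difference).
#'
#' @param coords features x 2 coordinate matrix.
#' @param k_range integer vector of candidate k (default 2:10).
#' @param seed integer seed.
#' @param tie_tol silhouette margin treated as a tie (default 0.01).
#' @return chosen k (integer) with attributes `"silhouette_by_k"` and
#'   `"wss_by_k"`.
#' @export
select_k <- function(coords, k_range = 2:10, seed = 1L, tie_tol = 0.01) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n_features - 1]")
  if (all(apply(coords, 2, stats::var) == 0))
    stop("degenerate coordinates: all points identical")
  k_range <- sort(unique(as.integer(k_range)))
  d <- as.matrix(stats::dist(coords))
  sil <- numeric(length(k_range))
  wss <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    set.seed(seed)
    km <- stats::kmeans(coords, centers = k_range[i], nstart = 10,
                        iter.max = 100)
    sil[i] <- mean_silhouette(d, km$cluster)
    wss[i] <- km$tot.withinss
  }
  names(sil) <- names(wss) <- k_range
  best <- which(sil >= max(sil) - tie_tol)
  if (length(best) > 1 && length(k_range) >= 3) {
    # elbow: largest second difference of the WSS curve
    d2 <- rep(-Inf, length(k_range))
    inner <- 2:(length(k_range) - 1)
    d2[inner] <- wss[inner - 1] - 2 * wss[inner] + wss[inner + 1]
    best <- best[which.max(d2[best])]
  } else {
    best <- best[which.max(sil[best])]
  }
  k <- k_range[best]
  attr(k, "silhouette_by_k") <- sil
  attr(k, "wss_by_k") <- wss
  k
}

#' Assign features to k clusters by k-means on the embedded coordinates
#'
#' @param coords features x 2 coordinate matrix (rownames = feature ids).
#' @param k number of clusters (>= 2).
#' @param seed integer seed; at least 10 restarts are used. If a cluster
#'   comes back empty the fit is retried with a new seed (max 5 attempts).
#' @return integer vector of labels in `1:k`, named by feature id.
#' @export
assign_clusters <- function(coords, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  coords <- as.matrix(coords)
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    km <- try(stats::kmeans(coords, centers = k, nstart = 10,
                            iter.max = 100), silent = TRUE)
    if (!inherits(km, "try-error") && length(unique(km$cluster)) == k)
      return(stats::setNames(km$cluster, rownames(coords)))
  }
  stop("k-means produced an empty cluster in 5 attempts")
}

#' Name clusters by their predominant compound class
#'
#' Each cluster is named after the modal `class` among its member features;
#' a cluster whose modal class holds less than `others_threshold` of its
#' members is named `"Others"`. Names are made unique ("Others (2)" etc.)
#' and are invariant to how the integer labels are numbered.
#'
#' @param labels named integer vector from [assign_clusters()].
#' @param feature_metadata data.frame with columns `feature_id`, `class`.
#' @param others_threshold modal-class share below which a cluster is
#'   called "Others" (default 0.5).
#' @return character vector mapping cluster label -> name (names of the
#'   vector are the label values as character).
#' @export
label_clusters <- function(labels, feature_metadata,
                           others_threshold = 0.5) {
  cls <- feature_metadata$class[match(names(labels),
                                      feature_metadata$feature_id)]
  if (anyNA(cls)) stop("features missing from feature_metadata")
  out <- character(0)
  for (lab in sort(unique(labels))) {
    tab <- sort(table(cls[labels == lab]), decreasing = TRUE)
    share <- tab[1] / sum(tab)
    nm <- if (share < others_threshold) "Others" else names(tab)[1]
    out[as.character(lab)] <- nm
  }
  # disambiguate duplicates deterministically
  dup <- duplicated(out)
  if (any(dup)) {
    for (nm in unique(out[dup])) {
      idx <- which(out == nm)
      out[idx[-1]] <- sprintf("%s (%d)", nm, seq_along(idx[-1]) + 1L)
    }
  }
  out
}

#' Full feature-clustering stage
#'
#' Embeds both platforms jointly, selects k, assigns clusters and names
#' them. The embedding is treated as a fixed preprocessing transform
#' (seeded, not refit downstream).
#'
#' @inheritParams embed_features
#' @param feature_metadata metadata with `feature_id` and `class` columns.
#' @param k_range candidate numbers of clusters.
#' @param k fixed number of clusters; if `NULL` (default) chosen by
#'   [select_k()].
#' @param others_threshold see [label_clusters()].
#' @return object of class `cluster_assignment`: list with `feature_ids`,
#'   `coords`, `labels`, `k`, `cluster_names`, `silhouette_by_k`.
#' @export
cluster_features <- function(input_matrix, target_matrix, feature_metadata,
                             params = embedding_params(),
                             sample_ids = NULL, k_range = 2:10, k = NULL,
                             others_threshold = 0.5) {
  coords <- embed_features(input_matrix, target_matrix, params, sample_ids)
  sil <- NULL
  if (is.null(k)) {
    k <- select_k(coords, k_range = k_range, seed = params$seed)
    sil <- attr(k, "silhouette_by_k")
  }
  labels <- assign_clusters(coords, as.integer(k), seed = params$seed)
  nms <- label_clusters(labels, feature_metadata, others_threshold)
  structure(list(feature_ids = rownames(coords), coords = coords,
                 labels = labels, k = as.integer(k), cluster_names = nms,
                 silhouette_by_k = sil),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d features in %d clusters\n",
              length(x$labels), x$k))
  tab <- table(x$cluster_names[as.character(x$labels)])
  for (nm in names(tab)) cat(sprintf("  %-20s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Write a cluster assignment to CSV (+ optional silhouette JSON)
#'
#' @param assignment a `cluster_assignment`.
#' @param file CSV path (feature_id, x, y, cluster, cluster_name).
#' @param silhouette_file optional JSON path for the silhouette curve.
#' @return `file`, invisibly.
#' @export
write_cluster_assignment <- function(assignment, file,
                                     silhouette_file = NULL) {
  df <- data.frame(feature_id = assignment$feature_ids,
                   x = assignment$coords[, 1], y = assignment$coords[, 2],
                   cluster = as.integer(assignment$labels),
                   cluster_name =
                     assignment$cluster_names[as.character(assignment$labels)],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(silhouette_file) && !is.null(assignment$silhouette_by_k))
    jsonlite::write_json(as.list(assignment$silhouette_by_k),
                         silhouette_file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
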