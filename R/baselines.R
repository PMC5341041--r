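#' Ward hierarchical clustering on Pearson correlation distance
#'
#' The conventional comparison method: agglomerative clustering with Ward
#' linkage on d = 1 - Pearson r between protein profiles, cut into `k`
#' clusters.
#'
#' @param features `feature_matrix` or numeric matrix (rows = proteins).
#' @param k number of clusters, 1 <= k <= n.
#' @return a `flat_clustering`: list with `labels` (named integer vector),
#'   `method`, `k`, `mean_silhouette` (euclidean; NA for k = 1 or k = n).
#' @export
hclust_ward <- function(features, k) {
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of proteins")
  if (k < 1) stop("k must be >= 1")
  D <- distance_matrix(X, "correlation")
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(X)
  structure(list(labels = labels, method = "hclust_ward_pearson", k = k,
                 mean_silhouette = .mean_silhouette(labels, X)),
            class = "flat_clustering")
}

# Mean silhouette width on euclidean dissimilarities (the daisy default for
# all-numeric data); undefined for trivial clusterings.
.mean_silhouette <- function(labels, X) {
  k <- length(unique(labels))
  if (k < 2 || k >= nrow(X)) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(X))
  mean(sil[, "sil_width"])
}

#' k-means with silhouette-based selection of k
#'
#' Runs Hartigan-Wong k-means (10 restarts) for every k in `k_range`,
#' scores each clustering by mean silhouette width on euclidean
#' dissimilarities, and returns the clustering with maximal mean silhouette
#' (ties to the smallest k). Deterministic under a fixed seed.
#'
#' @param features `feature_matrix` or numeric matrix.
#' @param k_range integer vector of candidate k, within [2, n - 1].
#' @param max_iter k-means iteration cap.
#' @param seed integer seed.
#' @return a `flat_clustering` with the extra element `silhouette_table`
#'   (data.frame `k`, `mean_silhouette`) for inspection.
#' @export
kmeans_silhouette <- function(features, k_range, max_iter = 500000,
                              seed = 1L) {
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  if (!length(k_range)) stop("k_range must be non-empty")
  n <- nrow(X)
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range must lie within [2, n - 1]")
  if (nrow(unique(X)) == 1)
    stop("degenerate input: all feature rows are identical")
  guard <- .seed_guard(seed)
  on.exit(guard())
  fits <- list(); sils <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fits[[i]] <- stats::kmeans(X, centers = k, iter.max = max_iter,
                               nstart = 10, algorithm = "Hartigan-Wong")
    sils[i] <- .mean_silhouette(fits[[i]]$cluster, X)
  }
  best <- which.max(sils)   # ties: first (smallest) k
  labels <- fits[[best]]$cluster
  names(labels) <- rownames(X)
  structure(list(labels = labels, method = "kmeans_hartigan_wong",
                 k = k_range[best], mean_silhouette = sils[best],
                 silhouette_table = data.frame(k = k_range,
                                               mean_silhouette = sils)),
            class = "flat_clustering")
}

#' @export
print.flat_clustering <- function(x, ...) {
  cat(sprintf("flat_clustering (%s): k = %d, mean silhouette = %s\n",
              x$method, x$k, format(x$mean_silhouette, digits = 3)))
  invisible(x)
}

#' Contingency table between a TNM partition and a flat clustering
#'
#' Cross-tabulates module membership against cluster labels over a shared
#' protein universe and reports, per module, the single cluster with the
#' largest intersection.
#'
#' @param partition_a a `tnm_partition`.
#' @param clustering_b a `flat_clustering` over the same proteins.
#' @return list with `table` (contingency matrix, modules x clusters) and
#'   `max_overlap` (data.frame `tnm`, `best_cluster`, `overlap`).
#' @export
overlap_count <- function(partition_a, clustering_b) {
  stopifnot(inherits(partition_a, "tnm_partition"),
            inherits(clustering_b, "flat_clustering"))
  part_label <- rep(names(partition_a$modules),
                    lengths(partition_a$modules))
  names(part_label) <- unlist(partition_a$modules, use.names = FALSE)
  universe_a <- names(part_label)
  universe_b <- names(clustering_b$labels)
  if (!setequal(universe_a, universe_b))
    stop("partition and clustering cover different protein universes")
  b <- clustering_b$labels[universe_a]
  tab <- table(tnm = part_label, cluster = b)
  mo <- do.call(rbind, lapply(rownames(tab), function(m) {
    row <- tab[m, ]
    data.frame(tnm = m, best_cluster = colnames(tab)[which.max(row)],
               overlap = as.integer(max(row)), stringsAsFactors = FALSE)
  }))
  list(table = tab, max_overlap = mo)
}
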