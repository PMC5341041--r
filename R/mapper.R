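#' Pairwise distance matrix over feature rows
#'
#' Metrics:
#' \describe{
#'   \item{correlation}{d(X, Y) = 1 - Pearson r(X, Y), in [0, 2].}
#'   \item{norm_correlation}{d = 1 - <X', Y'>/(n - 1) with X', Y' mean
#'     centred and unit-variance scaled; identical to the correlation
#'     distance for non-degenerate rows.}
#'   \item{euclidean}{ordinary Euclidean distance (testing aid).}
#' }
#' Zero-variance rows have no defined correlation: they get distance 0 to
#' bit-identical rows and 1 (the uncorrelated value) to everything else.
#'
#' @param features a `feature_matrix` or numeric matrix (rows = points).
#' @param metric one of `"correlation"`, `"norm_correlation"`,
#'   `"euclidean"`.
#' @return symmetric numeric matrix with zero diagonal and attribute
#'   `metric`.
#' @export
distance_matrix <- function(features,
                            metric = c("correlation", "norm_correlation",
                                       "euclidean")) {
  metric <- match.arg(metric)
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  if (nrow(X) < 2) stop("need >= 2 rows to form a distance matrix")
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(X))
  } else {
    if (ncol(X) < 2)
      stop("correlation metrics need >= 2 feature columns")
    if (metric == "correlation") {
      r <- suppressWarnings(stats::cor(t(X)))
    } else {
      # literal norm-correlation: inner product of variance-normalized rows
      mu <- rowMeans(X)
      sdv <- apply(X, 1, stats::sd)
      Xp <- (X - mu) / ifelse(sdv > 0, sdv, 1)
      r <- tcrossprod(Xp) / (ncol(X) - 1)
      r[sdv == 0, ] <- NA; r[, sdv == 0] <- NA
    }
    D <- 1 - r
    if (anyNA(D)) {
      # degenerate (constant) rows: distance 1 unless bit-identical
      na_idx <- which(is.na(D), arr.ind = TRUE)
      same <- vapply(seq_len(nrow(na_idx)), function(i)
        identical(X[na_idx[i, 1], ], X[na_idx[i, 2], ]), logical(1))
      D[na_idx] <- ifelse(same, 0, 1)
    }
    D[D < 0] <- 0; D[D > 2] <- 2
  }
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(X), rownames(X))
  attr(D, "metric") <- metric
  D
}

# Deterministic sign convention: the largest-magnitude entry is positive.
.fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

#' Metric SVD lens (classical multidimensional scaling)
#'
#' The principal and secondary metric-SVD coordinates of the distance
#' matrix: double-centre -D^2/2, take the two leading non-negative
#' eigenpairs, and scale each eigenvector by the square root of its
#' eigenvalue. Signs are fixed so the largest-magnitude loading of each
#' coordinate is positive. Under a Euclidean metric this reproduces the
#' ordinary principal-component scores.
#'
#' @param distances matrix from [distance_matrix()], n >= 3.
#' @return n x 2 matrix (`lens_1`, `lens_2`) with attribute `lens_kind`.
#' @export
metric_svd_lens <- function(distances) {
  n <- nrow(distances)
  if (n < 3) stop("metric SVD lens needs >= 3 points")
  B <- -0.5 * distances^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  e <- eigen(B, symmetric = TRUE)
  coords <- sapply(1:2, function(j) {
    if (j <= length(e$values) && e$values[j] > 1e-12)
      .fix_sign(e$vectors[, j]) * sqrt(e$values[j])
    else rep(0, n)
  })
  dimnames(coords) <- list(rownames(distances), c("lens_1", "lens_2"))
  attr(coords, "lens_kind") <- c("metric_svd_1", "metric_svd_2")
  coords
}

#' Neighborhood lens (kNN-graph spectral embedding)
#'
#' Builds the symmetric k-nearest-neighbour graph (an edge whenever either
#' endpoint lists the other) and embeds each connected component with the
#' eigenvectors of its symmetric normalized Laplacian belonging to the two
#' smallest nonzero eigenvalues. Components are laid out side by side along
#' the first coordinate (each scaled to unit range) so that disconnected
#' groups occupy disjoint lens-1 intervals.
#'
#' @param distances matrix from [distance_matrix()].
#' @param k neighbour count, 1 <= k < n; default `ceiling(sqrt(n))`.
#' @return n x 2 lens matrix with attribute `lens_kind`.
#' @export
neighborhood_lens <- function(distances, k = NULL) {
  n <- nrow(distances)
  if (is.null(k)) k <- ceiling(sqrt(n))
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- distances[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]   # index tie-break: deterministic
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(A, mode = "undirected"))$membership
  coords <- matrix(0, n, 2)
  offset <- 0
  comp_order <- order(-tabulate(comp), sort(unique(comp)))
  for (cid in unique(comp)[comp_order]) {
    idx <- which(comp == cid)
    m <- length(idx)
    if (m >= 2) {
      Ac <- A[idx, idx, drop = FALSE]
      deg <- rowSums(Ac)
      Dm <- 1 / sqrt(deg)
      L <- diag(m) - Dm * Ac * rep(Dm, each = m)
      e <- eigen((L + t(L)) / 2, symmetric = TRUE)
      vals <- rev(e$values)
      vecs <- e$vectors[, rev(seq_len(m)), drop = FALSE]
      nonzero <- which(vals > 1e-8)
      for (j in 1:2) {
        if (j <= length(nonzero))
          coords[idx, j] <- .fix_sign(vecs[, nonzero[j]])
      }
    }
    # normalize lens 1 of this component to [0, 1] and shift clear of others
    rng <- range(coords[idx, 1])
    span <- diff(rng)
    coords[idx, 1] <- if (span > 0) (coords[idx, 1] - rng[1]) / span else 0.5
    coords[idx, 1] <- coords[idx, 1] + offset
    offset <- offset + 2
  }
  coords[abs(coords) < 1e-12] <- 0   # quench eigen sign jitter at zero
  dimnames(coords) <- list(rownames(distances), c("lens_1", "lens_2"))
  attr(coords, "lens_kind") <- c("neighborhood_1", "neighborhood_2")
  attr(coords, "k") <- k
  coords
}

#' Build an overlapping cover over lens space
#'
#' Per lens dimension, `resolution` base intervals are laid over the data
#' range — equal width (`equalized = FALSE`) or at empirical quantiles
#' (`equalized = TRUE`, the "eq." cover) — and each interval is expanded
#' about its centre by the factor `gain`, so adjacent intervals overlap by
#' the fraction 1 - 1/gain. Two-dimensional bins are the cross product of
#' the per-dimension intervals; interval membership is closed on both ends,
#' except that an unexpanded uniform cover (`gain = 1`) uses half-open
#' intervals (last interval closed) so that it partitions the data.
#'
#' @param lenses n x d lens matrix (d = 1 or 2), finite values.
#' @param resolution intervals per lens dimension (>= 1).
#' @param gain overlap multiplier (>= 1).
#' @param equalized quantile-based interval boundaries?
#' @return a `cover_spec`: list with `resolution`, `gain`, `equalized`,
#'   `intervals` (per-dimension data.frames of expanded lo/hi), and `bins`
#'   (non-empty bins, each `list(index, members)` with integer row indices).
#' @export
build_cover <- function(lenses, resolution, gain, equalized = FALSE) {
  lenses <- as.matrix(lenses)
  if (any(!is.finite(lenses))) stop("lens values must be finite")
  if (resolution < 1) stop("resolution must be >= 1")
  if (gain < 1) stop("gain must be >= 1")
  d <- ncol(lenses)
  if (!d %in% 1:2) stop("cover supports 1 or 2 lens dimensions")
  n <- nrow(lenses)

  dims <- lapply(seq_len(d), function(j) {
    x <- lenses[, j]
    br <- if (equalized)
      stats::quantile(x, probs = seq(0, 1, length.out = resolution + 1),
                      names = FALSE, type = 7)
    else seq(min(x), max(x), length.out = resolution + 1)
    lo0 <- br[-(resolution + 1)]; hi0 <- br[-1]
    if (gain == 1) {
      # exact base breakpoints: recomputing them via centre +/- half-width
      # can drop boundary points to rounding
      lo <- lo0; hi <- hi0
    } else {
      ctr <- (lo0 + hi0) / 2; half <- (hi0 - lo0) / 2 * gain
      lo <- ctr - half; hi <- ctr + half
    }
    partition <- (gain == 1 && !equalized)
    member <- matrix(FALSE, resolution, n)
    for (i in seq_len(resolution)) {
      member[i, ] <- if (partition && i < resolution)
        x >= lo[i] & x < hi[i]
      else x >= lo[i] & x <= hi[i]
    }
    list(intervals = data.frame(lo = lo, hi = hi), member = member)
  })

  bins <- list()
  if (d == 1) {
    for (i in seq_len(resolution)) {
      mem <- which(dims[[1]]$member[i, ])
      if (length(mem))
        bins[[length(bins) + 1L]] <- list(index = i, members = mem)
    }
  } else {
    for (i in seq_len(resolution)) for (j in seq_len(resolution)) {
      mem <- which(dims[[1]]$member[i, ] & dims[[2]]$member[j, ])
      if (length(mem))
        bins[[length(bins) + 1L]] <- list(index = c(i, j), members = mem)
    }
  }
  structure(list(resolution = as.integer(resolution), gain = gain,
                 equalized = equalized,
                 intervals = lapply(dims, `[[`, "intervals"),
                 bins = bins),
            class = "cover_spec")
}

#' Cluster one cover bin by single linkage with the histogram heuristic
#'
#' Single-linkage clustering of the bin's points, cut at a scale chosen by
#' a fixed heuristic: the bin's pairwise distances are histogrammed into
#' `n_hist_bins` equal-width bars over [0, `scale_max`]; the dendrogram is
#' cut at the left edge of the first empty bar that follows an occupied
#' bar. With no such gap the bin stays a single cluster.
#'
#' `scale_max` defaults to the largest pairwise distance of the whole
#' dataset, so the candidate cut scales are comparable across bins; a
#' histogram rescaled to each bin's own diameter would be scale-free and
#' shred arbitrarily tight clusters at their internal relative gaps.
#'
#' @param member_points integer indices of the bin's points.
#' @param distances full distance matrix.
#' @param n_hist_bins bars in the distance histogram, default 10.
#' @param scale_max upper edge of the distance histogram; default
#'   `max(distances)`.
#' @return list of integer vectors (clusters), each sorted.
#' @export
cluster_bin <- function(member_points, distances, n_hist_bins = 10,
                        scale_max = NULL) {
  m <- length(member_points)
  if (!m) stop("bin member set must be non-empty")
  if (m == 1) return(list(member_points))
  if (is.null(scale_max)) scale_max <- max(distances)
  sub <- distances[member_points, member_points, drop = FALSE]
  pd <- sub[upper.tri(sub)]
  dmax <- scale_max
  cut_h <- NULL
  if (dmax > 0) {
    breaks <- seq(0, dmax, length.out = n_hist_bins + 1)
    bar <- findInterval(pd, breaks, rightmost.closed = TRUE)
    counts <- tabulate(bar, nbins = n_hist_bins)
    first_filled <- which(counts > 0)[1]
    empties <- which(counts == 0 & seq_len(n_hist_bins) > first_filled)
    if (length(empties)) cut_h <- breaks[empties[1]]
  }
  if (is.null(cut_h)) return(list(sort(member_points)))
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  labels <- stats::cutree(hc, h = cut_h)
  unname(lapply(split(member_points, labels), sort))
}

new_mapper_graph <- function(nodes, members, edges, cover, metric,
                             lens_kinds, protein_ids = NULL) {
  structure(list(nodes = nodes, members = members, edges = edges,
                 cover = cover, metric = metric, lens_kinds = lens_kinds,
                 protein_ids = protein_ids),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("mapper_graph: %d nodes, %d edges", nrow(x$nodes),
              nrow(x$edges)))
  if (!is.null(x$cover) && !is.null(x$cover$resolution))
    cat(sprintf(" (resolution %s, gain %s%s)", x$cover$resolution,
                x$cover$gain,
                if (isTRUE(x$cover$equalized)) " eq." else ""))
  cat("\n")
  invisible(x)
}

#' Convert a Mapper graph to igraph
#'
#' @param graph a `mapper_graph`.
#' @return an [igraph::graph] with the node/edge attributes written by
#'   [write_network()].
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "mapper_graph"))
  vdf <- data.frame(
    name = graph$nodes$node_id,
    member_protein_ids = vapply(graph$members, paste, "", collapse = ","),
    n_members = graph$nodes$n_members,
    mean_lens_1 = graph$nodes$mean_lens_1,
    mean_lens_2 = graph$nodes$mean_lens_2,
    stringsAsFactors = FALSE
  )
  if (!is.null(graph$nodes$tnm_label)) vdf$tnm_label <- graph$nodes$tnm_label
  edf <- graph$edges
  igraph::graph_from_data_frame(
    if (nrow(edf)) edf else data.frame(from = character(0),
                                       to = character(0),
                                       n_shared = integer(0)),
    directed = FALSE, vertices = vdf)
}

#' Build a Mapper graph from a feature matrix
#'
#' The full topological engine: compute the distance matrix, the two lens
#' coordinates, the overlapping cover at the requested resolution and gain,
#' cluster every bin by single linkage with the histogram scale heuristic,
#' make one node per cluster, and connect two nodes whenever their clusters
#' share a data point. Node attributes carry the member proteins, member
#' count and mean lens coordinates (the values used to colour nodes).
#'
#' Inputs with fewer than 3 rows cannot support the spectral lenses and are
#' handled directly: one node per point (two points at distance 0 share one
#' node).
#'
#' @param features `feature_matrix` or numeric matrix (rows = proteins).
#' @param metric metric name, see [distance_matrix()].
#' @param lens `"metric_svd"` or `"neighborhood"`.
#' @param resolution cover intervals per lens dimension.
#' @param gain cover overlap multiplier (>= 1).
#' @param equalized quantile-based cover boundaries?
#' @param k neighbour count for the neighborhood lens (default sqrt(n)).
#' @param n_hist_bins histogram bars for the per-bin scale heuristic.
#' @return a `mapper_graph`; nodes are ordered canonically by their sorted
#'   member ids, so fixed inputs give an identical graph.
#' @export
build_mapper_graph <- function(features,
                               metric = c("correlation", "norm_correlation",
                                          "euclidean"),
                               lens = c("metric_svd", "neighborhood"),
                               resolution = 30, gain = 3, equalized = TRUE,
                               k = NULL, n_hist_bins = 10) {
  metric <- match.arg(metric)
  lens <- match.arg(lens)
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  if (is.null(rownames(X))) rownames(X) <- paste0("p", seq_len(nrow(X)))
  ids <- rownames(X)
  n <- nrow(X)
  lens_kinds <- if (lens == "metric_svd")
    c("metric_svd_1", "metric_svd_2") else c("neighborhood_1", "neighborhood_2")
  cover_info <- list(resolution = as.integer(resolution), gain = gain,
                     equalized = equalized)

  if (n <= 2) {
    if (n == 2 && metric != "euclidean" && ncol(X) >= 2) {
      D <- distance_matrix(X, metric)
    } else if (n == 2) {
      D <- as.matrix(stats::dist(X))
    } else D <- matrix(0, 1, 1)
    clusters <- if (n == 2 && D[1, 2] == 0) list(1:2)
                else as.list(seq_len(n))
    lenses <- matrix(0, n, 2, dimnames = list(ids, c("lens_1", "lens_2")))
    return(.assemble_graph(clusters, lenses, ids, cover_info, metric,
                           lens_kinds))
  }

  D <- distance_matrix(X, metric)
  lenses <- if (lens == "metric_svd") metric_svd_lens(D)
            else neighborhood_lens(D, k)
  cover <- build_cover(lenses, resolution, gain, equalized)
  clusters <- list()
  for (bin in cover$bins)
    clusters <- c(clusters, cluster_bin(bin$members, D, n_hist_bins))
  .assemble_graph(clusters, lenses, ids, cover_info, metric, lens_kinds)
}

# Shared node/edge assembly with canonical node ordering.
.assemble_graph <- function(clusters, lenses, ids, cover_info, metric,
                            lens_kinds) {
  if (length(clusters)) {
    keys <- vapply(clusters, function(cl) paste(cl, collapse = ","), "")
    ord <- order(keys)
    clusters <- clusters[ord]
    keys <- keys[ord]
    # identical clusters arising from overlapping bins collapse to one node
    dedupe <- !duplicated(keys)
    clusters <- clusters[dedupe]
  }
  v <- length(clusters)
  nodes <- data.frame(
    node_id = if (v) paste0("n", seq_len(v)) else character(0),
    n_members = if (v) lengths(clusters) else integer(0),
    mean_lens_1 = if (v) vapply(clusters, function(cl)
      mean(lenses[cl, 1]), 0) else numeric(0),
    mean_lens_2 = if (v) vapply(clusters, function(cl)
      mean(lenses[cl, 2]), 0) else numeric(0),
    stringsAsFactors = FALSE
  )
  members <- lapply(clusters, function(cl) ids[cl])
  names(members) <- nodes$node_id
  edges <- list()
  if (v > 1) {
    for (a in seq_len(v - 1)) for (b in (a + 1):v) {
      shared <- length(intersect(clusters[[a]], clusters[[b]]))
      if (shared >= 1)
        edges[[length(edges) + 1L]] <-
          data.frame(from = nodes$node_id[a], to = nodes$node_id[b],
                     n_shared = shared, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(0), to = character(0),
                           n_shared = integer(0), stringsAsFactors = FALSE)
  new_mapper_graph(nodes, members, edges, cover_info, metric, lens_kinds,
                   protein_ids = ids)
}
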