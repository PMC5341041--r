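test_that("correlation distances match a brute-force Pearson oracle", {
  X <- rbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(3, 2, 1))
  D <- distance_matrix(X, "correlation")
  expect_equal(D["a", "b"], 1 - cor(c(1, 2, 3), c(1, 2, 4)),
               tolerance = 1e-12)
  expect_equal(D["a", "b"], 0.018, tolerance = 1e-2)
  expect_equal(D["a", "c"], 2)              # perfect anti-correlation
  expect_equal(D["a", "a"], 0)              # identity
  expect_equal(D, t(D), tolerance = 1e-12)  # symmetry

  # norm correlation is identical for non-degenerate rows
  Dn <- distance_matrix(X, "norm_correlation")
  expect_equal(unclass(D), unclass(Dn), tolerance = 1e-12,
               ignore_attr = TRUE)

  # constant rows: 0 to identical twin, 1 to everything else
  Xc <- rbind(a = c(1, 1, 1), b = c(1, 1, 1), c = c(5, 5, 5),
              d = c(1, 2, 3))
  Dc <- distance_matrix(Xc, "correlation")
  expect_equal(Dc["a", "b"], 0)
  expect_equal(Dc["a", "c"], 1)
  expect_equal(Dc["a", "d"], 1)

  expect_error(distance_matrix(X[, 1, drop = FALSE], "correlation"),
               "2 feature columns")
})

test_that("metric SVD lens reproduces classical MDS geometry", {
  # collinear points under euclidean metric: lens 1 recovers spacing,
  # lens 2 vanishes
  x <- c(0, 1, 2, 5, 9)
  D <- distance_matrix(cbind(x, 0), "euclidean")
  L <- metric_svd_lens(D)
  expect_equal(as.matrix(dist(L[, 1])), as.matrix(dist(x)),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(unname(L[, 2]), rep(0, 5), tolerance = 1e-9)

  # agreement with the stats::cmdscale oracle up to sign
  set.seed(8)
  Y <- matrix(rnorm(40), 10, 4)
  DY <- distance_matrix(Y, "euclidean")
  LY <- metric_svd_lens(DY)
  ref <- stats::cmdscale(stats::as.dist(DY), k = 2)
  for (j in 1:2)
    expect_equal(abs(unname(LY[, j])), abs(unname(ref[, j])),
                 tolerance = 1e-8)

  # three equidistant points embed as an equilateral triangle
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  L3 <- metric_svd_lens(D3)
  side <- dist(L3)
  expect_lt(max(side) - min(side), 1e-9)

  # duplicated points share lens values
  Xd <- rbind(p = c(1, 2, 3), q = c(1, 2, 3), r = c(9, 1, 4),
              s = c(2, 8, 1))
  Ld <- metric_svd_lens(distance_matrix(Xd, "euclidean"))
  expect_equal(Ld["p", ], Ld["q", ], tolerance = 1e-9)

  expect_error(metric_svd_lens(D3[1:2, 1:2]), ">= 3")
})

test_that("neighborhood lens separates blobs and respects permutations", {
  set.seed(5)
  blob_a <- matrix(rnorm(28, 0, 0.3), 14, 2)
  blob_b <- matrix(rnorm(32, 10, 0.3), 16, 2)
  X <- rbind(blob_a, blob_b)
  rownames(X) <- paste0("p", 1:30)
  D <- distance_matrix(X, "euclidean")
  L <- neighborhood_lens(D, k = 3)
  # all of blob A on one side of blob B's lens-1 range
  a_rng <- range(L[1:14, 1]); b_rng <- range(L[15:30, 1])
  expect_true(a_rng[2] < b_rng[1] || b_rng[2] < a_rng[1])

  # degenerate complete-graph regime still returns finite values
  De <- matrix(1, 6, 6) - diag(6)
  dimnames(De) <- list(paste0("q", 1:6), paste0("q", 1:6))
  Le <- neighborhood_lens(De, k = 5)
  expect_true(all(is.finite(Le)))

  # permutation equivariance (k large enough that each blob is one
  # component with a non-degenerate spectrum)
  L5 <- neighborhood_lens(D, k = 5)
  perm <- sample(30)
  Lp <- neighborhood_lens(D[perm, perm], k = 5)
  expect_equal(unname(Lp), unname(L5[perm, ]), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(neighborhood_lens(D, k = 30), "k must satisfy")
})

test_that("cover construction follows the resolution/gain expansion rule", {
  x <- matrix(0:9, ncol = 1)
  # resolution 2, gain 2: base [0,4.5],[4.5,9] expand about centres to
  # [-2.25,6.75] and [2.25,11.25] -> memberships {0..6} and {3..9}
  cov <- build_cover(x, resolution = 2, gain = 2, equalized = FALSE)
  expect_equal(cov$intervals[[1]]$lo, c(-2.25, 2.25))
  expect_equal(cov$intervals[[1]]$hi, c(6.75, 11.25))
  expect_equal(cov$bins[[1]]$members, 1:7)   # values 0..6
  expect_equal(cov$bins[[2]]$members, 4:10)  # values 3..9

  # resolution 1 is a single bin containing everything
  cov1 <- build_cover(x, 1, 3, FALSE)
  expect_length(cov1$bins, 1)
  expect_equal(cov1$bins[[1]]$members, 1:10)

  # gain 1 uniform: exact partition, max point in the last interval
  for (res in c(2, 3, 5)) {
    covp <- build_cover(x, res, 1, FALSE)
    membership <- integer(10)
    for (b in covp$bins) membership[b$members] <- membership[b$members] + 1L
    expect_equal(membership, rep(1L, 10))
  }
  expect_error(build_cover(matrix(c(1, NA), 2, 1), 2, 1), "finite")
})

test_that("bin clustering cuts at the first distance-histogram gap", {
  # two tight pairs far apart -> 2 clusters
  D <- matrix(5, 4, 4); D[1, 2] <- D[2, 1] <- 0.1
  D[3, 4] <- D[4, 3] <- 0.1; diag(D) <- 0
  dimnames(D) <- list(paste0("p", 1:4), paste0("p", 1:4))
  cl <- cluster_bin(1:4, D)
  expect_equal(cl[order(vapply(cl, min, 1L))], list(c(1L, 2L), c(3L, 4L)))

  # all pairwise distances equal -> single cluster
  De <- matrix(1, 4, 4); diag(De) <- 0
  expect_equal(cluster_bin(1:4, De), list(1:4))

  # singleton bin
  expect_equal(cluster_bin(3L, D), list(3L))

  # subset of a larger matrix: tight triple stays together even though
  # its internal distances have relative gaps (global scale anchor)
  Dg <- matrix(1.5, 6, 6); diag(Dg) <- 0
  Dg[1:3, 1:3] <- 0.01 * matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3)
  cl2 <- cluster_bin(1:3, Dg)
  expect_equal(cl2, list(1:3))
})

test_that("mapper graph separates anti-correlated groups into pure components", {
  X <- anticorrelated_features(20, 6, noise = 0.05, seed = 2)
  g <- build_mapper_graph(X, metric = "correlation", lens = "metric_svd",
                          resolution = 4, gain = 2.5, equalized = FALSE)
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  expect_equal(comp$no, 2)
  for (cid in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == cid]
    members <- unique(unlist(g$members[nodes]))
    groups <- unique(substr(members, 1, 1))
    expect_length(groups, 1)   # component pure in profile group
  }
})

test_that("mapper graph on a noisy circle has cycle rank >= 1", {
  X <- noisy_circle(100, noise = 0.05, seed = 6)
  g <- build_mapper_graph(X, metric = "euclidean", lens = "metric_svd",
                          resolution = 8, gain = 3, equalized = FALSE)
  ig <- as_igraph(g)
  cycle_rank <- igraph::ecount(ig) - igraph::vcount(ig) +
    igraph::components(ig)$no
  expect_equal(igraph::components(ig)$no, 1)
  expect_gte(cycle_rank, 1)
})

test_that("mapper invariants hold over random instances", {
  set.seed(123)
  for (i in 1:40) {
    n <- sample(5:25, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    rownames(X) <- paste0("p", seq_len(n))
    res <- sample(2:6, 1); gain <- runif(1, 1, 3)
    eq <- sample(c(TRUE, FALSE), 1)
    g <- build_mapper_graph(X, metric = "euclidean", lens = "metric_svd",
                            resolution = res, gain = gain, equalized = eq)
    # coverage: every point in >= 1 node
    expect_setequal(unique(unlist(g$members)), rownames(X))
    # edge oracle: edge iff member intersection, n_shared correct
    v <- nrow(g$nodes)
    if (v > 1) {
      key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
      have <- setNames(g$edges$n_shared,
                       mapply(key, g$edges$from, g$edges$to))
      for (a in seq_len(v - 1)) for (b in (a + 1):v) {
        shared <- length(intersect(g$members[[a]], g$members[[b]]))
        k <- key(g$nodes$node_id[a], g$nodes$node_id[b])
        if (shared >= 1) expect_equal(unname(have[k]), shared)
        else expect_false(k %in% names(have))
      }
    }
  }
})

test_that("gain-1 single-lens covers yield partitions with no edges", {
  set.seed(77)
  X <- matrix(rnorm(60), 20, 3)
  rownames(X) <- paste0("p", 1:20)
  D <- distance_matrix(X, "euclidean")
  L <- metric_svd_lens(D)[, 1, drop = FALSE]
  cov <- build_cover(L, resolution = 4, gain = 1, equalized = FALSE)
  clusters <- list()
  for (bin in cov$bins)
    clusters <- c(clusters, cluster_bin(bin$members, D))
  # partition: each point in exactly one cluster
  expect_equal(sort(unlist(clusters)), 1:20)
  # therefore no shared points between any two clusters
  for (a in seq_along(clusters)) for (b in seq_along(clusters))
    if (a < b)
      expect_length(intersect(clusters[[a]], clusters[[b]]), 0)
})

test_that("resolution-1 graphs reduce to global single-linkage clustering", {
  X <- anticorrelated_features(8, 6, seed = 4)
  g <- build_mapper_graph(X, metric = "correlation", lens = "metric_svd",
                          resolution = 1, gain = 3, equalized = FALSE)
  all_members <- unlist(g$members)
  expect_equal(sort(unname(all_members)), sort(rownames(X)))
  expect_equal(anyDuplicated(all_members), 0L)  # nodes partition the data
})

test_that("mapper graphs are deterministic and handle tiny inputs", {
  X <- anticorrelated_features(10, 6, seed = 9)
  g1 <- build_mapper_graph(X, resolution = 5, gain = 2, equalized = TRUE)
  g2 <- build_mapper_graph(X, resolution = 5, gain = 2, equalized = TRUE)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$members, g2$members)
  expect_identical(g1$edges, g2$edges)

  g0 <- build_mapper_graph(matrix(c(1, 2, 3), 1, 3,
                                  dimnames = list("solo", NULL)),
                           resolution = 10, gain = 3)
  expect_equal(nrow(g0$nodes), 1)
  expect_equal(nrow(g0$edges), 0)
  expect_equal(g0$members[[1]], "solo")
})
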