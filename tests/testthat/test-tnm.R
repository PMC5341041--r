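make_graph <- function(members, edges = NULL) {
  v <- length(members)
  ids <- if (v) paste0("n", seq_len(v)) else character(0)
  if (v) names(members) <- ids
  nodes <- data.frame(node_id = ids,
                      n_members = if (v) lengths(members) else integer(0),
                      mean_lens_1 = numeric(v), mean_lens_2 = numeric(v),
                      stringsAsFactors = FALSE)
  if (is.null(edges)) {
    # derive edges from member intersections (the mapper invariant)
    e <- list()
    if (v > 1)
      for (a in seq_len(v - 1)) for (b in (a + 1):v) {
        s <- length(intersect(members[[a]], members[[b]]))
        if (s) e[[length(e) + 1]] <- data.frame(
          from = ids[a], to = ids[b], n_shared = s,
          stringsAsFactors = FALSE)
      }
    edges <- if (length(e)) do.call(rbind, e)
             else data.frame(from = character(0), to = character(0),
                             n_shared = integer(0), stringsAsFactors = FALSE)
  }
  tnmapper:::new_mapper_graph(
    nodes, members, edges,
    cover = list(resolution = 45L, gain = 3, equalized = FALSE),
    metric = "correlation",
    lens_kinds = c("metric_svd_1", "metric_svd_2"),
    protein_ids = sort(unique(unlist(members))))
}

test_that("TNM extraction follows component size and multiplicity rules", {
  # chains of overlapping nodes -> two TNMs; isolated singleton proteins
  # pool into "disconnected"
  g <- make_graph(list(
    c("A1", "A2"), c("A2", "A3"), c("A3", "A4"),        # component 1
    c("B1", "B2"), c("B2", "B3"),                        # component 2
    "X1", "Y1"))                                         # singletons
  part <- extract_tnms(g)
  expect_equal(names(part$modules), c("TNM 1", "TNM 2", "disconnected"))
  expect_equal(part$modules[["TNM 1"]], c("A1", "A2", "A3", "A4"))
  expect_equal(part$modules[["TNM 2"]], c("B1", "B2", "B3"))
  expect_setequal(part$modules$disconnected, c("X1", "Y1"))

  # protein in nodes of two components goes to higher node multiplicity
  g2 <- make_graph(list(c("A1", "S"), c("A1", "A2", "S"), c("A2", "S"),
                        c("B1", "S"), c("B1", "B2")))
  part2 <- extract_tnms(g2)
  in_tnm <- names(part2$modules)[vapply(part2$modules,
                                        function(m) "S" %in% m, TRUE)]
  big <- names(part2$modules)[vapply(part2$modules,
                                     function(m) "A1" %in% m, TRUE)]
  expect_equal(in_tnm, big)   # S occurs in 3 nodes of A's component

  # fully connected graph -> one TNM, empty disconnected module
  g3 <- make_graph(list(c("A", "B"), c("B", "C")))
  part3 <- extract_tnms(g3)
  expect_length(part3$modules, 2)
  expect_equal(part3$modules$disconnected, character(0))

  # empty graph -> empty partition
  g4 <- make_graph(list())
  part4 <- extract_tnms(g4)
  expect_equal(part4$modules, list(disconnected = character(0)))
})

test_that("isolated single-node clusters with several proteins are modules", {
  g <- make_graph(list(c("M1", "M2", "M3"), "X1"))
  part <- extract_tnms(g)
  expect_equal(part$modules[["TNM 1"]], c("M1", "M2", "M3"))
  expect_setequal(part$modules$disconnected, "X1")
  # threshold exposed: demand 2-node components only
  part2 <- extract_tnms(g, min_singleton_proteins = 5)
  expect_length(part2$modules, 1)  # everything disconnected
})

test_that("partition completeness holds on pipeline-built graphs", {
  sim <- simulate_deletion_network(simulation_config(seed = 3))
  tab <- differential_table(sim$counts,
                            make_contrasts(sim$counts, "deletion"))
  fm <- depletion_filter(tab)
  g <- build_mapper_graph(fm, resolution = 45, gain = 3, equalized = FALSE)
  part <- extract_tnms(g)
  assigned <- unlist(part$modules)
  expect_setequal(assigned, rownames(fm$values))
  expect_equal(anyDuplicated(assigned), 0L)
  # ordering: non-increasing protein counts among TNMs
  sizes <- lengths(part$modules[names(part$modules) != "disconnected"])
  expect_true(all(diff(sizes) <= 0))
})

test_that("superposition highlights the right base nodes and adjacency", {
  base <- make_graph(list(c("A1", "A2"), c("A2", "B1"), c("B1", "B2"),
                          c("C1", "C2")))
  part <- structure(list(modules = list(
    "TNM 1" = c("A1", "A2"), "TNM 2" = c("B1", "B2"),
    "TNM 3" = c("C1", "C2"), disconnected = character(0)),
    params = NULL), class = "tnm_partition")
  sup <- superimpose(base, part)
  expect_setequal(sup$highlight[["TNM 1"]], c("n1", "n2"))
  expect_setequal(sup$highlight[["TNM 3"]], "n4")
  pairs <- paste(sup$adjacency$tnm_a, sup$adjacency$tnm_b)
  expect_true("TNM 1 TNM 2" %in% pairs)   # share node n2 / edge
  expect_false(any(grepl("TNM 3", pairs)))  # C is isolated
  # full-universe partition highlights every base node
  part_all <- structure(list(modules = list(
    "TNM 1" = c("A1", "A2", "B1", "B2", "C1", "C2"),
    disconnected = character(0)), params = NULL),
    class = "tnm_partition")
  expect_setequal(superimpose(base, part_all)$highlight[["TNM 1"]],
                  base$nodes$node_id)
  # unknown protein is reported by name
  part_bad <- structure(list(modules = list("TNM 1" = "ZZZ",
                                            disconnected = character(0)),
                             params = NULL), class = "tnm_partition")
  expect_error(superimpose(base, part_bad), "ZZZ")
})

test_that("summary ARI agrees with a brute-force oracle", {
  part <- structure(list(modules = list(
    "TNM 1" = c("A1", "A2", "A3"), "TNM 2" = c("B1", "B2"),
    disconnected = character(0)), params = NULL), class = "tnm_partition")
  truth <- list(labels = c(A1 = "M1", A2 = "M1", A3 = "M1",
                           B1 = "M2", B2 = "M2"))
  s <- tnm_summary(part, truth)
  expect_equal(s$ari, 1)

  # split module: ARI < 1, matches definitional oracle, purity reported
  part2 <- structure(list(modules = list(
    "TNM 1" = c("A1", "A2"), "TNM 2" = c("B1", "B2"),
    "TNM 3" = "A3", disconnected = character(0)), params = NULL),
    class = "tnm_partition")
  s2 <- tnm_summary(part2, truth)
  lab <- rep(names(part2$modules), lengths(part2$modules))
  names(lab) <- unlist(part2$modules)
  expect_equal(s2$ari,
               brute_force_ari(lab[names(truth$labels)], truth$labels),
               tolerance = 1e-12)
  expect_lt(s2$ari, 1)
  m1 <- s2$purity[s2$purity$true_label == "M1", ]
  expect_equal(m1$overlap, 2L)
  expect_equal(m1$purity, 2 / 3)

  # random labels have ARI near zero
  set.seed(10)
  aris <- replicate(20, {
    ids <- paste0("p", 1:60)
    mods <- split(ids, sample(rep(1:4, 15)))
    names(mods) <- paste("TNM", 1:4)
    p <- structure(list(modules = c(mods,
                                    list(disconnected = character(0))),
                        params = NULL), class = "tnm_partition")
    tr <- list(labels = setNames(sample(rep(paste0("M", 1:4), 15)), ids))
    tnm_summary(p, tr)$ari
  })
  expect_lt(abs(mean(aris)), 0.1)
})

test_that("interaction overlap counts deduplicated within-module pairs", {
  part <- structure(list(modules = list(
    "TNM 1" = c("A", "B", "C"), disconnected = character(0)),
    params = NULL), class = "tnm_partition")
  edges <- rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                 c("B", "A"),       # duplicate in reverse orientation
                 c("A", "A"))       # self pair
  n <- biogrid_overlap(part, edges)
  expect_equal(unname(n[["TNM 1"]]), 2L)
  expect_equal(unname(biogrid_overlap(part, edges[0, ])[["TNM 1"]]), 0L)
})
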