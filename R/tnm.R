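#' Extract topological network modules from a fragmented Mapper graph
#'
#' TNMs are the connected components of the graph built at the higher
#' (fragmenting) resolution. Components with at least `min_component_nodes`
#' nodes become modules; their protein sets are the unions of their nodes'
#' member sets. Because Mapper clusters overlap, a protein can occur in
#' nodes of several components: it is assigned to the component in which it
#' occurs in more nodes, ties going to the component with more nodes (then
#' to the first in canonical node order). Proteins claimed by no qualifying
#' component are pooled into a final `"disconnected"` module. Modules are
#' ordered by non-increasing protein count, ties broken by smallest member
#' id.
#'
#' Isolated single-node clusters also become TNMs when they carry at least
#' `min_singleton_proteins` proteins: a whole structural module can
#' collapse into one well-separated cluster, which is a module, not noise.
#' Single-protein singletons always pool into `"disconnected"`.
#'
#' @param fragment_graph a `mapper_graph` built at fragmenting resolution.
#' @param min_component_nodes minimum nodes for a component to become a TNM.
#' @param min_singleton_proteins minimum proteins for a single-node
#'   component to qualify as a TNM.
#' @return a `tnm_partition`: list with `modules` (named list of protein id
#'   vectors, `"TNM 1"`, ..., plus `"disconnected"`), and `params` (the
#'   fragment cover parameters).
#' @export
extract_tnms <- function(fragment_graph, min_component_nodes = 2,
                         min_singleton_proteins = 2) {
  stopifnot(inherits(fragment_graph, "mapper_graph"))
  universe <- fragment_graph$protein_ids
  if (is.null(universe))
    universe <- sort(unique(unlist(fragment_graph$members)))
  v <- nrow(fragment_graph$nodes)
  if (v == 0) {
    return(structure(list(modules = list(disconnected = character(0)),
                          params = fragment_graph$cover),
                     class = "tnm_partition"))
  }
  ig <- as_igraph(fragment_graph)
  comp <- igraph::components(ig)$membership
  comp_nodes <- split(names(comp), comp)
  comp_proteins <- vapply(comp_nodes, function(nids)
    length(unique(unlist(fragment_graph$members[nids]))), integer(1))
  qualifying <- names(comp_nodes)[
    lengths(comp_nodes) >= min_component_nodes |
      (lengths(comp_nodes) == 1L &
         comp_proteins >= min_singleton_proteins)]

  # protein -> per-qualifying-component node multiplicity
  assignment <- list()
  if (length(qualifying)) {
    counts <- list()
    for (cid in qualifying) {
      for (nid in comp_nodes[[cid]]) {
        for (p in fragment_graph$members[[nid]]) {
          if (is.null(counts[[p]])) counts[[p]] <- integer(0)
          counts[[p]][cid] <- sum(counts[[p]][cid], 1L, na.rm = TRUE)
        }
      }
    }
    comp_size <- lengths(comp_nodes)[qualifying]
    names(comp_size) <- qualifying
    for (p in names(counts)) {
      tab <- counts[[p]]
      best <- names(tab)[tab == max(tab)]
      if (length(best) > 1) {
        sz <- comp_size[best]
        best <- best[sz == max(sz)]
        best <- best[order(as.integer(best))][1]
      }
      assignment[[p]] <- best
    }
  }

  module_sets <- if (length(assignment))
    split(names(assignment), unlist(assignment, use.names = FALSE))
  else list()
  module_sets <- lapply(module_sets, sort)
  module_sets <- module_sets[lengths(module_sets) > 0]
  if (length(module_sets)) {
    sizes <- lengths(module_sets)
    firsts <- vapply(module_sets, `[[`, "", 1L)
    ord <- order(-sizes, firsts)
    module_sets <- module_sets[ord]
    names(module_sets) <- paste("TNM", seq_along(module_sets))
  }
  disconnected <- sort(setdiff(universe, unlist(module_sets)))
  modules <- c(module_sets, list(disconnected = disconnected))
  structure(list(modules = modules, params = fragment_graph$cover),
            class = "tnm_partition")
}

#' @export
print.tnm_partition <- function(x, ...) {
  cat("tnm_partition:\n")
  for (nm in names(x$modules))
    cat(sprintf("  %s: %d proteins\n", nm, length(x$modules[[nm]])))
  invisible(x)
}

#' Superimpose TNMs onto the base Mapper network
#'
#' For every module, the highlighted nodes are the base-network nodes whose
#' member sets intersect the module's proteins. Two modules are adjacent
#' when a base edge joins their highlighted sets or they share a
#' highlighted node.
#'
#' @param base_graph the `mapper_graph` built at base resolution; must
#'   cover every protein of the partition.
#' @param partition a `tnm_partition`.
#' @return a `superposition`: list with `highlight` (named list of node id
#'   vectors per module) and `adjacency` (data.frame `tnm_a`, `tnm_b`).
#' @export
superimpose <- function(base_graph, partition) {
  stopifnot(inherits(base_graph, "mapper_graph"),
            inherits(partition, "tnm_partition"))
  covered <- unique(unlist(base_graph$members))
  missing <- setdiff(unlist(partition$modules), covered)
  if (length(missing))
    stop("protein(s) absent from base graph: ",
         paste(missing, collapse = ", "))
  highlight <- lapply(partition$modules, function(prot) {
    hits <- vapply(base_graph$members,
                   function(mem) length(intersect(mem, prot)) > 0,
                   logical(1))
    names(base_graph$members)[hits]
  })
  labels <- names(partition$modules)
  adj <- list()
  if (length(labels) > 1) {
    for (a in seq_len(length(labels) - 1)) for (b in (a + 1):length(labels)) {
      ha <- highlight[[a]]; hb <- highlight[[b]]
      touching <- length(intersect(ha, hb)) > 0
      if (!touching && nrow(base_graph$edges)) {
        e <- base_graph$edges
        touching <- any((e$from %in% ha & e$to %in% hb) |
                          (e$from %in% hb & e$to %in% ha))
      }
      if (touching)
        adj[[length(adj) + 1L]] <-
          data.frame(tnm_a = labels[a], tnm_b = labels[b],
                     stringsAsFactors = FALSE)
    }
  }
  adjacency <- if (length(adj)) do.call(rbind, adj)
               else data.frame(tnm_a = character(0), tnm_b = character(0),
                               stringsAsFactors = FALSE)
  structure(list(highlight = highlight, adjacency = adjacency),
            class = "superposition")
}

#' Write a superposition to JSON
#'
#' @param superposition a `superposition`.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_superposition <- function(superposition, path) {
  stopifnot(inherits(superposition, "superposition"))
  payload <- list(
    highlight = superposition$highlight,
    adjacency = if (nrow(superposition$adjacency))
      lapply(seq_len(nrow(superposition$adjacency)), function(i)
        list(tnm_a = superposition$adjacency$tnm_a[i],
             tnm_b = superposition$adjacency$tnm_b[i]))
    else list()
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Summarize a TNM partition, optionally against ground truth
#'
#' Reports per-module protein counts. Given ground-truth labels, also
#' reports the adjusted Rand index between the partition and the labels and
#' each true module's best-matching TNM with its purity
#' (overlap / true module size). `label_subset` restricts the comparison to
#' proteins whose true label is in the subset (e.g. the planted structural
#' modules, excluding background).
#'
#' @param partition a `tnm_partition`.
#' @param ground_truth optional `truth` element from the simulators (list
#'   with named `labels` vector).
#' @param label_subset optional character vector of true labels to compare
#'   on.
#' @return list with `counts` (data.frame), and with truth: `ari` and
#'   `purity` (data.frame `true_label`, `best_tnm`, `overlap`, `purity`).
#' @export
tnm_summary <- function(partition, ground_truth = NULL,
                        label_subset = NULL) {
  stopifnot(inherits(partition, "tnm_partition"))
  counts <- data.frame(tnm = names(partition$modules),
                       n_proteins = lengths(partition$modules),
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- list(counts = counts)
  if (!is.null(ground_truth)) {
    truth <- ground_truth$labels
    part_label <- rep(names(partition$modules), lengths(partition$modules))
    names(part_label) <- unlist(partition$modules, use.names = FALSE)
    common <- intersect(names(part_label), names(truth))
    if (!is.null(label_subset))
      common <- common[truth[common] %in% label_subset]
    if (length(common) < 2) {
      out$ari <- NA_real_
    } else {
      out$ari <- mclust::adjustedRandIndex(part_label[common],
                                           truth[common])
      tl <- unique(truth[common])
      purity <- do.call(rbind, lapply(tl, function(lb) {
        members <- common[truth[common] == lb]
        tab <- table(part_label[members])
        best <- names(tab)[which.max(tab)]
        data.frame(true_label = lb, best_tnm = best,
                   overlap = as.integer(max(tab)),
                   purity = as.numeric(max(tab)) / length(members),
                   stringsAsFactors = FALSE)
      }))
      out$purity <- purity
    }
  }
  out
}

#' Count supplied interactions internal to each TNM
#'
#' Given a user-supplied edge list of known protein-protein interactions
#' (e.g. exported from an interaction database), counts, per module, the
#' pairs with both endpoints inside the module. Duplicate pairs (in either
#' orientation) and self-pairs are ignored.
#'
#' @param partition a `tnm_partition`.
#' @param edge_list two-column data.frame or matrix of protein id pairs.
#' @return named integer vector of within-module interaction counts.
#' @export
biogrid_overlap <- function(partition, edge_list) {
  stopifnot(inherits(partition, "tnm_partition"))
  edge_list <- as.matrix(edge_list)
  if (nrow(edge_list)) {
    edge_list <- edge_list[edge_list[, 1] != edge_list[, 2], , drop = FALSE]
    key <- apply(edge_list, 1, function(r) paste(sort(r), collapse = "\r"))
    edge_list <- edge_list[!duplicated(key), , drop = FALSE]
  }
  vapply(partition$modules, function(prot) {
    if (!nrow(edge_list)) return(0L)
    sum(edge_list[, 1] %in% prot & edge_list[, 2] %in% prot)
  }, integer(1))
}
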