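#' Read a spectral count table and run manifest from TSV
#'
#' The count table is a UTF-8 tab-separated file whose first two columns are
#' `protein_id` and `length` (amino acids), followed by one column of
#' spectral counts per run. The manifest is a TSV with columns `run_id`,
#' `bait`, `genotype_or_treatment`, `replicate_index`, `role`. Proteins not
#' detected in a run are encoded as count 0, never as missing.
#'
#' @param path path to the count table TSV.
#' @param manifest_path path to the run manifest TSV.
#' @return a validated [spectral_count_table()].
#' @export
read_count_table <- function(path, manifest_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3 || names(tab)[1] != "protein_id")
    stop("count table must start with columns protein_id, length")
  if (names(tab)[2] != "length")
    stop("count table missing 'length' column (second column)")
  manifest <- utils::read.delim(manifest_path, check.names = FALSE,
                                stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(counts) <- tab$protein_id
  spectral_count_table(counts, tab$length, manifest)
}

#' Write a spectral count table (and its manifest) to TSV
#'
#' @param x a `spectral_count_table`.
#' @param path output path for the count table TSV.
#' @param manifest_path optional output path for the run manifest TSV.
#' @return invisibly, `path`.
#' @export
write_count_table <- function(x, path, manifest_path = NULL) {
  stopifnot(inherits(x, "spectral_count_table"))
  out <- data.frame(protein_id = x$protein_ids,
                    length = unname(x$lengths),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest_path))
    utils::write.table(x$run_meta, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Write a Mapper graph to GraphML or JSON
#'
#' Node attributes carried: `member_protein_ids` (comma-separated),
#' `n_members`, `mean_lens_1`, `mean_lens_2`, and `tnm_label` when a module
#' assignment is present. Edges carry `n_shared`, the number of proteins the
#' two clusters have in common. The JSON mirror additionally embeds the
#' cover parameters.
#'
#' @param graph a `mapper_graph`.
#' @param path output file path.
#' @param format `"graphml"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(graph, path, format = c("graphml", "json")) {
  stopifnot(inherits(graph, "mapper_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- as_igraph(graph)
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    nodes <- lapply(seq_len(nrow(graph$nodes)), function(i) {
      nd <- list(
        node_id = graph$nodes$node_id[i],
        member_protein_ids = graph$members[[i]],
        n_members = graph$nodes$n_members[i],
        mean_lens_1 = graph$nodes$mean_lens_1[i],
        mean_lens_2 = graph$nodes$mean_lens_2[i]
      )
      if (!is.null(graph$nodes$tnm_label))
        nd$tnm_label <- graph$nodes$tnm_label[i]
      nd
    })
    edges <- if (nrow(graph$edges)) {
      lapply(seq_len(nrow(graph$edges)), function(i)
        list(source = graph$edges$from[i], target = graph$edges$to[i],
             n_shared = graph$edges$n_shared[i]))
    } else list()
    payload <- list(nodes = nodes, edges = edges, cover = graph$cover,
                    metric = graph$metric, lens_kinds = graph$lens_kinds)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a Mapper graph written by [write_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"json"`.
#' @return a `mapper_graph` (cover parameters are only recovered from JSON).
#' @export
read_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    members <- strsplit(igraph::V(ig)$member_protein_ids, ",", fixed = TRUE)
    nodes <- data.frame(
      node_id = igraph::V(ig)$name,
      n_members = as.integer(igraph::V(ig)$n_members),
      mean_lens_1 = as.numeric(igraph::V(ig)$mean_lens_1),
      mean_lens_2 = as.numeric(igraph::V(ig)$mean_lens_2),
      stringsAsFactors = FALSE
    )
    if ("tnm_label" %in% igraph::vertex_attr_names(ig))
      nodes$tnm_label <- igraph::V(ig)$tnm_label
    el <- igraph::as_edgelist(ig, names = TRUE)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        n_shared = if (igraph::ecount(ig))
                          as.integer(igraph::E(ig)$n_shared) else integer(0),
                        stringsAsFactors = FALSE)
    cover <- NULL; metric <- NA_character_; lens_kinds <- NULL
  } else {
    payload <- jsonlite::read_json(path, simplifyVector = FALSE)
    nodes <- data.frame(
      node_id = vapply(payload$nodes, function(n) n$node_id, character(1)),
      n_members = vapply(payload$nodes, function(n) as.integer(n$n_members),
                         integer(1)),
      mean_lens_1 = vapply(payload$nodes,
                           function(n) as.numeric(n$mean_lens_1), numeric(1)),
      mean_lens_2 = vapply(payload$nodes,
                           function(n) as.numeric(n$mean_lens_2), numeric(1)),
      stringsAsFactors = FALSE
    )
    if (length(payload$nodes) && !is.null(payload$nodes[[1]]$tnm_label))
      nodes$tnm_label <- vapply(payload$nodes,
                                function(n) n$tnm_label, character(1))
    members <- lapply(payload$nodes,
                      function(n) unlist(n$member_protein_ids))
    edges <- if (length(payload$edges)) {
      data.frame(
        from = vapply(payload$edges, function(e) e$source, character(1)),
        to = vapply(payload$edges, function(e) e$target, character(1)),
        n_shared = vapply(payload$edges,
                          function(e) as.integer(e$n_shared), integer(1)),
        stringsAsFactors = FALSE
      )
    } else data.frame(from = character(0), to = character(0),
                      n_shared = integer(0), stringsAsFactors = FALSE)
    cover <- payload$cover
    metric <- if (is.null(payload$metric)) NA_character_ else payload$metric
    lens_kinds <- unlist(payload$lens_kinds)
  }
  if (length(members)) names(members) <- nodes$node_id
  new_mapper_graph(nodes = nodes, members = members, edges = edges,
                   cover = cover, metric = metric, lens_kinds = lens_kinds)
}

#' Export per-TNM protein lists as plain text
#'
#' One file per module (`TNM_1.txt`, ..., `disconnected.txt`), one protein
#' id per line — the format enrichment web tools paste directly.
#'
#' @param partition a `tnm_partition`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
export_protein_lists <- function(partition, out_dir) {
  stopifnot(inherits(partition, "tnm_partition"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  labels <- names(partition$modules)
  files <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_]+", "_", labels),
                                     ".txt"))
  for (i in seq_along(labels))
    writeLines(partition$modules[[i]], files[i])
  invisible(files)
}

#' Write / read a feature matrix as TSV
#'
#' First column `protein_id`, then one numeric column per contrast. The
#' feature kind (`log2fc` or `zscore`) is stored in a `# feature_kind:`
#' comment header line.
#'
#' @param features a `feature_matrix`.
#' @param path file path.
#' @return invisibly `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# feature_kind: ", features$feature_kind), con)
  out <- data.frame(protein_id = rownames(features$values),
                    as.data.frame(features$values, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- "log2fc"
  if (startsWith(first, "# feature_kind:"))
    kind <- trimws(sub("# feature_kind:", "", first, fixed = TRUE))
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$protein_id
  feature_matrix(values, feature_kind = kind)
}

#' Write a TNM partition as TSV (protein_id, tnm_label)
#'
#' @param partition a `tnm_partition`.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_tnm_partition <- function(partition, path) {
  stopifnot(inherits(partition, "tnm_partition"))
  labels <- rep(names(partition$modules),
                lengths(partition$modules))
  out <- data.frame(protein_id = unlist(partition$modules, use.names = FALSE),
                    tnm_label = labels, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
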