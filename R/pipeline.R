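#' Assemble contrasts from a run manifest
#'
#' Deletion designs: one contrast per perturbed `genotype_or_treatment`,
#' test = that genotype's runs, reference = all wild-type runs. Drug
#' designs: one contrast per treated bait with, by this package's
#' convention, reference = the bait's treated runs and test = its paired
#' control (DMSO) runs, so that proteins lost under treatment carry
#' positive Z scores as required by the Z-score filter.
#'
#' @param counts a [spectral_count_table()].
#' @param mode `"deletion"` or `"drug"`.
#' @return list of [contrast()] objects.
#' @export
make_contrasts <- function(counts, mode = c("deletion", "drug")) {
  mode <- match.arg(mode)
  m <- counts$run_meta
  if (mode == "deletion") {
    wt <- m$run_id[m$role == "wildtype"]
    if (!length(wt)) stop("no wild-type runs in manifest")
    perts <- unique(m$genotype_or_treatment[m$role == "perturbed"])
    if (!length(perts)) stop("no perturbed runs in manifest")
    lapply(perts, function(g)
      contrast(g, reference_runs = wt,
               test_runs = m$run_id[m$role == "perturbed" &
                                      m$genotype_or_treatment == g]))
  } else {
    baits <- unique(m$bait[m$role == "perturbed"])
    if (!length(baits)) stop("no treated runs in manifest")
    lapply(baits, function(b) {
      ctrl <- m$run_id[m$bait == b & m$role == "wildtype"]
      trt <- m$run_id[m$bait == b & m$role == "perturbed"]
      if (!length(ctrl))
        stop("bait '", b, "' has no paired control runs")
      contrast(b, reference_runs = trt, test_runs = ctrl)
    })
  }
}

.config_keys <- c("mode", "counts", "manifest", "simulate", "sim",
                  "filters", "metric", "lens", "base", "fragment",
                  "min_component_nodes", "seed", "out_dir")
.filter_keys <- c("min_fold", "log2fc_cutoff", "z_cutoff", "fdr_cutoff")
.cover_keys <- c("resolution", "gain", "equalized")

#' Validate a pipeline configuration
#'
#' Unknown keys are errors (typo protection for parameters such as `gain`).
#' A fragment resolution below the base resolution triggers a warning: the
#' fragmenting pass is meant to break the base network apart.
#'
#' @param config named list, e.g. parsed from YAML.
#' @return validated `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$mode) || !config$mode %in% c("deletion", "drug"))
    stop("config mode must be 'deletion' or 'drug'")
  defaults <- list(
    simulate = FALSE, sim = list(),
    filters = list(),
    metric = if (config$mode == "deletion") "correlation"
             else "norm_correlation",
    lens = if (config$mode == "deletion") "metric_svd" else "neighborhood",
    base = list(resolution = if (config$mode == "deletion") 30 else 20,
                gain = 3, equalized = TRUE),
    fragment = list(resolution = if (config$mode == "deletion") 45 else 30,
                    gain = 3, equalized = TRUE),
    min_component_nodes = 2, seed = 1L, out_dir = "."
  )
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  fdef <- list(min_fold = 4, log2fc_cutoff = -2, z_cutoff = 2,
               fdr_cutoff = 0.05)
  unknown <- setdiff(names(config$filters), .filter_keys)
  if (length(unknown))
    stop("unknown filters key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(fdef))
    if (is.null(config$filters[[nm]])) config$filters[[nm]] <- fdef[[nm]]
  for (blk in c("base", "fragment")) {
    unknown <- setdiff(names(config[[blk]]), .cover_keys)
    if (length(unknown))
      stop("unknown ", blk, " key(s): ", paste(unknown, collapse = ", "))
    if (is.null(config[[blk]]$resolution) || config[[blk]]$resolution < 1)
      stop(blk, " resolution must be >= 1")
    if (is.null(config[[blk]]$gain) || config[[blk]]$gain < 1)
      stop(blk, " gain must be >= 1")
    if (is.null(config[[blk]]$equalized)) config[[blk]]$equalized <- TRUE
  }
  if (config$fragment$resolution < config$base$resolution)
    warning("fragment resolution below base resolution; ",
            "the fragmenting pass normally uses more bins")
  if (!isTRUE(config$simulate) &&
      (is.null(config$counts) || is.null(config$manifest)))
    stop("config needs counts and manifest paths (or simulate: true)")
  if (config$filters$fdr_cutoff < 0 || config$filters$fdr_cutoff > 1)
    stop("fdr_cutoff must lie in [0, 1]")
  class(config) <- "pipeline_config"
  config
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full TNM pipeline
#'
#' Quantify (dNSAF) -> control-specificity filter (deletion mode) ->
#' Poisson/Wald differential statistics -> depletion or Z-score filter ->
#' base Mapper network -> fragmenting Mapper network -> TNM extraction ->
#' superposition onto the base network. Writes `features.tsv`,
#' `network_base.graphml`/`.json`, `network_fragment.graphml`/`.json`,
#' `tnms.tsv`, `superposition.json` and `summary.tsv` into
#' `config$out_dir`, plus `provenance.json` recording all parameters. The
#' run is deterministic given the config (including its seed); on error the
#' stage name is reported and partial outputs are removed.
#'
#' @param config a `pipeline_config` (or plain list; validated here).
#' @param counts optional in-memory [spectral_count_table()] overriding the
#'   config's paths.
#' @param truth optional ground-truth list (as from the simulators) used
#'   for the summary.
#' @return invisibly, a list with the in-memory artifacts: `features`,
#'   `base_graph`, `fragment_graph`, `partition`, `superposition`,
#'   `summary`, `log` (per-stage protein counts).
#' @export
run_pipeline <- function(config, counts = NULL, truth = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifacts <- file.path(out_dir,
    c("features.tsv", "network_base.graphml", "network_base.json",
      "network_fragment.graphml", "network_fragment.json", "tnms.tsv",
      "superposition.json", "summary.tsv", "provenance.json"))
  stage <- "input"
  result <- tryCatch({
    if (is.null(counts)) {
      if (isTRUE(config$simulate)) {
        stage <- "simulate"
        sim_args <- config$sim
        sim_args$seed <- config$seed
        cfg <- do.call(simulation_config, sim_args)
        sim <- if (config$mode == "deletion") simulate_deletion_network(cfg)
               else simulate_drug_network(cfg)
        counts <- sim$counts
        if (is.null(truth)) truth <- sim$truth
      } else {
        stage <- "read_counts"
        counts <- read_count_table(config$counts, config$manifest)
      }
    }
    log <- list(n_proteins = length(counts$protein_ids),
                n_runs = ncol(counts$counts))

    stage <- "quantify"
    dnsaf <- compute_dnsaf(counts)

    specific <- counts$protein_ids
    if (config$mode == "deletion") {
      stage <- "control_specificity_filter"
      wt <- mean_abundance(dnsaf, runs_by(counts, role = "wildtype"))
      ctrl_runs <- runs_by(counts, role = "control")
      if (length(ctrl_runs)) {
        ctrl <- mean_abundance(dnsaf, ctrl_runs)
        specific <- control_specificity_filter(wt, ctrl,
                                               config$filters$min_fold)
      }
    }
    log$n_specific <- length(specific)

    stage <- "differential"
    sub <- .subset_proteins(counts, specific)
    contrasts <- make_contrasts(sub, config$mode)
    direction <- if (config$mode == "deletion") "decrease" else "increase"
    diff_tab <- differential_table(sub, contrasts, direction)

    stage <- "filter"
    features <- if (config$mode == "deletion")
      depletion_filter(diff_tab, config$filters$log2fc_cutoff,
                       config$filters$fdr_cutoff)
    else zscore_filter(diff_tab, config$filters$z_cutoff,
                       config$filters$fdr_cutoff)
    log$n_filtered <- nrow(features$values)
    if (log$n_filtered < 1)
      stop("no proteins pass the filters; nothing to analyse")

    stage <- "mapper_base"
    base_graph <- build_mapper_graph(
      features, metric = config$metric, lens = config$lens,
      resolution = config$base$resolution, gain = config$base$gain,
      equalized = config$base$equalized)
    stage <- "mapper_fragment"
    fragment_graph <- build_mapper_graph(
      features, metric = config$metric, lens = config$lens,
      resolution = config$fragment$resolution, gain = config$fragment$gain,
      equalized = config$fragment$equalized)

    stage <- "extract_tnms"
    partition <- extract_tnms(fragment_graph, config$min_component_nodes)
    stage <- "superimpose"
    sup <- superimpose(base_graph, partition)
    stage <- "summary"
    planted <- if (!is.null(truth))
      grep("^M[0-9]+$", unique(truth$labels), value = TRUE) else NULL
    summ <- tnm_summary(partition, truth, label_subset = planted)

    stage <- "write"
    write_feature_matrix(features, artifacts[1])
    write_network(base_graph, artifacts[2], "graphml")
    write_network(base_graph, artifacts[3], "json")
    write_network(fragment_graph, artifacts[4], "graphml")
    write_network(fragment_graph, artifacts[5], "json")
    write_tnm_partition(partition, artifacts[6])
    write_superposition(sup, artifacts[7])
    stab <- summ$counts
    if (!is.null(summ$ari)) stab$ari <- summ$ari
    utils::write.table(stab, artifacts[8], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    prov <- config
    class(prov) <- NULL
    prov$stage_log <- log
    jsonlite::write_json(prov, artifacts[9], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

    list(features = features, base_graph = base_graph,
         fragment_graph = fragment_graph, partition = partition,
         superposition = sup, summary = summ, log = log)
  }, error = function(e) {
    unlink(artifacts)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# Restrict a spectral_count_table to a protein subset (order preserved).
.subset_proteins <- function(counts, ids) {
  keep <- counts$protein_ids %in% ids
  spectral_count_table(counts$counts[keep, , drop = FALSE],
                       counts$lengths[keep], counts$run_meta)
}
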