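#' Configuration for the synthetic AP-MS generator
#'
#' Describes a bait-purified protein complex partitioned into structural
#' modules plus an unaffected scaffold group, background (non-specific)
#' preys, and a small set of proteins depleted in every perturbation.
#' Perturbations are genetic deletions (or drug treatments) that deplete
#' the members of their ablated modules by `depletion_factor`.
#'
#' Defaults describe the package's reference deletion-network study
#' condition: three planted structural modules of sizes 4-6, a scaffold
#' group of 5, 40 background preys, 4 ubiquitously lost proteins, one
#' perturbation per module at 8-fold depletion, and 3 replicates per
#' condition.
#'
#' @param n_modules number of structural modules.
#' @param module_sizes integer vector (one entry per module, all >= 2).
#' @param n_scaffold number of unaffected core (scaffold) proteins.
#' @param n_background number of background preys, present at low abundance
#'   in every run including mock controls.
#' @param n_ubiquitous_loss number of proteins depleted in all perturbations.
#' @param baits bait names; each bait is itself a scaffold-class protein and
#'   is boosted `bait_boost`-fold in runs it was used to purify.
#' @param perturbations list of `list(name=, ablated_modules=, depletion_factor=)`;
#'   `NULL` gives one perturbation per module at `depletion_factor` 8.
#' @param n_replicates replicates per condition (per arm for drug designs).
#' @param mean_depth expected total spectral counts per run.
#' @param length_range protein length range (amino acids), sampled
#'   log-uniformly.
#' @param bait_boost self-enrichment factor for the tagged bait.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_modules = 3,
                              module_sizes = c(4L, 5L, 6L),
                              n_scaffold = 5,
                              n_background = 40,
                              n_ubiquitous_loss = 4,
                              baits = "INO80",
                              perturbations = NULL,
                              n_replicates = 3,
                              mean_depth = 8000,
                              length_range = c(150, 1200),
                              bait_boost = 10,
                              seed = 1L) {
  if (length(module_sizes) != n_modules)
    stop("module_sizes must have n_modules entries")
  if (any(module_sizes < 2)) stop("all module_sizes must be >= 2")
  if (is.null(perturbations)) {
    # two deletion genotypes probing each module, mirroring a deletion
    # network in which several deleted subunits collapse the same module
    perturbations <- unlist(lapply(seq_len(n_modules), function(i)
      lapply(c("a", "b"), function(s)
        list(name = sprintf("del_M%d%s", i, s),
             ablated_modules = paste0("M", i),
             depletion_factor = 8))), recursive = FALSE)
  }
  module_names <- paste0("M", seq_len(n_modules))
  for (p in perturbations) {
    if (is.null(p$name) || is.null(p$ablated_modules) ||
        is.null(p$depletion_factor))
      stop("each perturbation needs name, ablated_modules, depletion_factor")
    unknown <- setdiff(p$ablated_modules, module_names)
    if (length(unknown))
      stop("perturbation '", p$name, "' ablates unknown module(s): ",
           paste(unknown, collapse = ", "))
    if (p$depletion_factor < 1) stop("depletion_factor must be >= 1")
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  structure(
    list(n_modules = as.integer(n_modules),
         module_sizes = as.integer(module_sizes),
         n_scaffold = as.integer(n_scaffold),
         n_background = as.integer(n_background),
         n_ubiquitous_loss = as.integer(n_ubiquitous_loss),
         baits = baits, perturbations = perturbations,
         n_replicates = as.integer(n_replicates),
         mean_depth = mean_depth, length_range = length_range,
         bait_boost = bait_boost, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Protein universe shared by both designs. Complex-class proteins (modules,
# scaffold, baits, ubiquitous-loss) get lognormal relative abundance around
# 1; background sits ~10x lower, emulating carry-over binding to the resin.
.sim_proteins <- function(config) {
  module_labels <- rep(paste0("M", seq_len(config$n_modules)),
                       config$module_sizes)
  ids <- c(unlist(lapply(seq_len(config$n_modules), function(i)
            sprintf("M%d_P%02d", i, seq_len(config$module_sizes[i])))),
           config$baits,
           sprintf("SCF_P%02d", seq_len(config$n_scaffold)),
           sprintf("UBL_P%02d", seq_len(config$n_ubiquitous_loss)),
           sprintf("BG_P%03d", seq_len(config$n_background)))
  labels <- c(module_labels,
              rep("scaffold", length(config$baits) + config$n_scaffold),
              rep("ubiquitous_loss", config$n_ubiquitous_loss),
              rep("background", config$n_background))
  names(labels) <- ids
  n <- length(ids)
  lengths <- round(exp(stats::runif(n, log(config$length_range[1]),
                                    log(config$length_range[2]))))
  names(lengths) <- ids
  abundance <- exp(stats::rnorm(n, 0, 0.3))
  abundance[labels == "background"] <-
    0.1 * exp(stats::rnorm(config$n_background, 0, 0.3))
  names(abundance) <- ids
  list(ids = ids, labels = labels, lengths = lengths, abundance = abundance)
}

# Draw one run's Poisson counts given per-protein relative abundances.
# lambda_i = depth * a_i * L_i / sum_j a_j L_j, so E[column sum] = depth.
.sim_run <- function(abundance, lengths, depth) {
  w <- abundance * lengths
  lambda <- depth * w / sum(w)
  stats::rpois(length(lambda), lambda)
}

#' Simulate a deletion-network AP-MS dataset
#'
#' Emulates a bait-purified complex analysed in wild-type and deletion
#' strains: wild-type and mock-control replicates plus `n_replicates` runs
#' per perturbation. In a perturbed run the abundance of every truly
#' depleted protein (ablated module members plus the ubiquitous-loss group)
#' is divided by that perturbation's `depletion_factor`. Mock controls
#' capture background preys only. Counts are Poisson with mean proportional
#' to protein length x abundance x run depth.
#'
#' @param config a [simulation_config()].
#' @return list with elements `counts` (a [spectral_count_table()]) and
#'   `truth` (list: `labels`, a named vector over proteins with levels
#'   `M1..Mm`, `scaffold`, `background`, `ubiquitous_loss`; and `depleted`,
#'   a per-perturbation list of truly depleted protein ids).
#' @export
simulate_deletion_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr_seed <- .seed_guard(config$seed)
  on.exit(withr_seed())

  pr <- .sim_proteins(config)
  bait <- config$baits[1]
  base_ab <- pr$abundance
  base_ab[bait] <- base_ab[bait] * config$bait_boost

  ctrl_ab <- pr$abundance
  ctrl_ab[pr$labels != "background"] <- 0  # mock purification

  depleted <- lapply(config$perturbations, function(p) {
    members <- names(pr$labels)[pr$labels %in% p$ablated_modules |
                                  pr$labels == "ubiquitous_loss"]
    members
  })
  names(depleted) <- vapply(config$perturbations, `[[`, "", "name")

  runs <- list(); meta <- list()
  add_run <- function(id, ab, bait_id, genotype, rep_i, role) {
    runs[[id]] <<- .sim_run(ab, pr$lengths, config$mean_depth)
    meta[[id]] <<- data.frame(run_id = id, bait = bait_id,
                              genotype_or_treatment = genotype,
                              replicate_index = rep_i, role = role,
                              stringsAsFactors = FALSE)
  }
  for (r in seq_len(config$n_replicates))
    add_run(sprintf("WT_rep%d", r), base_ab, bait, "WT", r, "wildtype")
  for (r in seq_len(config$n_replicates))
    add_run(sprintf("CTRL_rep%d", r), ctrl_ab, "mock", "control", r, "control")
  for (p in config$perturbations) {
    ab <- base_ab
    ab[depleted[[p$name]]] <- ab[depleted[[p$name]]] / p$depletion_factor
    for (r in seq_len(config$n_replicates))
      add_run(sprintf("%s_rep%d", p$name, r), ab, bait, p$name, r, "perturbed")
  }

  counts <- do.call(cbind, runs)
  rownames(counts) <- pr$ids
  sct <- spectral_count_table(counts, pr$lengths,
                              do.call(rbind, meta))
  list(counts = sct,
       truth = list(labels = pr$labels, depleted = depleted))
}

#' Simulate a drug-perturbation AP-MS dataset
#'
#' Emulates paired control (DMSO) and treated (SAHA-like) purifications for
#' several baits: each perturbation names a treated bait whose ablated
#' module members (plus the ubiquitous-loss group) are depleted in that
#' bait's treated runs. Control runs use role `wildtype`, treated runs role
#' `perturbed`; `genotype_or_treatment` records `DMSO` / `treated`.
#'
#' @param config a [simulation_config()]; `perturbations` must be non-empty
#'   and their names are the treated baits.
#' @return as [simulate_deletion_network()].
#' @export
simulate_drug_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!length(config$perturbations))
    stop("drug design requires at least one treated bait (perturbation)")
  withr_seed <- .seed_guard(config$seed)
  on.exit(withr_seed())

  pr <- .sim_proteins(config)
  depleted <- lapply(config$perturbations, function(p)
    names(pr$labels)[pr$labels %in% p$ablated_modules |
                       pr$labels == "ubiquitous_loss"])
  names(depleted) <- vapply(config$perturbations, `[[`, "", "name")

  runs <- list(); meta <- list()
  for (p in config$perturbations) {
    bait <- p$name
    ab_ctrl <- pr$abundance
    if (bait %in% names(ab_ctrl))
      ab_ctrl[bait] <- ab_ctrl[bait] * config$bait_boost
    ab_trt <- ab_ctrl
    ab_trt[depleted[[bait]]] <- ab_trt[depleted[[bait]]] / p$depletion_factor
    for (r in seq_len(config$n_replicates)) {
      id <- sprintf("%s_DMSO_rep%d", bait, r)
      runs[[id]] <- .sim_run(ab_ctrl, pr$lengths, config$mean_depth)
      meta[[id]] <- data.frame(run_id = id, bait = bait,
                               genotype_or_treatment = "DMSO",
                               replicate_index = r, role = "wildtype",
                               stringsAsFactors = FALSE)
      id <- sprintf("%s_treated_rep%d", bait, r)
      runs[[id]] <- .sim_run(ab_trt, pr$lengths, config$mean_depth)
      meta[[id]] <- data.frame(run_id = id, bait = bait,
                               genotype_or_treatment = "treated",
                               replicate_index = r, role = "perturbed",
                               stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, runs)
  rownames(counts) <- pr$ids
  sct <- spectral_count_table(counts, pr$lengths, do.call(rbind, meta))
  list(counts = sct,
       truth = list(labels = pr$labels, depleted = depleted))
}

# Seed the RNG for a reproducible draw, restoring caller state on exit.
.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
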