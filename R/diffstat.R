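#' Define a contrast between two run groups
#'
#' @param name contrast label (e.g. the deleted genotype or treated bait).
#' @param reference_runs run ids of the reference arm (wild-type / control).
#' @param test_runs run ids of the test arm (mutant / treated).
#' @return a `contrast` object.
#' @export
contrast <- function(name, reference_runs, test_runs) {
  if (!length(reference_runs) || !length(test_runs))
    stop("contrast '", name, "': both run sets must be non-empty")
  if (length(intersect(reference_runs, test_runs)))
    stop("contrast '", name, "': run sets must be disjoint")
  structure(list(name = name, reference_runs = reference_runs,
                 test_runs = test_runs), class = "contrast")
}

#' Upper-tail standard-normal probability of a Z score
#'
#' The one-sided p value of a Z score: a Z of 2 gives 0.0228, which rounds
#' to the conventional 0.02 quoted for this threshold.
#'
#' @param z finite numeric Z score(s).
#' @return one-sided p value(s).
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  stats::pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false discovery rate control within one contrast.
#'
#' @param p_values numeric vector of p values in [0, 1].
#' @return BH-adjusted values (same order as input).
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Control-specificity filter
#'
#' Retains proteins whose mean wild-type abundance exceeds the mean control
#' (mock purification) abundance by at least `min_fold`. Because control
#' tables are dominated by missing (zero) values, a zero control mean is
#' floored at a pseudocount (1% of the smallest nonzero wild-type mean) so
#' the ratio is defined; any protein detected in wild-type but never in the
#' controls is therefore always retained. The threshold is inclusive.
#'
#' @param wt_mean,ctrl_mean named per-protein mean dNSAF vectors over the
#'   same protein universe.
#' @param min_fold minimum wild-type:control fold ratio (> 0), default 4.
#' @return character vector of retained (specific) protein ids.
#' @export
control_specificity_filter <- function(wt_mean, ctrl_mean, min_fold = 4) {
  if (min_fold <= 0) stop("min_fold must be positive")
  if (length(wt_mean) != length(ctrl_mean) ||
      !identical(names(wt_mean), names(ctrl_mean)))
    stop("wt_mean and ctrl_mean must cover the same protein universe")
  nz <- wt_mean[wt_mean > 0]
  eps <- if (length(nz)) min(nz) * 1e-2 else .Machine$double.eps
  ratio <- wt_mean / pmax(ctrl_mean, eps)
  names(wt_mean)[ratio >= min_fold | (ctrl_mean == 0 & wt_mean > 0)]
}

#' Poisson/Wald contrast on summed spectral counts
#'
#' A documented approximation to hierarchical-Bayes spectral-count testing:
#' per protein, the rate ratio between arms is estimated from counts summed
#' over each arm's runs with offsets = protein length x run total counts
#' and 0.5 pseudocounts, giving
#' log2FC = log2(((sum test + 0.5)/test offset) / ((sum ref + 0.5)/ref offset)).
#' The Wald Z is the natural-log rate ratio divided by
#' sqrt(1/(sum test + 0.5) + 1/(sum ref + 0.5)); Z shares the sign of the
#' fold change. The p value is the one-sided tail probability in the stated
#' direction of interest (`"decrease"`: depletion in the test arm is
#' significant; `"increase"`: enrichment), so p is uniform under the null.
#'
#' @param counts a [spectral_count_table()].
#' @param contrast a [contrast()].
#' @param direction direction of interest for the p value.
#' @return data.frame with columns `protein_id`, `log2fc`, `z`, `p`.
#' @export
poisson_contrast <- function(counts, contrast,
                             direction = c("decrease", "increase")) {
  stopifnot(inherits(counts, "spectral_count_table"),
            inherits(contrast, "contrast"))
  direction <- match.arg(direction)
  all_runs <- colnames(counts$counts)
  missing <- setdiff(c(contrast$reference_runs, contrast$test_runs), all_runs)
  if (length(missing))
    stop("contrast '", contrast$name, "': unknown run(s): ",
         paste(missing, collapse = ", "))
  run_tot <- colSums(counts$counts)
  off <- function(runs) counts$lengths * sum(run_tot[runs])
  ct <- rowSums(counts$counts[, contrast$test_runs, drop = FALSE])
  cr <- rowSums(counts$counts[, contrast$reference_runs, drop = FALSE])
  ot <- off(contrast$test_runs)
  or <- off(contrast$reference_runs)
  if (any(ot == 0) || any(or == 0))
    stop("zero total offset in contrast '", contrast$name, "'")
  log2fc <- log2(((ct + 0.5) / ot) / ((cr + 0.5) / or))
  se <- sqrt(1 / (ct + 0.5) + 1 / (cr + 0.5))
  z <- log2fc * log(2) / se
  p <- if (direction == "decrease") stats::pnorm(z)
       else stats::pnorm(z, lower.tail = FALSE)
  undefined <- ct == 0 & cr == 0
  log2fc[undefined] <- 0; z[undefined] <- 0; p[undefined] <- 1
  data.frame(protein_id = counts$protein_ids, log2fc = log2fc, z = z, p = p,
             undefined = undefined, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-protein, per-contrast differential table
#'
#' Runs [poisson_contrast()] for every contrast and adds a within-contrast
#' Benjamini-Hochberg FDR.
#'
#' @param counts a [spectral_count_table()].
#' @param contrasts list of [contrast()] objects.
#' @param direction passed to [poisson_contrast()].
#' @return a `differential_table`: data.frame with columns `protein_id`,
#'   `contrast`, `log2fc`, `z`, `p`, `fdr` (+ logical `undefined`).
#' @export
differential_table <- function(counts, contrasts,
                               direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  parts <- lapply(contrasts, function(cn) {
    res <- poisson_contrast(counts, cn, direction)
    res$contrast <- cn$name
    res$fdr <- bh_fdr(res$p)
    res
  })
  tab <- do.call(rbind, parts)
  tab <- tab[, c("protein_id", "contrast", "log2fc", "z", "p", "fdr",
                 "undefined")]
  class(tab) <- c("differential_table", "data.frame")
  tab
}

#' Read an externally produced differential table
#'
#' Accepts TSV output with columns `protein_id` (or `protein`), `contrast`,
#' `log2fc`, `z`, `fdr` and optionally `p`, e.g. exported from a dedicated
#' hierarchical-Bayes spectral-count tool, so the downstream filters can be
#' reproduced on externally computed statistics.
#'
#' @param path TSV file path.
#' @return a `differential_table`.
#' @export
read_external_differential <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if ("protein" %in% names(tab) && !"protein_id" %in% names(tab))
    names(tab)[names(tab) == "protein"] <- "protein_id"
  required <- c("protein_id", "contrast", "log2fc", "z", "fdr")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("differential table missing column(s): ",
         paste(missing, collapse = ", "))
  if (!"p" %in% names(tab)) tab$p <- NA_real_
  if (any(tab$fdr < 0 | tab$fdr > 1))
    stop("fdr values must lie in [0, 1]")
  if (any(!is.na(tab$p) & (tab$p < 0 | tab$p > 1)))
    stop("p values must lie in [0, 1]")
  if (!"undefined" %in% names(tab)) tab$undefined <- FALSE
  tab <- tab[, c("protein_id", "contrast", "log2fc", "z", "p", "fdr",
                 "undefined")]
  class(tab) <- c("differential_table", "data.frame")
  tab
}

#' Write a differential table to TSV
#'
#' @param table a `differential_table`.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_differential_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filtered protein-by-contrast feature matrix
#'
#' @param values numeric matrix, proteins in rows, contrasts in columns.
#' @param feature_kind `"log2fc"` or `"zscore"`.
#' @param provenance list recording the filters and thresholds applied.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, feature_kind = c("log2fc", "zscore"),
                           provenance = list()) {
  feature_kind <- match.arg(feature_kind)
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix must have no missing entries")
  structure(list(values = values, feature_kind = feature_kind,
                 provenance = provenance), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix (%s): %d proteins x %d contrasts\n",
              x$feature_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Pivot a differential_table to a protein x contrast matrix of one statistic.
.stat_matrix <- function(table, stat) {
  proteins <- unique(table$protein_id)
  contrasts <- unique(table$contrast)
  m <- matrix(NA_real_, length(proteins), length(contrasts),
              dimnames = list(proteins, contrasts))
  m[cbind(match(table$protein_id, proteins),
          match(table$contrast, contrasts))] <- table[[stat]]
  if (anyNA(m)) m[is.na(m)] <- if (stat == "fdr") 1 else 0
  m
}

#' Depletion filter (log2 fold-change rule)
#'
#' Retains proteins showing a significant decrease — log2 fold change at or
#' below `log2fc_cutoff` (default -2, i.e. a 4-fold loss) with FDR at or
#' below `fdr_cutoff` — in at least one contrast, and emits their log2
#' fold changes over all contrasts as the Mapper feature matrix.
#'
#' @param table a `differential_table`.
#' @param log2fc_cutoff inclusive log2FC threshold, default -2.
#' @param fdr_cutoff inclusive FDR threshold, default 0.05.
#' @return a `feature_matrix` with `feature_kind = "log2fc"`.
#' @export
depletion_filter <- function(table, log2fc_cutoff = -2, fdr_cutoff = 0.05) {
  if (!nrow(table)) stop("differential table is empty")
  lfc <- .stat_matrix(table, "log2fc")
  fdr <- .stat_matrix(table, "fdr")
  hit <- lfc <= log2fc_cutoff & fdr <= fdr_cutoff
  keep <- rownames(lfc)[rowSums(hit) >= 1]
  feature_matrix(lfc[keep, , drop = FALSE], "log2fc",
                 provenance = list(filter = "depletion",
                                   log2fc_cutoff = log2fc_cutoff,
                                   fdr_cutoff = fdr_cutoff,
                                   n_retained = length(keep),
                                   n_tested = nrow(lfc),
                                   imputed = any(table$undefined)))
}

#' Z-score filter
#'
#' Retains proteins with Z at or above `z_cutoff` and FDR at or below
#' `fdr_cutoff` in at least one contrast (both thresholds inclusive), and
#' emits their Z scores over all contrasts as the Mapper feature matrix.
#'
#' @param table a `differential_table`.
#' @param z_cutoff inclusive Z threshold, default 2.
#' @param fdr_cutoff inclusive FDR threshold, default 0.05.
#' @return a `feature_matrix` with `feature_kind = "zscore"`.
#' @export
zscore_filter <- function(table, z_cutoff = 2, fdr_cutoff = 0.05) {
  if (!nrow(table)) stop("differential table is empty")
  z <- .stat_matrix(table, "z")
  fdr <- .stat_matrix(table, "fdr")
  hit <- z >= z_cutoff & fdr <= fdr_cutoff
  keep <- rownames(z)[rowSums(hit) >= 1]
  feature_matrix(z[keep, , drop = FALSE], "zscore",
                 provenance = list(filter = "zscore", z_cutoff = z_cutoff,
                                   fdr_cutoff = fdr_cutoff,
                                   n_retained = length(keep),
                                   n_tested = nrow(z),
                                   imputed = any(table$undefined)))
}
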