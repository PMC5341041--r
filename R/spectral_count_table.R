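#' Spectral count table
#'
#' The raw input of the pipeline: an integer prey-by-run matrix of spectral
#' counts, per-protein sequence lengths (amino acids), and per-run metadata
#' describing bait, genotype or treatment, replicate and role.
#'
#' @param counts non-negative integer matrix, proteins in rows, runs in
#'   columns. Row names are protein ids, column names run ids.
#' @param lengths positive integer vector of protein lengths (amino acids),
#'   one per row of `counts`.
#' @param run_meta data.frame with one row per run and columns `run_id`,
#'   `bait`, `genotype_or_treatment`, `replicate_index`, `role`. `role` must
#'   be one of `"wildtype"`, `"control"`, `"perturbed"`.
#'
#' @return An object of class `spectral_count_table`: a list with elements
#'   `counts` (integer matrix), `lengths` (named integer vector),
#'   `protein_ids`, and `run_meta`.
#' @export
spectral_count_table <- function(counts, lengths, run_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have protein ids as rownames and run ids as colnames")
  protein_ids <- rownames(counts)
  if (anyDuplicated(protein_ids))
    stop("duplicate protein_id: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate run_id in count matrix")
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage) || any(storage < 0) || any(storage != round(storage))) {
    bad <- which(is.na(storage) | storage < 0 | storage != round(storage))[1L]
    idx <- arrayInd(bad, dim(counts))
    stop(sprintf("non-negative integer count required at protein '%s', run '%s'",
                 protein_ids[idx[1L]], colnames(counts)[idx[2L]]))
  }
  mode(counts) <- "integer"

  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts))
    stop("lengths must have one entry per protein")
  if (anyNA(lengths) || any(lengths <= 0) || any(lengths != round(lengths)))
    stop("all protein lengths must be positive integers")
  lengths <- as.integer(lengths)
  names(lengths) <- protein_ids

  run_meta <- validate_run_manifest(run_meta)
  missing_runs <- setdiff(colnames(counts), run_meta$run_id)
  if (length(missing_runs))
    stop("runs absent from manifest: ", paste(missing_runs, collapse = ", "))
  run_meta <- run_meta[match(colnames(counts), run_meta$run_id), , drop = FALSE]
  rownames(run_meta) <- NULL

  structure(
    list(counts = counts, lengths = lengths, protein_ids = protein_ids,
         run_meta = run_meta),
    class = "spectral_count_table"
  )
}

#' @export
print.spectral_count_table <- function(x, ...) {
  cat(sprintf("spectral_count_table: %d proteins x %d runs\n",
              nrow(x$counts), ncol(x$counts)))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$run_meta$role)),
                              table(x$run_meta$role)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_count_table <- function(x) dim(x$counts)

.manifest_cols <- c("run_id", "bait", "genotype_or_treatment",
                    "replicate_index", "role")
.run_roles <- c("wildtype", "control", "perturbed")

validate_run_manifest <- function(run_meta) {
  run_meta <- as.data.frame(run_meta, stringsAsFactors = FALSE)
  missing <- setdiff(.manifest_cols, names(run_meta))
  if (length(missing))
    stop("run manifest missing column(s): ", paste(missing, collapse = ", "))
  run_meta <- run_meta[, .manifest_cols, drop = FALSE]
  if (anyDuplicated(run_meta$run_id))
    stop("duplicate run_id in manifest: ",
         paste(unique(run_meta$run_id[duplicated(run_meta$run_id)]),
               collapse = ", "))
  if (!all(run_meta$role %in% .run_roles))
    stop("manifest role must be one of: ", paste(.run_roles, collapse = ", "))
  run_meta$replicate_index <- as.integer(run_meta$replicate_index)
  run_meta
}

#' Select run ids by role and/or genotype
#'
#' Convenience selector over the run manifest.
#'
#' @param x a `spectral_count_table`.
#' @param role optional role filter (`"wildtype"`, `"control"`, `"perturbed"`).
#' @param genotype optional genotype_or_treatment filter.
#' @param bait optional bait filter.
#' @return character vector of run ids.
#' @export
runs_by <- function(x, role = NULL, genotype = NULL, bait = NULL) {
  stopifnot(inherits(x, "spectral_count_table"))
  m <- x$run_meta
  keep <- rep(TRUE, nrow(m))
  if (!is.null(role)) keep <- keep & m$role %in% role
  if (!is.null(genotype)) keep <- keep & m$genotype_or_treatment %in% genotype
  if (!is.null(bait)) keep <- keep & m$bait %in% bait
  m$run_id[keep]
}
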