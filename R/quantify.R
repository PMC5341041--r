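#' Distributed normalized spectral abundance factors (dNSAF)
#'
#' Converts spectral counts to relative abundances. Per run, each protein's
#' length-normalized count S_i/L_i is divided by the run total of
#' length-normalized counts, so abundances are dimensionless fractions that
#' sum to 1 over detected proteins. With no shared counts this is the NSAF.
#' Spectra shared between proteins of a group are first distributed to each
#' member proportionally to its unique counts in that run
#' (d_i = shared x u_i / sum(u)); a group with zero unique counts splits
#' its shared spectra uniformly.
#'
#' @param counts a [spectral_count_table()] of unique (uniquely assigned)
#'   spectral counts.
#' @param shared_map optional list describing shared spectra; each element is
#'   `list(proteins = <ids>, shared = <per-run numeric vector or scalar>)`.
#' @return numeric matrix of dNSAF values with the axes of `counts`
#'   (class `abundance_table`). Runs with no spectra at all give a column
#'   of zeros with a warning.
#' @export
compute_dnsaf <- function(counts, shared_map = NULL) {
  stopifnot(inherits(counts, "spectral_count_table"))
  S <- counts$counts * 1.0
  if (!is.null(shared_map)) {
    for (entry in shared_map) {
      ids <- entry$proteins
      if (!all(ids %in% counts$protein_ids))
        stop("shared_map references unknown protein(s): ",
             paste(setdiff(ids, counts$protein_ids), collapse = ", "))
      shared <- entry$shared
      if (length(shared) == 1L) shared <- rep(shared, ncol(S))
      if (length(shared) != ncol(S))
        stop("shared counts must be scalar or one value per run")
      u <- S[ids, , drop = FALSE]
      tot <- colSums(u)
      for (j in seq_len(ncol(S))) {
        frac <- if (tot[j] > 0) u[, j] / tot[j]
                else rep(1 / length(ids), length(ids))
        S[ids, j] <- S[ids, j] + shared[j] * frac
      }
    }
  }
  saf <- S / counts$lengths
  run_tot <- colSums(saf)
  if (any(run_tot == 0))
    warning("run(s) with no spectra: ",
            paste(colnames(S)[run_tot == 0], collapse = ", "))
  dnsaf <- sweep(saf, 2, ifelse(run_tot > 0, run_tot, 1), "/")
  class(dnsaf) <- c("abundance_table", class(dnsaf))
  dnsaf
}

#' Mean dNSAF over a run subset
#'
#' Arithmetic mean of each protein's abundance over the selected runs;
#' zeros (non-detections) are included in the mean, mirroring spectral
#' counting semantics where absence is a measured zero.
#'
#' @param abundance an `abundance_table` from [compute_dnsaf()].
#' @param runs non-empty character vector of run ids (columns).
#' @return named numeric vector of per-protein means.
#' @export
mean_abundance <- function(abundance, runs) {
  if (!length(runs)) stop("run subset must be non-empty")
  missing <- setdiff(runs, colnames(abundance))
  if (length(missing))
    stop("unknown run(s): ", paste(missing, collapse = ", "))
  rowMeans(unclass(abundance)[, runs, drop = FALSE])
}
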