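# Fixture builders shared across test files. Everything is generated in
# code; no data files.

toy_manifest <- function(run_ids, roles = NULL, baits = "B1",
                         genotypes = "WT") {
  n <- length(run_ids)
  data.frame(run_id = run_ids,
             bait = rep_len(baits, n),
             genotype_or_treatment = rep_len(genotypes, n),
             replicate_index = seq_len(n),
             role = if (is.null(roles)) rep("wildtype", n)
                    else rep_len(roles, n),
             stringsAsFactors = FALSE)
}

toy_count_table <- function(counts, lengths = NULL, roles = NULL,
                            genotypes = "WT") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("P", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("run", seq_len(ncol(counts)))
  if (is.null(lengths)) lengths <- rep(100L, nrow(counts))
  spectral_count_table(counts, lengths,
                       toy_manifest(colnames(counts), roles,
                                    genotypes = genotypes))
}

# Two groups of anti-correlated alternating profiles with small noise.
anticorrelated_features <- function(n_per_group = 20, n_col = 6,
                                    noise = 0.05, seed = 1) {
  set.seed(seed)
  a <- rep(c(1, 0), length.out = n_col)
  b <- rep(c(0, 1), length.out = n_col)
  X <- rbind(
    matrix(rep(a, n_per_group), ncol = n_col, byrow = TRUE),
    matrix(rep(b, n_per_group), ncol = n_col, byrow = TRUE)
  ) + matrix(rnorm(2 * n_per_group * n_col, 0, noise), ncol = n_col)
  rownames(X) <- c(paste0("A", seq_len(n_per_group)),
                   paste0("B", seq_len(n_per_group)))
  X
}

noisy_circle <- function(n = 100, noise = 0.05, seed = 1) {
  set.seed(seed)
  theta <- sort(runif(n, 0, 2 * pi))
  X <- cbind(cos(theta), sin(theta)) + matrix(rnorm(2 * n, 0, noise),
                                              ncol = 2)
  rownames(X) <- paste0("pt", seq_len(n))
  X
}

# Independent step-up oracle for Benjamini-Hochberg adjusted values.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Contingency-table adjusted Rand index, straight from the definition.
brute_force_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Default deletion-network pipeline configuration used by recovery tests:
# uniform covers at base 30 / fragment 45, gain 3.
recovery_config <- function(seed, out_dir = tempfile()) {
  list(mode = "deletion", simulate = TRUE, seed = seed, out_dir = out_dir,
       base = list(resolution = 30, gain = 3, equalized = FALSE),
       fragment = list(resolution = 45, gain = 3, equalized = FALSE))
}
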