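---
title: "Detecting topological network modules in perturbed AP-MS networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting topological network modules in perturbed AP-MS networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnmapper)
```

## The problem

Affinity purification coupled to mass spectrometry (AP-MS) measures which
prey proteins co-purify with a tagged bait, and in what amounts (spectral
counts). Perturbing the system — deleting individual subunits of a
complex, or treating cells with a drug — and re-purifying reveals the
*modular* organisation of the interaction network: groups of subunits that
are lost together define structural modules, and proteins whose levels
shift together across many perturbations share a functional response.

`tnmapper` implements a topology-based analysis of such perturbation
panels. Filtered per-protein response profiles (log2 fold changes or Z
scores across perturbations) are embedded with the Mapper construction: a
network whose nodes are clusters of proteins with similar profiles and
whose edges record cluster overlap. Built at a coarse cover resolution the
network shows the global shape of the perturbed interactome; rebuilt at a
higher resolution it fragments into connected components we call
**topological network modules (TNMs)**, which are then superimposed back
onto the coarse network to show where each module lives and which modules
are linked.

## Pipeline overview

1. **Quantitation** — spectral counts to dNSAF (`compute_dnsaf()`).
2. **Control specificity** — drop preys not enriched over mock controls
   (`control_specificity_filter()`).
3. **Differential statistics** — per-contrast log2 fold change, Z and FDR
   from a Poisson/Wald contrast (`differential_table()`), or an imported
   table from external software (`read_external_differential()`).
4. **Feature filter** — `depletion_filter()` (deletion panels, log2FC
   ≤ −2 and FDR ≤ 0.05 in ≥ 1 contrast) or `zscore_filter()`
   (drug panels, Z ≥ 2 and FDR ≤ 0.05).
5. **Mapper** — `build_mapper_graph()` at base and fragmenting
   resolution.
6. **Modules** — `extract_tnms()`, `superimpose()`, `tnm_summary()`.

`run_pipeline()` drives all stages from a validated YAML config; two
ready-made recipes ship in `inst/extdata/`.

## Quantitation: dNSAF

For protein $i$ with length $L_i$ and spectral count $S_i$ in a run,

$$\mathrm{NSAF}_i = \frac{S_i/L_i}{\sum_j S_j/L_j},$$

so each run's abundances are length-corrected fractions summing to 1.
When spectra are shared between the proteins of a group, the *distributed*
variant first allocates the shared count to each member in proportion to
its unique spectra ($d_i = s \cdot u_i / \sum_k u_k$, uniform when the
group has no unique evidence), then normalizes as above. Non-detections
are zeros, not missing values — in spectral counting, absence is a
measurement.

## Differential statistics

The package approximates a hierarchical-Bayes spectral-count test with a
summed-count Poisson/Wald contrast: counts are pooled over each arm's
runs, offsets are protein length × arm total counts, and with 0.5
pseudocounts

$$\widehat{\log_2 \mathrm{FC}} =
 \log_2 \frac{(C_T + 0.5)/O_T}{(C_R + 0.5)/O_R}, \qquad
 Z = \frac{\ln 2 \cdot \widehat{\log_2 \mathrm{FC}}}
          {\sqrt{1/(C_T+0.5) + 1/(C_R+0.5)}}.$$

The p value is the one-sided normal tail in the stated direction of
interest (depletion for deletion panels), so it is uniform under the null;
the familiar Z = 2 ⇔ p ≈ 0.02 equivalence holds for `z_to_p()`. FDR is
Benjamini–Hochberg within each contrast. Proteins absent from both arms
are flagged and imputed as log2FC = 0, Z = 0, FDR = 1. Output from a
dedicated external tool can be slotted in unchanged via
`read_external_differential()`, so the filters can be reproduced on
externally computed statistics.

Two filter conventions deserve notes:

* **Control specificity.** The wild-type:control dNSAF ratio is taken as
  `wt / max(ctrl, eps)` with `eps` = 1% of the smallest nonzero wild-type
  mean. Control tables are dominated by zeros; flooring only the
  denominator keeps the intended inclusive boundary (a protein at exactly
  the 4-fold ratio is retained) while making the ratio defined for
  never-detected controls, which are always retained.
* **Drug panels.** The Z filter selects the positive tail (Z ≥ 2). Drug
  treatment typically *depletes* subunits from the purifications, so the
  drug-mode recipe defines each bait's contrast as test = control (DMSO)
  versus reference = treated: proteins lost under treatment then carry
  positive Z. This is a package convention, recorded in the provenance
  block of every run.

## The Mapper engine

**Metrics.** `correlation` is $d = 1 - r$ (Pearson, over feature rows),
bounded in $[0, 2]$; `norm_correlation` is the inner product of
variance-normalized rows, identical for non-degenerate rows and retained
as a separately named metric for clarity; `euclidean` supports testing.
Constant rows have no defined correlation: they get $d = 0$ to
bit-identical rows and $d = 1$ (the uncorrelated value) to all others —
the filters can produce near-constant rows, and this convention places
them "equidistant from everything" rather than undefined.

**Lenses.** The *metric SVD* lens is classical multidimensional scaling:
double-centre $-D^2/2$, keep the two leading non-negative eigenpairs,
scale eigenvectors by $\sqrt{\lambda}$. Under a Euclidean metric this
equals ordinary PCA scores. The *neighborhood* lens builds the symmetric
k-nearest-neighbour graph (default $k = \lceil\sqrt{n}\rceil$) and uses
the eigenvectors of the symmetric normalized Laplacian at the two smallest
nonzero eigenvalues, per connected component; components are laid out side
by side along lens 1 so disconnected groups occupy disjoint intervals.
Both lenses fix eigenvector signs so the largest-magnitude loading is
positive, making runs deterministic. Commercial "neighborhood lens"
constructions are unpublished; this spectral-embedding implementation is
the package's documented stand-in, and no node-level fidelity to any
proprietary layout is claimed.

**Cover.** Per lens dimension, `resolution` base intervals span the data
range — equal-width, or at empirical quantiles when `equalized` ("eq.")
is set — and each interval is expanded about its centre by `gain`, giving
adjacent-interval overlap $1 - 1/\mathrm{gain}$ (gain 3 ⇒ 66.7%).
Two-dimensional bins are the cross product. Interval membership is closed
on both ends; the unexpanded uniform cover (`gain = 1`) uses half-open
intervals (last closed) so it partitions the data exactly. A single
shared resolution is used for both lens dimensions (per-axis override
possible via direct `build_cover()` calls).

**Per-bin clustering.** Each bin is clustered by single linkage, cut at a
scale chosen by a fixed histogram heuristic: pairwise distances are
histogrammed into `n_hist_bins = 10` equal-width bars over
$[0, d_{\max}]$, and the dendrogram is cut at the left edge of the first
empty bar that follows an occupied bar (no gap ⇒ one cluster).
$d_{\max}$ is the *dataset's* largest pairwise distance, not the bin's:
a histogram rescaled to each bin's own diameter is scale-free, and any
tight cluster has internal relative gaps at some magnification — bin-local
scaling was observed to shred structural modules of diameter ~0.01 in a
metric where modules sit ~1.5 apart. Anchoring the candidate cut scales
globally makes "close" mean the same thing in every bin. The bar count is
exposed as a parameter.

**Graph assembly.** One node per cluster (identical clusters arising from
overlapping bins collapse to a single node); an edge joins two nodes
whenever their member sets intersect, weighted by the shared-protein
count. Nodes carry member lists, sizes and mean lens coordinates (used
for colouring). Node order is canonicalized by sorted member ids, so a
fixed input yields a byte-identical graph.

## TNM extraction

TNMs are connected components of the fragment-resolution graph. A
component qualifies when it has ≥ `min_component_nodes` (default 2)
nodes, or when it is a single node carrying ≥ `min_singleton_proteins`
(default 2) proteins — a well-separated structural module can collapse
into exactly one cluster, and a multi-protein isolated node is a module,
not noise. Because Mapper clusters overlap, a protein can appear in nodes
of several components; it is assigned where it occurs in more nodes (ties
to the larger component), since the reported module lists are disjoint.
Everything else — proteins seen only as single-protein clusters — pools
into the final `"disconnected"` module, the analogue of proteins depleted
everywhere that scatter through the network without stable neighbours.
Modules are numbered in decreasing size. The TNM count is emergent from
the fragmenting resolution, never fixed in advance.

`superimpose()` maps each TNM onto the base network (nodes containing ≥ 1
module protein) and reports which module pairs are linked by a shared or
adjacent base node — the module-level connectivity that flat clusterings
cannot provide.

## The synthetic data generator

`simulate_deletion_network()` emulates a deletion panel over a bait-
purified complex: three structural modules (default sizes 4, 5, 6), an
unaffected scaffold group (5 proteins + the bait, boosted 10× for
self-enrichment), 40 low-abundance background preys present in every run
including mock controls, and 4 proteins depleted in *all* perturbations
(the "ubiquitous loss" group that should end up disconnected). The
default design uses two deletion genotypes per module — six perturbed
genotypes, three replicates each, plus wild-type and mock-control
triplicates (24 runs) — reflecting the scale of real deletion panels in
which several deleted subunits collapse the same module. Counts are
Poisson with mean ∝ length × abundance × run depth (default 8,000 spectra
per run), lengths log-uniform on 150–1200 aa, and the depletion factor
defaults to 8; the magnitude of partial subunit loss is not something the
underlying studies pin down, so it is an explicit parameter rather than a
constant. `simulate_drug_network()` produces paired control/treated runs
per bait under the same count model.

What the generator does *not* emulate: count overdispersion beyond
Poisson (real biological replicates vary more), shared-peptide ambiguity
(counts are uniquely assigned, so dNSAF = NSAF in simulations),
correlated background binding, and the long abundance tail of a real
interactome. Pipeline tests passing on these simulations demonstrate that
the machinery recovers planted structure under its stated noise model —
not that any particular biological dataset will fragment into a given
number of modules.

At exactly a 4-fold depletion the estimator is centred on the −2 cutoff,
so about half of truly depleted proteins fall on either side of the
inclusive boundary; detection-rate properties are therefore exercised at
the generator's default 8-fold depletion, where the cutoff sits well
inside the effect distribution.

## Numerical and design choices

* Eigen-decompositions use symmetric solvers; lens values below 1e-12 are
  zeroed to quench sign jitter; kNN ties break by index for determinism.
* Quantile covers use type-7 empirical quantiles.
* `bh_fdr()`, single-linkage dendrograms, k-means (Hartigan–Wong,
  10 restarts), silhouettes and the adjusted Rand index are delegated to
  `stats`, `cluster` and `mclust`; the Mapper engine, dNSAF, the
  Poisson/Wald contrast, the filters and the TNM logic are implemented
  in-package.
* Baseline comparisons follow convention: Ward linkage (`ward.D2`) on
  Pearson-correlation distance, and k-means with k selected by maximal
  mean silhouette width on Euclidean dissimilarities — automated argmax
  with the full k-vs-silhouette table returned for inspection.
* Problem sizes in the test-suite and acceptance runs: simulated panels
  of ~65 proteins × 24 runs, Mapper instances of 5–100 points, 11
  simulation seeds for end-to-end recovery, 20 for null calibration.

## Worked example

```{r example, eval = FALSE}
library(tnmapper)

sim <- simulate_deletion_network(simulation_config(seed = 1))
res <- run_pipeline(list(
  mode = "deletion", simulate = TRUE, seed = 1, out_dir = "ino80_out",
  base = list(resolution = 30, gain = 3, equalized = FALSE),
  fragment = list(resolution = 45, gain = 3, equalized = FALSE)),
  counts = sim$counts, truth = sim$truth)

res$summary$counts   # per-TNM protein counts
res$summary$ari      # agreement with the planted modules
```

## Limitations

* The Mapper construction is unsupervised and resolution-dependent; the
  base/fragment resolutions are analysis choices, and module counts
  should be read as descriptive, not inferential.
* The Poisson/Wald contrast ignores replicate-level variance components;
  for panels with strong biological overdispersion, import statistics
  from a dedicated tool instead.
* Functional enrichment of modules is out of scope; `export_protein_lists()`
  writes per-module protein lists for external enrichment services, and
  `biogrid_overlap()` counts within-module pairs of a user-supplied
  interaction list.
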