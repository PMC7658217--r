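# diffproj

Adaptive diffusion embedding, clustering and trajectory analysis for
single-cell RNA-seq data, in R.

`diffproj` is for computational biologists who want to go from a sparse
cell×gene count matrix to an interpretable picture of cellular structure:
which discrete states exist, what genes mark them, how cells order along
differentiation continua, where those continua branch, and which states
are terminal. It implements a diffusion-based manifold approximation and
projection workflow and every standard stage around it, exercisable
entirely on built-in simulators with ground truth — no external data
required.

## The method

The core estimator, `dbmap()`, builds a density-adaptive Gaussian kernel
on the exact kNN graph of the cells (per-cell bandwidth σᵢ = distance to
the ⌈K/2⌉-th neighbor; *w*ᵢⱼ = exp(−dᵢⱼ²/σᵢ²), symmetrized), applies the
anisotropic normalization *W̃*ᵢⱼ = *W*ᵢⱼ/(qᵢᵅ qⱼᵅ) with α = 1 — the
Laplace–Beltrami limit, which decouples manifold geometry from sampling
density — and row-normalizes into a Markov diffusion operator *P*. Its top
*N* eigenvectors, weighted by λ/(1−λ) (the closed-form sum of a
component's contribution over random walks of every length), are the
**multiscale diffusion components**; the number of *structure components*
carrying signal is chosen at the largest eigengap. Downstream:

* `embed_layout()` — 2-D/3-D UMAP layout of the selected components, with
  minimum distance `M` and scale `S`; seed-stable, spectral initialization.
* `cluster_cells()` / `snn_graph()` + `cluster_snn()` — shared-nearest-
  neighbor Jaccard graph and Louvain modularity clustering (resolution 0.8
  by default, 0.3 for coarse main types), singletons removed.
* `rank_markers()` — one-vs-rest Wilcoxon rank-sum tests (exact by
  enumeration for small groups, tie-corrected normal approximation
  otherwise), natural-log fold changes, BH adjustment, `top_markers()` for
  the top-2-per-cluster view; `dotplot_stats()` for panel summaries;
  `flag_doublet_clusters()` for marker-absence doublet candidates.
* `score_cell_cycle()` — S and G2/M module scores against
  expression-matched control sets; G1 iff both scores ≤ 0.
* `run_trajectory()` — waypoint-refined pseudotime from a start cell,
  automatic (overridable) terminal-state detection at the component
  extrema, absorbing-Markov-chain branch probabilities and
  differentiation entropy; `impute_diffusion()` (Pᵗ · expression) and
  `gene_trends()` for branch-weighted expression dynamics.
* `simulate_cluster_counts()`, `simulate_branching_counts()`,
  `make_noisy_circle()`, `make_gaussian_mixture()`, `inject_doublets()` —
  negative-binomial simulators with ground-truth labels, pseudotime,
  planted markers and doublet flags.
* `read_mtx_dir()` / `write_mtx_dir()` — 10x-style Matrix Market
  directories (plain or gzip, either orientation), plus dense TSV tables,
  gene-set files and key=value run configuration.

## Worked example

```r
library(diffproj)

sim <- simulate_branching_counts(3000, 1500, n_branches = 3, seed = 5)
pp  <- preprocess(sim$counts, run_config(list(preprocess = list(n_hvg = 800))))
sp  <- dbmap(pp$scaled$values, N = 30, K = 15)
summary(sp)
#> Diffusion embedding of 3000 cells
#>   components computed: 29, selected by eigengap: 3
#>   nontrivial eigengaps: 0.0041, 0.0367, 0.2156, 0.0323, 0.0167, 0.0043, 0.0036, 0.0048

tr <- run_trajectory(sp, start_cell = which.min(sim$truth$pseudotime_true))
tr
#> trajectory_result: 3000 cells, start cell 459, 3 terminal state(s)
#>   terminal cells: 173, 1915, 2601
#>   entropy: median 0.000, max 1.098 (bound ln(3) = 1.099)

cor(tr$pseudotime, sim$truth$pseudotime_true, method = "spearman")
#> [1] 0.915
```

The eigengap after three nontrivial components mirrors the three simulated
lineage branches; the three detected terminal cells sit one per true leaf,
the transient branch-point cells carry entropy near the ln 3 bound while
terminal cells have entropy exactly 0, and the estimated ordering
correlates at ρ ≈ 0.92 with the simulated depth. `plot(sp)` (or
`plot(embed_layout(sp))`) draws the 2-D layout, optionally colored by
cluster labels or by a gene with a fixed color threshold.

A command-line interface over the same functions ships in
`inst/cli/diffproj.R`:

```sh
Rscript inst/cli/diffproj.R simulate --kind branches --n 3000 --genes 1500 --seed 5 --outdir sim
Rscript inst/cli/diffproj.R preprocess --counts sim --n-hvg 800 --outdir pp
Rscript inst/cli/diffproj.R embed --input pp/scaled.tsv --n-components 30 --knn 15 --layout --outdir em
Rscript inst/cli/diffproj.R cluster --components em/components.tsv --outdir cl
Rscript inst/cli/diffproj.R markers --counts pp/filtered --clusters cl/clusters.tsv --top 2 --outdir mk
Rscript inst/cli/diffproj.R trajectory --components em/components.tsv --start-cell cell_00459 --outdir tr
```

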