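# lssd

Cell clustering for scRNA-seq by **l**ocal-**s**caling **s**elf-**d**iffusion:
denoise the cell–cell similarity graph, then cluster on the denoised graph.

scRNA-seq count matrices are sparse, noisy and high-dimensional, and plain
Euclidean (or cosine) similarity between cells is unstable there. `lssd`
attacks the problem at the graph level:

1. **Self-tuned affinity.** Each cell *i* gets a local bandwidth
   `σᵢ = d(i, k-th nearest neighbour)` (default k = 5), and the affinity is
   `W(i,j) = exp(−d²(i,j) / σᵢσⱼ)`. The kernel adapts to local density and
   is exactly invariant to a uniform rescaling of the input.
2. **Self-diffusion.** With `P` the affinity restricted to each cell's
   `K_nn` strongest neighbours and row-normalized, iterate
   `S_{t+1} = τ·Sₜ·P + (1−τ)·I` from `S₀ = W` (defaults `t = 4`,
   `τ = 0.8`, `K_nn = min(30, n−1)`). Similarity mass accumulates along
   reliable within-cluster paths; weak noisy edges fade.
3. **Spectral clustering** (normalized cut, k-means on row-normalized
   Laplacian eigenvectors) on the symmetrized diffused graph. The number of
   clusters can be estimated automatically by rotating the top eigenvectors
   toward an indicator matrix and minimizing the separation cost
   `J = Σᵢ Σⱼ Z²ᵢⱼ / maxⱼ|Zᵢⱼ|²`.

The package also ships NMI/ARI concordance metrics, a grouped
negative-binomial count simulator with dropout (so every experiment runs
without downloads), readers/writers for dense TSV/CSV and 10x-style Matrix
Market triplet directories, and a small command-line front end.

## Worked example

```r
library(lssd)

# simulate 600 cells, 1,000 genes, 6 groups with known labels
sim <- simulate_counts(sim_params(600, 1000, 6, seed = 1))

# full pipeline with automatic cluster-number estimation
cl <- lssd_cluster(sim$counts, cmin = 2, cmax = 12, log1p = TRUE, seed = 0)
cl$curve$chosen_C
#> [1] 6
table(cluster = cl$labels, truth = sim$labels)   # one group per cluster
nmi(cl$labels, sim$labels)
#> [1] 1
ari(cl$labels, sim$labels)
#> [1] 1
```

Step by step, the same run is:

```r
W <- affinity_graph(log1p_transform(sim$counts), k_scale = 5)
P <- build_transition(W)                  # K_nn = min(30, n-1)
S <- symmetrize(self_diffuse(W, P, t = 4, tau = 0.8))
est <- estimate_C(S, C_min = 2, C_max = 12)  # separation-cost curve
cl  <- spectral_cluster(S, C = est$chosen_C, seed = 0)
```

`est$J_values` holds the separation-cost curve over candidate C for
inspection; `cl$labels` are integer labels in first-appearance order.

From a shell, the same pipeline over files:

```sh
Rscript inst/scripts/lssd simulate --cells 600 --genes 1000 --groups 6 --seed 1 --out sim/
Rscript inst/scripts/lssd cluster sim/ --log1p --cmin 2 --cmax 12 --report --out run/
Rscript inst/scripts/lssd eval run/labels.tsv sim/truth_labels.tsv
```

## Vignette

`vignettes/lssd-methods.Rmd` documents the model, every tunable parameter
with its default and rationale, what the simulator does and does not
emulate, the numerical corner cases, and known limitations of the
cluster-number estimate.
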