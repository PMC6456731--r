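# scdmm — hierarchical Dirichlet-multinomial clustering of multi-individual single-cell UMI counts

`scdmm` clusters droplet-based scRNA-seq UMI count matrices collected from
**multiple individuals at once**, for analysts who want one-step joint
clustering instead of a batch-correct-then-cluster pipeline. Donor-to-donor
heterogeneity — unequal depths, library chemistry, genuine biological
variation — is part of the model rather than a nuisance scrubbed away
beforehand.

## The model

Cell *j* of individual *l* has UMI counts
*x*<sub>·jl</sub> ~ Multinomial(*T*<sub>jl</sub>, *p*<sub>·jl</sub>), and
given its latent cell type *z*<sub>jl</sub> = *k* the probability vector is
*p*<sub>·jl</sub> ~ Dirichlet(*α*<sub>·lk</sub>). Integrating *p* out gives
the collapsed Dirichlet-multinomial likelihood

P(x | z = k, α) = (T! / ∏ᵢ xᵢ!) · ∏ᵢ [Γ(xᵢ + αᵢₗₖ) / Γ(αᵢₗₖ)] · Γ(|α·ₗₖ|) / Γ(T + |α·ₗₖ|),

and the hierarchy α<sub>ilk</sub> ~ LN(μ<sub>ik</sub>, σ²<sub>ik</sub>)
ties each cell type's per-individual concentrations to a shared profile
μ<sub>ik</sub>, with σ²<sub>ik</sub> quantifying individual-level
heterogeneity (Gamma hyper-prior shared across genes). Inference is
Metropolis-within-Gibbs over labels, concentrations, hyper-parameters and
per-individual mixing proportions; a closed-form supervised mode trains on
a per-individual subset of cells and classifies the rest as
P(z = k | x) ∝ DM(x | α̂<sub>·lk</sub>) π̂<sub>lk</sub>. Details are in the
methods vignette (`vignettes/hierarchical-dm-clustering.Rmd`).

The package also ships a model-based simulator, 10x-style MTX and dense
text input, the standard preprocessing steps (low-expression filter,
highly-variable-gene selection), evaluation metrics (adjusted Rand index,
matched accuracy, APN stability, silhouette, AIC/BIC) and a command-line
interface.

## Worked example

```r
library(scdmm)

# simulate 4 donors x 150 cells, 100 genes, 3 cell types,
# individual-level heterogeneity sigma^2 = 0.1
cfg <- simulation_config(G = 100, K = 3, L = 4, cells_per_individual = 150,
                         sigma2 = 0.1, separation = 2, seed = 42)
sim <- simulate_dataset(cfg)
sim$dataset
#> count_dataset: 100 genes, 4 individuals, 600 cells total
#> cells per individual: 150, 150, 150, 150

res <- run_mcmc(sim$dataset,
                sampler_config(K = 3, n_iter = 300, burn_in = 100, seed = 42))
res
#> clustering_result: K = 3, 600 cells, 4 individuals
#>   300 sweeps (100 burn-in); alpha acceptance 0.67
#>   cluster sizes: 194, 194, 212

evaluation_report(unlist(res$final_labels), truth = unlist(sim$true_labels),
                  posterior = res$posterior, result = res,
                  dataset = sim$dataset)
#> evaluation_report
#>   ari              1
#>   accuracy         1
#>   aic              283314.6
#>   bic              288626.1
#>   n_vague          0
```

The inferred partition matches the generating cell types exactly
(ARI = accuracy = 1); no cell is "vague" (largest posterior cluster
probability below 0.95); AIC/BIC are the plug-in criteria used by
`scan_k()` to choose the number of clusters.

The same workflow from a shell:

```sh
scdmm simulate --config sim.yaml --seed 42 --out simdir
scdmm cluster simdir/ind1 simdir/ind2 --k 3 --seed 42 --out clusdir
scdmm evaluate clusdir/labels.tsv --truth simdir/truth_labels.tsv --out evaldir
scdmm classify newdir/ind1 --params clusdir/params.json --out clsdir
```

Every run writes a `manifest.json` (seed, options, version) from which it
can be reproduced; `--scan-k MIN:MAX` sweeps the cluster number and
reports AIC/BIC; `--train-fraction` below 1 switches `cluster` to the
supervised mode.

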