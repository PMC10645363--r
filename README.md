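# cloneCNA

Joint inference of **copy-number clones** from single-cell RNA-seq and
ATAC-seq counts. Tumours are mixtures of clones that differ by copy number
alterations (CNAs); because DNA dosage is a linear predictor of both
transcription and chromatin accessibility, those clones leave a footprint in
both assays. `cloneCNA` clusters cells into clones and infers each clone's
integer copy-number profile per genomic segment, from either independent
RNA/ATAC assays or a multiome assay measuring both in the same cells.

It is aimed at analysts with per-cell count matrices (10x-style MatrixMarket
triplets or pre-aggregated cells-by-segments tables) and a genome
segmentation (BED; chromosome arms or a bulk-derived profile), who want a
probabilistic clone decomposition rather than per-cell CNA scores.

## Model

For cell *n* and segment *i*, counts are Negative Binomial with mean linear
in the latent copy number:

```
x[n,i] | z_n = k  ~  NB( mean = rho_n * theta_i * sum_h Phi[k,i,h] * h ,  size = r_i )
```

with `rho_n` the observed library-size factor, `theta_i` a learnt
counts-per-copy rate, `r_i` a learnt NB size, and `Phi[k,i,·]` the
probability of each copy state `h = 1..H` in clone *k* (Dirichlet prior
skewed to the expected ploidy: 0.6 on the expected state, 0.1 elsewhere).
Marginalising `z` gives a K-component mixture per modality; the modalities
share `Phi` and are combined with a shrinkage weight:

```
L = lambda * L_RNA + (1 - lambda) * L_ATAC ,   lambda in [0,1], default 0.5
```

Fitting is stochastic variational inference (Adam) with a Gumbel-Softmax
relaxation of the categorical copy states plus an exact discrete refinement
sweep; responsibilities are computed exactly by enumeration. The number of
clones is selected by BIC (default), AIC or ICL. A clone-tree simulator and
an ARI/MAE evaluation module make the whole pipeline testable end to end.
See the vignette (`vignettes/clone-inference.Rmd`) for the full account.

## Worked example

```r
library(cloneCNA)

# simulate 3 clones, 20 segments, 300 cells per modality
sim <- simulate_dataset(K = 3, I = 20, n_rna = 300, n_atac = 300, seed = 7)

prior <- default_prior(rep(2, 20), H = 4, segment_ids = sim$rna$segment_ids)
cfg <- fit_config(K_range = 1:6, lam = 0.5, steps = 400, restarts = 2,
                  seed = 7, mode = "flat")
sel <- select_model(sim$rna, sim$atac, prior, cfg)
sel$best_K
#> [1] 3
evaluate_fit(sel$best_fit, sim)
#> <evaluation_report> ARI 0.906 (RNA 0.859, ATAC 0.955) | MAE 0.133
```

The report reads: the BIC-selected fit recovers the simulated clone
memberships with adjusted Rand index 0.906 over all 600 cells, and after
optimally matching inferred clusters to true clones the integer copy numbers
are off by 0.133 copies per clone-segment on average. `sel$table` holds one
row per candidate K with log-likelihood, parameter count and BIC/AIC/ICL;
`sel$best_fit$map_cn` is the clusters-by-segments integer profile matrix.

A command-line wrapper with `simulate | fit | benchmark | evaluate`
subcommands is installed at `inst/cli/clonecna`:

```sh
Rscript inst/cli/clonecna simulate --K 3 --seed 7 --outdir sim_out
Rscript inst/cli/clonecna fit --rna sim_out/rna_counts.tsv \
    --atac sim_out/atac_counts.tsv --kmin 1 --kmax 6 --seed 7 --outdir fit_out
```

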