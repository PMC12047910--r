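# transst

Transfer learning for clustering spatial transcriptomics data.

Spatial transcriptomics measures the transcriptome at spatially
resolved capture spots, but limited resolution and sequencing depth
make it hard to recover cell-level structure from one tissue section
alone. Meanwhile, labeled expression data for related tissue —
annotated scRNA-seq atlases, or other sections from the same study —
are often abundant. `transst` is for analysts who want to use that
external, labeled information to sharpen the clustering of a new,
unlabeled spatial dataset.

## The method

Three steps, each exposed as a plain R function:

1. **Supervised factor learning** (`fit_pldr`). On the labeled source
   $X_{src} \in \mathbb{R}^{n_1 \times p}$, fit by EM the factor model

   $$x_i = W_0 u_i + \epsilon_i,\quad \epsilon_i \sim N(0,\Lambda),\quad
     u_i \mid z_i = k \sim N(\mu_k, \Sigma_k),$$

   with known class labels $z_i$, learning the loading
   $\hat W_0 \in \mathbb{R}^{p \times q}$.

2. **Adaptive transfer** (`fit_transfer`, `select_lambda`). On the
   unlabeled target $X_{tgt} \in \mathbb{R}^{n_0 \times p}$, estimate
   factors $V$ and loading $W$ by alternating least squares on

   $$\sum_{i=1}^{n_0} \lVert x_{tgt,i} - W v_i\rVert_2^2
     + \lambda \lVert W - \hat W_0\rVert_F^2,$$

   with $\lambda$ picked by two-fold held-out reconstruction, so the
   amount of transfer adapts to how useful the source actually is.

3. **Spatial mixture clustering** (`build_knn_graph`, `fit_spgmm`,
   `select_K`). Cluster the target factors with a Gaussian mixture
   whose labels carry a Potts Markov-random-field prior over the
   5-nearest-neighbor graph of the spot coordinates,

   $$f(z) \propto \exp\Big\{-\tfrac12\textstyle\sum_i\sum_{i' \in N_i}
     \beta\,(1 - I\{z_i = z_{i'}\})\Big\},$$

   fitted by ICM-EM, with the smoothing $\beta \in [0,1]$ chosen by a
   pseudo-likelihood line search ($\beta = 0$ recovers a plain GMM)
   and, when K is unknown, a BIC-type criterion over a K range.

A lattice benchmark simulator (`simulate_dataset`: Potts labels,
cluster-conditional Gaussian factors, designated marker genes),
evaluation helpers (`adjusted_rand_index`, `rank_markers`,
`k_error`), and an orchestrated pipeline (`run_pipeline`) round out
the package. See `vignettes/transst-methods.Rmd` for the modeling
details and design choices.

## Worked example

Simulate a paired source/target benchmark and run the full pipeline:

```r
library(transst)

cfg <- sim_config(height = 20, width = 20, n1 = 1000, p = 100,
                  q = 6, seed = 42)
d   <- simulate_dataset(cfg)

rc  <- run_config(d$source$expr, d$source$labels, d$target, d$coords,
                  q = 6, n_hvg = 100, normalize = FALSE, K = 4, seed = 1)
res <- run_pipeline(rc, true_labels = d$target_labels)
res
#> run_result: n0 = 400 , K = 4 , beta = 1 , lambda = 2465, ARI = 0.499
```

The report says the 400 target spots were clustered into the
requested K = 4 groups; the $\lambda$ CV settled on a strong pull
toward the source loading, the line search chose maximal spatial
smoothing $\beta = 1$ (the simulated label field is strongly
clumped), and the clustering recovers the ground truth with adjusted
Rand index 0.499 at this deliberately small problem size.

Marker detection on the fitted clusters (cluster ids are arbitrary;
in this draw genes 1–3 and the 4–10 block are the planted markers):

```r
head(top_markers(rank_markers(d$target, res$labels), n = 2), 8)
#>     cluster gene_id statistic    lfc  p_value p_adjusted rank
#> 8         1  gene_8     25646  0.607 2.16e-12   2.16e-10    1
#> 2         1  gene_2     10481 -1.410 9.09e-12   4.55e-10    2
#> 102       2  gene_2     32368  2.979 3.60e-46   3.60e-44    1
#> 101       2  gene_1     10217 -1.220 1.14e-10   5.71e-09    2
#> 201       3  gene_1     27164  2.413 3.18e-33   3.18e-31    1
#> 202       3  gene_2      8951 -1.339 9.35e-10   4.68e-08    2
#> 303       4  gene_3     12606  2.647 4.87e-16   4.87e-14    1
#> 352       4 gene_52     4390  -0.374 1.12e-04   5.62e-03    2
```

A thin command-line wrapper lives at `inst/cli/transst.R`
(`simulate`, `run --config run.yaml`, `evaluate` subcommands).

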