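# setgnn

Gene-set-informed graph neural networks for predicting continuous
phenotypes from proteomics.

## The problem

High-throughput plasma proteomics yields thousands of protein levels per
individual. Predicting a continuous trait (e.g. glycated hemoglobin) from
such panels is a high-dimensional regression in which relevant biology is
plausibly nonlinear, but cohort sizes rarely support unconstrained deep
networks. `setgnn` injects prior knowledge of protein co-functionality
directly into the architecture: proteins and curated protein sets (GMT
libraries, e.g. ontology exports) form the two partitions of a bipartite
graph whose edges encode set membership. Two graph-convolution layers

    H' = tanh( D^-1/2 (A + I) D^-1/2  H  W ),    dims 1 -> 2 -> 1

propagate information between proteins that share a set; the resulting
per-protein embedding (plus covariates, and optionally the raw expression
vector as a "global head") feeds a four-layer dense network with widths
`[2*emb + extras, 256, 32, 1]` that outputs the phenotype estimate.

The package provides, behind one training/evaluation contract:

* **single-head**, **parallel multi-graph** (k independent subgraphs +
  global head), and **merged large single-head** GNNs;
* capacity-matched null controls: **permuted-label graphs**, **uniform
  random libraries** (200 sets, sizes 2–20), **geometric random
  libraries** (density sweep 100–1000 sets, sizes fitted to a curated
  reference by `fit_geometric_size_model()`);
* an **informed feed-forward network** (sparse set-masked first layer,
  then 256/128/64/32) and **ridge regression** baselines;
* cohort QC (missingness filters, mean imputation, train-only
  standardization, 75/25 splits with a 15% validation carve-out and
  training-fraction subsampling);
* Adam/MSE training with plateau LR halving and early stopping;
* **gradient saliency** over protein *and* set nodes;
* a **synthetic cohort generator** with planted set-structured signal so
  the whole pipeline runs without access-restricted biobank data;
* a paired multi-seed **experiment harness** with mean R² ± SEM and
  permutation-gap reporting.

## Worked example

```r
library(setgnn)

# a synthetic cohort emulating a proteomics release at desk scale:
# 600 samples x 150 proteins, 80 sets (8 carry a quadratic signal),
# 20 covariates, 2% missing cells
cohort <- generate_cohort(
  synthetic_config(n_samples = 600, n_proteins = 150, n_sets = 80,
                   n_active_sets = 8),
  seed = 42)
cohort
#> <proteomics_cohort> 600 samples x 150 proteins, 20 covariates; 1840 missing cells; 0 missing phenotypes

cohort <- mean_impute(cohort)
lib    <- filter_library(cohort_truth(cohort)$library, cohort$panel)
splits <- split_cohort(cohort, split_spec(seed = 7))

graph <- build_bipartite_graph(cohort$panel, lib)
model <- build_gnn(graph, n_covariates = 20, seed = 1)
model
#> <gnn_model> single_head: 1 subgraph(s), P = 150, C = 20
#>   dense widths: 170 -> 320 -> 256 -> 32 -> 1
#>   trainable parameters: 145157

fit <- train_model(model, splits, train_config(seed = 1))
fit
#> <setgnn_fit> single_head: best epoch 63 (validation MSE 0.7815), test R^2 0.1312

glance(fit)           # one-row summary
tidy(fit)             # per-epoch loss curves

# linear baseline on the same splits
ridge_fit(splits)
#> <ridge_fit> lambda = 890 (validation R^2 0.03954), test R^2 0.02435

# set-level interpretation of the trained model
sal <- compute_saliency(fit, splits$test)
rank_nodes(sal, node_type = "set", top_k = 5)
#> # A tibble: 5 x 6
#>   node_id node_type subgraph  score n_samples  rank
#> 1 SET0017 set       go_like  0.0189       150     1
#> 2 SET0068 set       go_like  0.0117       150     2
#> 3 SET0059 set       go_like  0.0115       150     3
#> 4 SET0061 set       go_like  0.0104       150     4
#> 5 SET0012 set       go_like  0.0103       150     5
```

The phenotype here is quadratic in set-mean expression, so ridge captures
little beyond the covariates (test R² 0.024) while the GNN extracts part
of the set-level signal (0.131); `SET0068` in the saliency top five is one
of the generator's eight truly active sets. At this cohort size the effect
is modest and grows with the training fraction (see the harness below and
the methods vignette for what these numbers do and do not show).

A paired informed-vs-permuted comparison:

```r
arms <- list(
  experiment_arm("informed", "single_head"),
  experiment_arm("permuted", "single_head", permuted = TRUE)
)
report <- run_experiment(cohort, arms, libraries = list(go = lib),
                         n_seeds = 10, base_seed = 100)
summarize_experiment(report)
permutation_gap(report, "informed", "permuted")
autoplot(report)
```

Command-line wrappers live in `scripts/`: `simulate.R` writes a fixture
bundle (expression/covariates/phenotype TSVs + GMT + truth JSON) and
`benchmark.R` runs `compare`, `heads`, `density`, and `saliency`
subcommands over a synthetic cohort.

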