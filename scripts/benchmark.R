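#!/usr/bin/env Rscript
# Controlled model comparisons on a synthetic cohort.
#
#   Rscript scripts/benchmark.R compare  --out dir [--n-seeds 10] [--smoke]
#   Rscript scripts/benchmark.R heads    --out dir [--n-seeds 3]  [--smoke]
#   Rscript scripts/benchmark.R density  --out dir [--n-seeds 3]  [--smoke]
#   Rscript scripts/benchmark.R saliency --out dir [--seed 1]
#
# `compare` runs informed vs permuted single-head arms (plus ridge) over
# training fractions; `heads` and `density` run the capacity sweeps;
# `saliency` trains one single-head model and exports ranked node scores.
# --smoke shrinks the cohort and seed count for a quick end-to-end pass.

suppressPackageStartupMessages({
  library(optparse)
  library(setgnn)
  library(readr)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0) stop("usage: benchmark.R <compare|heads|density|saliency> ...")
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "benchmark_out"),
  make_option("--n-seeds", type = "integer", default = NA),
  make_option("--seed", type = "integer", default = 1),
  make_option("--smoke", action = "store_true", default = FALSE)
)), args = args[-1])

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)

scfg <- if (opts$smoke) {
  synthetic_config(n_samples = 600, n_proteins = 150, n_sets = 80,
                   n_active_sets = 8)
} else synthetic_config()
cohort <- mean_impute(drop_missing_phenotype(generate_cohort(scfg, seed = opts$seed)))
lib <- cohort_truth(cohort)$library
cfg <- train_config(seed = opts$seed)

save_report <- function(report, name) {
  write_tsv(report, file.path(opts$out, paste0(name, "_per_seed.tsv")))
  write_tsv(summarize_experiment(report),
            file.path(opts$out, paste0(name, "_summary.tsv")))
  ggplot2::ggsave(file.path(opts$out, paste0(name, ".pdf")),
                  ggplot2::autoplot(report), width = 9, height = 5)
}

if (cmd == "compare") {
  n_seeds <- if (!is.na(opts[["n-seeds"]])) opts[["n-seeds"]] else
    if (opts$smoke) 2 else 10
  arms <- list()
  for (f in c(0.25, 0.5, 1)) {
    arms <- c(arms, list(
      experiment_arm(sprintf("informed_f%s", f), "single_head", fraction = f),
      experiment_arm(sprintf("permuted_f%s", f), "single_head", fraction = f,
                     permuted = TRUE),
      experiment_arm(sprintf("ridge_f%s", f), "ridge", fraction = f)
    ))
  }
  report <- run_experiment(cohort, arms, libraries = list(go_like = lib),
                           n_seeds = n_seeds, base_seed = opts$seed,
                           config = cfg)
  save_report(report, "compare")
  for (f in c(0.25, 0.5, 1)) {
    gap <- permutation_gap(report, sprintf("informed_f%s", f),
                           sprintf("permuted_f%s", f))
    print(gap)
  }
} else if (cmd == "heads") {
  n_seeds <- if (!is.na(opts[["n-seeds"]])) opts[["n-seeds"]] else
    if (opts$smoke) 1 else 3
  report <- head_sweep(cohort, k_range = 1:5,
                       fractions = if (opts$smoke) 1 else c(0.25, 0.5, 1),
                       n_seeds = n_seeds, base_seed = opts$seed, config = cfg)
  save_report(report, "heads")
} else if (cmd == "density") {
  n_seeds <- if (!is.na(opts[["n-seeds"]])) opts[["n-seeds"]] else
    if (opts$smoke) 1 else 3
  p_hat <- fit_geometric_size_model(filter_library(lib, cohort$panel))
  report <- density_sweep(cohort,
                          n_sets_range = if (opts$smoke) c(100, 300) else
                            seq(100, 1000, 100),
                          geom_p = p_hat, n_seeds = n_seeds,
                          base_seed = opts$seed, config = cfg)
  save_report(report, "density")
} else if (cmd == "saliency") {
  flib <- filter_library(lib, cohort$panel)
  splits <- split_cohort(cohort, split_spec(seed = opts$seed))
  model <- build_gnn(build_bipartite_graph(cohort$panel, flib),
                     ncol(cohort$covariates), seed = opts$seed)
  fit <- train_model(model, splits, cfg)
  cat("test R^2:", round(fit$test_r2, 4), "\n")
  rep_ <- compute_saliency(fit, splits$test)
  write_tsv(rank_nodes(rep_, top_k = nrow(rep_)),
            file.path(opts$out, "saliency.tsv"))
  ggplot2::ggsave(file.path(opts$out, "saliency_sets.pdf"),
                  ggplot2::autoplot(rep_, node_type = "set", top_k = 20),
                  width = 7, height = 6)
} else stop("unknown subcommand: ", cmd)
cat("done; outputs in ", opts$out, "\n")
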