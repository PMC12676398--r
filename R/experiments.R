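#' Define an experiment arm
#'
#' One model configuration in a controlled comparison: an architecture, a
#' graph recipe, a training fraction, and optionally a permuted-label null.
#' A permuted arm shares its architecture (and hence parameter count) with
#' its informed partner; only the protein labels are shuffled before graph
#' construction.
#'
#' @param label Unique arm label.
#' @param kind One of `"single_head"`, `"parallel"`, `"large_single_head"`,
#'   `"informed_ffnn"`, `"ridge"`.
#' @param fraction Training fraction in (0, 1] (default 1; the sweeps use
#'   0.25 / 0.5 / 1).
#' @param permuted Shuffle protein labels before graph construction
#'   (default `FALSE`).
#' @param graph_source `"library"` (curated libraries passed to
#'   [run_experiment()]), `"uniform_random"` (fresh 200-set, size 2-20
#'   uniform libraries per head), or `"geometric_random"` (one library with
#'   geometric set sizes, for the density sweep).
#' @param libraries For `graph_source = "library"`: indices or names of the
#'   supplied libraries to use (default 1 for single-head architectures,
#'   all for parallel/merged).
#' @param n_heads Number of subgraphs for random-head parallel arms.
#' @param n_random_sets Library size for `"geometric_random"` arms.
#' @param geom_p Geometric size parameter for `"geometric_random"` arms
#'   (e.g. from [fit_geometric_size_model()]).
#' @return An `experiment_arm`.
#' @export
experiment_arm <- function(label,
                           kind = c("single_head", "parallel",
                                    "large_single_head", "informed_ffnn",
                                    "ridge"),
                           fraction = 1, permuted = FALSE,
                           graph_source = c("library", "uniform_random",
                                            "geometric_random"),
                           libraries = NULL, n_heads = NULL,
                           n_random_sets = NULL, geom_p = NULL) {
  kind <- match.arg(kind)
  graph_source <- match.arg(graph_source)
  stopifnot(fraction > 0, fraction <= 1)
  structure(list(label = label, kind = kind, fraction = fraction,
                 permuted = permuted, graph_source = graph_source,
                 libraries = libraries, n_heads = n_heads,
                 n_random_sets = n_random_sets, geom_p = geom_p),
            class = "experiment_arm")
}

# Resolve the libraries an arm trains on for one replicate.
arm_libraries <- function(arm, panel, filtered_libs, rep_seed) {
  libs <- switch(arm$graph_source,
    library = {
      sel <- arm$libraries %||%
        if (arm$kind %in% c("parallel", "large_single_head")) {
          seq_along(filtered_libs)
        } else 1L
      filtered_libs[sel]
    },
    uniform_random = {
      k <- arm$n_heads %||% 1L
      lapply(seq_len(k), function(i) {
        make_uniform_random_library(panel, n_sets = 200, size_min = 2,
                                    size_max = 20,
                                    seed = derive_seed(rep_seed, 100 + i))
      })
    },
    geometric_random = {
      list(make_geometric_random_library(
        panel, n_sets = arm$n_random_sets,
        p = arm$geom_p %||% 1 / 7,
        seed = derive_seed(rep_seed, 200)
      ))
    }
  )
  if (arm$permuted) {
    perm <- permute_protein_labels(panel, seed = derive_seed(rep_seed, 13))
    libs <- lapply(libs, permute_library, perm = perm)
  }
  libs
}

# Build and fit one arm on one replicate's splits; returns test R^2 and
# the parameter count (NA for ridge's closed form is avoided: counted too).
fit_arm <- function(arm, splits, panel, filtered_libs, rep_seed, config) {
  libs <- arm_libraries(arm, panel, filtered_libs, rep_seed)
  C <- ncol(splits$train$covariates)
  init_seed <- derive_seed(rep_seed, 17)
  if (arm$kind == "ridge") {
    fit <- ridge_fit(splits)
    return(list(test_r2 = fit$test_r2, n_parameters = count_parameters(fit),
                fit = fit))
  }
  model <- switch(arm$kind,
    single_head = build_gnn(build_bipartite_graph(panel, libs[[1]]), C,
                            kind = "single_head",
                            dropout_rate = config$dropout_rate,
                            seed = init_seed),
    parallel = build_gnn(assemble_parallel(panel, libs), C,
                         kind = "parallel",
                         dropout_rate = config$dropout_rate,
                         seed = init_seed),
    large_single_head = build_gnn(
      if (length(libs) >= 2) build_merged_graph(panel, libs) else
        build_bipartite_graph(panel, libs[[1]]),
      C, kind = "large_single_head",
      dropout_rate = config$dropout_rate, seed = init_seed),
    informed_ffnn = build_informed_ffnn(panel, libs[[1]], C,
                                        dropout_rate = config$dropout_rate,
                                        seed = init_seed)
  )
  fit <- train_model(model, splits, config)
  list(test_r2 = fit$test_r2, n_parameters = count_parameters(fit$model),
       fit = fit)
}

#' Run a paired multi-seed experiment
#'
#' Trains every arm `n_seeds` times. Within a replicate all arms share the
#' same split seed, so the train/validation/test indices are identical
#' across arms (and subsampling only shrinks the training pool), making
#' arm contrasts attributable to the graph recipe rather than split noise.
#' Permuted arms draw one fresh label permutation per replicate.
#'
#' @param cohort A preprocessed `proteomics_cohort` (QC'd, phenotype
#'   complete, imputed).
#' @param arms List of [experiment_arm()]s.
#' @param libraries Named list of `gene_set_library` objects for
#'   `graph_source = "library"` arms (filtered against the cohort panel
#'   internally with `min_size`/`max_size`).
#' @param n_seeds Replicates per arm (default 10).
#' @param base_seed Base seed; replicate r uses a seed derived from
#'   `base_seed` and `r`.
#' @param config A [train_config()] shared by all neural arms.
#' @param min_size,max_size Library filter bounds (defaults 2 and 100).
#' @param keep_fits Keep the fitted models (default `FALSE`; they are
#'   large).
#' @return An `experiment_report` tibble: `label`, `kind`, `fraction`,
#'   `replicate`, `seed`, `test_r2`, `n_parameters`, `n_train`. Failed
#'   single replicates are recorded with `NA` R^2 and a warning; an arm
#'   failing all replicates is an error.
#' @export
run_experiment <- function(cohort, arms, libraries = NULL, n_seeds = 10,
                           base_seed = 100, config = train_config(),
                           min_size = 2, max_size = 100, keep_fits = FALSE) {
  stopifnot(inherits(cohort, "proteomics_cohort"))
  if (anyNA(cohort$expression)) stop("impute the cohort before running", call. = FALSE)
  if (anyNA(cohort$phenotype)) stop("drop missing phenotypes before running", call. = FALSE)
  if (inherits(arms, "experiment_arm")) arms <- list(arms)
  labels <- vapply(arms, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate arm labels", call. = FALSE)
  panel <- cohort$panel
  filtered_libs <- lapply(libraries %||% list(), filter_library,
                          panel = panel, min_size = min_size,
                          max_size = max_size)
  rows <- list()
  fits <- list()
  for (r in seq_len(n_seeds)) {
    rep_seed <- derive_seed(base_seed, r)
    split_cache <- list()
    for (a in seq_along(arms)) {
      arm <- arms[[a]]
      fkey <- format(arm$fraction)
      if (is.null(split_cache[[fkey]])) {
        split_cache[[fkey]] <- split_cohort(
          cohort, split_spec(train_fraction = arm$fraction, seed = rep_seed))
      }
      splits <- split_cache[[fkey]]
      res <- tryCatch(
        fit_arm(arm, splits, panel, filtered_libs, rep_seed, config),
        error = function(e) {
          warning("arm '", arm$label, "' replicate ", r, " failed: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        }
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = arm$label, kind = arm$kind, fraction = arm$fraction,
        replicate = r, seed = rep_seed,
        test_r2 = if (is.null(res)) NA_real_ else res$test_r2,
        n_parameters = if (is.null(res)) NA_integer_ else
          as.integer(res$n_parameters),
        n_train = n_samples(splits$train)
      )
      if (keep_fits && !is.null(res)) {
        fits[[paste(arm$label, r, sep = "#")]] <- res$fit
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  failed <- dplyr::summarise(dplyr::group_by(out, .data$label),
                             all_failed = all(is.na(.data$test_r2)))
  if (any(failed$all_failed)) {
    stop("arm(s) failed on every replicate: ",
         paste(failed$label[failed$all_failed], collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("experiment_report", class(out))
  attr(out, "fits") <- if (keep_fits) fits else NULL
  attr(out, "base_seed") <- base_seed
  out
}

#' Summarize an experiment report
#'
#' Mean test R^2 and its standard error (`sd / sqrt(n)`) per arm and
#' training fraction; the SEM is `NA` for a single replicate.
#'
#' @param report An `experiment_report`.
#' @return A tibble with `label`, `kind`, `fraction`, `n_seeds`,
#'   `mean_r2`, `sem_r2`.
#' @export
summarize_experiment <- function(report) {
  dplyr::summarise(
    dplyr::group_by(report, .data$label, .data$kind, .data$fraction),
    n_seeds = sum(!is.na(.data$test_r2)),
    mean_r2 = mean(.data$test_r2, na.rm = TRUE),
    sem_r2 = ifelse(.data$n_seeds >= 2,
                    stats::sd(.data$test_r2[!is.na(.data$test_r2)]) /
                      sqrt(.data$n_seeds), NA_real_),
    .groups = "drop"
  )
}

#' Percent improvement over a permuted baseline
#'
#' `100 * (mean R2_informed - mean R2_permuted) / mean R2_permuted`,
#' computed on arm means per fraction, plus the paired per-replicate
#' version (mean of per-seed percent gaps) and the paired win count.
#' The gap is flagged `NA` when the permuted mean is not positive.
#'
#' @param report An `experiment_report` containing both arms.
#' @param informed_label,permuted_label Arm labels to compare.
#' @return A tibble with one row per training fraction.
#' @export
permutation_gap <- function(report, informed_label, permuted_label) {
  inf <- dplyr::filter(report, .data$label == informed_label)
  per <- dplyr::filter(report, .data$label == permuted_label)
  if (nrow(inf) == 0 || nrow(per) == 0) {
    stop("both arms must be present in the report", call. = FALSE)
  }
  paired <- dplyr::inner_join(
    dplyr::select(inf, "fraction", "replicate", informed_r2 = "test_r2"),
    dplyr::select(per, "fraction", "replicate", permuted_r2 = "test_r2"),
    by = c("fraction", "replicate")
  )
  out <- dplyr::summarise(
    dplyr::group_by(paired, .data$fraction),
    n_pairs = dplyr::n(),
    mean_informed = mean(.data$informed_r2, na.rm = TRUE),
    mean_permuted = mean(.data$permuted_r2, na.rm = TRUE),
    paired_gap_pct = mean(
      100 * (.data$informed_r2 - .data$permuted_r2) /
        abs(.data$permuted_r2), na.rm = TRUE),
    wins = sum(.data$informed_r2 > .data$permuted_r2, na.rm = TRUE),
    .groups = "drop"
  )
  out$gap_pct <- ifelse(out$mean_permuted > 0,
                        100 * (out$mean_informed - out$mean_permuted) /
                          out$mean_permuted, NA_real_)
  if (any(out$mean_permuted <= 0)) {
    warning("permuted mean R^2 <= 0 for some fraction(s); gap undefined there",
            call. = FALSE)
  }
  dplyr::relocate(out, "fraction", "n_pairs", "mean_informed",
                  "mean_permuted", "gap_pct", "paired_gap_pct", "wins")
}

#' Arms for the random-head sweep
#'
#' Parallel GNNs with 1 to 5 random uniform-library subgraphs (200 sets of
#' 2-20 proteins per head) plus the global head, per training fraction.
#'
#' @param k_range Head counts (default `1:5`).
#' @param fractions Training fractions (default `c(0.25, 0.5, 1)`).
#' @return List of [experiment_arm()]s.
#' @export
head_sweep_arms <- function(k_range = 1:5, fractions = c(0.25, 0.5, 1)) {
  arms <- list()
  for (f in fractions) for (k in k_range) {
    arms[[length(arms) + 1]] <- experiment_arm(
      label = sprintf("random_heads_k%d_f%s", k, format(f)),
      kind = "parallel", fraction = f, graph_source = "uniform_random",
      n_heads = k
    )
  }
  arms
}

#' Arms for the graph-density sweep
#'
#' Single-head GNNs on geometric-size random libraries of 100 to 1000 sets
#' in steps of 100; the architecture is identical across points except for
#' the graph itself.
#'
#' @param n_sets_range Library sizes (default `seq(100, 1000, by = 100)`).
#' @param geom_p Geometric size parameter (fit one with
#'   [fit_geometric_size_model()] on a curated reference).
#' @param fractions Training fractions (default 1).
#' @return List of [experiment_arm()]s.
#' @export
density_sweep_arms <- function(n_sets_range = seq(100, 1000, by = 100),
                               geom_p = 1 / 7, fractions = 1) {
  arms <- list()
  for (f in fractions) for (s in n_sets_range) {
    arms[[length(arms) + 1]] <- experiment_arm(
      label = sprintf("random_density_s%d_f%s", s, format(f)),
      kind = "single_head", fraction = f, graph_source = "geometric_random",
      n_random_sets = s, geom_p = geom_p
    )
  }
  arms
}

#' Random-head sweep
#'
#' Runs the [head_sweep_arms()] grid through [run_experiment()].
#'
#' @inheritParams run_experiment
#' @inheritParams head_sweep_arms
#' @return An `experiment_report` with `n_heads` attached per row.
#' @export
head_sweep <- function(cohort, k_range = 1:5, fractions = c(0.25, 0.5, 1),
                       n_seeds = 10, base_seed = 100,
                       config = train_config()) {
  arms <- head_sweep_arms(k_range, fractions)
  report <- run_experiment(cohort, arms, n_seeds = n_seeds,
                           base_seed = base_seed, config = config)
  report$n_heads <- as.integer(sub("random_heads_k(\\d+)_f.*", "\\1",
                                   report$label))
  report
}

#' Graph-density sweep
#'
#' Runs the [density_sweep_arms()] grid through [run_experiment()].
#'
#' @inheritParams run_experiment
#' @inheritParams density_sweep_arms
#' @return An `experiment_report` with `n_sets` attached per row.
#' @export
density_sweep <- function(cohort, n_sets_range = seq(100, 1000, by = 100),
                          geom_p = 1 / 7, fractions = 1, n_seeds = 10,
                          base_seed = 100, config = train_config()) {
  arms <- density_sweep_arms(n_sets_range, geom_p, fractions)
  report <- run_experiment(cohort, arms, n_seeds = n_seeds,
                           base_seed = base_seed, config = config)
  report$n_sets <- as.integer(sub("random_density_s(\\d+)_f.*", "\\1",
                                  report$label))
  report
}

#' Plot an experiment report
#'
#' Mean test R^2 with SEM error bars per arm, faceted by training
#' fraction.
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, ...) {
  s <- summarize_experiment(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$label, y = .data$mean_r2,
                                  fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_r2 - .data$sem_r2,
      ymax = .data$mean_r2 + .data$sem_r2), width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~fraction, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = expression(mean ~ test ~ R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
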