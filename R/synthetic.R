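#' Synthetic cohort configuration
#'
#' Describes a desk-scale cohort with the statistical structure the models
#' assume: protein expression with within-set correlation induced by a
#' one-factor model per set, a phenotype driven by a nonlinearity of
#' active-set aggregate expression plus linear covariate effects plus
#' Gaussian noise, and completely-at-random per-cell missingness. Defaults
#' mirror a biobank-style proteomics panel at desk scale: 1500 samples,
#' 300 proteins, a 150-set ontology-like library with 10 active sets,
#' quadratic set-level signal, 20 covariates (one binary), and noise
#' calibrated so the total signal explains about 60% of phenotype variance.
#'
#' @param n_samples,n_proteins Cohort dimensions (defaults 1500, 300).
#' @param n_sets Library size when no `library` is supplied (default 150).
#' @param n_active_sets Number of sets carrying signal (default 10).
#' @param signal Per-active-set nonlinearity applied to the set-mean
#'   aggregate: `"quadratic"` (default), `"linear"`, `"threshold"`, or
#'   `"interaction"` (products of consecutive active-set aggregates).
#' @param beta_set Effect size per active set (default 1).
#' @param within_set_cor One-factor within-set correlation rho (default 0.3).
#' @param n_covariates Number of covariates; the first is binary, the rest
#'   standard normal (default 20: sex, age, a technical covariate, 16
#'   ancestry components, BMI).
#' @param beta_cov_sd SD of the Gaussian covariate effect sizes (default 0.15).
#' @param noise_sd Noise SD; if `NULL` (default) it is calibrated from the
#'   realized signal variance so the signal fraction equals `target_r2`.
#' @param target_r2 Population signal fraction used to calibrate the noise
#'   (default 0.6; ignored when `noise_sd` is given).
#' @param missing_rate Per-cell MCAR missingness probability (default 0.02).
#' @param overlap_rate Expected fraction of each generated set's members
#'   drawn from proteins already used by earlier sets (default 0.1).
#' @param mean_set_size Mean of the shifted-geometric set-size distribution
#'   used for generated libraries (default 8).
#' @param library Optional externally supplied `gene_set_library` (takes
#'   precedence over `n_sets`/`overlap_rate`/`mean_set_size`).
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 1500, n_proteins = 300,
                             n_sets = 150, n_active_sets = 10,
                             signal = c("quadratic", "linear", "threshold",
                                        "interaction"),
                             beta_set = 1, within_set_cor = 0.3,
                             n_covariates = 20, beta_cov_sd = 0.15,
                             noise_sd = NULL, target_r2 = 0.6,
                             missing_rate = 0.02, overlap_rate = 0.1,
                             mean_set_size = 8, library = NULL) {
  signal <- match.arg(signal)
  stopifnot(n_samples >= 10, n_proteins >= 2, n_active_sets >= 0,
            within_set_cor >= 0, within_set_cor < 1,
            missing_rate >= 0, missing_rate < 1,
            overlap_rate >= 0, overlap_rate <= 1,
            is.null(noise_sd) || noise_sd >= 0,
            target_r2 > 0, target_r2 < 1)
  structure(list(n_samples = n_samples, n_proteins = n_proteins,
                 n_sets = n_sets, n_active_sets = n_active_sets,
                 signal = signal, beta_set = beta_set,
                 within_set_cor = within_set_cor,
                 n_covariates = n_covariates, beta_cov_sd = beta_cov_sd,
                 noise_sd = noise_sd, target_r2 = target_r2,
                 missing_rate = missing_rate, overlap_rate = overlap_rate,
                 mean_set_size = mean_set_size, library = library),
            class = "synthetic_config")
}

#' Generate an ontology-like random library
#'
#' Set sizes follow a shifted geometric (support from `size_min`, mean
#' `mean_set_size`); members are drawn so that on average a fraction
#' `overlap_rate` of each set's members are proteins already used by
#' earlier sets, giving controlled pairwise overlap. `overlap_rate = 0`
#' yields disjoint sets (an error if the panel is too small to support
#' them).
#'
#' @param panel Protein panel.
#' @param n_sets Number of sets.
#' @param overlap_rate Expected reused-member fraction (default 0.1).
#' @param mean_set_size Mean set size (default 8).
#' @param size_min Smallest set size (default 2).
#' @param seed Integer seed.
#' @return A `gene_set_library`.
#' @export
make_go_like_library <- function(panel, n_sets, overlap_rate = 0.1,
                                 mean_set_size = 8, size_min = 2, seed = 1) {
  panel <- protein_panel(panel)
  stopifnot(n_sets >= 1, mean_set_size >= size_min)
  p <- 1 / (1 + mean_set_size - size_min)
  sets <- with_seed(seed, {
    sizes <- pmin(size_min + stats::rgeom(n_sets, p), length(panel))
    used <- character(0)
    unused <- panel
    out <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      s <- sizes[i]
      n_old <- min(stats::rbinom(1, s, overlap_rate), length(used))
      n_new <- min(s - n_old, length(unused))
      shortfall <- s - n_old - n_new
      if (shortfall > 0) {
        # fresh proteins exhausted; reuse more (panel always covers s)
        if (overlap_rate == 0) {
          stop("panel too small for ", n_sets, " disjoint sets", call. = FALSE)
        }
        n_old <- n_old + shortfall
      }
      members <- c(if (n_old > 0) sample(used, n_old),
                   if (n_new > 0) sample(unused, n_new))
      unused <- setdiff(unused, members)
      used <- union(used, members)
      out[[i]] <- members
    }
    out
  })
  names(sets) <- sprintf("SET%04d", seq_len(n_sets))
  gene_set_library(sets, name = "go_like")
}

# Set-mean aggregates for a library: samples x sets.
set_aggregates <- function(X, lib, panel) {
  vapply(lib$sets, function(m) rowMeans(X[, match(m, panel), drop = FALSE]),
         numeric(nrow(X)))
}

#' Generate a synthetic proteomics cohort with planted set signal
#'
#' Expression is standard normal with within-set correlation induced by one
#' latent factor per set; the phenotype is
#' `sum over active sets of beta_set * g(set mean) + covariates %*% beta_cov
#' + N(0, sigma^2)`; missingness is applied completely at random per cell.
#' The ground truth (active sets, coefficients, realized noise SD, the
#' library) is attached for recovery tests via [cohort_truth()].
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @return A `proteomics_cohort` with a `truth` attribute.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  P <- config$n_proteins
  panel <- sprintf("PROT%04d", seq_len(P))
  lib <- config$library %||%
    make_go_like_library(panel, config$n_sets,
                         overlap_rate = config$overlap_rate,
                         mean_set_size = config$mean_set_size,
                         seed = derive_seed(seed, 1))
  if (config$n_active_sets > length(lib)) {
    stop("n_active_sets exceeds library size", call. = FALSE)
  }
  with_seed(derive_seed(seed, 2), {
    # one latent factor per set; a protein in m sets splits the set
    # variance share across its sets so every column has unit variance
    rho <- config$within_set_cor
    FF <- matrix(stats::rnorm(n * length(lib)), n, length(lib))
    X <- matrix(stats::rnorm(n * P), n, P) * sqrt(1 - rho)
    memb <- lapply(panel, function(pr)
      which(vapply(lib$sets, function(m) pr %in% m, TRUE)))
    for (j in seq_len(P)) {
      m <- memb[[j]]
      if (length(m) == 0L) {
        X[, j] <- X[, j] / sqrt(1 - rho) # unannotated protein: pure noise
      } else {
        X[, j] <- X[, j] +
          sqrt(rho) * rowSums(FF[, m, drop = FALSE]) / sqrt(length(m))
      }
    }
    colnames(X) <- panel
    active <- sort(sample(seq_along(lib$sets), config$n_active_sets))
    U <- if (length(active)) {
      set_aggregates(X, gene_set_library(lib$sets[active]), panel)
    } else matrix(0, n, 0)
    g <- switch(config$signal,
      linear = function(u) u,
      quadratic = function(u) u^2 - mean(u^2),
      threshold = function(u) (u > 0) - 0.5,
      interaction = NULL
    )
    set_signal <- if (length(active) == 0) rep(0, n) else if
      (config$signal == "interaction") {
      # products of consecutive active-set aggregates (cyclic pairing)
      k <- ncol(U)
      prt <- U * U[, c(seq_len(k)[-1], 1), drop = FALSE]
      config$beta_set * rowSums(sweep(prt, 2, colMeans(prt)))
    } else {
      config$beta_set * rowSums(apply(U, 2, g))
    }
    C <- config$n_covariates
    Cov <- if (C > 0) {
      cbind(stats::rbinom(n, 1, 0.5),
            if (C > 1) matrix(stats::rnorm(n * (C - 1)), n, C - 1))
    } else matrix(0, n, 0)
    if (C == 20) {
      colnames(Cov) <- c("sex", "age", "plasma_volume",
                         paste0("pc", 1:16), "bmi")
    } else if (C > 0) {
      colnames(Cov) <- c("sex", if (C > 1) paste0("cov", seq_len(C - 1)))
    }
    beta_cov <- if (C > 0) stats::rnorm(C, 0, config$beta_cov_sd) else numeric(0)
    signal <- set_signal + if (C > 0) as.numeric(Cov %*% beta_cov) else 0
    sigma <- config$noise_sd %||%
      (stats::sd(signal) * sqrt((1 - config$target_r2) / config$target_r2))
    phenotype <- signal + stats::rnorm(n, 0, sigma)
    Xobs <- X
    if (config$missing_rate > 0) {
      miss <- matrix(stats::rbinom(n * P, 1, config$missing_rate) == 1, n, P)
      Xobs[miss] <- NA_real_
    }
    cohort <- proteomics_cohort(
      expression = Xobs, covariates = Cov, phenotype = phenotype,
      sample_ids = sprintf("S%05d", seq_len(n)), panel = panel
    )
    attr(cohort, "truth") <- list(
      library = lib,
      active_sets = names(lib$sets)[active],
      beta_set = config$beta_set,
      beta_cov = beta_cov,
      signal = config$signal,
      noise_sd = sigma,
      signal_values = signal,
      config = config,
      seed = seed
    )
    cohort
  })
}

#' Ground truth of a synthetic cohort
#' @param cohort A cohort from [generate_cohort()].
#' @return The truth list (active sets, coefficients, library, noise SD).
#' @export
cohort_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) stop("cohort carries no ground truth", call. = FALSE)
  tr
}

#' Write a fixture bundle to disk
#'
#' Emits exactly the formats the loaders consume: `expression.tsv`,
#' `covariates.tsv`, `phenotype.tsv` (sample ids in the first column, `NA`
#' for missing cells), `library.gmt`, and `truth.json` when the cohort
#' carries ground truth.
#'
#' @param cohort A `proteomics_cohort`.
#' @param library A `gene_set_library`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture_bundle <- function(cohort, library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             library = file.path(dir, "library.gmt"),
             truth = file.path(dir, "truth.json"))
  as_df <- function(m) {
    tibble::as_tibble(as.data.frame(m), rownames = "sample_id")
  }
  expr <- cohort$expression
  expr[cohort$missing_mask] <- NA_real_
  readr::write_tsv(as_df(expr), paths["expression"])
  readr::write_tsv(as_df(cohort$covariates), paths["covariates"])
  readr::write_tsv(tibble::tibble(sample_id = cohort$sample_ids,
                                  phenotype = cohort$phenotype),
                   paths["phenotype"])
  write_gmt(library, paths["library"])
  tr <- attr(cohort, "truth")
  if (!is.null(tr)) {
    jsonlite::write_json(list(active_sets = tr$active_sets,
                              beta_set = tr$beta_set,
                              beta_cov = tr$beta_cov,
                              signal = tr$signal,
                              noise_sd = tr$noise_sd,
                              seed = tr$seed),
                         paths["truth"], auto_unbox = TRUE, digits = NA)
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}
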