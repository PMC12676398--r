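#' Proteomics cohorts
#'
#' A `proteomics_cohort` bundles a samples-by-proteins expression matrix
#' (with a missingness mask), a samples-by-covariates matrix, a per-sample
#' continuous phenotype (possibly missing), and the protein panel that
#' defines the column layout.
#'
#' @param expression Numeric matrix, samples x proteins, `NA` where missing.
#' @param covariates Numeric matrix, samples x covariates, named columns.
#' @param phenotype Numeric vector, one value per sample (`NA` allowed).
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `rownames(expression)`.
#' @param panel Protein panel; defaults to `colnames(expression)`.
#' @return A `proteomics_cohort`.
#' @export
proteomics_cohort <- function(expression, covariates, phenotype,
                              sample_ids = rownames(expression),
                              panel = colnames(expression)) {
  expression <- as.matrix(expression)
  covariates <- as.matrix(covariates)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(expression)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  panel <- protein_panel(panel %||% paste0("P", seq_len(ncol(expression))))
  stopifnot(
    nrow(expression) == length(sample_ids),
    ncol(expression) == length(panel),
    nrow(covariates) == length(sample_ids),
    length(phenotype) == length(sample_ids)
  )
  if (ncol(covariates) > 0 && is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  }
  if (anyDuplicated(colnames(covariates))) stop("duplicate covariate names", call. = FALSE)
  rownames(expression) <- sample_ids
  colnames(expression) <- panel
  rownames(covariates) <- sample_ids
  structure(list(
    sample_ids = sample_ids,
    expression = expression,
    missing_mask = is.na(expression),
    covariates = covariates,
    phenotype = as.numeric(phenotype),
    panel = panel
  ), class = "proteomics_cohort")
}

#' @export
print.proteomics_cohort <- function(x, ...) {
  cat("<proteomics_cohort> ", length(x$sample_ids), " samples x ",
      length(x$panel), " proteins, ", ncol(x$covariates), " covariates; ",
      sum(x$missing_mask), " missing cells; ",
      sum(is.na(x$phenotype)), " missing phenotypes\n", sep = "")
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort A `proteomics_cohort`.
#' @return Integer count.
#' @export
n_samples <- function(cohort) length(cohort$sample_ids)

# Row-subset a cohort, preserving panel and covariate layout (and any
# synthetic ground-truth annotation).
subset_cohort <- function(cohort, idx) {
  out <- structure(list(
    sample_ids = cohort$sample_ids[idx],
    expression = cohort$expression[idx, , drop = FALSE],
    missing_mask = cohort$missing_mask[idx, , drop = FALSE],
    covariates = cohort$covariates[idx, , drop = FALSE],
    phenotype = cohort$phenotype[idx],
    panel = cohort$panel
  ), class = "proteomics_cohort")
  attr(out, "truth") <- attr(cohort, "truth")
  out
}

#' Load a cohort from delimited text files
#'
#' Each file has a header row and sample identifiers in the first column;
#' blank cells and `NA` sentinels mark missing values. Files are aligned on
#' the intersection of their sample ids, preserving the expression file's
#' order; samples absent from any file are dropped with a warning.
#'
#' @param expression_path,covariates_path,phenotype_path Paths to delimited
#'   (TSV/CSV, auto-detected by extension) text files. The phenotype file's
#'   second column is used as the phenotype.
#' @return A [proteomics_cohort()].
#' @export
load_cohort <- function(expression_path, covariates_path, phenotype_path) {
  read_one <- function(path) {
    reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
    df <- reader(path, show_col_types = FALSE, progress = FALSE,
                 na = c("", "NA", "NaN"))
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicate sample ids in ", path, call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
  expr <- read_one(expression_path)
  covs <- read_one(covariates_path)
  phen <- read_one(phenotype_path)
  common <- intersect(intersect(rownames(expr), rownames(covs)), rownames(phen))
  if (length(common) == 0L) stop("no overlapping samples across input files", call. = FALSE)
  dropped <- length(unique(c(rownames(expr), rownames(covs), rownames(phen)))) - length(common)
  if (dropped > 0L) {
    warning(dropped, " sample(s) absent from at least one file were dropped",
            call. = FALSE)
  }
  keep <- rownames(expr)[rownames(expr) %in% common]
  proteomics_cohort(
    expression = expr[keep, , drop = FALSE],
    covariates = covs[keep, , drop = FALSE],
    phenotype = phen[keep, 1],
    sample_ids = keep
  )
}

#' Quality-control filter on missingness
#'
#' Two fixed passes: first drop samples whose missing-cell count exceeds
#' `max_missing_per_sample`, then drop proteins whose missing count among
#' the remaining samples exceeds `max_missing_per_protein`. Defaults match
#' a large biobank-scale panel (500 and 2000); they are absolute counts and
#' should be rescaled for small cohorts.
#'
#' @param cohort A `proteomics_cohort`.
#' @param max_missing_per_sample,max_missing_per_protein Non-negative counts.
#' @return The filtered cohort (panel updated).
#' @export
qc_filter <- function(cohort, max_missing_per_sample = 500,
                      max_missing_per_protein = 2000) {
  stopifnot(inherits(cohort, "proteomics_cohort"),
            max_missing_per_sample >= 0, max_missing_per_protein >= 0)
  keep_s <- rowSums(cohort$missing_mask) <= max_missing_per_sample
  if (!any(keep_s)) stop("QC removed all samples", call. = FALSE)
  out <- subset_cohort(cohort, which(keep_s))
  keep_p <- colSums(out$missing_mask) <= max_missing_per_protein
  if (!any(keep_p)) stop("QC removed all proteins", call. = FALSE)
  out$expression <- out$expression[, keep_p, drop = FALSE]
  out$missing_mask <- out$missing_mask[, keep_p, drop = FALSE]
  out$panel <- out$panel[keep_p]
  out
}

#' Drop samples with missing phenotype
#' @param cohort A `proteomics_cohort`.
#' @return Cohort restricted to samples with an observed phenotype.
#' @export
drop_missing_phenotype <- function(cohort) {
  stopifnot(inherits(cohort, "proteomics_cohort"))
  keep <- !is.na(cohort$phenotype)
  if (!any(keep)) stop("all samples missing the phenotype", call. = FALSE)
  subset_cohort(cohort, which(keep))
}

#' Mean-impute missing expression values
#'
#' Replaces each missing cell with the average observed expression of that
#' protein across the (post-QC) cohort. The missingness mask is retained
#' for provenance.
#'
#' @param cohort A `proteomics_cohort`; every protein must have at least one
#'   observed value (run [qc_filter()] first).
#' @return The imputed cohort.
#' @export
mean_impute <- function(cohort) {
  stopifnot(inherits(cohort, "proteomics_cohort"))
  n_obs <- colSums(!cohort$missing_mask)
  if (any(n_obs == 0L)) {
    stop("protein(s) with zero observed values: ",
         paste(utils::head(cohort$panel[n_obs == 0L], 5), collapse = ", "),
         "; run qc_filter() first", call. = FALSE)
  }
  mu <- colMeans(cohort$expression, na.rm = TRUE)
  idx <- which(cohort$missing_mask, arr.ind = TRUE)
  if (nrow(idx)) cohort$expression[idx] <- mu[idx[, 2]]
  cohort
}

#' Standardize expression (and covariates) on training statistics
#'
#' Per-protein z-scoring using mean and standard deviation estimated on the
#' training cohort only, applied to the training cohort and any further
#' cohorts (validation, test) — leakage-safe. Proteins constant in training
#' map to all-zeros with a warning. Continuous covariates are z-scored the
#' same way; binary 0/1 covariates are left untouched.
#'
#' @param train A `proteomics_cohort` (imputation complete).
#' @param ... Further cohorts to transform with the training statistics.
#' @return A list with `$train`, one transformed entry per `...` cohort (in
#'   order, named if the arguments were named), and `$stats` (per-protein
#'   `center`/`scale` and per-covariate `cov_center`/`cov_scale`).
#' @export
standardize_cohorts <- function(train, ...) {
  stopifnot(inherits(train, "proteomics_cohort"))
  if (anyNA(train$expression)) stop("impute before standardizing", call. = FALSE)
  center <- colMeans(train$expression)
  scale_ <- apply(train$expression, 2, stats::sd)
  n_const <- sum(scale_ == 0)
  if (n_const > 0) {
    warning(n_const, " constant protein column(s) mapped to zeros", call. = FALSE)
  }
  scale_safe <- ifelse(scale_ == 0, 1, scale_)
  is_binary <- apply(train$covariates, 2, function(v) all(v %in% c(0, 1)))
  cov_center <- ifelse(is_binary, 0, colMeans(train$covariates))
  cov_sd <- apply(train$covariates, 2, stats::sd)
  cov_scale <- ifelse(is_binary | cov_sd == 0, 1, cov_sd)
  apply_stats <- function(co) {
    co$expression <- sweep(sweep(co$expression, 2, center), 2, scale_safe, "/")
    if (n_const > 0) co$expression[, scale_ == 0] <- 0
    co$covariates <- sweep(sweep(co$covariates, 2, cov_center), 2, cov_scale, "/")
    co
  }
  others <- lapply(list(...), apply_stats)
  c(list(train = apply_stats(train)), others,
    list(stats = list(center = center, scale = scale_safe,
                      cov_center = cov_center, cov_scale = cov_scale)))
}

#' Split specification
#'
#' Holdout scheme: `test_fraction` of the cohort goes to test; 15% of the
#' remaining training pool (by default) is reserved for validation; the
#' training pool may then be subsampled to `train_fraction` (0.25, 0.5, 1.0
#' in the data-availability sweeps) AFTER the validation carve-out, so the
#' validation and test sets are invariant across fractions at a fixed seed.
#'
#' @param test_fraction Proportion held out for testing (default 0.25).
#' @param validation_fraction Proportion of the training pool reserved for
#'   validation (default 0.15).
#' @param train_fraction Proportion of the post-validation training pool
#'   actually used for training (default 1.0).
#' @param seed Integer seed controlling the shuffle.
#' @return A `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.25, validation_fraction = 0.15,
                       train_fraction = 1.0, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            validation_fraction > 0, validation_fraction < 1,
            train_fraction > 0, train_fraction <= 1)
  structure(list(test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a cohort into train / validation / test
#'
#' Sizes use floor for test and validation with the remainder to train:
#' `test = floor(N * test_fraction)`,
#' `validation = floor((N - test) * validation_fraction)`,
#' `train = floor((N - test - validation) * train_fraction)`.
#' Subsampling shrinks only the training set; validation and test indices
#' are identical across `train_fraction` values at a fixed seed.
#'
#' @param cohort A `proteomics_cohort` with at least 10 samples.
#' @param spec A [split_spec()].
#' @return A list of cohorts `train`, `validation`, `test` plus `indices`
#'   (the integer index sets into the input cohort).
#' @export
split_cohort <- function(cohort, spec = split_spec()) {
  stopifnot(inherits(cohort, "proteomics_cohort"), inherits(spec, "split_spec"))
  n <- n_samples(cohort)
  if (n < 10L) stop("cohort too small to split (need >= 10 samples)", call. = FALSE)
  ord <- with_seed(spec$seed, sample.int(n))
  n_test <- floor(n * spec$test_fraction)
  pool <- n - n_test
  n_val <- floor(pool * spec$validation_fraction)
  n_train_full <- pool - n_val
  n_train <- floor(n_train_full * spec$train_fraction)
  if (n_test < 1L || n_val < 1L || n_train < 1L) {
    stop("empty split under this specification", call. = FALSE)
  }
  idx_test <- sort(ord[seq_len(n_test)])
  idx_val <- sort(ord[n_test + seq_len(n_val)])
  idx_train <- sort(ord[n_test + n_val + seq_len(n_train)])
  list(train = subset_cohort(cohort, idx_train),
       validation = subset_cohort(cohort, idx_val),
       test = subset_cohort(cohort, idx_test),
       indices = list(train = idx_train, validation = idx_val, test = idx_test))
}
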