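test_that("the noiseless single-set linear cohort equals its formula", {
  lib <- gene_set_library(list(ONLY = paste0("PROT", sprintf("%04d", 1:5))))
  cfg <- synthetic_config(n_samples = 50, n_proteins = 10, n_active_sets = 1,
                          signal = "linear", beta_set = 2, noise_sd = 0,
                          n_covariates = 0, missing_rate = 0, library = lib)
  co <- generate_cohort(cfg, seed = 3)
  truth <- cohort_truth(co)
  expect_equal(truth$active_sets, "ONLY")
  u <- rowMeans(co$expression[, 1:5])
  expect_equal(unname(co$phenotype), unname(2 * u), tolerance = 1e-12)
})

test_that("generation is seed-reproducible and missingness is calibrated", {
  cfg <- synthetic_config(n_samples = 1000, n_proteins = 200, n_sets = 40,
                          missing_rate = 0.1)
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$expression, b$expression)
  expect_identical(a$phenotype, b$phenotype)
  rate <- mean(a$missing_mask)
  se <- sqrt(0.1 * 0.9 / (1000 * 200))
  expect_lt(abs(rate - 0.1), 3 * se)
  c_ <- generate_cohort(cfg, seed = 12)
  expect_false(identical(a$phenotype, c_$phenotype))
})

test_that("noise calibration hits the requested signal fraction", {
  cfg <- synthetic_config(n_samples = 4000, n_proteins = 150, n_sets = 60,
                          n_active_sets = 8, target_r2 = 0.6,
                          missing_rate = 0)
  co <- generate_cohort(cfg, seed = 5)
  tr <- cohort_truth(co)
  realized <- var(tr$signal_values) /
    (var(tr$signal_values) + tr$noise_sd^2)
  expect_lt(abs(realized - 0.6), 0.03)
})

test_that("ontology-like libraries respect overlap and size constraints", {
  panel <- paste0("G", 1:400)
  disjoint <- make_go_like_library(panel, 20, overlap_rate = 0, seed = 2)
  all_members <- unlist(disjoint$sets)
  expect_equal(anyDuplicated(all_members), 0L) # overlap 0 -> disjoint
  expect_true(all(set_sizes(disjoint) >= 2))

  lib <- make_go_like_library(panel, 3000, overlap_rate = 0.2,
                              mean_set_size = 6, seed = 3)
  sz <- set_sizes(lib)
  se <- sqrt(4 / (1 / (1 + 6 - 2))^2) / sqrt(3000) # geometric sd / sqrt(n)
  expect_lt(abs(mean(sz) - 6), 4 * se)
  # infeasible disjoint request errors
  expect_error(make_go_like_library(paste0("G", 1:10), 50, overlap_rate = 0,
                                    mean_set_size = 5, seed = 1),
               "too small")
})

test_that("with sigma = 0 a linear model on true set means reaches R^2 = 1", {
  cfg <- synthetic_config(n_samples = 300, n_proteins = 60, n_sets = 12,
                          n_active_sets = 3, signal = "linear", noise_sd = 0,
                          missing_rate = 0, n_covariates = 2)
  co <- generate_cohort(cfg, seed = 9)
  tr <- cohort_truth(co)
  U <- sapply(tr$library$sets[tr$active_sets], function(m)
    rowMeans(co$expression[, m, drop = FALSE]))
  fitted <- lm(co$phenotype ~ U + co$covariates)
  # suppressed: lm warns about the (intended) essentially perfect fit
  expect_gt(suppressWarnings(summary(fitted)$r.squared), 1 - 1e-9)
})

test_that("quadratic signal is invisible to the best linear predictor", {
  cfg <- synthetic_config(n_samples = 3000, n_proteins = 100, n_sets = 20,
                          n_active_sets = 5, signal = "quadratic",
                          n_covariates = 0, missing_rate = 0, target_r2 = 0.6)
  co <- generate_cohort(cfg, seed = 17)
  fitted <- lm(co$phenotype ~ co$expression)
  # linear R^2 far below the planted signal fraction of 0.6
  expect_lt(summary(fitted)$r.squared, 0.2)
})

test_that("fixture bundles round-trip through the text loaders", {
  cfg <- synthetic_config(n_samples = 40, n_proteins = 15, n_sets = 6,
                          n_active_sets = 2, missing_rate = 0.05,
                          n_covariates = 3)
  co <- generate_cohort(cfg, seed = 21)
  lib <- cohort_truth(co)$library
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(co, lib, dir)
  back <- load_cohort(paths["expression"], paths["covariates"],
                      paths["phenotype"])
  expect_equal(back$sample_ids, co$sample_ids)
  expect_equal(back$missing_mask, co$missing_mask)
  got <- back$expression
  want <- co$expression
  want[co$missing_mask] <- NA
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(back$phenotype, co$phenotype, tolerance = 1e-10)
  lib_back <- read_gmt(paths["library"])
  expect_identical(lib_back$sets, lib$sets)
  truth_json <- jsonlite::read_json(paths["truth"])
  expect_length(truth_json$active_sets, 2)

  # a bundle without missingness loads with an all-false mask
  cfg0 <- synthetic_config(n_samples = 20, n_proteins = 8, n_sets = 4,
                           n_active_sets = 1, missing_rate = 0)
  co0 <- generate_cohort(cfg0, seed = 2)
  p0 <- write_fixture_bundle(co0, cohort_truth(co0)$library,
                             file.path(dir, "b0"))
  expect_false(any(load_cohort(p0["expression"], p0["covariates"],
                               p0["phenotype"])$missing_mask))
})

test_that("the planted quadratic is decodable from informed set aggregates", {
  # at the generator's default scale, 25% of the training pool (~240
  # samples) suffices for a penalized linear read-out of the informed
  # graph's squared set aggregates, while the permuted aggregates carry
  # far less signal -- the information content behind the inductive bias
  cohort <- mean_impute(generate_cohort(synthetic_config(), seed = 42))
  truth <- cohort_truth(cohort)
  lib <- filter_library(truth$library, cohort$panel)
  splits <- split_cohort(cohort, split_spec(train_fraction = 0.25, seed = 1))
  perm <- permute_protein_labels(cohort$panel, seed = 5)
  plib <- permute_library(lib, perm)
  ridge_r2 <- function(l) {
    agg <- function(co) {
      U <- vapply(l$sets, function(m)
        rowMeans(co$expression[, m, drop = FALSE]),
        numeric(n_samples(co)))
      cbind(U^2, co$covariates)
    }
    Ftr <- agg(splits$train)
    Fte <- agg(splits$test)
    mu <- colMeans(Ftr)
    Ftr <- sweep(Ftr, 2, mu)
    Fte <- sweep(Fte, 2, mu)
    ym <- mean(splits$train$phenotype)
    sv <- svd(Ftr)
    uty <- crossprod(sv$u, splits$train$phenotype - ym)
    max(vapply(10^seq(-1, 3, 0.5), function(lam) {
      b <- sv$v %*% (uty * sv$d / (sv$d^2 + lam))
      evaluate_r2(as.numeric(Fte %*% b) + ym, splits$test$phenotype)
    }, 0))
  }
  informed <- ridge_r2(lib)
  permuted <- ridge_r2(plib)
  expect_gt(informed, 0.2)
  expect_gt(informed - permuted, 0.1)
})

test_that("threshold and interaction signal modes generate reproducibly", {
  for (sig in c("threshold", "interaction")) {
    cfg <- synthetic_config(n_samples = 60, n_proteins = 30, n_sets = 8,
                            n_active_sets = 4, signal = sig,
                            missing_rate = 0, n_covariates = 2)
    a <- generate_cohort(cfg, seed = 8)
    b <- generate_cohort(cfg, seed = 8)
    expect_identical(a$phenotype, b$phenotype)
    expect_true(all(is.finite(a$phenotype)))
    expect_equal(length(cohort_truth(a)$active_sets), 4)
  }
  # more active sets than the library holds is rejected
  tiny <- synthetic_config(n_samples = 20, n_proteins = 20, n_sets = 3,
                           n_active_sets = 5)
  expect_error(generate_cohort(tiny, seed = 1), "exceeds library")
})
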