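# Small planted-signal splits shared by the training tests.
linear_splits <- function(n = 200, p = 12, seed = 21, noise = 0.05) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("P", 1:p)))
    beta <- rnorm(p)
    Cov <- cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n))
    y <- as.numeric(X %*% beta) + 0.5 * Cov[, "age"] + rnorm(n, 0, noise)
    co <- proteomics_cohort(X, Cov, y, sample_ids = sprintf("s%04d", 1:n))
    split_cohort(co, split_spec(seed = seed))
  })
}

tiny_gnn <- function(splits, seed = 1, dropout = 0) {
  lib <- random_library(splits$train$panel, 4, seed = 3)
  build_gnn(build_bipartite_graph(splits$train$panel, lib), 2,
            dropout_rate = dropout, hidden_widths = c(32, 8), seed = seed)
}

test_that("R^2 evaluation matches hand arithmetic and flags degeneracy", {
  expect_equal(evaluate_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  truth <- c(2, 4, 6, 8)
  expect_equal(evaluate_r2(rep(mean(truth), 4), truth), 0)
  pred <- c(1, 5, 5, 9)
  # SS_res = 1+1+1+1 = 4, SS_tot = 9+1+1+9 = 20
  expect_equal(evaluate_r2(pred, truth), 1 - 4 / 20)
  expect_error(evaluate_r2(c(1, 2), c(3, 3)), "zero-variance")
  expect_error(evaluate_r2(1, 1))
})

test_that("training is deterministic and learns a linear toy signal", {
  splits <- linear_splits()
  cfg <- train_config(max_epochs = 60, seed = 5, dropout_rate = 0)
  fit1 <- train_model(tiny_gnn(splits), splits, cfg)
  fit2 <- train_model(tiny_gnn(splits), splits, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$test_predictions, fit2$test_predictions)
  expect_gt(fit1$test_r2, 0.5)
  expect_lte(fit1$test_r2, 1)
  expect_lte(fit1$best_epoch, nrow(fit1$history))
  # restored weights achieve the recorded best validation loss
  expect_equal(fit1$best_validation_loss,
               min(fit1$history$validation_loss))
})

test_that("the scheduler halves the learning rate after five flat epochs", {
  # a low signal-to-noise target makes validation improvements rare, so the
  # plateau rule fires repeatedly within the epoch budget
  splits <- linear_splits(n = 100, noise = 6, seed = 2)
  cfg <- train_config(max_epochs = 60, seed = 2, dropout_rate = 0.3,
                      early_stopping_patience = 40)
  fit <- train_model(tiny_gnn(splits, dropout = 0.3), splits, cfg)
  h <- fit$history
  # replay the plateau logic from the recorded validation curve and check
  # the logged learning rates agree with it
  lr <- cfg$learning_rate
  best <- Inf
  wait <- 0
  for (e in seq_len(nrow(h))) {
    expect_equal(h$learning_rate[e], lr)
    if (h$validation_loss[e] < best) {
      best <- h$validation_loss[e]
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$scheduler_patience) {
        lr <- max(lr / 2, cfg$lr_floor)
        wait <- 0
      }
    }
  }
  # the run was long/noisy enough for at least one halving to occur
  expect_lt(min(h$learning_rate), cfg$learning_rate)
  # and the first halving happened exactly 5 epochs after a best epoch
  first_drop <- which(diff(h$learning_rate) < 0)[1] + 1
  expect_equal(h$learning_rate[first_drop], h$learning_rate[1] / 2)
})

test_that("early stopping terminates and never returns a worse epoch", {
  splits <- linear_splits(n = 120, noise = 3)
  cfg <- train_config(max_epochs = 300, seed = 3, dropout_rate = 0.3,
                      early_stopping_patience = 8)
  fit <- train_model(tiny_gnn(splits, dropout = 0.3), splits, cfg)
  h <- fit$history
  expect_lt(nrow(h), 300) # stopped early
  expect_equal(fit$best_validation_loss, min(h$validation_loss))
  expect_equal(fit$best_epoch, which.min(h$validation_loss))
  # after restoration the model reproduces the best validation loss
  std <- standardize_cohorts(splits$train, validation = splits$validation)
  yva <- (std$validation$phenotype - fit$model$y_center) / fit$model$y_scale
  pred <- (predict(fit$model, std$validation) - fit$model$y_center) /
    fit$model$y_scale
  expect_equal(mean((pred - yva)^2), fit$best_validation_loss,
               tolerance = 1e-10)
})

test_that("a constant phenotype is handled with a zero R^2 and warning", {
  splits <- linear_splits(n = 80)
  splits$train$phenotype[] <- 1
  splits$validation$phenotype[] <- 1
  splits$test$phenotype[] <- 1
  cfg <- train_config(max_epochs = 3, seed = 1, dropout_rate = 0)
  expect_warning(fit <- train_model(tiny_gnn(splits), splits, cfg),
                 "undefined")
  expect_equal(fit$test_r2, 0)
})

test_that("tidy and glance expose history and summary", {
  splits <- linear_splits(n = 100)
  fit <- train_model(tiny_gnn(splits),
                     splits, train_config(max_epochs = 5, seed = 1))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "train_loss", "validation_loss",
                     "learning_rate"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$test_r2, fit$test_r2)
  expect_equal(gl$n_parameters, count_parameters(fit$model))
})

test_that("hyperparameter selection minimizes validation loss with tie-breaks", {
  splits <- linear_splits(n = 150)
  factory <- function(dropout) tiny_gnn(splits, dropout = dropout)
  base <- train_config(max_epochs = 25, seed = 4)
  grid <- data.frame(learning_rate = c(1e-3, 1e-7),
                     dropout_rate = c(0, 0))
  sel <- select_hyperparameters(factory, splits, grid, base)
  expect_equal(nrow(sel$results), 2)
  expect_equal(sel$best_config$learning_rate,
               sel$results$learning_rate[which.min(sel$results$validation_loss)])
  # a one-point grid returns that point
  one <- select_hyperparameters(factory, splits,
                                data.frame(learning_rate = 1e-3,
                                           dropout_rate = 0.1), base)
  expect_equal(one$best_config$dropout_rate, 0.1)
  # exact ties break toward the lower learning rate
  fake <- list(validation_loss = c(1, 1))
  ord <- order(fake$validation_loss, c(1e-3, 1e-5), c(0.5, 0.5))
  expect_equal(ord[1], 2)
})

test_that("the informed FFNN learns a linear signal through its set layer", {
  splits <- linear_splits(n = 400, p = 10)
  # the three masks cover the whole panel, so the set layer can represent
  # any linear signal
  lib <- gene_set_library(list(
    S1 = paste0("P", 1:4), S2 = paste0("P", 4:8), S3 = paste0("P", 8:10)
  ))
  m <- build_informed_ffnn(splits$train$panel, lib, 2, dropout_rate = 0.2,
                           seed = 2)
  fit <- train_model(m, splits,
                     train_config(learning_rate = 1e-2, dropout_rate = 0.2,
                                  batch_size = 32, max_epochs = 200,
                                  early_stopping_patience = 40,
                                  scheduler_patience = 15, seed = 6))
  expect_gt(fit$test_r2, 0.8)
})
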