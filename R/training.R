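#' Training configuration
#'
#' Adam on mean-squared-error loss with an adaptive scheduler that halves
#' the learning rate after `scheduler_patience` epochs without validation
#' improvement ("improvement" = any strict decrease in validation MSE) and
#' early stopping after `early_stopping_patience` non-improving epochs.
#' The best-validation weights are restored before test evaluation.
#'
#' @param learning_rate Initial Adam learning rate (default 1e-3).
#' @param dropout_rate Dropout probability (default 0.5).
#' @param batch_size Minibatch size (default 128); the graph topology is
#'   shared, so batching is over node-feature columns.
#' @param max_epochs Epoch cap (default 200).
#' @param early_stopping_patience Non-improving epochs before stopping
#'   (default 15; must be at least `scheduler_patience`).
#' @param scheduler_patience Non-improving epochs before halving the
#'   learning rate (default 5).
#' @param lr_floor Smallest admissible learning rate (default 1e-8).
#' @param seed Integer seed for shuffling and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, dropout_rate = 0.5,
                         batch_size = 128, max_epochs = 200,
                         early_stopping_patience = 15, scheduler_patience = 5,
                         lr_floor = 1e-8, seed = 1) {
  stopifnot(learning_rate > 0, dropout_rate >= 0, dropout_rate < 1,
            batch_size >= 1, max_epochs >= 1,
            early_stopping_patience >= scheduler_patience,
            scheduler_patience >= 1, lr_floor > 0)
  structure(list(learning_rate = learning_rate, dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 scheduler_patience = as.integer(scheduler_patience),
                 lr_floor = lr_floor, seed = as.integer(seed)),
            class = "train_config")
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` of predictions against observed values.
#'
#' @param predictions,truth Equal-length numeric vectors (length >= 2).
#' @return A single numeric value (at most 1; can be negative).
#' @export
evaluate_r2 <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth), length(truth) >= 2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("zero-variance truth: R^2 undefined", call. = FALSE)
  1 - sum((truth - predictions)^2) / ss_tot
}

mse <- function(pred, truth) mean((pred - truth)^2)

#' Train a model on cohort splits
#'
#' End-to-end gradient training (GCN encoder and dense head jointly) with
#' Adam on MSE. Splits are standardized internally on training statistics
#' (expression, continuous covariates, and the phenotype), so raw imputed
#' splits from [split_cohort()] can be passed directly. After every epoch
#' the validation MSE is evaluated (dropout off); the learning rate is
#' halved after `scheduler_patience` epochs without strict improvement and
#' training stops after `early_stopping_patience` such epochs or
#' `max_epochs`. The returned model carries the best-validation weights.
#'
#' @param model A `setgnn_model` from [build_gnn()] or
#'   [build_informed_ffnn()].
#' @param splits List with `train`, `validation`, `test` cohorts (e.g. from
#'   [split_cohort()]).
#' @param config A [train_config()].
#' @return A `setgnn_fit`: the trained model, `history` tibble (epoch,
#'   train/validation loss, learning rate), `best_epoch`, `test_r2`,
#'   `test_predictions`, and the config. Use [tidy()] / [glance()].
#' @export
train_model <- function(model, splits, config = train_config()) {
  stopifnot(inherits(model, "setgnn_model"), inherits(config, "train_config"))
  for (nm in c("train", "validation", "test")) {
    if (is.null(splits[[nm]]) || n_samples(splits[[nm]]) == 0) {
      stop("empty ", nm, " split", call. = FALSE)
    }
  }
  std <- standardize_cohorts(splits$train, validation = splits$validation,
                             test = splits$test)
  y_center <- mean(std$train$phenotype)
  y_scale <- stats::sd(std$train$phenotype)
  if (is.na(y_scale) || y_scale == 0) y_scale <- 1
  ytr <- (std$train$phenotype - y_center) / y_scale
  yva <- (std$validation$phenotype - y_center) / y_scale
  model$dropout_rate <- config$dropout_rate
  model$y_center <- y_center
  model$y_scale <- y_scale
  Xtr <- std$train$expression; Ctr <- std$train$covariates
  Xva <- std$validation$expression; Cva <- std$validation$covariates
  n_tr <- nrow(Xtr)
  params <- trainable_params(model)
  opt <- adam_init(params)
  lr <- config$learning_rate
  best <- list(val = Inf, params = params, epoch = 0L,
               full = model$params)
  history <- vector("list", config$max_epochs)
  no_improve <- 0L
  sched_wait <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      batch_losses <- c()
      for (start in seq(1, n_tr, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n_tr)]
        if (length(idx) < 2 && !inherits(model, "gnn_model")) next # BN needs B >= 2
        fw <- model_forward(model, Xtr[idx, , drop = FALSE],
                            Ctr[idx, , drop = FALSE], training = TRUE)
        if (!inherits(model, "gnn_model")) model <- ffnn_commit_bn(model, fw)
        resid <- fw$out - ytr[idx]
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               " (learning rate ", lr, "); reduce the learning rate",
               call. = FALSE)
        }
        bk <- model_backward(model, fw, 2 * resid / length(idx))
        grads <- if (inherits(model, "gnn_model")) bk$grads else
          list(Ws = bk$grads$Ws, bs = bk$grads$bs, dense = bk$grads$dense,
               bn = bk$grads$bn)
        upd <- adam_step(params, grads, opt, lr)
        params <- upd$params
        opt <- upd$state
        model <- set_trainable_params(model, params)
        batch_losses <- c(batch_losses, loss)
      }
      val_pred <- model_forward(model, Xva, Cva, training = FALSE)$out
      val_loss <- mse(as.numeric(val_pred), yva)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(batch_losses),
        validation_loss = val_loss, learning_rate = lr
      )
      if (val_loss < best$val) {
        best <- list(val = val_loss, params = params, epoch = epoch,
                     full = model$params)
        no_improve <- 0L
        sched_wait <- 0L
      } else {
        no_improve <- no_improve + 1L
        sched_wait <- sched_wait + 1L
        if (sched_wait >= config$scheduler_patience) {
          lr <- max(lr / 2, config$lr_floor)
          sched_wait <- 0L
        }
      }
      if (no_improve >= config$early_stopping_patience) break
    }
  })
  model$params <- best$full
  model <- set_trainable_params(model, best$params)
  test_pred <- predict(model, std$test)
  test_r2 <- tryCatch(evaluate_r2(test_pred, splits$test$phenotype),
                      error = function(e) {
                        warning("test R^2 undefined (", conditionMessage(e),
                                "); reported as 0", call. = FALSE)
                        0
                      })
  structure(list(
    model = model,
    standardization = std$stats,
    best_epoch = best$epoch,
    best_validation_loss = best$val,
    history = dplyr::bind_rows(history[!vapply(history, is.null, TRUE)]),
    test_r2 = test_r2,
    test_predictions = test_pred,
    test_truth = splits$test$phenotype,
    config = config,
    seed = config$seed
  ), class = "setgnn_fit")
}

#' @export
print.setgnn_fit <- function(x, ...) {
  cat("<setgnn_fit> ", x$model$kind, ": best epoch ", x$best_epoch,
      " (validation MSE ", signif(x$best_validation_loss, 4),
      "), test R^2 ", signif(x$test_r2, 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn train_model Per-epoch training history as a tibble.
#' @param x,object A `setgnn_fit`.
#' @param ... Unused.
#' @export
tidy.setgnn_fit <- function(x, ...) x$history

#' @describeIn train_model One-row fit summary.
#' @export
glance.setgnn_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$model$kind,
    n_parameters = count_parameters(x$model),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_validation_loss = x$best_validation_loss,
    test_r2 = x$test_r2,
    seed = x$seed
  )
}

#' Select hyperparameters on the validation split
#'
#' Trains once per grid point and returns the configuration minimizing
#' validation MSE; ties are broken by lower learning rate, then lower
#' dropout rate.
#'
#' @param model_factory Function `(dropout_rate)` returning a fresh
#'   `setgnn_model` (called per grid point so initialization is identical).
#' @param splits As in [train_model()].
#' @param grid Data frame with columns `learning_rate` and `dropout_rate`.
#' @param config Base [train_config()] supplying the remaining settings.
#' @return List with `best_config` (a `train_config`), `best_fit`, and
#'   `results` (tibble of grid points and validation losses).
#' @export
select_hyperparameters <- function(model_factory, splits, grid,
                                   config = train_config()) {
  grid <- as.data.frame(grid)
  stopifnot(nrow(grid) >= 1,
            all(c("learning_rate", "dropout_rate") %in% names(grid)))
  fits <- vector("list", nrow(grid))
  val <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$learning_rate <- grid$learning_rate[i]
    cfg$dropout_rate <- grid$dropout_rate[i]
    fits[[i]] <- tryCatch(
      train_model(model_factory(grid$dropout_rate[i]), splits, cfg),
      error = function(e) NULL
    )
    if (!is.null(fits[[i]])) val[i] <- fits[[i]]$best_validation_loss
  }
  if (all(is.na(val))) stop("all hyperparameter runs diverged", call. = FALSE)
  ord <- order(val, grid$learning_rate, grid$dropout_rate)
  best <- ord[1]
  best_cfg <- config
  best_cfg$learning_rate <- grid$learning_rate[best]
  best_cfg$dropout_rate <- grid$dropout_rate[best]
  list(best_config = best_cfg, best_fit = fits[[best]],
       results = tibble::tibble(learning_rate = grid$learning_rate,
                                dropout_rate = grid$dropout_rate,
                                validation_loss = val))
}
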