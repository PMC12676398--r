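#' Gradient saliency over graph input features
#'
#' For each test sample the gradient of the per-sample squared-error loss
#' (or, optionally, of the raw prediction) with respect to every input node
#' feature is computed by backpropagation through the trained model —
#' protein features and the constant-initialized set features alike (set
#' nodes receive gradients through message passing even though they are
#' never fed to the dense head). Absolute values are averaged across test
#' samples to give one importance score per node.
#'
#' @param fit A `setgnn_fit` wrapping a trained `gnn_model`, or a trained
#'   `gnn_model` itself (then `cohort` must already be standardized and
#'   phenotype scaling is taken from the model).
#' @param cohort Test cohort. When `fit` is a `setgnn_fit`, raw imputed
#'   cohorts are accepted and standardized with the fit's training
#'   statistics.
#' @param target `"loss"` (default) backpropagates the per-sample squared
#'   error; `"output"` backpropagates the raw prediction.
#' @param average `"mean"` (default) or `"median"` across samples.
#' @return A `saliency_report` tibble: `node_id`, `node_type`
#'   (`"protein"`/`"set"`), `subgraph`, `score`, `n_samples`.
#' @export
compute_saliency <- function(fit, cohort, target = c("loss", "output"),
                             average = c("mean", "median")) {
  target <- match.arg(target)
  average <- match.arg(average)
  if (inherits(fit, "setgnn_fit")) {
    model <- fit$model
    st <- fit$standardization
    X <- sweep(sweep(cohort$expression, 2, st$center), 2, st$scale, "/")
    Cov <- sweep(sweep(cohort$covariates, 2, st$cov_center), 2, st$cov_scale, "/")
  } else {
    model <- fit
    X <- cohort$expression
    Cov <- cohort$covariates
  }
  if (!inherits(model, "gnn_model")) {
    stop("saliency requires a GNN model with gradient support", call. = FALSE)
  }
  y <- (cohort$phenotype - model$y_center) / model$y_scale
  fw <- model_forward(model, X, Cov, training = FALSE)
  dout <- if (target == "loss") 2 * (fw$out - y) else
    matrix(1, nrow(fw$out), 1)
  bk <- gnn_backward(model, fw, dout)
  agg <- if (average == "mean") {
    function(m) rowMeans(abs(m))
  } else {
    function(m) apply(abs(m), 1, stats::median)
  }
  reports <- lapply(seq_along(model$graphs), function(i) {
    g <- model$graphs[[i]]
    sc <- agg(bk$dN0[[i]])
    tibble::tibble(
      node_id = c(g$panel, g$set_ids),
      node_type = rep(c("protein", "set"), c(g$n_proteins, g$n_sets)),
      subgraph = g$library_name,
      score = sc,
      n_samples = nrow(X)
    )
  })
  out <- dplyr::bind_rows(reports)
  class(out) <- c("saliency_report", class(out))
  out
}

#' Rank nodes by saliency
#'
#' Descending by score, ties broken lexicographically by node id.
#'
#' @param report A `saliency_report` from [compute_saliency()].
#' @param node_type Restrict to `"protein"` or `"set"` nodes (default both).
#' @param top_k Number of nodes to keep (default 20, the usual reporting
#'   depth); if larger than the node count, all nodes are returned with a
#'   warning.
#' @return The ranked tibble with a `rank` column.
#' @export
rank_nodes <- function(report, node_type = NULL, top_k = 20) {
  stopifnot(inherits(report, "saliency_report") || is.data.frame(report))
  out <- report
  if (!is.null(node_type)) {
    nt <- match.arg(node_type, c("protein", "set"))
    out <- dplyr::filter(out, .data$node_type == nt)
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$node_id)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  if (top_k > nrow(out)) {
    warning("top_k = ", top_k, " exceeds node count ", nrow(out),
            "; returning all nodes", call. = FALSE)
    top_k <- nrow(out)
  }
  dplyr::slice_head(out, n = top_k)
}

#' Plot top saliency scores
#'
#' Horizontal bar chart of the top-k nodes by mean absolute gradient.
#'
#' @param object A `saliency_report`.
#' @param node_type `"set"` (default) or `"protein"`.
#' @param top_k Bars to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saliency_report <- function(object, node_type = "set", top_k = 20, ...) {
  ranked <- suppressWarnings(rank_nodes(object, node_type = node_type,
                                        top_k = top_k))
  ggplot2::ggplot(ranked, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$node_id, .data$score)
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "mean |gradient|", y = NULL,
                  title = paste("Top", nrow(ranked), node_type, "nodes")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
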