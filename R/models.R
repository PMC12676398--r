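#' Graph convolution layer
#'
#' One GCN propagation step over a bipartite graph:
#' `tanh( Ahat %*% features %*% weights )`, where `Ahat` is the graph's
#' degree-normalized adjacency with self-loops (see
#' [build_bipartite_graph()]). Exposed mainly for verification against a
#' dense hand-computed oracle; the architectures below stack two of these
#' (dimensions 1 -> 2 -> 1).
#'
#' @param features Numeric matrix, nodes x d_in.
#' @param graph A `bipartite_graph`.
#' @param weights Numeric matrix, d_in x d_out.
#' @return Numeric matrix, nodes x d_out, entries in (-1, 1).
#' @export
gcn_layer <- function(features, graph, weights) {
  stopifnot(inherits(graph, "bipartite_graph"))
  features <- as.matrix(features)
  weights <- as.matrix(weights)
  n <- graph$n_proteins + graph$n_sets
  if (nrow(features) != n) stop("features must have one row per node", call. = FALSE)
  if (ncol(features) != nrow(weights)) stop("dimension mismatch", call. = FALSE)
  tanh(as.matrix(graph$adjacency_hat %*% features %*% weights))
}

# ---- Model construction ----------------------------------------------

new_gcn_params <- function() {
  list(W1 = glorot_uniform(1, 2), W2 = glorot_uniform(2, 1))
}

new_dense_params <- function(widths) {
  out <- list()
  for (l in seq_len(length(widths) - 1)) {
    out[[paste0("W", l)]] <- glorot_uniform(widths[l], widths[l + 1])
    out[[paste0("b", l)]] <- rep(0, widths[l + 1])
  }
  out
}

#' Build a graph neural network model
#'
#' Constructs one of the three GNN architectures over a fixed graph
#' topology:
#' * `single_head` — one bipartite graph; the dense head consumes the
#'   protein embedding plus covariates.
#' * `parallel` — k independent subgraphs (a `protein_multigraph`); the k
#'   protein embeddings are concatenated with the raw expression vector
#'   (global head) and covariates.
#' * `large_single_head` — one merged graph (see [build_merged_graph()]);
#'   architecture otherwise identical to the parallel model, including the
#'   global head.
#'
#' All variants share the GCN encoder (two layers, dims 1 -> 2 -> 1, tanh)
#' and a four-layer dense head with widths
#' `[2 * embedding_dim + extra_inputs, 256, 32, 1]`, LeakyReLU(0.01) after
#' the first three affine layers, linear output, and dropout after each
#' LeakyReLU.
#'
#' @param graph A `bipartite_graph` (single/merged head) or
#'   `protein_multigraph` (parallel).
#' @param n_covariates Number of scalar covariates appended to the head.
#' @param kind Architecture; inferred from the graph class when omitted
#'   (`parallel` for a multigraph, `single_head` otherwise).
#' @param dropout_rate Dropout probability in `[0, 1)` (default 0.5).
#' @param include_global_head Concatenate the raw expression vector before
#'   the dense head. Defaults to `TRUE` for `parallel` and
#'   `large_single_head`, `FALSE` for `single_head`.
#' @param hidden_widths Interior dense widths (default `c(256, 32)`).
#' @param seed Integer seed for Glorot-uniform initialization.
#' @return A `gnn_model` (also class `setgnn_model`).
#' @export
build_gnn <- function(graph, n_covariates, kind = NULL, dropout_rate = 0.5,
                      include_global_head = NULL, hidden_widths = c(256, 32),
                      seed = 1) {
  if (inherits(graph, "bipartite_graph")) {
    graphs <- list(graph)
    kind <- kind %||% "single_head"
  } else if (inherits(graph, "protein_multigraph")) {
    graphs <- graph$subgraphs
    kind <- kind %||% "parallel"
  } else stop("graph must be a bipartite_graph or protein_multigraph", call. = FALSE)
  kind <- match.arg(kind, c("single_head", "parallel", "large_single_head"))
  stopifnot(dropout_rate >= 0, dropout_rate < 1, n_covariates >= 0)
  include_global_head <- include_global_head %||%
    (kind %in% c("parallel", "large_single_head"))
  P <- graphs[[1]]$n_proteins
  k <- length(graphs)
  emb_dim <- k * P
  extra <- n_covariates + if (include_global_head) P else 0
  widths <- c(emb_dim + extra, 2 * emb_dim + extra, hidden_widths, 1)
  params <- with_seed(seed, list(
    gcn = lapply(graphs, function(g) new_gcn_params()),
    dense = new_dense_params(widths)
  ))
  structure(list(
    kind = kind,
    graphs = graphs,
    panel = graphs[[1]]$panel,
    n_proteins = P,
    n_covariates = n_covariates,
    n_subgraphs = k,
    include_global_head = include_global_head,
    dropout_rate = dropout_rate,
    widths = widths,
    params = params,
    y_center = 0, y_scale = 1
  ), class = c("gnn_model", "setgnn_model"))
}

#' @export
print.gnn_model <- function(x, ...) {
  cat("<gnn_model> ", x$kind, ": ", x$n_subgraphs, " subgraph(s), P = ",
      x$n_proteins, ", C = ", x$n_covariates,
      if (x$include_global_head) ", global head", "\n  dense widths: ",
      paste(x$widths, collapse = " -> "), "\n  trainable parameters: ",
      count_parameters(x), "\n", sep = "")
  invisible(x)
}

#' Build the informed feed-forward baseline
#'
#' A feed-forward network whose first hidden layer has one unit per gene
#' set, connected only to that set's member proteins in the input layer (a
#' sparsity mask over the first weight matrix). Covariates are concatenated
#' after this set layer. Hidden widths are
#' `[n_sets, 256, 128, 64, 32]` followed by a linear output; the set layer
#' uses tanh, later layers LeakyReLU(0.01); batch normalization and dropout
#' are applied to every hidden layer.
#'
#' @param panel Protein panel.
#' @param lib A non-empty `gene_set_library` filtered against `panel`.
#' @param n_covariates Number of scalar covariates.
#' @param dropout_rate Dropout probability (default 0.5).
#' @param seed Integer seed for initialization.
#' @return An `informed_ffnn` model (also class `setgnn_model`).
#' @export
build_informed_ffnn <- function(panel, lib, n_covariates, dropout_rate = 0.5,
                                seed = 1) {
  panel <- protein_panel(panel)
  stopifnot(inherits(lib, "gene_set_library"))
  if (length(lib) == 0L) stop("empty library: no first hidden layer", call. = FALSE)
  members <- unlist(lib$sets, use.names = FALSE)
  if (!all(members %in% panel)) stop("library not filtered against panel", call. = FALSE)
  P <- length(panel)
  S <- length(lib)
  mask <- matrix(0, P, S, dimnames = list(panel, names(lib$sets)))
  mask[cbind(match(members, panel),
             rep(seq_len(S), times = lengths(lib$sets)))] <- 1
  widths <- c(S + n_covariates, 256, 128, 64, 32, 1)
  params <- with_seed(seed, {
    p <- list(Ws = glorot_uniform(P, S) * mask, bs = rep(0, S),
              dense = new_dense_params(widths))
    p$bn <- c(list(bn_init(S)),
              lapply(widths[2:(length(widths) - 1)], bn_init))
    p
  })
  structure(list(
    kind = "informed_ffnn",
    panel = panel,
    set_ids = names(lib$sets),
    mask = mask,
    n_proteins = P,
    n_sets = S,
    n_covariates = n_covariates,
    dropout_rate = dropout_rate,
    widths = widths,
    params = params,
    y_center = 0, y_scale = 1
  ), class = c("informed_ffnn", "setgnn_model"))
}

#' @export
print.informed_ffnn <- function(x, ...) {
  cat("<informed_ffnn> P = ", x$n_proteins, ", set layer = ", x$n_sets,
      ", C = ", x$n_covariates, "\n  widths: ",
      paste(c(x$n_sets, 256, 128, 64, 32, 1), collapse = " -> "),
      "\n  trainable parameters: ", count_parameters(x), "\n", sep = "")
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (masked-out entries of the informed
#' FFNN's sparse first layer are excluded; batch-norm running statistics
#' are not trainable and are not counted). Used to verify that permuted
#' null controls are capacity-matched to their informed partners.
#'
#' @param model A `setgnn_model` or `ridge_fit`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.gnn_model <- function(model) {
  n_gcn <- length(model$params$gcn) * 4L # W1 (1x2) + W2 (2x1) per subgraph
  n_dense <- sum(vapply(model$params$dense, length, 0L))
  n_gcn + n_dense
}

#' @export
count_parameters.informed_ffnn <- function(model) {
  sum(model$mask) + length(model$params$bs) +
    sum(vapply(model$params$dense, length, 0L)) +
    sum(vapply(model$params$bn, function(b) length(b$gamma) + length(b$beta), 0L))
}

#' @export
count_parameters.ridge_fit <- function(model) {
  length(model$coef) + 1L # + intercept
}

# ---- Forward / backward: GNN -----------------------------------------

# Encode one subgraph for a batch. X: B x P standardized expression.
# Returns the protein embedding (B x P) plus intermediates for backward.
gcn_encode <- function(graph, gp, X) {
  N0 <- init_node_feature_matrix(graph, X) # n x B
  Ahat <- graph$adjacency_hat
  M <- as.matrix(Ahat %*% N0)
  H1a <- tanh(M * gp$W1[1, 1])
  H1b <- tanh(M * gp$W1[1, 2])
  A1a <- as.matrix(Ahat %*% H1a)
  A1b <- as.matrix(Ahat %*% H1b)
  H2 <- tanh(A1a * gp$W2[1, 1] + A1b * gp$W2[2, 1])
  list(M = M, H1a = H1a, H1b = H1b, A1a = A1a, A1b = A1b, H2 = H2,
       E = t(H2[seq_len(graph$n_proteins), , drop = FALSE]))
}

# Backward through one subgraph given dE (B x P). Returns GCN weight
# gradients and the gradient w.r.t. the input node features (n x B).
gcn_encode_backward <- function(graph, gp, cache, dE) {
  P <- graph$n_proteins
  n <- P + graph$n_sets
  Ahat <- graph$adjacency_hat
  dH2 <- matrix(0, n, ncol(cache$M))
  dH2[seq_len(P), ] <- t(dE)
  dZ2 <- dH2 * (1 - cache$H2^2)
  gW2 <- matrix(c(sum(cache$A1a * dZ2), sum(cache$A1b * dZ2)), 2, 1)
  dA1a <- dZ2 * gp$W2[1, 1]
  dA1b <- dZ2 * gp$W2[2, 1]
  dH1a <- as.matrix(Ahat %*% dA1a)
  dH1b <- as.matrix(Ahat %*% dA1b)
  dZ1a <- dH1a * (1 - cache$H1a^2)
  dZ1b <- dH1b * (1 - cache$H1b^2)
  gW1 <- matrix(c(sum(cache$M * dZ1a), sum(cache$M * dZ1b)), 1, 2)
  dM <- dZ1a * gp$W1[1, 1] + dZ1b * gp$W1[1, 2]
  dN0 <- as.matrix(Ahat %*% dM)
  list(gcn = list(W1 = gW1, W2 = gW2), dN0 = dN0)
}

# Full forward. Returns prediction column (B x 1) and caches.
gnn_forward <- function(model, X, Cov, training = FALSE) {
  enc <- lapply(seq_along(model$graphs), function(i) {
    gcn_encode(model$graphs[[i]], model$params$gcn[[i]], X)
  })
  D0 <- do.call(cbind, c(lapply(enc, `[[`, "E"),
                         if (model$include_global_head) list(X),
                         if (model$n_covariates > 0) list(Cov)))
  dn <- model$params$dense
  rate <- if (training) model$dropout_rate else 0
  B <- nrow(D0)
  Z1 <- sweep(D0 %*% dn$W1, 2, dn$b1, "+"); A1 <- leaky_relu(Z1)
  m1 <- dropout_mask(B, ncol(A1), rate); U1 <- if (is.null(m1)) A1 else A1 * m1
  Z2 <- sweep(U1 %*% dn$W2, 2, dn$b2, "+"); A2 <- leaky_relu(Z2)
  m2 <- dropout_mask(B, ncol(A2), rate); U2 <- if (is.null(m2)) A2 else A2 * m2
  Z3 <- sweep(U2 %*% dn$W3, 2, dn$b3, "+"); A3 <- leaky_relu(Z3)
  m3 <- dropout_mask(B, ncol(A3), rate); U3 <- if (is.null(m3)) A3 else A3 * m3
  out <- sweep(U3 %*% dn$W4, 2, dn$b4, "+")
  list(out = out, enc = enc, D0 = D0, X = X,
       Z1 = Z1, U1 = U1, Z2 = Z2, U2 = U2, Z3 = Z3, U3 = U3,
       m1 = m1, m2 = m2, m3 = m3)
}

# Backward from dout (B x 1). Returns grads (same shape as params), the
# gradient w.r.t. the expression input (B x P, all paths), and per-subgraph
# input node-feature gradients (for saliency).
gnn_backward <- function(model, fw, dout) {
  dn <- model$params$dense
  bp <- function(dU, m) if (is.null(m)) dU else dU * m
  gW4 <- t(fw$U3) %*% dout; gb4 <- colSums(dout)
  dU3 <- dout %*% t(dn$W4)
  dZ3 <- bp(dU3, fw$m3) * leaky_relu_grad(fw$Z3)
  gW3 <- t(fw$U2) %*% dZ3; gb3 <- colSums(dZ3)
  dU2 <- dZ3 %*% t(dn$W3)
  dZ2 <- bp(dU2, fw$m2) * leaky_relu_grad(fw$Z2)
  gW2 <- t(fw$U1) %*% dZ2; gb2 <- colSums(dZ2)
  dU1 <- dZ2 %*% t(dn$W2)
  dZ1 <- bp(dU1, fw$m1) * leaky_relu_grad(fw$Z1)
  gW1 <- t(fw$D0) %*% dZ1; gb1 <- colSums(dZ1)
  dD0 <- dZ1 %*% t(dn$W1)
  P <- model$n_proteins
  k <- model$n_subgraphs
  gcn_grads <- vector("list", k)
  dN0 <- vector("list", k)
  dX <- matrix(0, nrow(fw$X), P)
  for (i in seq_len(k)) {
    dE <- dD0[, ((i - 1) * P + 1):(i * P), drop = FALSE]
    bk <- gcn_encode_backward(model$graphs[[i]], model$params$gcn[[i]],
                              fw$enc[[i]], dE)
    gcn_grads[[i]] <- bk$gcn
    dN0[[i]] <- bk$dN0
    dX <- dX + t(bk$dN0[seq_len(P), , drop = FALSE])
  }
  off <- k * P
  if (model$include_global_head) {
    dX <- dX + dD0[, (off + 1):(off + P), drop = FALSE]
  }
  list(grads = list(gcn = gcn_grads,
                    dense = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                                 W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)),
       dX = dX, dN0 = dN0)
}

# ---- Forward / backward: informed FFNN -------------------------------

ffnn_forward <- function(model, X, Cov, training = FALSE) {
  p <- model$params
  rate <- if (training) model$dropout_rate else 0
  B <- nrow(X)
  Wm <- p$Ws * model$mask
  Zs <- sweep(X %*% Wm, 2, p$bs, "+")
  bn1 <- bn_forward(Zs, p$bn[[1]], training)
  Hs <- tanh(bn1$out)
  ms <- dropout_mask(B, ncol(Hs), rate); Us <- if (is.null(ms)) Hs else Hs * ms
  D0 <- if (model$n_covariates > 0) cbind(Us, Cov) else Us
  caches <- list(Zs = Zs, bn1 = bn1, Hs = Hs, ms = ms, D0 = D0)
  H <- D0
  n_dense <- length(model$widths) - 1
  for (l in seq_len(n_dense)) {
    W <- p$dense[[paste0("W", l)]]; b <- p$dense[[paste0("b", l)]]
    Z <- sweep(H %*% W, 2, b, "+")
    if (l < n_dense) {
      bnc <- bn_forward(Z, p$bn[[l + 1]], training)
      A <- leaky_relu(bnc$out)
      m <- dropout_mask(B, ncol(A), rate)
      U <- if (is.null(m)) A else A * m
      caches[[paste0("L", l)]] <- list(H_in = H, Z = Z, bn = bnc, A = A, m = m)
      H <- U
    } else {
      caches[[paste0("L", l)]] <- list(H_in = H, Z = Z)
      H <- Z
    }
  }
  c(list(out = H, X = X), caches)
}

ffnn_backward <- function(model, fw, dout) {
  p <- model$params
  n_dense <- length(model$widths) - 1
  dH <- dout
  g_dense <- list()
  g_bn <- vector("list", length(p$bn))
  for (l in rev(seq_len(n_dense))) {
    cache <- fw[[paste0("L", l)]]
    W <- p$dense[[paste0("W", l)]]
    if (l < n_dense) {
      dU <- dH
      dA <- if (is.null(cache$m)) dU else dU * cache$m
      dBNout <- dA * leaky_relu_grad(cache$bn$out)
      bb <- bn_backward(dBNout, cache$bn, cache$Z, p$bn[[l + 1]]$gamma)
      dZ <- bb$dZ
      g_bn[[l + 1]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    } else {
      dZ <- dH
    }
    g_dense[[paste0("W", l)]] <- t(cache$H_in) %*% dZ
    g_dense[[paste0("b", l)]] <- colSums(dZ)
    dH <- dZ %*% t(W)
  }
  S <- model$n_sets
  dUs <- dH[, seq_len(S), drop = FALSE]
  dHs <- if (is.null(fw$ms)) dUs else dUs * fw$ms
  dBN1out <- dHs * (1 - fw$Hs^2)
  bb1 <- bn_backward(dBN1out, fw$bn1, fw$Zs, p$bn[[1]]$gamma)
  g_bn[[1]] <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  dZs <- bb1$dZ
  gWs <- (t(fw$X) %*% dZs) * model$mask
  gbs <- colSums(dZs)
  dX <- dZs %*% t(p$Ws * model$mask)
  list(grads = list(Ws = gWs, bs = gbs,
                    dense = g_dense[paste0(rep(c("W", "b"), n_dense),
                                           rep(seq_len(n_dense), each = 2))],
                    bn = g_bn),
       dX = dX)
}

# BN forward mutates running stats during training; commit them back.
ffnn_commit_bn <- function(model, fw) {
  model$params$bn[[1]]$run_mean <- fw$bn1$bn$run_mean
  model$params$bn[[1]]$run_var <- fw$bn1$bn$run_var
  n_dense <- length(model$widths) - 1
  for (l in seq_len(n_dense - 1)) {
    cache <- fw[[paste0("L", l)]]
    model$params$bn[[l + 1]]$run_mean <- cache$bn$bn$run_mean
    model$params$bn[[l + 1]]$run_var <- cache$bn$bn$run_var
  }
  model
}

# Dispatch helpers shared by training and prediction.
model_forward <- function(model, X, Cov, training = FALSE) {
  if (inherits(model, "gnn_model")) gnn_forward(model, X, Cov, training)
  else ffnn_forward(model, X, Cov, training)
}

model_backward <- function(model, fw, dout) {
  if (inherits(model, "gnn_model")) gnn_backward(model, fw, dout)
  else ffnn_backward(model, fw, dout)
}

# Trainable parameter subtree (informed FFNN keeps BN running stats
# alongside gamma/beta; Adam must only touch the trainable leaves).
trainable_params <- function(model) {
  if (inherits(model, "gnn_model")) {
    model$params
  } else {
    list(Ws = model$params$Ws, bs = model$params$bs,
         dense = model$params$dense,
         bn = lapply(model$params$bn, function(b) b[c("gamma", "beta")]))
  }
}

set_trainable_params <- function(model, params) {
  if (inherits(model, "gnn_model")) {
    model$params <- params
  } else {
    model$params$Ws <- params$Ws * model$mask
    model$params$bs <- params$bs
    model$params$dense <- params$dense
    for (i in seq_along(params$bn)) {
      model$params$bn[[i]]$gamma <- params$bn[[i]]$gamma
      model$params$bn[[i]]$beta <- params$bn[[i]]$beta
    }
  }
  model
}

#' Encode proteins through the GCN layers
#'
#' Runs only the two-layer GCN encoder of a `gnn_model` and returns the
#' per-protein embedding (set-node outputs are discarded), in panel order.
#' Values lie strictly in (-1, 1).
#'
#' @param model A `gnn_model`.
#' @param expression Numeric vector over the panel, or a samples x proteins
#'   matrix.
#' @param subgraph Which subgraph's encoder to use (default 1).
#' @return A samples x proteins embedding matrix (one row for a vector
#'   input).
#' @export
encode_proteins <- function(model, expression, subgraph = 1) {
  stopifnot(inherits(model, "gnn_model"))
  X <- if (is.matrix(expression)) expression else matrix(expression, nrow = 1)
  if (ncol(X) != model$n_proteins) stop("expression length != panel size", call. = FALSE)
  gcn_encode(model$graphs[[subgraph]], model$params$gcn[[subgraph]], X)$E
}

#' Predict phenotype values
#'
#' Deterministic inference (dropout disabled; batch normalization uses
#' running statistics). Output is independent of how samples are batched
#' for GNN models, whose topology is shared across individuals.
#'
#' @param object A trained `setgnn_model`.
#' @param newdata A (standardized) `proteomics_cohort`, or a list with
#'   `expression` and `covariates` matrices.
#' @param ... Unused.
#' @return Numeric vector of predictions on the original phenotype scale.
#' @export
predict.setgnn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "proteomics_cohort")) {
    X <- newdata$expression
    Cov <- newdata$covariates
  } else {
    X <- as.matrix(newdata$expression)
    Cov <- as.matrix(newdata$covariates)
  }
  if (ncol(X) != object$n_proteins) stop("expression width != panel size", call. = FALSE)
  if (object$n_covariates > 0 && ncol(Cov) != object$n_covariates) {
    stop("covariate width mismatch", call. = FALSE)
  }
  fw <- model_forward(object, X, Cov, training = FALSE)
  as.numeric(fw$out) * object$y_scale + object$y_center
}
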