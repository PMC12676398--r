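#' Bipartite protein/set graphs
#'
#' One node partition holds the measured proteins (panel order), the other
#' the gene sets of a filtered library (library order); undirected edges
#' encode set membership and every node carries a self-loop so that
#' unconnected proteins still participate in message passing. Node order is
#' proteins first, then sets; all downstream flattening relies on this.
#'
#' The symmetric degree-normalized adjacency
#' \eqn{\hat A = D^{-1/2}(A + I)D^{-1/2}} (self-loop-inclusive degrees) is
#' precomputed once, since the topology is shared by all individuals — only
#' node features vary per sample.
#'
#' @param panel Protein panel (defines protein-node order).
#' @param lib A `gene_set_library` already filtered against `panel`
#'   (see [filter_library()]); an empty library yields isolated protein
#'   nodes with self-loops only.
#' @param set_constant Scalar used to initialize every set node's feature
#'   (default 1.0; any nonzero constant is equivalent up to first-layer
#'   weight scaling).
#' @param normalization `"sym"` (default) for symmetric degree
#'   normalization, `"mean"` for row-mean aggregation.
#' @return A `bipartite_graph`.
#' @export
build_bipartite_graph <- function(panel, lib, set_constant = 1.0,
                                  normalization = c("sym", "mean")) {
  panel <- protein_panel(panel)
  stopifnot(inherits(lib, "gene_set_library"))
  normalization <- match.arg(normalization)
  members <- unlist(lib$sets, use.names = FALSE)
  unknown <- setdiff(members, panel)
  if (length(unknown)) {
    stop("library references protein(s) not in panel: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         "; filter_library() first", call. = FALSE)
  }
  P <- length(panel)
  S <- length(lib)
  p_idx <- match(members, panel)
  s_idx <- rep(seq_len(S), times = lengths(lib$sets))
  edges <- cbind(protein = p_idx, set = s_idx)
  g <- structure(list(
    panel = panel,
    set_ids = names(lib$sets),
    library_name = lib$name,
    edges = edges,
    n_proteins = P,
    n_sets = S,
    set_constant = set_constant,
    normalization = normalization
  ), class = "bipartite_graph")
  g$adjacency_hat <- normalized_adjacency(g)
  g
}

# \hat A for GCN propagation; nodes are proteins 1..P then sets P+1..P+S.
normalized_adjacency <- function(g) {
  n <- g$n_proteins + g$n_sets
  i <- c(g$edges[, 1], g$edges[, 2] + g$n_proteins, seq_len(n))
  j <- c(g$edges[, 2] + g$n_proteins, g$edges[, 1], seq_len(n))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  if (g$normalization == "sym") {
    d <- 1 / sqrt(deg)
    Matrix::Diagonal(n, d) %*% A %*% Matrix::Diagonal(n, d)
  } else {
    Matrix::Diagonal(n, 1 / deg) %*% A
  }
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat("<bipartite_graph> ", x$n_proteins, " proteins + ", x$n_sets,
      " sets (", x$library_name, "), ", nrow(x$edges),
      " membership edges + self-loops\n", sep = "")
  invisible(x)
}

#' Degree sequences of a bipartite graph
#'
#' Membership-edge degrees (self-loops excluded) for one partition.
#'
#' @param graph A `bipartite_graph`.
#' @param partition `"protein"` or `"set"`.
#' @return Named integer vector of degrees.
#' @export
degree_sequence <- function(graph, partition = c("protein", "set")) {
  partition <- match.arg(partition)
  if (partition == "protein") {
    deg <- tabulate(graph$edges[, 1], nbins = graph$n_proteins)
    names(deg) <- graph$panel
  } else {
    deg <- tabulate(graph$edges[, 2], nbins = graph$n_sets)
    names(deg) <- graph$set_ids
  }
  deg
}

#' Merge several libraries into one dense single-head graph
#'
#' Concatenates the set partitions of two or more filtered libraries into
#' one bipartite graph over the shared protein partition (set ids are
#' namespaced by library to avoid collisions) — the densely connected
#' merged-graph baseline.
#'
#' @param panel Protein panel.
#' @param libs List of >= 2 filtered `gene_set_library` objects.
#' @param set_constant,normalization As in [build_bipartite_graph()].
#' @return A `bipartite_graph`.
#' @export
build_merged_graph <- function(panel, libs, set_constant = 1.0,
                               normalization = "sym") {
  stopifnot(is.list(libs), length(libs) >= 2)
  merged <- merge_libraries(libs)
  build_bipartite_graph(panel, merged, set_constant = set_constant,
                        normalization = normalization)
}

merge_libraries <- function(libs) {
  stopifnot(all(vapply(libs, inherits, TRUE, "gene_set_library")))
  lib_names <- names(libs) %||% vapply(libs, function(l) l$name, "")
  if (any(lib_names == "")) lib_names <- vapply(libs, function(l) l$name, "")
  sets <- list()
  for (i in seq_along(libs)) {
    s <- libs[[i]]$sets
    if (length(s)) names(s) <- paste0(lib_names[i], "::", names(s))
    sets <- c(sets, s)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate namespaced set id after merging", call. = FALSE)
  }
  gene_set_library(sets, name = paste(lib_names, collapse = "+"))
}

#' Assemble a parallel multi-graph
#'
#' One independent bipartite subgraph per library over a duplicated protein
#' partition, with no edges between subgraphs — the parallel architecture's
#' input. `k = 1` behaves exactly like a single bipartite graph.
#'
#' @param panel Protein panel.
#' @param libs List of >= 1 filtered `gene_set_library` objects.
#' @param set_constant,normalization As in [build_bipartite_graph()].
#' @return A `protein_multigraph` (list of `bipartite_graph`s).
#' @export
assemble_parallel <- function(panel, libs, set_constant = 1.0,
                              normalization = "sym") {
  stopifnot(is.list(libs), length(libs) >= 1)
  subgraphs <- lapply(libs, build_bipartite_graph, panel = panel,
                      set_constant = set_constant, normalization = normalization)
  names(subgraphs) <- names(libs) %||% vapply(subgraphs, function(g) g$library_name, "")
  structure(list(subgraphs = subgraphs, panel = protein_panel(panel)),
            class = "protein_multigraph")
}

#' @export
print.protein_multigraph <- function(x, ...) {
  cat("<protein_multigraph> ", length(x$subgraphs), " subgraph(s) over ",
      length(x$panel), " proteins\n", sep = "")
  for (g in x$subgraphs) print(g)
  invisible(x)
}

#' Initialize node features for one sample
#'
#' Protein node `i` receives the sample's standardized expression value for
#' panel protein `i`; every set node receives the graph's constant scalar.
#' For a multi-graph the protein features are replicated into each
#' subgraph.
#'
#' @param graph A `bipartite_graph` or `protein_multigraph`.
#' @param expression Numeric vector over the panel (standardized, no
#'   missing values).
#' @return Numeric feature vector of length `n_proteins + n_sets` (or a
#'   list of such vectors, one per subgraph).
#' @export
init_node_features <- function(graph, expression) {
  if (inherits(graph, "protein_multigraph")) {
    return(lapply(graph$subgraphs, init_node_features, expression = expression))
  }
  stopifnot(inherits(graph, "bipartite_graph"))
  if (length(expression) != graph$n_proteins) {
    stop("expression length ", length(expression), " != panel size ",
         graph$n_proteins, call. = FALSE)
  }
  if (anyNA(expression)) stop("missing values in expression vector", call. = FALSE)
  c(as.numeric(expression), rep(graph$set_constant, graph$n_sets))
}

# Batched node features: samples-by-proteins matrix -> nodes-by-samples.
init_node_feature_matrix <- function(graph, X) {
  stopifnot(inherits(graph, "bipartite_graph"), ncol(X) == graph$n_proteins)
  rbind(t(X), matrix(graph$set_constant, graph$n_sets, nrow(X)))
}

#' Edge-list export
#'
#' @param graph A `bipartite_graph`.
#' @param self_loops Include self-loop rows (default `FALSE`).
#' @return A tibble with `source`, `target`, `source_type`, `target_type`.
#' @export
export_edges <- function(graph, self_loops = FALSE) {
  stopifnot(inherits(graph, "bipartite_graph"))
  out <- tibble::tibble(
    source = graph$panel[graph$edges[, 1]],
    target = graph$set_ids[graph$edges[, 2]],
    source_type = "protein",
    target_type = "set"
  )
  if (self_loops) {
    ids <- c(graph$panel, graph$set_ids)
    types <- rep(c("protein", "set"), c(graph$n_proteins, graph$n_sets))
    out <- dplyr::bind_rows(out, tibble::tibble(
      source = ids, target = ids, source_type = types, target_type = types
    ))
  }
  out
}

#' Graph summary
#'
#' @param graph A `bipartite_graph`.
#' @return One-row tibble of node/edge counts and degree summaries.
#' @export
graph_summary <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  pd <- degree_sequence(graph, "protein")
  sd_ <- degree_sequence(graph, "set")
  tibble::tibble(
    library = graph$library_name,
    n_proteins = graph$n_proteins,
    n_sets = graph$n_sets,
    n_membership_edges = nrow(graph$edges),
    n_self_loops = graph$n_proteins + graph$n_sets,
    mean_protein_degree = mean(pd),
    max_protein_degree = if (length(pd)) max(pd) else 0L,
    mean_set_size = if (length(sd_)) mean(sd_) else NA_real_,
    n_isolated_proteins = sum(pd == 0)
  )
}
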