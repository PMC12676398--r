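test_that("sparse GCN propagation equals the dense normalized-adjacency oracle", {
  # every bipartite topology with at most 6 nodes over a 3-protein panel
  panel <- toy_panel(3)
  subsets <- list(c("P1"), c("P2"), c("P3"), c("P1", "P2"), c("P1", "P3"),
                  c("P2", "P3"), c("P1", "P2", "P3"))
  combos <- c(list(list()),
              lapply(seq_along(subsets), function(i) subsets[i]),
              unlist(lapply(seq_along(subsets), function(i)
                lapply(seq_along(subsets), function(j)
                  list(subsets[[i]], subsets[[j]]))), recursive = FALSE),
              list(subsets[c(1, 4, 7)]))
  withr::with_seed(11, {
    for (sets in combos) {
      sets <- setNames(sets, if (length(sets)) paste0("S", seq_along(sets)))
      lib <- if (length(sets)) gene_set_library(sets) else
        filter_library(toy_library(), "P9", min_size = 1)
      g <- build_bipartite_graph(panel, lib)
      n <- g$n_proteins + g$n_sets
      X <- matrix(rnorm(n * 2), n, 2)
      W <- matrix(rnorm(2 * 2), 2, 2)
      oracle <- tanh(dense_ahat(panel, sets) %*% X %*% W)
      expect_lt(max(abs(gcn_layer(X, g, W) - oracle)), 1e-6)
    }
  })
})

test_that("gcn_layer honors degenerate weights and isolated nodes", {
  panel <- toy_panel(3)
  g <- build_bipartite_graph(panel, toy_library_p3())
  n <- g$n_proteins + g$n_sets
  expect_true(all(gcn_layer(matrix(rnorm(n), n, 1), g,
                            matrix(0, 1, 1)) == 0))
  # isolated node with self-loop and identity weight: pure tanh(x)
  iso <- build_bipartite_graph("P1", filter_library(toy_library(), "P9", 1))
  x <- matrix(0.37, 1, 1)
  expect_equal(gcn_layer(x, iso, diag(1)), tanh(x), ignore_attr = TRUE)
  expect_error(gcn_layer(matrix(0, 2, 1), g, diag(1)), "one row per node")
  expect_error(gcn_layer(matrix(0, n, 2), g, matrix(0, 3, 1)), "mismatch")
})

test_that("protein embeddings stay in (-1,1), respect isolation, and are equivariant", {
  panel <- toy_panel(6)
  lib <- gene_set_library(list(A = c("P1", "P2"), B = c("P2", "P3")))
  g <- build_bipartite_graph(panel, lib)
  m <- build_gnn(g, n_covariates = 0, dropout_rate = 0, seed = 2)
  x <- rnorm(6)
  e <- encode_proteins(m, x)
  expect_equal(dim(e), c(1, 6))
  expect_true(all(abs(e) < 1))

  # protein in no set: embedding is the two-layer tanh chain of its own value
  w <- m$params$gcn[[1]]
  chain <- function(v) {
    h1 <- tanh(v * w$W1)                      # 1 x 2
    tanh(sum(h1 * t(w$W2)))
  }
  expect_equal(e[1, 5], chain(x[5]), tolerance = 1e-12)
  expect_equal(e[1, 6], chain(x[6]), tolerance = 1e-12)

  # panel reordering permutes embedding entries identically
  ord <- c(3, 1, 2, 6, 5, 4)
  lib_perm <- gene_set_library(list(A = c("P1", "P2"), B = c("P2", "P3")))
  g2 <- build_bipartite_graph(panel[ord], lib_perm)
  m2 <- build_gnn(g2, 0, dropout_rate = 0, seed = 7)
  m2$params$gcn <- m$params$gcn
  e2 <- encode_proteins(m2, x[ord])
  expect_equal(as.numeric(e2), as.numeric(e[, ord]), tolerance = 1e-12)
})

test_that("two GCN layers reach exactly the 2-hop receptive field", {
  # 10 proteins, 4 sets; exhaustive pairwise check against shared membership
  panel <- toy_panel(10)
  lib <- gene_set_library(list(
    S1 = c("P1", "P2", "P3"), S2 = c("P3", "P4"),
    S3 = c("P5", "P6", "P7"), S4 = c("P8", "P9")
  )) # P10 isolated
  g <- build_bipartite_graph(panel, lib)
  m <- build_gnn(g, 0, dropout_rate = 0, seed = 4)
  shares_set <- function(p, q) {
    any(vapply(lib$sets, function(s)
      panel[p] %in% s && panel[q] %in% s, TRUE))
  }
  x0 <- rnorm(10)
  e0 <- encode_proteins(m, x0)
  for (q in 1:10) {
    xq <- x0
    xq[q] <- xq[q] + 1
    eq <- encode_proteins(m, xq)
    changed <- which(abs(eq - e0) > 1e-12)
    expected <- sort(unique(c(q, which(vapply(1:10, shares_set, TRUE, q = q)))))
    expect_equal(changed, expected, info = paste("perturbing protein", q))
  }
})

test_that("architectures assemble with the documented widths and global heads", {
  panel <- toy_panel(12)
  libs <- list(mf = random_library(panel, 3, seed = 1),
               cc = random_library(panel, 4, seed = 2))
  C <- 5
  single <- build_gnn(build_bipartite_graph(panel, libs$mf), C)
  expect_equal(single$widths, c(12 + 5, 2 * 12 + 5, 256, 32, 1))
  expect_false(single$include_global_head)

  par <- build_gnn(assemble_parallel(panel, libs), C)
  expect_equal(par$n_subgraphs, 2)
  expect_true(par$include_global_head)
  expect_equal(par$widths, c(2 * 12 + 12 + 5, 2 * (2 * 12) + 12 + 5, 256, 32, 1))

  merged <- build_gnn(build_merged_graph(panel, libs), C,
                      kind = "large_single_head")
  expect_true(merged$include_global_head)
  expect_equal(merged$widths[1], 12 + 12 + 5)

  expect_gt(count_parameters(par), count_parameters(single))
})

test_that("informed FFNN wires sets sparsely with the documented widths", {
  panel <- toy_panel(8)
  lib <- gene_set_library(list(A = c("P1", "P2", "P3"), B = c("P4", "P5")))
  m <- build_informed_ffnn(panel, lib, n_covariates = 3, seed = 1)
  expect_equal(m$widths, c(2 + 3, 256, 128, 64, 32, 1))
  expect_equal(sum(m$mask), 5)
  # non-member protein cannot influence its set unit: perturb and compare
  X <- matrix(rnorm(16), 2, 8)
  Cov <- matrix(0, 2, 3)
  fw <- setgnn:::ffnn_forward(m, X, Cov, training = FALSE)
  X2 <- X
  X2[, 7] <- X2[, 7] + 5 # P7 belongs to no set
  fw2 <- setgnn:::ffnn_forward(m, X2, Cov, training = FALSE)
  expect_equal(fw$Zs, fw2$Zs)
  expect_error(build_informed_ffnn(panel,
                                   filter_library(lib, "P9", min_size = 1), 3),
               "empty library")
})

test_that("permuted variants are capacity-matched to informed partners", {
  panel <- toy_panel(30)
  libs <- list(a = random_library(panel, 6, seed = 1),
               b = random_library(panel, 5, seed = 2))
  C <- 4
  for (s in 1:20) {
    perm <- permute_protein_labels(panel, seed = s)
    plibs <- lapply(libs, permute_library, perm = perm)
    expect_identical(
      count_parameters(build_gnn(build_bipartite_graph(panel, libs$a), C)),
      count_parameters(build_gnn(build_bipartite_graph(panel, plibs$a), C)))
    expect_identical(
      count_parameters(build_gnn(assemble_parallel(panel, libs), C)),
      count_parameters(build_gnn(assemble_parallel(panel, plibs), C)))
    expect_identical(
      count_parameters(build_informed_ffnn(panel, libs$a, C)),
      count_parameters(build_informed_ffnn(panel, plibs$a, C)))
  }
})

test_that("prediction is deterministic, batch-invariant, and shape-checked", {
  panel <- toy_panel(7)
  lib <- random_library(panel, 3, seed = 5)
  m <- build_gnn(build_bipartite_graph(panel, lib), 2, dropout_rate = 0.5,
                 seed = 9)
  X <- matrix(rnorm(21), 3, 7)
  Cov <- matrix(rnorm(6), 3, 2)
  nd <- list(expression = X, covariates = Cov)
  p1 <- predict(m, nd)
  expect_identical(p1, predict(m, nd)) # dropout off at inference
  # one-at-a-time equals batched
  singles <- vapply(1:3, function(i) {
    predict(m, list(expression = X[i, , drop = FALSE],
                    covariates = Cov[i, , drop = FALSE]))
  }, 0)
  expect_equal(singles, p1, tolerance = 1e-12)
  expect_error(predict(m, list(expression = X[, 1:3], covariates = Cov)),
               "width")
  # zeroed output layer predicts exactly zero
  m0 <- m
  m0$params$dense$W4[] <- 0
  m0$params$dense$b4[] <- 0
  expect_true(all(predict(m0, nd) == 0))
})

test_that("a parallel model over empty subgraphs reduces to an MLP oracle", {
  panel <- toy_panel(4)
  empty <- filter_library(toy_library(), "P9", min_size = 1)
  mg <- assemble_parallel(panel, list(e1 = empty, e2 = empty))
  m <- build_gnn(mg, n_covariates = 2, dropout_rate = 0, seed = 6)
  X <- matrix(rnorm(8), 2, 4)
  Cov <- matrix(rnorm(4), 2, 2)
  got <- predict(m, list(expression = X, covariates = Cov))
  # oracle: per-protein two-layer tanh chains (self-loops only), then the
  # dense head applied with plain R arithmetic
  chain <- function(x, w) tanh(tanh(x * w$W1[1, 1]) * w$W2[1, 1] +
                                 tanh(x * w$W1[1, 2]) * w$W2[2, 1])
  E1 <- chain(X, m$params$gcn[[1]])
  E2 <- chain(X, m$params$gcn[[2]])
  D0 <- cbind(E1, E2, X, Cov)
  dn <- m$params$dense
  lr <- function(z) ifelse(z > 0, z, 0.01 * z)
  H <- lr(sweep(D0 %*% dn$W1, 2, dn$b1, "+"))
  H <- lr(sweep(H %*% dn$W2, 2, dn$b2, "+"))
  H <- lr(sweep(H %*% dn$W3, 2, dn$b3, "+"))
  oracle <- as.numeric(sweep(H %*% dn$W4, 2, dn$b4, "+"))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("end-to-end gradients pass a finite-difference check on a toy model", {
  panel <- toy_panel(5)
  lib <- gene_set_library(list(A = c("P1", "P2"), B = c("P2", "P3", "P4")))
  g <- build_bipartite_graph(panel, lib)
  m <- build_gnn(g, 2, dropout_rate = 0, seed = 3, hidden_widths = c(7, 4))
  withr::with_seed(8, {
    X <- matrix(rnorm(15), 3, 5)
    Cov <- matrix(rnorm(6), 3, 2)
    y <- rnorm(3)
  })
  fw <- setgnn:::gnn_forward(m, X, Cov)
  bk <- setgnn:::gnn_backward(m, fw, 2 * (fw$out - y) / 3)
  loss_of <- function(mm) {
    f <- setgnn:::gnn_forward(mm, X, Cov)
    mean((f$out - y)^2)
  }
  eps <- 1e-5
  check_block <- function(get, set, grads) {
    p <- get(m)
    for (i in seq_along(p)) {
      up <- m; pp <- p; pp[i] <- pp[i] + eps; up <- set(up, pp)
      dn_ <- m; pm <- p; pm[i] <- pm[i] - eps; dn_ <- set(dn_, pm)
      fd <- (loss_of(up) - loss_of(dn_)) / (2 * eps)
      expect_equal(grads[i], fd, tolerance = 1e-4)
    }
  }
  check_block(function(m) m$params$gcn[[1]]$W1,
              function(m, p) { m$params$gcn[[1]]$W1[] <- p; m },
              as.numeric(bk$grads$gcn[[1]]$W1))
  check_block(function(m) m$params$gcn[[1]]$W2,
              function(m, p) { m$params$gcn[[1]]$W2[] <- p; m },
              as.numeric(bk$grads$gcn[[1]]$W2))
  check_block(function(m) m$params$dense$W4,
              function(m, p) { m$params$dense$W4[] <- p; m },
              as.numeric(bk$grads$dense$W4))
  check_block(function(m) m$params$dense$b2,
              function(m, p) { m$params$dense$b2[] <- p; m },
              as.numeric(bk$grads$dense$b2))
})
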