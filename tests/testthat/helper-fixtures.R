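# Small in-code fixtures shared across test files.

toy_panel <- function(n = 5) paste0("P", seq_len(n))

toy_library <- function() {
  gene_set_library(list(A = c("P1", "P2"), B = c("P2", "P3", "P4")),
                   name = "toy")
}

random_library <- function(panel, n_sets, seed, size_min = 2, size_max = 4) {
  make_uniform_random_library(panel, n_sets = n_sets, size_min = size_min,
                              size_max = size_max, seed = seed)
}

toy_library_p3 <- function() {
  gene_set_library(list(A = c("P1", "P2")))
}

toy_cohort <- function(n = 30, p = 6, seed = 1, missing = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%02d", 1:n), paste0("P", 1:p)))
    if (missing > 0) X[sample(length(X), missing)] <- NA
    Cov <- cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n))
    proteomics_cohort(X, Cov, rnorm(n))
  })
}

# Dense-by-hand normalized adjacency for oracle comparisons: builds A + I
# from the membership list and normalizes with plain R arithmetic.
dense_ahat <- function(panel, sets, normalization = "sym") {
  P <- length(panel)
  S <- length(sets)
  n <- P + S
  A <- diag(n)
  for (k in seq_along(sets)) {
    for (m in sets[[k]]) {
      j <- match(m, panel)
      A[j, P + k] <- 1
      A[P + k, j] <- 1
    }
  }
  deg <- rowSums(A)
  if (normalization == "sym") {
    diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
  } else {
    diag(1 / deg) %*% A
  }
}
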