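#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom Matrix t rowSums colSums
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library generation never perturbs an outer
# simulation stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed and a stream label, staying well
# below .Machine$integer.max.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 97L + as.integer(stream) * 7919L) %% 2147480009L
}
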