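# Minimal reverse-mode neural primitives for the fixed computation graphs
# used by the architectures in models.R. Everything operates on base
# matrices (batch in rows) with Matrix sparse products for graph
# propagation; Adam and backpropagation are explicit.

glorot_uniform <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

# Inverted dropout: scale at train time so inference needs no rescaling.
dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1, 1 - rate) / (1 - rate), nr, nc)
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  flat <- rapply(params, function(p) p * 0, how = "replace")
  list(m = flat, v = flat, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- Map(walk, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}

# ---- Batch normalization ---------------------------------------------

bn_init <- function(width) {
  list(gamma = rep(1, width), beta = rep(0, width),
       run_mean = rep(0, width), run_var = rep(1, width))
}

bn_forward <- function(Z, bn, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(Z)
    va <- colMeans(sweep(Z, 2, mu)^2)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * va
  } else {
    mu <- bn$run_mean
    va <- bn$run_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(Z, 2, mu), 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(out = out, xhat = xhat, inv_sd = inv_sd, mu = mu, bn = bn)
}

bn_backward <- function(dout, cache, Z, gamma) {
  B <- nrow(Z)
  xhat <- cache$xhat
  inv_sd <- cache$inv_sd
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  # dZ = inv_sd/B * (B*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dZ <- sweep(B * dxhat - matrix(s1, B, length(s1), byrow = TRUE) -
                sweep(xhat, 2, s2, "*"), 2, inv_sd / B, "*")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}
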