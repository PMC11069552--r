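# Minimal dense-network machinery: forward pass, backpropagation and Adam.
# Used by the auto-encoder imputer and the conditional-GAN classifier. All
# randomness comes from the caller's RNG stream; all math is base R matrix
# code. Hidden activation is leaky-rectified (slope 0.2); output activations
# are applied by the callers, which hand back gradients at the output
# pre-activation.

LRELU_SLOPE <- 0.2

mlp_init <- function(sizes) {
  # sizes: c(d_in, h1, ..., d_out). Xavier-uniform weights, zero biases.
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    layers[[l]] <- list(
      W = matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                 sizes[l], sizes[l + 1L]),
      b = rep(0, sizes[l + 1L]))
  }
  structure(list(layers = layers, sizes = sizes), class = "mlp")
}

lrelu <- function(z) ifelse(z > 0, z, LRELU_SLOPE * z)
lrelu_grad <- function(z) ifelse(z > 0, 1, LRELU_SLOPE)

# Forward pass. Hidden layers use leaky ReLU; the last layer is returned at
# its pre-activation (callers apply sigmoid/softmax/identity as needed).
mlp_forward <- function(net, X) {
  L <- length(net$layers)
  A <- list(X)
  Z <- vector("list", L)
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, "+")
    A[[l + 1L]] <- if (l < L) lrelu(Z[[l]]) else Z[[l]]
  }
  list(out = Z[[L]], A = A, Z = Z)
}

# Backward pass from a gradient at the output pre-activation. Returns the
# per-layer parameter gradients and the gradient with respect to the input.
mlp_backward <- function(net, cache, dZout) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dZ <- dZout
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(cache$A[[l]], dZ), b = colSums(dZ))
    dA <- dZ %*% t(net$layers[[l]]$W)
    dZ <- if (l > 1L) dA * lrelu_grad(cache$Z[[l - 1L]]) else dA
  }
  list(grads = grads, dX = dZ)
}

adam_init <- function(net) {
  lapply(net$layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]; s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Numerically safe binary cross-entropy of probabilities p against targets y.
bce <- function(p, y, eps = 1e-12) {
  p <- pmin(1 - eps, pmax(eps, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
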