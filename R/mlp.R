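# Minimal multilayer-perceptron machinery used by the conditional GAN:
# leaky-rectifier hidden layers, linear output, manual backpropagation and
# Adam updates. Rows are samples; W is (fan_in x fan_out).

mlp_init <- function(sizes) {
  layers <- vector("list", length(sizes) - 1)
  for (i in seq_along(layers)) {
    fan_in <- sizes[i]
    layers[[i]] <- list(
      W = matrix(rnorm(fan_in * sizes[i + 1], 0, sqrt(2 / fan_in)),
                 fan_in, sizes[i + 1]),
      b = rep(0, sizes[i + 1])
    )
  }
  structure(list(layers = layers, sizes = sizes), class = "telepain_mlp")
}

lrelu <- function(x, slope = 0.2) x * (x > 0) + slope * x * (x <= 0)

mlp_forward <- function(net, X) {
  L <- length(net$layers)
  A <- vector("list", L)
  h <- X
  for (i in seq_len(L)) {
    a <- h %*% net$layers[[i]]$W
    a <- a + rep(net$layers[[i]]$b, each = nrow(a))
    A[[i]] <- a
    h <- if (i < L) lrelu(a) else a
  }
  list(out = h, A = A, X = X)
}

# dOut must already carry any 1/n averaging factor
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  d <- dOut
  dX <- NULL
  for (i in L:1) {
    h_prev <- if (i == 1) cache$X else lrelu(cache$A[[i - 1]])
    grads[[i]] <- list(W = crossprod(h_prev, d), b = colSums(d))
    dh <- d %*% t(net$layers[[i]]$W)
    if (i > 1) {
      a <- cache$A[[i - 1]]
      d <- dh * ((a > 0) + 0.2 * (a <= 0))
    } else {
      dX <- dh
    }
  }
  list(grads = grads, dX = dX)
}

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    s <- state[[i]]
    g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[i]]$W <- net$layers[[i]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b -
      lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax, numerically stable
softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}
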