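# Minimal dense-network kernel: ReLU MLPs with linear output heads, plus an
# Adam optimizer.  All forward/backward passes are batched matrix products;
# the networks here have at most a few thousand parameters, so base-R BLAS
# calls dominate and no compiled code is needed.

#' Construct a multilayer perceptron
#'
#' Hidden layers use rectified-linear activations with biases; the output
#' layer is linear (Q-value heads must represent negative values, which a
#' rectifier cannot).
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param seed integer seed for weight initialization.
#' @param init_scale if \code{NULL}, He-style scaling \code{sqrt(2/fan_in)}.
#' @return object of class \code{mlp}.
#' @export
mlp <- function(sizes, seed = NULL, init_scale = NULL) {
  stopifnot(length(sizes) >= 2L)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    set.seed(seed)
    on.exit(.Random.seed_restore(old))
  }
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sc <- if (is.null(init_scale)) sqrt(2 / sizes[l]) else init_scale
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sc),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, sizes = as.integer(sizes)), class = "mlp")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Forward pass.  X: batch x input matrix.  Returns list(out, cache) when
# cache = TRUE; the cache holds post-activation values per layer.
mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  acts <- if (cache) vector("list", L + 1L) else NULL
  A <- X
  if (cache) acts[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    A <- if (l < L) Z * (Z > 0) else Z
    if (cache) acts[[l + 1L]] <- A
  }
  if (cache) list(out = A, acts = acts) else A
}

# Backward pass from dL/d(output).  Returns list(gW, gb, gX).
mlp_backward <- function(net, fwd, G) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    A_prev <- fwd$acts[[l]]
    if (l < L) G <- G * (fwd$acts[[l + 1L]] > 0)   # ReLU mask
    gW[[l]] <- crossprod(A_prev, G)
    gb[[l]] <- colSums(G)
    G <- G %*% t(net$W[[l]])
  }
  list(gW = gW, gb = gb, gX = G)
}

#' Number of trainable parameters
#'
#' @param net a network object (\code{mlp} or \code{language_net}).
#' @param weights_only count weight parameters only, excluding biases.
#' @return integer count.
#' @export
param_count <- function(net, weights_only = FALSE) UseMethod("param_count")

#' @export
param_count.mlp <- function(net, weights_only = FALSE) {
  n <- sum(vapply(net$W, length, 1L))
  if (!weights_only) n <- n + sum(vapply(net$b, length, 1L))
  as.integer(n)
}

# ---- Adam -------------------------------------------------------------

# params/grads are flat lists of numeric arrays in matching order.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    params[[i]] <- params[[i]] -
      opt$lr * (opt$m[[i]] / c1) / (sqrt(opt$v[[i]] / c2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# pack/unpack an mlp's parameters as a flat list (W1, b1, W2, b2, ...)
mlp_params <- function(net) {
  out <- list()
  for (l in seq_along(net$W)) { out <- c(out, list(net$W[[l]], net$b[[l]])) }
  out
}

mlp_set_params <- function(net, params) {
  k <- 1L
  for (l in seq_along(net$W)) {
    net$W[[l]] <- params[[k]]; k <- k + 1L
    net$b[[l]] <- params[[k]]; k <- k + 1L
  }
  net
}
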