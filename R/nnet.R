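#' Small multilayer perceptrons
#'
#' The interaction functions learned by the EM procedure are plain fully
#' connected networks mapping the concatenated states of an edge's two
#' endpoints to a force (or message) vector. The networks are deliberately
#' small and are trained with explicit reverse-mode gradients and Adam, so
#' that every training step is deterministic given the seed and gradients can
#' be verified against finite differences.
#'
#' @param layer_sizes integer vector, e.g. `c(10, 64, 64, 2)`: input width,
#'   hidden widths, output width. The output layer is linear.
#' @param activation hidden-layer nonlinearity: `"elu"` (default; linear for
#'   positive inputs, `exp(x) - 1` below zero) or `"tanh"`.
#' @param seed optional integer; when given, initialization is drawn under
#'   this seed without touching the caller's RNG state.
#' @return an object of class `mlp`: a list of weight matrices `W` (in x out)
#'   and bias vectors `b`.
#' @examples
#' net <- mlp_new(c(4, 16, 2), seed = 1)
#' y <- mlp_forward(net, matrix(rnorm(40), 10, 4))
#' @export
mlp_new <- function(layer_sizes, activation = c("elu", "tanh"), seed = NULL) {
  activation <- match.arg(activation)
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  draw <- function() {
    W <- vector("list", length(layer_sizes) - 1L)
    b <- vector("list", length(layer_sizes) - 1L)
    for (l in seq_along(W)) {
      n_in <- layer_sizes[l]
      n_out <- layer_sizes[l + 1L]
      # Xavier/Glorot uniform keeps pre-activations in the responsive range
      lim <- sqrt(6 / (n_in + n_out))
      W[[l]] <- matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
      b[[l]] <- numeric(n_out)
    }
    structure(list(W = W, b = b, sizes = layer_sizes,
                   activation = activation), class = "mlp")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Forward pass of a small MLP
#'
#' @param net an `mlp` object.
#' @param X numeric matrix, one row per input.
#' @param cache if `TRUE`, return the layer activations needed by
#'   [mlp_backward()] as an attribute.
#' @return matrix of outputs (rows align with `X`); with `cache = TRUE` the
#'   attribute `"cache"` holds the intermediate activations.
#' @export
mlp_forward <- function(net, X, cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  stopifnot(ncol(X) == net$sizes[1L])
  L <- length(net$W)
  acts <- if (cache) vector("list", L) else NULL
  act_fun <- if (identical(net$activation, "tanh")) tanh else .elu
  A <- X
  for (l in seq_len(L)) {
    if (cache) acts[[l]] <- A
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    A <- if (l < L) act_fun(Z) else Z
  }
  if (cache) attr(A, "cache") <- acts
  A
}

#' Reverse-mode gradients of a small MLP
#'
#' Backpropagates an output cotangent `dY` through the network, returning the
#' parameter gradients (same shapes as the parameters).
#'
#' @param net an `mlp` object.
#' @param out the output of `mlp_forward(net, X, cache = TRUE)`.
#' @param dY matrix of partial derivatives of the scalar loss with respect to
#'   the network output, aligned with `out`.
#' @return list with `W` and `b` gradient lists and `dX`, the gradient with
#'   respect to the network input (needed when networks are composed).
#' @export
mlp_backward <- function(net, out, dY) {
  acts <- attr(out, "cache")
  if (is.null(acts)) stop("forward pass must be run with cache = TRUE")
  if (!is.matrix(dY)) dY <- matrix(dY, nrow = 1L)
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dY                       # output layer is linear
  for (l in rev(seq_len(L))) {
    A <- acts[[l]]
    gW[[l]] <- crossprod(A, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      dA <- tcrossprod(delta, net$W[[l]])
      # acts[[l]] is the activation output of layer l-1; both nonlinearities
      # have derivatives expressible in their output: tanh' = 1 - tanh^2,
      # elu' = 1 (x > 0) or elu + 1 (x <= 0)
      H <- acts[[l]]
      delta <- if (identical(net$activation, "tanh")) {
        dA * (1 - H * H)
      } else {
        dA * ifelse(H > 0, 1, H + 1)
      }
    }
  }
  list(W = gW, b = gb, dX = tcrossprod(delta, net$W[[1L]]))
}

#' @rdname mlp_new
#' @param net an `mlp` object.
#' @export
mlp_flatten <- function(net) {
  unlist(c(lapply(net$W, as.numeric), lapply(net$b, as.numeric)))
}

#' @rdname mlp_new
#' @param theta numeric vector as produced by [mlp_flatten()].
#' @export
mlp_unflatten <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    n <- length(net$W[[l]])
    net$W[[l]][] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  for (l in seq_along(net$b)) {
    n <- length(net$b[[l]])
    net$b[[l]][] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  stopifnot(pos == length(theta))
  net
}

# flatten a gradient list in the same order as mlp_flatten
.grad_flatten <- function(g) {
  unlist(c(lapply(g$W, as.numeric), lapply(g$b, as.numeric)))
}

#' Adam optimizer state and update
#'
#' Standard Adam with bias-corrected first and second moments, operating on
#' the flattened parameter vector of one network.
#'
#' @param n_par number of parameters.
#' @return an opaque optimizer-state list.
#' @export
adam_new <- function(n_par) {
  list(m = numeric(n_par), v = numeric(n_par), t = 0L)
}

#' @rdname adam_new
#' @param state optimizer state from [adam_new()].
#' @param theta current flat parameter vector.
#' @param grad flat gradient of the loss (the step is taken downhill).
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @return list with updated `theta` and `state`.
#' @export
adam_step <- function(state, theta, grad, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (any(!is.finite(grad))) stop("non-finite gradient in optimizer step")
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}

# exponential linear unit
.elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
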