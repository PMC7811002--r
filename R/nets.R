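#' Initialize a feed-forward atomic network
#'
#' Small multilayer perceptron mapping a descriptor vector (plus, for
#' charge-aware energy networks, one charge input) to a scalar: tanh
#' hidden layers, strictly linear output.  Default architecture is two
#' hidden layers of 15 neurons.  Weights are drawn uniformly from
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`, biases start at zero;
#' deterministic for a given seed.
#'
#' @param n_inputs input dimension (>= 1).
#' @param hidden integer vector of hidden-layer widths.
#' @param seed integer RNG seed.
#' @return object of class `"nnet_params"`: list with `sizes` and per-layer
#'   `W` (matrices, rows = outputs) and `b` (vectors).
#' @export
init_network <- function(n_inputs, hidden = c(15, 15), seed = 1) {
  if (n_inputs < 1) stop("n_inputs must be >= 1")
  sizes <- c(n_inputs, hidden, 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    bound <- 1 / sqrt(fan_in)
    W[[l]] <- matrix(stats::runif(sizes[l + 1] * fan_in, -bound, bound),
                     nrow = sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  base::structure(list(sizes = sizes, W = W, b = b,
                       center = NULL, scale = NULL),
                  class = "nnet_params")
}

#' Attach input standardization to a network
#'
#' Stores a fixed (non-trainable) per-input center/scale transform
#' `x' = (x - center)/scale` applied inside every forward/backward pass.
#' Computed from a training design matrix; greatly improves the
#' conditioning of the training problem when inputs span different
#' magnitudes.
#'
#' @param params a `"nnet_params"` object.
#' @param X training input matrix (n x n_inputs).
#' @return the updated `"nnet_params"` object.
#' @export
net_set_scaling <- function(params, X) {
  if (ncol(X) != params$sizes[1]) stop("input width mismatch")
  params$center <- colMeans(X)
  params$scale <- pmax(apply(X, 2, stats::sd), 1e-8)
  params
}

# apply the stored input transform (identity when unset)
.net_scale_x <- function(params, X) {
  if (is.null(params$center)) return(X)
  n <- nrow(X)
  (X - rep(params$center, each = n)) * rep(1 / params$scale, each = n)
}

#' Flatten network parameters to a vector
#'
#' Layout: for each layer in order, `as.vector(W)` (column-major) followed
#' by `b`.  The inverse is [net_unflatten()]; optimizers treat networks as
#' flat vectors through this pair.
#'
#' @param params a `"nnet_params"` object.
#' @return numeric vector.
#' @export
net_flatten <- function(params) {
  unlist(lapply(seq_along(params$W), function(l)
    c(as.vector(params$W[[l]]), params$b[[l]])), use.names = FALSE)
}

#' @rdname net_flatten
#' @param theta flat parameter vector in [net_flatten()] layout.
#' @export
net_unflatten <- function(params, theta) {
  pos <- 0L
  for (l in seq_along(params$W)) {
    nw <- length(params$W[[l]]); nb <- length(params$b[[l]])
    params$W[[l]] <- matrix(theta[pos + seq_len(nw)], nrow = nrow(params$W[[l]]))
    params$b[[l]] <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  if (pos != length(theta)) stop("theta length does not match network layout")
  params
}

# Batched forward pass: X is n x d. Returns list(y, A) where A are the
# per-layer activations (kept for backward passes).
.net_fwd <- function(params, X) {
  L <- length(params$W)
  A <- vector("list", L)  # A[[l]] = activations after layer l (n x h_l)
  Xs <- .net_scale_x(params, X)
  cur <- Xs
  for (l in seq_len(L - 1L)) {
    cur <- tanh(tcrossprod(cur, params$W[[l]]) +
                  rep(params$b[[l]], each = nrow(cur)))
    A[[l]] <- cur
  }
  y <- drop(tcrossprod(cur, params$W[[L]])) + params$b[[L]]
  list(y = y, A = A, Xs = Xs)
}

#' Evaluate a network
#'
#' @param params a `"nnet_params"` object.
#' @param x input vector of length `n_inputs`, or an `n x d` matrix of
#'   inputs evaluated row-wise.
#' @return scalar (vector input) or length-`n` vector (matrix input).
#' @export
net_forward <- function(params, x) {
  d <- params$sizes[1]
  if (is.matrix(x)) {
    if (ncol(x) != d) stop("input width mismatch: expected ", d)
    return(.net_fwd(params, x)$y)
  }
  if (length(x) != d) stop("input length mismatch: expected ", d)
  .net_fwd(params, matrix(x, nrow = 1))$y
}

# Batched input-gradient: returns n x d matrix of dy/dx rows, plus the
# forward cache (for reuse by the mixed second-derivative pass).
.net_gradx <- function(params, X, fwd = NULL) {
  if (is.null(fwd)) fwd <- .net_fwd(params, X)
  L <- length(params$W)
  n <- nrow(X)
  D <- matrix(rep(as.vector(params$W[[L]]), each = n), nrow = n)
  for (l in seq(L - 1L, 1L)) {
    D <- ((1 - fwd$A[[l]]^2) * D) %*% params$W[[l]]
  }
  if (!is.null(params$center)) {
    D <- D * rep(1 / params$scale, each = n)
  }
  list(G = D, fwd = fwd)
}

# Batched parameter-gradient of sum_i coef_i * y_i. Returns flat vector.
.net_gradw <- function(params, X, coef, fwd = NULL) {
  if (is.null(fwd)) fwd <- .net_fwd(params, X)
  L <- length(params$W)
  grads <- vector("list", L)
  barA <- outer(coef, drop(params$W[[L]]))       # n x h_{L-1}
  grads[[L]] <- c(as.vector(crossprod(coef, fwd$A[[L - 1L]])), sum(coef))
  for (l in seq(L - 1L, 1L)) {
    barZ <- (1 - fwd$A[[l]]^2) * barA
    Aprev <- if (l == 1L) fwd$Xs else fwd$A[[l - 1L]]
    grads[[l]] <- c(as.vector(crossprod(barZ, Aprev)), colSums(barZ))
    if (l > 1L) barA <- barZ %*% params$W[[l]]
  }
  unlist(grads, use.names = FALSE)
}

#' Analytic network gradients
#'
#' Gradient of the scalar output with respect to the inputs and with
#' respect to all weights/biases (flat layout of [net_flatten()]).
#'
#' @param params a `"nnet_params"` object.
#' @param x input vector.
#' @return list with `dx` (length `n_inputs`) and `dtheta` (flat vector).
#' @export
net_gradients <- function(params, x) {
  X <- matrix(x, nrow = 1)
  if (ncol(X) != params$sizes[1]) stop("input length mismatch")
  fwd <- .net_fwd(params, X)
  list(dx = drop(.net_gradx(params, X, fwd)$G),
       dtheta = .net_gradw(params, X, 1, fwd))
}

# Mixed second derivative (forward-over-reverse): with s_i = v_i . dy/dx_i
# (rows v_i of V), returns d( sum_i coef_i s_i ) / dtheta as a flat vector.
# Needed for the gradient of force losses with respect to network weights.
.net_gradx_vjp <- function(params, X, V, coef, fwd = NULL) {
  if (is.null(fwd)) fwd <- .net_fwd(params, X)
  L <- length(params$W)
  n <- nrow(X)
  if (!is.null(params$center)) {
    V <- V * rep(1 / params$scale, each = n)
  }
  # tangent pass
  Tn <- vector("list", L - 1L)  # t_l
  Un <- vector("list", L - 1L)  # u_l
  tcur <- V
  for (l in seq_len(L - 1L)) {
    Un[[l]] <- tcrossprod(tcur, params$W[[l]])
    Tn[[l]] <- (1 - fwd$A[[l]]^2) * Un[[l]]
    tcur <- Tn[[l]]
  }
  gW <- lapply(params$W, function(w) matrix(0, nrow(w), ncol(w)))
  gB <- lapply(params$b, function(bb) numeric(length(bb)))
  # seed: s = W_L t_{L-1}
  gW[[L]] <- gW[[L]] + crossprod(coef, Tn[[L - 1L]])
  barT <- outer(coef, drop(params$W[[L]]))
  barA <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) barA[[l]] <- matrix(0, n, ncol(fwd$A[[l]]))
  for (l in seq(L - 1L, 1L)) {
    barU <- (1 - fwd$A[[l]]^2) * barT
    barA[[l]] <- barA[[l]] - 2 * fwd$A[[l]] * Un[[l]] * barT
    Tprev <- if (l == 1L) V else Tn[[l - 1L]]
    gW[[l]] <- gW[[l]] + crossprod(barU, Tprev)
    if (l > 1L) barT <- barU %*% params$W[[l]]
    # a-stream at level l
    barZ <- (1 - fwd$A[[l]]^2) * barA[[l]]
    Aprev <- if (l == 1L) fwd$Xs else fwd$A[[l - 1L]]
    gW[[l]] <- gW[[l]] + crossprod(barZ, Aprev)
    gB[[l]] <- gB[[l]] + colSums(barZ)
    if (l > 1L) barA[[l - 1L]] <- barA[[l - 1L]] + barZ %*% params$W[[l]]
  }
  unlist(lapply(seq_len(L), function(l) c(as.vector(gW[[l]]), gB[[l]])),
         use.names = FALSE)
}
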