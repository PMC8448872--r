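# The attention-based domain-adversarial network.
#
# Architecture (per input speed series of length l):
#   feature block:    conv1d -> ReLU -> dropout -> conv1d -> ReLU -> dropout
#   attention block:  conv1d -> ReLU -> conv1d -> ReLU  => Z  (F x l)
#   attention:        a = softmax_t( W_a2 %*% tanh(W_a1 %*% Z) )   (no biases)
#   attended pooling: c = sum_t a_t * H[, t]                       (F vector)
#   class head:       dense-tanh -> dense-softmax on c
#   1st domain head:  GRL(mu) -> dense-tanh -> dense-softmax on c
#   2nd domain head:  GRL(mu) -> dense-tanh -> dense-softmax on each Z column
#
# All convolutions are stride 1 with zero ("same") padding so per-timestep
# outputs align 1:1 with input timesteps; both gradient reversal layers are
# identity in the forward pass. Everything is hand-backpropagated: batches are
# laid out as C x (l*n) matrices (columns series-major in time) so every layer
# is one BLAS matmul.

#' Network architecture configuration
#'
#' @param input_len Length `l` of the input speed series.
#' @param filter_width Convolution filter width `F_t` (odd), default 5.
#' @param n_filters Filters per convolutional layer (both blocks), default 16.
#' @param hidden Hidden width of the dense predictor layers, default 32.
#' @param attn_hidden Hidden width of the attention dense layers, default 32.
#' @param dropout_rate Dropout after each feature-block convolution during
#'   training, default 0.5.
#' @return An object of class `dann_config`.
#' @export
dann_config <- function(input_len, filter_width = 5L, n_filters = 16L,
                        hidden = 32L, attn_hidden = 32L, dropout_rate = 0.5) {
  input_len <- as.integer(input_len)
  filter_width <- as.integer(filter_width)
  if (input_len < 1L) stop("input_len must be positive", call. = FALSE)
  if (filter_width < 1L || filter_width %% 2L == 0L)
    stop("filter_width must be a positive odd integer", call. = FALSE)
  if (n_filters < 1L || hidden < 1L || attn_hidden < 1L)
    stop("layer sizes must be positive", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  structure(list(input_len = input_len, filter_width = filter_width,
                 n_filters = as.integer(n_filters), hidden = as.integer(hidden),
                 attn_hidden = as.integer(attn_hidden),
                 dropout_rate = dropout_rate, stride = 1L),
            class = "dann_config")
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, deterministic given `seed`. Parameters
#' are grouped as in the training objectives: `f` (feature block), `a`
#' (attention block convolutions plus the two bias-free attention dense
#' layers), `c` (class predictor), `d1` and `d2` (the two domain predictors).
#'
#' @param cfg A [dann_config()].
#' @param seed Integer RNG seed recorded in the model.
#' @return An object of class `dann_model`.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "dann_config"))
  set.seed(seed)
  Fn <- cfg$n_filters; K <- cfg$filter_width
  h <- cfg$hidden; ha <- cfg$attn_hidden
  conv <- function(c_in) list(W = glorot(Fn, c_in * K, c_in * K, Fn),
                              b = numeric(Fn))
  dense <- function(n_out, n_in) list(W = glorot(n_out, n_in, n_in, n_out),
                                      b = numeric(n_out))
  params <- list(
    f1 = conv(1L), f2 = conv(Fn),
    a1 = conv(1L), a2 = conv(Fn),
    Wa1 = glorot(ha, Fn, Fn, ha), Wa2 = glorot(1L, ha, ha, 1L),
    c1 = dense(h, Fn), c2 = dense(2L, h),
    d11 = dense(h, Fn), d12 = dense(2L, h),
    d21 = dense(h, Fn), d22 = dense(2L, h))
  structure(list(cfg = cfg, params = params, rng_seed = as.integer(seed)),
            class = "dann_model")
}

#' @export
print.dann_model <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 0))
  cat(sprintf("<dann_model: l=%d, %d filters (width %d), %d parameters>\n",
              x$cfg$input_len, x$cfg$n_filters, x$cfg$filter_width, np))
  invisible(x)
}

# Parameter group membership per named objective.
param_groups <- list(
  f = c("f1", "f2"),
  a = c("a1", "a2", "Wa1", "Wa2"),
  c = c("c1", "c2"),
  d1 = c("d11", "d12"),
  d2 = c("d21", "d22"))

#' Gradient reversal layer
#'
#' Identity in the forward pass; the backward pass multiplies the incoming
#' gradient by `-mu`. The layer is what turns the domain predictors'
#' minimization into adversarial pressure on the blocks beneath them.
#'
#' @param x Numeric vector/matrix.
#' @param mu Nonnegative reversal strength.
#' @return `x`, unchanged.
#' @seealso [grad_reverse_grad()] for the backward rule, [mu_schedule()] for
#'   how `mu` ramps during training.
#' @export
grad_reverse <- function(x, mu) {
  if (mu < 0) stop("mu must be nonnegative", call. = FALSE)
  x
}

#' @rdname grad_reverse
#' @param grad Gradient arriving from above.
#' @export
grad_reverse_grad <- function(grad, mu) {
  if (mu < 0) stop("mu must be nonnegative", call. = FALSE)
  -mu * grad
}

# ---- convolution machinery --------------------------------------------------
# A stride-1 same-padded 1D convolution over a batch activation A
# (C x l*n, columns series-major in time) is computed as K shifted matmuls:
# Y = b + sum_k W[, block k] %*% shift_k(A), where shift_k gathers columns at
# time offset (k - (K+1)/2), reading zeros across series boundaries. Gather
# indices are cached per (l, n, K); column l*n+1 of the zero-augmented
# activation serves as the out-of-range source.

.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(l, n, K) {
  key <- paste(l, n, K, sep = "_")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  half <- (K - 1L) %/% 2L
  pos <- rep(seq_len(l), n)                  # timestep of each column
  base <- rep((seq_len(n) - 1L) * l, each = l)
  idx <- vector("list", K)
  for (k in seq_len(K)) {
    src_t <- pos + (k - 1L - half)
    oob <- src_t < 1L | src_t > l
    src <- base + src_t
    src[oob] <- l * n + 1L                   # l*n+1 = zero column
    idx[[k]] <- src
  }
  .im2col_cache[[key]] <- idx
  idx
}

conv_forward <- function(A, layer, l, n, K) {
  C <- nrow(A)
  idx <- im2col_idx(l, n, K)
  Az <- cbind(A, numeric(C))
  shifted <- vector("list", K)
  Y <- matrix(layer$b, nrow(layer$W), l * n)
  for (k in seq_len(K)) {
    Sk <- Az[, idx[[k]], drop = FALSE]
    shifted[[k]] <- Sk
    Y <- Y + layer$W[, ((k - 1L) * C + 1L):(k * C), drop = FALSE] %*% Sk
  }
  list(out = Y, shifted = shifted)
}

conv_backward <- function(dY, layer, shifted, C_in, l, n, K) {
  Fn <- nrow(layer$W)
  dW <- matrix(0, Fn, C_in * K)
  idx <- im2col_idx(l, n, K)
  dAz <- matrix(0, C_in, l * n + 1L)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * C_in + 1L):(k * C_in)
    dW[, cols] <- tcrossprod(dY, shifted[[k]])
    contrib <- crossprod(layer$W[, cols, drop = FALSE], dY)
    tgt <- idx[[k]]
    # accumulate: targets are unique within k, collisions only across k
    dAz[, tgt] <- dAz[, tgt] + contrib
  }
  list(dW = dW, db = rowSums(dY), dA = dAz[, seq_len(l * n), drop = FALSE])
}

softmax_cols <- function(M) {
  if (nrow(M) == 2L) {
    mx <- pmax(M[1L, ], M[2L, ])
    E <- exp(M - rep(mx, each = 2L))
  } else {
    mx <- M[cbind(max.col(t.default(M)), seq_len(ncol(M)))]
    E <- exp(sweep(M, 2L, mx))
  }
  sweep(E, 2L, colSums(E), "/")
}

#' Compute the attention vector from an attention-block feature matrix
#'
#' `a = softmax(W_a2 %*% tanh(W_a1 %*% Z))` with the softmax taken over time,
#' so the weights are nonnegative and sum to one: attention is a distribution
#' over timesteps. Both dense layers are bias-free.
#'
#' @param Z Feature matrix, one column per timestep (features x l).
#' @param Wa1 First attention weight matrix (hidden x features).
#' @param Wa2 Second attention weight matrix (1 x hidden).
#' @return Numeric attention vector of length `ncol(Z)` summing to 1.
#' @export
compute_attention <- function(Z, Wa1, Wa2) {
  if (ncol(Wa1) != nrow(Z) || ncol(Wa2) != nrow(Wa1) || nrow(Wa2) != 1L)
    stop("attention weight shapes incompatible with Z", call. = FALSE)
  e <- Wa2 %*% tanh(Wa1 %*% Z)
  as.numeric(softmax_cols(t(e)))  # softmax over time (single column)
}

# ---- full forward pass ------------------------------------------------------

# X: l x n matrix of input values (one series per column).
# Returns every intermediate needed by the backward pass.
dann_forward_batch <- function(model, X, training = FALSE) {
  cfg <- model$cfg; p <- model$params
  l <- cfg$input_len; K <- cfg$filter_width; Fn <- cfg$n_filters
  if (nrow(X) != l) stop("series length does not match cfg$input_len",
                         call. = FALSE)
  n <- ncol(X)
  A0 <- matrix(as.numeric(X), 1L, l * n)

  drop_mask <- function(dim1, dim2) {
    if (training && cfg$dropout_rate > 0) {
      keep <- 1 - cfg$dropout_rate
      matrix((stats::runif(dim1 * dim2) < keep) / keep, dim1, dim2)
    } else NULL
  }

  # feature block
  cf1 <- conv_forward(A0, p$f1, l, n, K)
  H1 <- pmax(cf1$out, 0)
  M1 <- drop_mask(Fn, l * n)
  H1d <- if (is.null(M1)) H1 else H1 * M1
  cf2 <- conv_forward(H1d, p$f2, l, n, K)
  H2 <- pmax(cf2$out, 0)
  M2 <- drop_mask(Fn, l * n)
  H <- if (is.null(M2)) H2 else H2 * M2

  # attention block
  ca1 <- conv_forward(A0, p$a1, l, n, K)
  G1 <- pmax(ca1$out, 0)
  ca2 <- conv_forward(G1, p$a2, l, n, K)
  Z <- pmax(ca2$out, 0)

  # attention weights (softmax over time within each series)
  Q <- tanh(p$Wa1 %*% Z)                       # ha x l*n
  e <- p$Wa2 %*% Q                             # 1 x l*n
  a_mat <- softmax_cols(matrix(e, l, n))       # l x n
  a_flat <- as.numeric(a_mat)                  # series-major

  # attended pooling: c_i = sum_t a_t H[, t]
  U <- H * rep(a_flat, each = Fn)
  grp <- rep(seq_len(n), each = l)
  Cpool <- t(rowsum(t(U), grp))                # Fn x n
  dimnames(Cpool) <- NULL

  dense_head <- function(W1, b1, W2, b2, input) {
    G <- tanh(W1 %*% input + b1)
    P <- softmax_cols(W2 %*% G + b2)
    list(G = G, P = P)
  }
  hc <- dense_head(p$c1$W, p$c1$b, p$c2$W, p$c2$b, Cpool)
  hd1 <- dense_head(p$d11$W, p$d11$b, p$d12$W, p$d12$b, Cpool)   # GRL above
  hd2 <- dense_head(p$d21$W, p$d21$b, p$d22$W, p$d22$b, Z)       # GRL above

  list(n = n, A0 = A0,
       cf1 = cf1, H1 = H1, M1 = M1, H1d = H1d, cf2 = cf2, H2 = H2, M2 = M2,
       H = H, ca1 = ca1, G1 = G1, ca2 = ca2, Z = Z, Q = Q,
       a_mat = a_mat, a_flat = a_flat, U = U, Cpool = Cpool,
       hc = hc, hd1 = hd1, hd2 = hd2,
       p_class = hc$P[2L, ], p_dom1 = hd1$P[2L, ],
       p_dom2 = matrix(hd2$P[2L, ], l, n))
}

#' Run the network forward on one speed series
#'
#' @param model A [dann_model()][init_model()].
#' @param s A normalized [speed_series()] of length `cfg$input_len`.
#' @param training Logical; enables feature-block dropout (draws from the
#'   current RNG stream).
#' @return A list with `class_prob` (probability of class 1), `domain_prob`
#'   (series-level, 1st domain predictor), `domain_prob_series` (per-timestep,
#'   2nd domain predictor), `attention` (length-l weights summing to 1) and
#'   `Z` (the attention-block feature matrix).
#' @export
dann_forward <- function(model, s, training = FALSE) {
  stopifnot(inherits(model, "dann_model"))
  v <- if (inherits(s, "speed_series")) s$values else as.numeric(s)
  fw <- dann_forward_batch(model, matrix(v, ncol = 1L), training = training)
  list(class_prob = fw$p_class[1L],
       domain_prob = fw$p_dom1[1L],
       domain_prob_series = as.numeric(fw$p_dom2),
       attention = fw$a_mat[, 1L],
       Z = matrix(fw$Z, model$cfg$n_filters, model$cfg$input_len))
}

# ---- backward pass ----------------------------------------------------------

# Backpropagate from head-level gradients into all blocks.
# dCpool: Fn x n gradient on the pooled attended features (or NULL)
# dZ_extra: Fn x l*n gradient arriving at Z from the 2nd domain head,
#           already scaled by its GRL factor (or NULL)
dann_backward_core <- function(model, fw, dCpool, dZ_extra) {
  cfg <- model$cfg; p <- model$params
  l <- cfg$input_len; K <- cfg$filter_width; Fn <- cfg$n_filters
  n <- fw$n
  g <- list()

  dH <- matrix(0, Fn, l * n)
  da_flat <- numeric(l * n)
  if (!is.null(dCpool)) {
    dU <- dCpool[, rep(seq_len(n), each = l), drop = FALSE]
    dH <- dU * rep(fw$a_flat, each = Fn)
    da_flat <- colSums(dU * fw$H)
  }

  # softmax (over time, per series) backward
  dA_mat <- matrix(da_flat, l, n)
  sum_term <- colSums(fw$a_mat * dA_mat)
  de_mat <- fw$a_mat * sweep(dA_mat, 2L, sum_term)
  de <- matrix(as.numeric(de_mat), 1L, l * n)

  # attention dense layers (no biases)
  g$Wa2 <- de %*% t(fw$Q)
  dQ <- crossprod(p$Wa2, de)
  dpreQ <- dQ * (1 - fw$Q^2)
  g$Wa1 <- dpreQ %*% t(fw$Z)
  dZ <- crossprod(p$Wa1, dpreQ)
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra

  # attention conv block
  dZpre <- dZ * (fw$ca2$out > 0)
  cb <- conv_backward(dZpre, p$a2, fw$ca2$shifted, Fn, l, n, K)
  g$a2 <- list(W = cb$dW, b = cb$db)
  dG1 <- cb$dA * (fw$ca1$out > 0)
  cb <- conv_backward(dG1, p$a1, fw$ca1$shifted, 1L, l, n, K)
  g$a1 <- list(W = cb$dW, b = cb$db)

  # feature conv block
  if (!is.null(fw$M2)) dH <- dH * fw$M2
  dH2pre <- dH * (fw$cf2$out > 0)
  cb <- conv_backward(dH2pre, p$f2, fw$cf2$shifted, Fn, l, n, K)
  g$f2 <- list(W = cb$dW, b = cb$db)
  dH1 <- cb$dA
  if (!is.null(fw$M1)) dH1 <- dH1 * fw$M1
  dH1pre <- dH1 * (fw$cf1$out > 0)
  cb <- conv_backward(dH1pre, p$f1, fw$cf1$shifted, 1L, l, n, K)
  g$f1 <- list(W = cb$dW, b = cb$db)

  g
}
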