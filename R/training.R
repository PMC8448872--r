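# Three-phase adversarial training.
#
# Per epoch the loop runs, over minibatches:
#   phase 1: minimize  mean L_c  with the per-timestep (2nd) domain head
#            trained on  lambda1 * L_d2  behind its gradient reversal layer
#            (updates theta_f, theta_a, theta_c, theta_d2);
#   phase 2: train the series-level (1st) domain head on L_d1 behind its
#            reversal layer (updates theta_f, theta_a, theta_d1);
#   phase 3: class loss again, now with the 1st domain head adversarial at
#            weight lambda2 (updates theta_f, theta_a, theta_c, theta_d1).
# Reported phase losses follow the stated objectives
#   E1 = mean L_c - lambda1 mean L_d2,  E2 = mean L_d1,
#   E3 = mean L_c - lambda2 mean L_d1;
# gradient flow follows gradient-reversal semantics: each domain head itself
# descends its own BCE while the blocks beneath the reversal layer receive
# that gradient multiplied by -mu, with mu ramped by mu_schedule().

#' Training configuration
#'
#' @param epochs Number of epochs, default 100.
#' @param lambda1,lambda2 Adversarial trade-off weights for the 2nd and 1st
#'   domain predictors, default 1.
#' @param L Upper bound of the reversal strength `mu`, default 1.
#' @param alpha,beta Shape constants of the `mu` ramp (1.4 and 10).
#' @param t1,t2 Ramp boundaries in (real-valued) epochs; defaults
#'   `epochs/10` and `epochs/1.2`, kept fractional.
#' @param lr Adam learning rate, default 1e-3.
#' @param batch_size Minibatch size, default 16.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, lambda1 = 1, lambda2 = 1, L = 1,
                         alpha = 1.4, beta = 10, t1 = epochs / 10,
                         t2 = epochs / 1.2, lr = 1e-3, batch_size = 16L,
                         seed = 1L) {
  if (lambda1 < 0 || lambda2 < 0 || L < 0)
    stop("lambda1, lambda2 and L must be nonnegative", call. = FALSE)
  if (!(t1 < t2 && t2 <= epochs))
    stop("need t1 < t2 <= epochs", call. = FALSE)
  structure(list(epochs = as.integer(epochs), lambda1 = lambda1,
                 lambda2 = lambda2, L = L, alpha = alpha, beta = beta,
                 t1 = t1, t2 = t2, lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

BCE_EPS <- 1e-7

#' Binary cross-entropy on the positive-class probability
#'
#' Probabilities are clipped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param p Predicted probability (vectorized).
#' @param y Label 0/1 (vectorized).
#' @return Elementwise loss `-(y log p + (1-y) log(1-p))`.
#' @export
bce <- function(p, y) {
  p <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Reversal-strength schedule
#'
#' Zero for the first tenth of training (the feature extractor must first
#' learn something worth un-learning domains from), then a smooth sigmoid-like
#' ramp, then pinned at the upper bound `L` from `t2` on. Note the ramp ends
#' with a small jump at `t2` for finite `beta` since `alpha^-beta > 0`; the
#' closed form is implemented exactly as stated.
#'
#' @param i Epoch index (0-based, may be fractional).
#' @param cfg A [train_config()].
#' @return The reversal strength `mu` in `[0, L]`.
#' @export
mu_schedule <- function(i, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (any(i < 0)) stop("epoch index must be nonnegative", call. = FALSE)
  L <- cfg$L
  ramp <- function(j)
    (L + 1) / (L * cfg$alpha^(-cfg$beta * (j - cfg$t1) / (cfg$t2 - cfg$t1)) + 1) - 1
  ifelse(i < cfg$t1, 0, ifelse(i < cfg$t2, ramp(i), L))
}

# ---- batch assembly ---------------------------------------------------------

series_batch <- function(series) {
  if (inherits(series, "speed_series")) series <- list(series)
  if (length(series) == 0L) stop("empty batch", call. = FALSE)
  lens <- vapply(series, function(s) length(s$values), 0L)
  if (length(unique(lens)) != 1L)
    stop("all series in a batch must share one length", call. = FALSE)
  list(X = vapply(series, function(s) s$values, numeric(lens[1L])),
       y = vapply(series, function(s) s$class_label, 0L),
       d = vapply(series, function(s) s$domain_label, 0L),
       ids = vapply(series, function(s) s$id, ""))
}

# ---- phase objective: value + gradients -------------------------------------

dense_head_grads <- function(head, W1, W2, input, y, w) {
  delta <- (head$P[2L, ] - y) * w           # dL/dz2; dL/dz1 = -delta
  dlog <- rbind(-delta, delta)
  dW2 <- dlog %*% t(head$G)
  db2 <- rowSums(dlog)
  dpre <- crossprod(W2, dlog) * (1 - head$G^2)
  list(dW1 = dpre %*% t(input), db1 = rowSums(dpre),
       dW2 = dW2, db2 = db2, dInput = crossprod(W1, dpre))
}

# Computes the reported objective value for `phase` plus gradients for every
# parameter group that phase updates. X is l x n; y, d length-n labels.
phase_step <- function(model, X, y, d, phase, mu, lambda, training = FALSE) {
  p <- model$params
  l <- model$cfg$input_len
  fw <- dann_forward_batch(model, X, training = training)
  n <- fw$n
  Lc <- mean(bce(fw$p_class, y))
  Ld1 <- mean(bce(fw$p_dom1, d))
  d_rep <- rep(d, each = l)
  Ld2 <- mean(bce(as.numeric(fw$p_dom2), d_rep))  # mean over t then series

  g <- list()
  dCpool <- NULL; dZ_extra <- NULL
  if (phase %in% c(1L, 3L)) {
    hg <- dense_head_grads(fw$hc, p$c1$W, p$c2$W, fw$Cpool, y, 1 / n)
    g$c1 <- list(W = hg$dW1, b = hg$db1)
    g$c2 <- list(W = hg$dW2, b = hg$db2)
    dCpool <- hg$dInput
  }
  if (phase == 1L) {
    hg <- dense_head_grads(fw$hd2, p$d21$W, p$d22$W, fw$Z, d_rep,
                           lambda / (l * n))
    g$d21 <- list(W = hg$dW1, b = hg$db1)
    g$d22 <- list(W = hg$dW2, b = hg$db2)
    dZ_extra <- grad_reverse_grad(hg$dInput, mu)
    value <- Lc - lambda * Ld2
  } else {
    w_d1 <- if (phase == 2L) 1 / n else lambda / n
    hg <- dense_head_grads(fw$hd1, p$d11$W, p$d12$W, fw$Cpool, d, w_d1)
    g$d11 <- list(W = hg$dW1, b = hg$db1)
    g$d12 <- list(W = hg$dW2, b = hg$db2)
    rev_grad <- grad_reverse_grad(hg$dInput, mu)
    dCpool <- if (is.null(dCpool)) rev_grad else dCpool + rev_grad
    value <- if (phase == 2L) Ld1 else Lc - lambda * Ld1
  }
  core <- dann_backward_core(model, fw, dCpool, dZ_extra)
  g <- c(g, core)
  list(value = value, grads = g, Lc = Lc, Ld1 = Ld1, Ld2 = Ld2, fw = fw)
}

phase_loss <- function(batch, model, phase, lambda) {
  b <- series_batch(batch)
  phase_step(model, b$X, b$y, b$d, phase, mu = 0, lambda = lambda)$value
}

#' Phase objectives (reported values)
#'
#' `loss_phase1` is the class loss minus `lambda1` times the per-timestep
#' domain loss (2nd domain predictor); `loss_phase2` is the series-level
#' domain loss (1st domain predictor); `loss_phase3` is the class loss minus
#' `lambda2` times the series-level domain loss. Evaluated without dropout.
#'
#' @param batch A list of normalized [speed_series()] (or a single series).
#' @param model A [dann_model()][init_model()].
#' @param lambda1,lambda2 Trade-off weights.
#' @return The scalar objective value.
#' @export
loss_phase1 <- function(batch, model, lambda1 = 1)
  phase_loss(batch, model, 1L, lambda1)

#' @rdname loss_phase1
#' @export
loss_phase2 <- function(batch, model) phase_loss(batch, model, 2L, 0)

#' @rdname loss_phase1
#' @export
loss_phase3 <- function(batch, model, lambda2 = 1)
  phase_loss(batch, model, 3L, lambda2)

# ---- Adam -------------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

adam_update <- function(params, grads, state, lr, which,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(state$t)) state$t <- 0L
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  step_one <- function(key, theta, grad) {
    if (is.null(state[[key]]))
      state[[key]] <- list(m = theta * 0, v = theta * 0)
    st <- state[[key]]
    st$m <- b1 * st$m + (1 - b1) * grad
    st$v <- b2 * st$v + (1 - b2) * grad^2
    state[[key]] <- st
    theta - lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
  }
  for (nm in which) {
    if (is.list(params[[nm]])) {
      for (part in names(params[[nm]]))
        params[[nm]][[part]] <- step_one(paste0(nm, ".", part),
                                         params[[nm]][[part]],
                                         grads[[nm]][[part]])
    } else {
      params[[nm]] <- step_one(nm, params[[nm]], grads[[nm]])
    }
  }
  params
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a model on a set of series
#'
#' Dropout disabled. Domain accuracy is reported for both predictors; the
#' per-timestep (2nd) accuracy pools all timesteps of all series.
#'
#' @param model A [dann_model()][init_model()].
#' @param series List of normalized [speed_series()].
#' @param chunk Number of series per forward chunk (memory control).
#' @return A list with `acc_class`, `acc_dom1`, `acc_dom2`, `loss_class`,
#'   `loss_dom1`, `loss_dom2`, and per-series matrices `attention`
#'   (l x n) and vectors `p_class`, `p_dom1`.
#' @export
evaluate_dann <- function(model, series, chunk = 32L) {
  b <- series_batch(series)
  n <- ncol(b$X); l <- nrow(b$X)
  p_class <- numeric(n); p_dom1 <- numeric(n)
  att <- matrix(0, l, n); pd2 <- matrix(0, l, n)
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    fw <- dann_forward_batch(model, b$X[, ix, drop = FALSE], training = FALSE)
    p_class[ix] <- fw$p_class
    p_dom1[ix] <- fw$p_dom1
    att[, ix] <- fw$a_mat
    pd2[, ix] <- fw$p_dom2
  }
  d_rep <- rep(b$d, each = l)
  list(acc_class = mean((p_class > 0.5) == (b$y == 1)),
       acc_dom1 = mean((p_dom1 > 0.5) == (b$d == 1)),
       acc_dom2 = mean((as.numeric(pd2) > 0.5) == (d_rep == 1)),
       loss_class = mean(bce(p_class, b$y)),
       loss_dom1 = mean(bce(p_dom1, b$d)),
       loss_dom2 = mean(bce(as.numeric(pd2), d_rep)),
       p_class = p_class, p_dom1 = p_dom1, attention = att, ids = b$ids)
}

#' Stratified train/test split
#'
#' 80/20 by default, stratified on the class-by-domain cell, seeded.
#'
#' @param series List of [speed_series()].
#' @param test_frac Fraction held out, default 0.2.
#' @param seed RNG seed.
#' @return A list with elements `train` and `test`.
#' @export
split_dataset <- function(series, test_frac = 0.2, seed = 1L) {
  y <- vapply(series, function(s) s$class_label, 0L)
  d <- vapply(series, function(s) s$domain_label, 0L)
  cell <- interaction(y, d)
  set.seed(seed)
  test_idx <- unlist(lapply(split(seq_along(series), cell), function(ix) {
    n_test <- round(length(ix) * test_frac)
    if (n_test == 0L) return(integer())
    sample(ix, n_test)
  }))
  list(train = series[-test_idx], test = series[test_idx])
}

#' Train the domain-adversarial network
#'
#' Runs the three-phase loop for `cfg$epochs` epochs with one Adam optimizer
#' state per phase and records a per-epoch history (evaluated on the training
#' set without dropout). Deterministic given `cfg$seed`.
#'
#' @param series List of normalized [speed_series()], all the same length,
#'   containing both classes and both domains.
#' @param net_cfg A [dann_config()]; defaults to one sized to the data.
#' @param cfg A [train_config()].
#' @param verbose Print a line every 10 epochs.
#' @return A list with `model` (trained [dann_model()][init_model()]) and
#'   `history` (data.frame: epoch, mu, phase losses, eval losses, accuracies).
#' @export
train_dann <- function(series, net_cfg = NULL, cfg = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  b <- series_batch(series)
  if (length(unique(b$y)) < 2L || length(unique(b$d)) < 2L)
    stop("invalid dataset: need both classes and both domains", call. = FALSE)
  l <- nrow(b$X); n <- ncol(b$X)
  if (is.null(net_cfg)) net_cfg <- dann_config(input_len = l)
  if (net_cfg$input_len != l)
    stop("net_cfg$input_len does not match the data", call. = FALSE)

  model <- init_model(net_cfg, seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  opt <- list(adam_state(), adam_state(), adam_state())
  groups <- list(c("f1", "f2", "a1", "a2", "Wa1", "Wa2", "c1", "c2",
                   "d21", "d22"),
                 c("f1", "f2", "a1", "a2", "Wa1", "Wa2", "d11", "d12"),
                 c("f1", "f2", "a1", "a2", "Wa1", "Wa2", "c1", "c2",
                   "d11", "d12"))
  lambdas <- c(cfg$lambda1, 0, cfg$lambda2)

  hist_rows <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    mu <- mu_schedule(ep - 1L, cfg)
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ph_loss <- numeric(3L)
    for (phase in 1:3) {
      tot <- 0
      for (s0 in starts) {
        ix <- perm[s0:min(s0 + cfg$batch_size - 1L, n)]
        st <- phase_step(model, b$X[, ix, drop = FALSE], b$y[ix], b$d[ix],
                         phase, mu, lambdas[phase], training = TRUE)
        model$params <- adam_update(model$params, st$grads, opt[[phase]],
                                    cfg$lr, groups[[phase]])
        tot <- tot + st$value * length(ix)
      }
      ph_loss[phase] <- tot / n
    }
    ev <- evaluate_dann(model, series)
    hist_rows[[ep]] <- data.frame(
      epoch = ep, mu = mu,
      phase1 = ph_loss[1L], phase2 = ph_loss[2L], phase3 = ph_loss[3L],
      loss_class = ev$loss_class, loss_dom1 = ev$loss_dom1,
      loss_dom2 = ev$loss_dom2, acc_class = ev$acc_class,
      acc_dom1 = ev$acc_dom1, acc_dom2 = ev$acc_dom2)
    if (verbose && ep %% 10L == 0L)
      message(sprintf(
        "epoch %3d  mu=%.3f  class acc %.3f  dom acc %.3f/%.3f", ep, mu,
        ev$acc_class, ev$acc_dom1, ev$acc_dom2))
  }
  list(model = model, history = do.call(rbind, hist_rows))
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the parameter collections, architecture configuration
#' and seed; `load_model()` returns a model whose forward pass reproduces the
#' saved one exactly.
#'
#' @param model A [dann_model()][init_model()].
#' @param path Checkpoint file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dann_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dann_model"))
  model
}
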