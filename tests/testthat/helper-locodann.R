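# Shared fixtures and independent oracles. ref_forward() reimplements the
# whole network forward pass with naive per-timestep loops, deliberately
# sharing no code with the package internals, so agreement is evidence and
# not tautology.

make_series <- function(values, id = "s", class_label = 0L, domain_label = 0L,
                        normalized = TRUE)
  speed_series(id, values, class_label, domain_label, normalized)

random_series <- function(l, class_label = 0L, domain_label = 0L, id = "s")
  make_series(rnorm(l), id = id, class_label = class_label,
              domain_label = domain_label)

tiny_cfg <- function(l = 12L, Fn = 3L, K = 3L, h = 4L, ha = 4L)
  dann_config(input_len = l, filter_width = K, n_filters = Fn, hidden = h,
              attn_hidden = ha, dropout_rate = 0)

# Mixed tiny dataset covering all four (class, domain) cells.
tiny_dataset <- function(l = 12L, n_per_cell = 2L, seed = 5L) {
  set.seed(seed)
  out <- list()
  for (cl in 0:1) for (dm in 0:1) for (i in seq_len(n_per_cell))
    out[[length(out) + 1L]] <- random_series(
      l, cl, dm, sprintf("c%dd%d_%d", cl, dm, i))
  out
}

# ---- loop-based reference forward pass --------------------------------------

ref_conv <- function(A, W, b, K) {
  # A: C x l; W: F x C*K; same padding, stride 1
  C <- nrow(A); l <- ncol(A); Fn <- nrow(W)
  half <- (K - 1) %/% 2
  Y <- matrix(0, Fn, l)
  for (f in seq_len(Fn)) for (t in seq_len(l)) {
    acc <- b[f]
    for (k in seq_len(K)) for (c in seq_len(C)) {
      src <- t + k - 1 - half
      if (src >= 1 && src <= l)
        acc <- acc + W[f, (k - 1) * C + c] * A[c, src]
    }
    Y[f, t] <- acc
  }
  Y
}

ref_softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

ref_forward <- function(model, v) {
  p <- model$params; K <- model$cfg$filter_width
  A0 <- matrix(v, 1L)
  H1 <- pmax(ref_conv(A0, p$f1$W, p$f1$b, K), 0)
  H <- pmax(ref_conv(H1, p$f2$W, p$f2$b, K), 0)
  G1 <- pmax(ref_conv(A0, p$a1$W, p$a1$b, K), 0)
  Z <- pmax(ref_conv(G1, p$a2$W, p$a2$b, K), 0)
  l <- length(v)
  e <- sapply(seq_len(l), function(t)
    as.numeric(p$Wa2 %*% tanh(p$Wa1 %*% Z[, t])))
  a <- ref_softmax(e)
  cpool <- rowSums(H * matrix(a, nrow(H), l, byrow = TRUE))
  head_prob <- function(W1, b1, W2, b2, input)
    ref_softmax(as.numeric(W2 %*% tanh(W1 %*% input + b1) + b2))[2L]
  list(
    class_prob = head_prob(p$c1$W, p$c1$b, p$c2$W, p$c2$b, cpool),
    domain_prob = head_prob(p$d11$W, p$d11$b, p$d12$W, p$d12$b, cpool),
    domain_prob_series = sapply(seq_len(l), function(t)
      head_prob(p$d21$W, p$d21$b, p$d22$W, p$d22$b, Z[, t])),
    attention = a)
}

ref_bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# Reference phase objective values computed solely from ref_forward outputs.
ref_phase_values <- function(model, series, lambda1 = 1, lambda2 = 1) {
  outs <- lapply(series, function(s) ref_forward(model, s$values))
  y <- vapply(series, function(s) s$class_label, 0L)
  d <- vapply(series, function(s) s$domain_label, 0L)
  Lc <- mean(mapply(function(o, yy) ref_bce(o$class_prob, yy), outs, y))
  Ld1 <- mean(mapply(function(o, dd) ref_bce(o$domain_prob, dd), outs, d))
  Ld2 <- mean(mapply(function(o, dd) mean(ref_bce(o$domain_prob_series, dd)),
                     outs, d))
  list(phase1 = Lc - lambda1 * Ld2, phase2 = Ld1, phase3 = Lc - lambda2 * Ld1,
       Lc = Lc, Ld1 = Ld1, Ld2 = Ld2)
}

# Set every dense predictor head to zero weights (softmax outputs 0.5).
zero_heads <- function(model) {
  for (nm in c("c1", "c2", "d11", "d12", "d21", "d22")) {
    model$params[[nm]]$W[] <- 0
    model$params[[nm]]$b[] <- 0
  }
  model
}
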