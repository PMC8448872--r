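test_that("bce matches the clipped elementwise formula", {
  expect_equal(bce(0.5, 1), log(2), tolerance = 1e-12)
  expect_lt(bce(1 - 1e-7, 1), 1e-6)
  expect_equal(bce(1, 1), bce(1 - 1e-7, 1))  # clipping
  set.seed(61)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(mean(bce(p, y)), mean(ref_bce(p, y)), tolerance = 1e-12)
})

test_that("mu_schedule follows the piecewise closed form", {
  cfg <- train_config(epochs = 100, L = 1)
  expect_equal(mu_schedule(0, cfg), 0)
  expect_equal(mu_schedule(9.99, cfg), 0)           # i < T1 = 10
  expect_equal(mu_schedule(10, cfg), 0)             # alpha^0: continuous at T1
  # midpoint of [T1, T2]: direct arithmetic oracle
  mid <- (10 + 100 / 1.2) / 2
  direct <- (1 + 1) / (1 * 1.4^(-10 * (mid - 10) / (100 / 1.2 - 10)) + 1) - 1
  expect_equal(mu_schedule(mid, cfg), direct, tolerance = 1e-12)
  expect_equal(mu_schedule(100 / 1.2, cfg), 1)      # pinned at L from T2
  expect_equal(mu_schedule(1000, cfg), 1)
  # monotone and bounded on a fine grid, for several configs
  for (L in c(0.5, 1, 2)) {
    cfg2 <- train_config(epochs = 60, L = L)
    mus <- mu_schedule(seq(0, 60, by = 0.25), cfg2)
    expect_true(all(diff(mus) >= -1e-12))
    expect_true(all(mus >= 0 & mus <= L + 1e-12))
  }
  expect_error(train_config(epochs = 10, t1 = 9, t2 = 8), "t1 < t2")
})

test_that("phase objectives match reference values on a toy batch", {
  ds <- tiny_dataset(l = 12L, n_per_cell = 1L, seed = 71)[1:3]
  model <- init_model(tiny_cfg(), seed = 72)
  want <- ref_phase_values(model, ds, lambda1 = 0.8, lambda2 = 0.6)
  expect_equal(loss_phase1(ds, model, lambda1 = 0.8), want$phase1,
               tolerance = 1e-6)
  expect_equal(loss_phase2(ds, model), want$phase2, tolerance = 1e-6)
  expect_equal(loss_phase3(ds, model, lambda2 = 0.6), want$phase3,
               tolerance = 1e-6)
  # reductions
  expect_equal(loss_phase1(ds, model, lambda1 = 0), want$Lc, tolerance = 1e-6)
  expect_equal(loss_phase3(ds, model, lambda2 = 0), want$Lc, tolerance = 1e-6)
  expect_error(loss_phase2(list(), model), "empty batch")
})

test_that("zeroed heads give the log-2 degeneracies", {
  ds <- tiny_dataset()
  model <- zero_heads(init_model(tiny_cfg(), seed = 1))
  expect_equal(loss_phase1(ds, model, lambda1 = 1), log(2) - log(2),
               tolerance = 1e-9)
  expect_equal(loss_phase1(ds, model, lambda1 = 0.3), (1 - 0.3) * log(2),
               tolerance = 1e-9)
  expect_equal(loss_phase2(ds, model), log(2), tolerance = 1e-9)
  expect_equal(loss_phase3(ds, model, lambda2 = 0.5), 0.5 * log(2),
               tolerance = 1e-9)
  # batch of one equals single-series BCE
  one <- ds[[1]]
  expect_equal(loss_phase2(list(one), model),
               bce(0.5, one$domain_label), tolerance = 1e-12)
})

test_that("phase gradients follow gradient-reversal semantics", {
  # finite differences of the phase VALUE give dE/dtheta; the implemented
  # gradient must equal +dLd/dtheta on domain heads (they descend their own
  # loss) and -mu * dLd/dtheta below the reversal layer.
  ds <- tiny_dataset(l = 10L, n_per_cell = 1L, seed = 81)
  model <- init_model(tiny_cfg(l = 10L), seed = 82)
  b <- locodann:::series_batch(ds)
  mu <- 0.9
  st <- locodann:::phase_step(model, b$X, b$y, b$d, 2L, mu, 0)
  num <- function(key, part, i) {
    eps <- 1e-6
    pert <- function(sign) {
      m <- model
      m$params[[key]][[part]][i] <- m$params[[key]][[part]][i] + sign * eps
      locodann:::phase_step(m, b$X, b$y, b$d, 2L, mu, 0)$value
    }
    (pert(1) - pert(-1)) / (2 * eps)
  }
  for (i in 1:3) {
    # head parameter: descends its own BCE (value IS Ld1)
    expect_equal(st$grads$d11$W[i], num("d11", "W", i), tolerance = 1e-5)
    # feature parameter below the reversal layer: -mu * dLd1/dtheta
    expect_equal(st$grads$f2$W[i], -mu * num("f2", "W", i), tolerance = 1e-5)
    expect_equal(st$grads$Wa1[i],
                 -mu * {
                   eps <- 1e-6
                   m1 <- model; m1$params$Wa1[i] <- m1$params$Wa1[i] + eps
                   m2 <- model; m2$params$Wa1[i] <- m2$params$Wa1[i] - eps
                   (locodann:::phase_step(m1, b$X, b$y, b$d, 2L, mu, 0)$value -
                    locodann:::phase_step(m2, b$X, b$y, b$d, 2L, mu, 0)$value) /
                     (2 * eps)
                 }, tolerance = 1e-5)
  }
})

test_that("with mu = 0 and lambda = 0 phase 1 reduces to supervised training", {
  ds <- tiny_dataset(l = 10L, n_per_cell = 1L, seed = 91)
  model <- init_model(tiny_cfg(l = 10L), seed = 92)
  b <- locodann:::series_batch(ds)
  st <- locodann:::phase_step(model, b$X, b$y, b$d, 1L, mu = 0, lambda = 0)
  # gradients on feature/attention/class params equal finite differences of
  # the pure class BCE (an independent supervised-only objective)
  class_loss <- function(m)
    mean(mapply(function(s) ref_bce(ref_forward(m, s$values)$class_prob,
                                    s$class_label), ds))
  for (probe in list(c("f1", "W"), c("f2", "W"), c("c1", "W"), c("c2", "W"))) {
    key <- probe[1]; part <- probe[2]
    for (i in 1:2) {
      eps <- 1e-6
      m1 <- model; m1$params[[key]][[part]][i] <-
        m1$params[[key]][[part]][i] + eps
      m2 <- model; m2$params[[key]][[part]][i] <-
        m2$params[[key]][[part]][i] - eps
      expect_equal(st$grads[[key]][[part]][i],
                   (class_loss(m1) - class_loss(m2)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("train_dann is deterministic, records history, validates input", {
  ds <- tiny_dataset(l = 16L, n_per_cell = 3L, seed = 101)
  nc <- tiny_cfg(l = 16L)
  tc <- train_config(epochs = 5, batch_size = 4, seed = 7)
  fit1 <- train_dann(ds, nc, tc)
  fit2 <- train_dann(ds, nc, tc)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_equal(nrow(fit1$history), 5L)
  expect_true(all(c("mu", "phase1", "phase2", "phase3", "acc_class",
                    "acc_dom1", "acc_dom2") %in% names(fit1$history)))
  expect_equal(fit1$history$mu[1], 0)
  # single-class / single-domain datasets are rejected
  ds_oneclass <- lapply(ds, function(s) { s$class_label <- 0L; s })
  expect_error(train_dann(ds_oneclass, nc, tc), "invalid dataset")
})

test_that("ablated training (no adversary) reduces class loss across seeds", {
  # scaled-down ablation: lambda1 = lambda2 = 0 and L = 0 make the loop a
  # plain supervised classifier; final-epoch class loss should fall below
  # the first epoch's in >= 90% of seeds
  set.seed(111)
  mk <- function(seed) {
    set.seed(seed)
    out <- list()
    for (cl in 0:1) for (dm in 0:1) for (i in 1:3) {
      base <- if (cl == 1) sin(seq(0, 6, length.out = 24)) else
        rep(0, 24)
      out[[length(out) + 1L]] <- make_series(
        base + rnorm(24, sd = 0.4), sprintf("s%d%d%d", cl, dm, i), cl, dm)
    }
    out
  }
  wins <- vapply(1:6, function(sd) {
    ds <- mk(200 + sd)
    tc <- train_config(epochs = 10, lambda1 = 0, lambda2 = 0, L = 0,
                       t1 = 1, t2 = 10, batch_size = 6, seed = sd)
    h <- train_dann(ds, tiny_cfg(l = 24L), tc)$history
    h$loss_class[10] < h$loss_class[1]
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})
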