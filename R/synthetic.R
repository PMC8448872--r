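# Synthetic two-species locomotion cohorts. The base process is a two-state
# (low/high speed) semi-Markov bout process with smooth ramps between bouts,
# multiplicative Gaussian speed noise, and a heading random walk that turns
# mostly during slow phases; speeds are integrated to 2D positions. The two
# domains emulate species recorded at very different spatial scales (~100x)
# and sampling rates, with mildly different bout-duration statistics (the
# residual domain signal adversarial training is supposed to erase). Class 1
# carries one of three planted micro-structure signatures.

#' Specification of a synthetic cohort
#'
#' @param n_per_cell Series per (class, domain) cell, default 40.
#' @param length Model-ready series length `l`, default 599 (a 600-point
#'   trajectory at 1 Hz).
#' @param scale_factors Spatial scale per domain, default `c(1, 100)`.
#' @param rates Sampling rate (Hz) per domain, default `c(1, 5)`; the
#'   faster-sampled domain is undersampled back to `length`.
#' @param effect Planted class-1 signature: `"speed-instability-at-high-speed"`
#'   (short multiplicative speed dips inside high-speed bouts, the default),
#'   `"unstable-acceleration"` (extra speed noise while accelerating), or
#'   `"abrupt-pre-turn-deceleration"` (compressed braking ramps before slow
#'   turns).
#' @param magnitude Effect magnitude in `[0, inf)`; 0 plants nothing (null
#'   cohort), 1 is the default stated strength.
#' @param noise_sd Multiplicative speed noise SD, default 0.1.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell = 40L, length = 599L,
                        scale_factors = c(1, 100), rates = c(1L, 5L),
                        effect = c("speed-instability-at-high-speed",
                                   "unstable-acceleration",
                                   "abrupt-pre-turn-deceleration"),
                        magnitude = 1, noise_sd = 0.1, seed = 1L) {
  effect <- match.arg(effect)
  if (n_per_cell < 1L) stop("n_per_cell must be >= 1", call. = FALSE)
  if (length < 50L) stop("length must be >= 50", call. = FALSE)
  if (any(scale_factors <= 0) || any(rates < 1))
    stop("scale factors and rates must be positive", call. = FALSE)
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  structure(list(n_per_cell = as.integer(n_per_cell),
                 length = as.integer(length),
                 scale_factors = scale_factors, rates = as.integer(rates),
                 effect = effect, magnitude = magnitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Fixed base-process constants (speed in arbitrary length-units/s at domain
# scale 1). Domain 2 gets shifted bout-duration ranges: that is the residual,
# scale-free domain signal.
.base <- list(
  low_speed = 0.25, high_speed = 1.0, ramp_s = 3,
  low_dur = list(c(20, 50), c(30, 70)),   # per-domain U[a, b] seconds
  high_dur = list(c(30, 80), c(20, 60)),
  turn_sd_low = 0.6, turn_sd_high = 0.08,
  dip_len = c(3, 7), dip_depth = c(0.4, 0.7), dip_every_s = 20)

simulate_one <- function(spec, class_label, domain_idx, id) {
  l <- spec$length
  rate <- spec$rates[domain_idx]
  dt <- 1 / rate
  n_steps <- l * rate
  ramp <- max(1L, as.integer(round(.base$ramp_s * rate)))

  # bout timeline
  state <- integer(0); bnd <- integer(0)   # state per step, bout starts
  cur <- sample(0:1, 1L)
  while (length(state) < n_steps) {
    rng <- if (cur == 0L) .base$low_dur[[domain_idx]]
           else .base$high_dur[[domain_idx]]
    dur <- as.integer(round(stats::runif(1, rng[1L], rng[2L]) * rate))
    bnd <- c(bnd, length(state) + 1L)
    state <- c(state, rep(cur, dur))
    cur <- 1L - cur
  }
  state <- state[seq_len(n_steps)]
  bnd <- bnd[bnd <= n_steps]

  means <- ifelse(state == 1L, .base$high_speed, .base$low_speed)
  mag <- spec$magnitude
  truth <- NULL
  add_truth <- function(a, b) {
    lo <- max(1L, as.integer(floor((a - 1) * l / n_steps) + 1L))
    hi <- min(l, as.integer(ceiling(b * l / n_steps)))
    truth <<- rbind(truth, data.frame(start = lo, end = hi))
  }

  # smooth (possibly class-asymmetric) ramps at bout starts
  for (k in bnd[-1L]) {
    to_high <- state[k] == 1L
    r <- ramp
    if (!to_high && class_label == 1L &&
        spec$effect == "abrupt-pre-turn-deceleration")
      r <- max(1L, as.integer(round(ramp / (1 + 3 * mag))))
    hi <- min(n_steps, k + r - 1L)
    from <- means[k - 1L]
    means[k:hi] <- from + (means[hi] - from) * seq_len(hi - k + 1L) /
      (hi - k + 1L)
    if (!to_high && class_label == 1L &&
        spec$effect == "abrupt-pre-turn-deceleration" && mag > 0)
      add_truth(max(1L, k - 1L), hi)
  }

  extra_noise <- numeric(n_steps)
  if (class_label == 1L && mag > 0 &&
      spec$effect == "unstable-acceleration") {
    for (k in bnd[-1L]) {
      if (state[k] != 1L) next                       # up-ramps only
      hi <- min(n_steps, k + ramp + as.integer(2 * rate))
      extra_noise[k:hi] <- spec$noise_sd * 4 * mag
      add_truth(k, hi)
    }
  }

  if (class_label == 1L && mag > 0 &&
      spec$effect == "speed-instability-at-high-speed") {
    # dips inside high bouts; the characteristic segment is the whole
    # destabilized bout (the dips are its expression, not the unit attention
    # is expected to resolve)
    bout_state <- state[bnd]
    bout_end <- c(bnd[-1L] - 1L, n_steps)
    for (j in which(bout_state == 1L)) {
      dur_s <- (bout_end[j] - bnd[j] + 1L) / rate
      if (dur_s < 10) next
      n_dips <- max(1L, floor(dur_s / .base$dip_every_s))
      planted <- FALSE
      for (dd in seq_len(n_dips)) {
        len <- as.integer(round(stats::runif(1, .base$dip_len[1L],
                                             .base$dip_len[2L]) * rate))
        lo_ok <- bnd[j] + ramp
        hi_ok <- bout_end[j] - len
        if (hi_ok <= lo_ok) next
        a <- as.integer(floor(stats::runif(1, lo_ok, hi_ok)))
        fac <- 1 - mag * stats::runif(1, .base$dip_depth[1L],
                                      .base$dip_depth[2L])
        means[a:(a + len - 1L)] <- means[a:(a + len - 1L)] * fac
        planted <- TRUE
      }
      if (planted) add_truth(bnd[j], bout_end[j])
    }
  }

  v <- pmax(means * (1 + stats::rnorm(n_steps, 0,
                                      spec$noise_sd + extra_noise)),
            0.01 * .base$low_speed)

  turn_sd <- ifelse(state == 1L, .base$turn_sd_high, .base$turn_sd_low)
  theta <- cumsum(stats::rnorm(n_steps, 0, turn_sd * sqrt(dt)))
  sc <- spec$scale_factors[domain_idx]
  x <- sc * c(0, cumsum(v * dt * cos(theta)))
  y <- sc * c(0, cumsum(v * dt * sin(theta)))
  t <- (0:n_steps) * dt

  tr <- trajectory(id, t, x, y, class_label, domain_idx - 1L)
  if (!is.null(truth) && nrow(truth) > 0L) truth <- cbind(id = id, truth)
  list(traj = tr, truth = truth)
}

#' Generate a synthetic two-species cohort
#'
#' Deterministic given `spec$seed`. Class labels are independent of the raw
#' spatial scale (which tracks the domain), so a classifier reading raw scale
#' learns the species, not the class — normalization plus adversarial
#' training is what the cohort is built to exercise.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `loco_cohort`: list with `trajectories` (list of
#'   [trajectory()]), `truth` (data.frame id/start/end of planted segments in
#'   model-ready index space; zero rows for a null cohort) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  trajs <- list(); truths <- list()
  for (cl in 0:1) for (dom in 1:2) for (i in seq_len(spec$n_per_cell)) {
    id <- sprintf("c%d_d%d_%03d", cl, dom - 1L, i)
    one <- simulate_one(spec, cl, dom, id)
    trajs[[length(trajs) + 1L]] <- one$traj
    if (!is.null(one$truth)) truths[[length(truths) + 1L]] <- one$truth
  }
  truth <- if (length(truths)) do.call(rbind, truths)
           else data.frame(id = character(), start = integer(),
                           end = integer())
  structure(list(trajectories = trajs, truth = truth, spec = spec),
            class = "loco_cohort")
}

#' Preprocess a cohort into model-ready speed series
#'
#' Runs the standard pipeline per trajectory: speed conversion,
#' undersampling to the spec length where needed, per-series z-scoring.
#'
#' @param cohort A `loco_cohort` from [generate_cohort()].
#' @return A list of normalized [speed_series()] of equal length.
#' @export
cohort_series <- function(cohort) {
  stopifnot(inherits(cohort, "loco_cohort"))
  l <- cohort$spec$length
  lapply(cohort$trajectories, function(tr) {
    s <- to_speed_series(tr)
    if (length(s$values) > l) s <- resample_to_length(s, l)
    normalize_series(s)
  })
}

#' Fraction of attention mass inside planted segments
#'
#' The uniform baseline equals the fraction of timesteps the segments cover,
#' so a ratio of score to baseline above 1 means attention concentrates on
#' the planted signature.
#'
#' @param attention Attention vector of length l.
#' @param segments data.frame with `start`/`end` columns (1-based, inclusive)
#'   for one series, e.g. a per-id subset of a cohort's `truth`.
#' @return A list with `score` (attention mass inside the segments),
#'   `baseline` (covered fraction of timesteps) and `ratio`.
#' @export
attention_recovery_score <- function(attention, segments) {
  a <- as.numeric(attention)
  l <- length(a)
  if (nrow(segments) == 0L)
    return(list(score = 0, baseline = 0, ratio = NA_real_))
  if (any(segments$start < 1L) || any(segments$end > l) ||
      any(segments$start > segments$end))
    stop("segments out of series bounds", call. = FALSE)
  covered <- unique(unlist(Map(seq, segments$start, segments$end)))
  score <- sum(a[covered])
  baseline <- length(covered) / l
  list(score = score, baseline = baseline, ratio = score / baseline)
}
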