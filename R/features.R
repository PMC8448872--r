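# Interpretable per-timestep features for the surrogate trees: speed,
# acceleration, their centered rolling statistics at several window lengths,
# and a local-minimum flag. Edge windows are truncated rather than padded.
# Features are min-max normalized per trajectory, matching how the tree
# figures are read (thresholds live in [0, 1]).

roll_bounds <- function(l, w) {
  h <- (w - 1L) %/% 2L
  t <- seq_len(l)
  list(lo = pmax(1L, t - h), hi = pmin(l, t + h))
}

# Rolling mean/std/skewness/kurtosis via cumulative power sums. Population
# std; adjusted Fisher-Pearson skewness; excess kurtosis. Zero-variance or
# too-short windows yield 0 for skewness/kurtosis by convention.
roll_moments <- function(x, w) {
  l <- length(x)
  b <- roll_bounds(l, w)
  cs <- function(p) {
    s <- c(0, cumsum(x^p))
    s[b$hi + 1L] - s[b$lo]
  }
  n <- b$hi - b$lo + 1
  s1 <- cs(1); s2 <- cs(2); s3 <- cs(3); s4 <- cs(4)
  m1 <- s1 / n
  m2 <- pmax(s2 / n - m1^2, 0)
  m3 <- s3 / n - 3 * m1 * s2 / n + 2 * m1^3
  m4 <- s4 / n - 4 * m1 * s3 / n + 6 * m1^2 * s2 / n - 3 * m1^4
  tol <- 1e-12 * max(1, max(abs(x))^2)
  ok2 <- m2 > tol
  skew <- ifelse(ok2 & n >= 3,
                 sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5, 0)
  kurt <- ifelse(ok2 & n >= 4, m4 / m2^2 - 3, 0)
  list(mean = m1, std = sqrt(m2), skew = skew, kurt = kurt)
}

roll_extreme <- function(x, w, fun) {
  b <- roll_bounds(length(x), w)
  vapply(seq_along(x), function(t) fun(x[b$lo[t]:b$hi[t]]), 0)
}

local_min_flag <- function(x) {
  l <- length(x)
  flag <- numeric(l)
  if (l >= 3L)
    flag[2:(l - 1)] <- as.numeric(x[2:(l - 1)] < x[1:(l - 2)] &
                                  x[2:(l - 1)] < x[3:l])
  flag
}

minmax_cols <- function(M) {
  rng <- apply(M, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  out <- sweep(M, 2L, rng[1L, ])
  out <- sweep(out, 2L, ifelse(span > 0, span, 1), "/")
  out[, span == 0] <- 0
  out
}

#' Extract per-timestep window features from a speed series
#'
#' One row per timestep; columns are speed, acceleration (first difference of
#' speed, zero-padded at the start), a local-minimum-of-speed flag, and
#' rolling mean/min/max/std/skewness/kurtosis of both speed and acceleration
#' at each window length. All columns are min-max normalized within the
#' trajectory, so every value lies in `[0, 1]` and tree thresholds are
#' comparable across series.
#'
#' @param s A [speed_series()] (or numeric vector).
#' @param windows Centered window lengths in timesteps, default `c(5, 11, 21)`.
#' @return A numeric matrix (`l` x features) of class `window_features` with
#'   unique column names; `attr(, "windows")` records the window lengths.
#' @export
extract_window_features <- function(s, windows = c(5L, 11L, 21L)) {
  v <- if (inherits(s, "speed_series")) s$values else as.numeric(s)
  l <- length(v)
  windows <- as.integer(windows)
  if (any(windows < 2L)) stop("window lengths must be >= 2", call. = FALSE)
  if (any(windows > l))
    stop("window longer than series", call. = FALSE)
  accel <- c(0, diff(v))
  cols <- list(speed = v, accel = accel, speed_localmin = local_min_flag(v))
  for (w in windows) {
    for (sig in c("speed", "accel")) {
      x <- if (sig == "speed") v else accel
      mo <- roll_moments(x, w)
      cols[[sprintf("%s_mean_w%d", sig, w)]] <- mo$mean
      cols[[sprintf("%s_min_w%d", sig, w)]] <- roll_extreme(x, w, min)
      cols[[sprintf("%s_max_w%d", sig, w)]] <- roll_extreme(x, w, max)
      cols[[sprintf("%s_std_w%d", sig, w)]] <- mo$std
      cols[[sprintf("%s_skew_w%d", sig, w)]] <- mo$skew
      cols[[sprintf("%s_kurt_w%d", sig, w)]] <- mo$kurt
    }
  }
  M <- minmax_cols(do.call(cbind, cols))
  colnames(M) <- names(cols)
  structure(M, windows = windows, class = c("window_features", "matrix",
                                            "array"))
}
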