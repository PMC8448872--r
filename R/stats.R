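# Validation layer: per-trajectory derived locomotion statistics and the
# two-sample tests used to compare dopamine-intact vs dopamine-deficient
# groups. The test is chosen per comparison: Welch's t when both samples look
# normal (Shapiro-Wilk), Brunner-Munzel otherwise.

loco_test <- function(method, statistic, df, p, effect, n1, n2) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p, effect_size = effect, n = c(n1, n2)),
            class = "loco_test")
}

#' @export
print.loco_test <- function(x, ...) {
  cat(sprintf("%s: stat=%.4g, df=%.2f, p=%.3g, effect=%.3f, n=%d/%d\n",
              x$method, x$statistic, x$df, x$p_value, x$effect_size,
              x$n[1L], x$n[2L]))
  invisible(x)
}

series_values <- function(s) if (inherits(s, "speed_series")) s$values else
  as.numeric(s)

partition_windows <- function(idx, window) {
  nw <- length(idx) %/% window
  if (nw < 1L) stop("series shorter than window", call. = FALSE)
  lapply(seq_len(nw), function(k) idx[((k - 1L) * window + 1L):(k * window)])
}

#' Mean within-window minimum speed during high-speed episodes
#'
#' Splits the series into consecutive non-overlapping windows, keeps the
#' windows whose mean speed lies in the top `top_frac` fraction, and returns
#' the mean over those windows of the within-window minimum speed. An animal
#' that sustains its high-speed bouts scores high; one whose fast episodes
#' are riddled with momentary dips scores low even at the same mean speed.
#'
#' @param s A (normally z-scored) [speed_series()] or numeric vector.
#' @param window Window length in timesteps, default 10.
#' @param top_frac Fraction of windows (by mean speed) selected, default 0.2.
#' @return A scalar.
#' @export
min_speed_during_high_speed <- function(s, window = 10L, top_frac = 0.2) {
  v <- series_values(s)
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]",
                                          call. = FALSE)
  wins <- partition_windows(seq_along(v), window)
  means <- vapply(wins, function(ix) mean(v[ix]), 0)
  k <- max(1L, ceiling(length(wins) * top_frac))
  sel <- order(means, decreasing = TRUE)[seq_len(k)]
  mean(vapply(wins[sel], function(ix) min(v[ix]), 0))
}

#' Mean within-window minimum speed during high-acceleration episodes
#'
#' Like [min_speed_during_high_speed()], but windows are ranked by mean
#' acceleration (first difference of speed). If the series has exactly zero
#' acceleration everywhere the ranking is vacuous and the statistic falls
#' back to averaging over all windows.
#'
#' @inheritParams min_speed_during_high_speed
#' @export
min_speed_during_acceleration <- function(s, window = 10L, top_frac = 0.2) {
  v <- series_values(s)
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]",
                                          call. = FALSE)
  acc <- diff(v)
  wins <- partition_windows(seq_along(acc), window)  # accel index space
  means <- vapply(wins, function(ix) mean(acc[ix]), 0)
  k <- if (all(acc == 0)) length(wins)
       else max(1L, ceiling(length(wins) * top_frac))
  sel <- order(means, decreasing = TRUE)[seq_len(k)]
  # accel index i sits between speed samples i and i+1; use speed at i+1
  mean(vapply(wins[sel], function(ix) min(v[ix + 1L]), 0))
}

#' Mean acceleration magnitude before turns
#'
#' Turns are proxied by local minima of speed falling below a low quantile
#' (direction changes happen at the slow points of a trajectory). For each
#' turn the mean absolute acceleration over the `pre_window` timesteps
#' immediately before it is computed; the per-trajectory statistic is the
#' mean over turns. An animal that brakes abruptly before turning scores
#' high.
#'
#' @param traj A [trajectory()] or a [speed_series()].
#' @param pre_window Timesteps before each turn to average over, default 5.
#' @param speed_quantile Quantile of speed below which a local minimum counts
#'   as a turn, default 0.25.
#' @return A scalar; errors with "no turns detected" if no local minimum
#'   qualifies.
#' @export
acceleration_before_turns <- function(traj, pre_window = 5L,
                                      speed_quantile = 0.25) {
  v <- if (inherits(traj, "loco_trajectory"))
    to_speed_series(traj)$values else series_values(traj)
  l <- length(v)
  acc <- c(0, diff(v))
  thr <- stats::quantile(v, speed_quantile, names = FALSE)
  is_min <- local_min_flag(v) == 1
  turns <- which(is_min & v <= thr & seq_len(l) > pre_window)
  if (length(turns) == 0L) stop("no turns detected", call. = FALSE)
  mean(vapply(turns, function(t) mean(abs(acc[(t - pre_window + 1L):t])), 0))
}

#' Brunner-Munzel two-sample test
#'
#' Rank-based test of the stochastic-superiority hypothesis
#' `P(X < Y) + 0.5 P(X = Y) = 0.5`, robust to unequal variances and
#' non-normality. Reports the studentized statistic, Satterthwaite-type
#' degrees of freedom, two-sided p from the t distribution, and the
#' superiority estimate as the effect size.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return A `loco_test` object.
#' @export
brunner_munzel <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("both samples need >= 2 values", call. = FALSE)
  pooled <- rank(c(x, y))
  r1 <- pooled[seq_len(n1)]; r2 <- pooled[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  v1 <- stats::var(r1 - rank(x))
  v2 <- stats::var(r2 - rank(y))
  if (v1 == 0 && v2 == 0)
    stop("degenerate samples: zero rank variance (complete separation)",
         call. = FALSE)
  sig <- n1 * v1 + n2 * v2
  w <- n1 * n2 * (m2 - m1) / ((n1 + n2) * sqrt(sig))
  df <- sig^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(w), df)
  effect <- (m2 - (n2 + 1) / 2) / n1  # P(X<Y) + 0.5 P(X=Y)
  loco_test("Brunner-Munzel", w, df, p, effect, n1, n2)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom.
#' The effect size is the signed point-biserial-type
#' `r = t / sqrt(t^2 + df)`.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return A `loco_test` object.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need >= 2 values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate samples: zero variance in both groups", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  t_stat <- unname(tt$statistic)
  df <- unname(tt$parameter)
  loco_test("Welch t", t_stat, df, tt$p.value,
            t_stat / sqrt(t_stat^2 + df), length(x), length(y))
}

#' Shapiro-Wilk normality check
#'
#' Drives the test-selection rule: a comparison uses Welch's t only when both
#' groups pass this check, otherwise Brunner-Munzel.
#'
#' @param x Numeric sample, n >= 3.
#' @return A `loco_test` object (df reported as n).
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("insufficient sample: n < 3", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate sample: constant values", call. = FALSE)
  sw <- stats::shapiro.test(x)
  loco_test("Shapiro-Wilk", unname(sw$statistic), length(x), sw$p.value,
            NA_real_, length(x), 0L)
}

#' Normality-gated two-sample comparison
#'
#' Applies [normality_check()] to both samples at level `alpha`; if both look
#' normal the groups are compared with [welch_t()], otherwise with
#' [brunner_munzel()].
#'
#' @param x,y Numeric samples.
#' @param alpha Normality-test level, default 0.05.
#' @return A `loco_test` object.
#' @export
select_and_test <- function(x, y, alpha = 0.05) {
  normal <- normality_check(x)$p_value > alpha &&
    normality_check(y)$p_value > alpha
  if (normal) welch_t(x, y) else brunner_munzel(x, y)
}

#' Tabular validation report
#'
#' One row per derived feature: group means, selected test, statistic, df,
#' p value, effect size and group sizes — the reporting format of the figure
#' captions.
#'
#' @param features Named list; each element is a `list(x = , y = )` pair of
#'   per-trajectory feature samples for the two groups.
#' @param alpha Normality-test level passed to [select_and_test()].
#' @return A data.frame.
#' @export
validation_report <- function(features, alpha = 0.05) {
  rows <- lapply(names(features), function(nm) {
    x <- features[[nm]]$x; y <- features[[nm]]$y
    ts <- select_and_test(x, y, alpha)
    data.frame(feature = nm, mean_group0 = mean(x), mean_group1 = mean(y),
               method = ts$method, statistic = ts$statistic, df = ts$df,
               p_value = ts$p_value, effect_size = ts$effect_size,
               n0 = ts$n[1L], n1 = ts$n[2L])
  })
  do.call(rbind, rows)
}
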