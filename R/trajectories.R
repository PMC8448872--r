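#' Construct a 2D locomotion trajectory
#'
#' A trajectory is an ordered sequence of timestamped planar positions plus a
#' binary class label (e.g. dopamine-intact vs dopamine-deficient) and a binary
#' domain label (the species / recording setup the animal came from).
#'
#' @param id Character scalar identifying the trajectory.
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y Numeric vectors of positions (any consistent length unit).
#' @param class_label Integer 0 or 1.
#' @param domain_label Integer 0 or 1.
#' @return An object of class `loco_trajectory`.
#' @examples
#' tr <- trajectory("w1", t = 0:3, x = c(0, 1, 2, 2), y = c(0, 0, 1, 1))
#' to_speed_series(tr)
#' @export
trajectory <- function(id, t, x, y, class_label = 0L, domain_label = 0L) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) < 2L)
    stop("trajectory needs at least 2 points", call. = FALSE)
  if (length(x) != length(t) || length(y) != length(t))
    stop("t, x, y must have equal length", call. = FALSE)
  if (anyNA(t) || anyNA(x) || anyNA(y))
    stop("trajectory contains missing values", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  check_binary_label(class_label, "class_label")
  check_binary_label(domain_label, "domain_label")
  structure(
    list(id = as.character(id), t = t, x = x, y = y,
         class_label = as.integer(class_label),
         domain_label = as.integer(domain_label)),
    class = "loco_trajectory")
}

check_binary_label <- function(v, what) {
  if (length(v) != 1L || is.na(v) || !(v %in% c(0, 1)))
    stop(what, " must be 0 or 1", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.loco_trajectory <- function(x, ...) {
  cat(sprintf("<loco_trajectory %s: %d points, %.1f s, class=%d domain=%d>\n",
              x$id, length(x$t), diff(range(x$t)), x$class_label,
              x$domain_label))
  invisible(x)
}

#' Construct a speed time-series
#'
#' The model's input representation: one speed value per inter-sample step of
#' a trajectory, with labels carried along. Usually produced by
#' [to_speed_series()] and then [normalize_series()].
#'
#' @param id Character scalar.
#' @param values Numeric vector of speeds (length-units per second), length
#'   `T - 1` for a `T`-point trajectory.
#' @param class_label,domain_label Binary labels, see [trajectory()].
#' @param normalized Logical; `TRUE` once the series has been z-scored.
#' @return An object of class `speed_series`.
#' @export
speed_series <- function(id, values, class_label = 0L, domain_label = 0L,
                         normalized = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values))
    stop("speed series must be non-empty and free of NA", call. = FALSE)
  check_binary_label(class_label, "class_label")
  check_binary_label(domain_label, "domain_label")
  structure(
    list(id = as.character(id), values = values,
         class_label = as.integer(class_label),
         domain_label = as.integer(domain_label),
         normalized = isTRUE(normalized)),
    class = "speed_series")
}

#' @export
print.speed_series <- function(x, ...) {
  cat(sprintf("<speed_series %s: l=%d, class=%d domain=%d, normalized=%s>\n",
              x$id, length(x$values), x$class_label, x$domain_label,
              x$normalized))
  invisible(x)
}

#' @export
length.speed_series <- function(x) length(x$values)

#' Convert a trajectory to a speed time-series
#'
#' Speed at step i is the Euclidean displacement between consecutive positions
#' divided by the elapsed time, giving a series of length `T - 1`. Absolute
#' coordinates are discarded, which is what makes trajectories from different
#' recording setups comparable at all.
#'
#' @param traj A [trajectory()].
#' @return An unnormalized [speed_series()] with labels carried over.
#' @export
to_speed_series <- function(traj) {
  stopifnot(inherits(traj, "loco_trajectory"))
  dt <- diff(traj$t)
  if (any(dt == 0)) stop("duplicate timestamps give zero dt", call. = FALSE)
  v <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt
  speed_series(traj$id, v, traj$class_label, traj$domain_label,
               normalized = FALSE)
}

#' Z-score a speed series
#'
#' Per-series standardization (subtract mean, divide by population standard
#' deviation). Removes the between-species scale difference so that, e.g., a
#' worm moving at 0.1 mm/s and a mouse at 100 mm/s land on the same scale.
#' The population (1/n) standard deviation is used, and this choice is fixed.
#'
#' @param s A [speed_series()].
#' @return The same series, z-scored, with `normalized = TRUE`.
#' @export
normalize_series <- function(s) {
  stopifnot(inherits(s, "speed_series"))
  v <- s$values
  if (length(v) < 2L)
    stop("need at least 2 values to normalize", call. = FALSE)
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop == 0)
    stop("degenerate series: zero variance", call. = FALSE)
  speed_series(s$id, (v - mu) / sd_pop, s$class_label, s$domain_label,
               normalized = TRUE)
}

#' Undersample a speed series to a target length
#'
#' Even-stride index selection (no interpolation), keeping the first element:
#' index k of the output is element `floor((k-1) * l / target_len) + 1` of the
#' input. Used to undersample the faster-sampled species so all series fed to
#' the network share one length.
#'
#' @param s A [speed_series()].
#' @param target_len Desired output length, between 1 and `length(s)`.
#' @return A [speed_series()] of length exactly `target_len`.
#' @export
resample_to_length <- function(s, target_len) {
  stopifnot(inherits(s, "speed_series"))
  l <- length(s$values)
  target_len <- as.integer(target_len)
  if (target_len < 1L || target_len > l)
    stop("target_len must be in [1, length(s)]", call. = FALSE)
  idx <- floor((seq_len(target_len) - 1) * l / target_len) + 1L
  speed_series(s$id, s$values[idx], s$class_label, s$domain_label,
               normalized = s$normalized)
}

#' Split a trajectory into fixed-duration segments
#'
#' Consecutive non-overlapping windows of `segment_seconds`; a trailing
#' remainder shorter than the window is dropped, as are segments whose total
#' path length falls below `min_movement` (an animal parked in a corner
#' carries no locomotion signal).
#'
#' @param traj A [trajectory()].
#' @param segment_seconds Window duration in seconds, > 0.
#' @param min_movement Minimum total path length (same unit as x/y) for a
#'   segment to be retained.
#' @return A list of [trajectory()] objects, ids suffixed `_seg<k>`.
#' @export
segment_trajectory <- function(traj, segment_seconds, min_movement = 0) {
  stopifnot(inherits(traj, "loco_trajectory"))
  if (segment_seconds <= 0) stop("segment_seconds must be > 0", call. = FALSE)
  t0 <- traj$t[1L]
  total <- traj$t[length(traj$t)] - t0
  n_seg <- floor(total / segment_seconds)
  out <- list()
  for (k in seq_len(n_seg)) {
    lo <- t0 + (k - 1) * segment_seconds
    hi <- t0 + k * segment_seconds
    sel <- traj$t >= lo & traj$t < hi
    if (k == n_seg) sel <- traj$t >= lo & traj$t <= hi
    if (sum(sel) < 2L) next
    xs <- traj$x[sel]; ys <- traj$y[sel]
    path <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
    if (path < min_movement) next
    out[[length(out) + 1L]] <- trajectory(
      paste0(traj$id, "_seg", k), traj$t[sel], xs, ys,
      traj$class_label, traj$domain_label)
  }
  out
}

#' Construct a per-foot ground-reaction-force recording
#'
#' @param id Character scalar.
#' @param left,right Numeric vectors of summed vertical ground-reaction force
#'   per foot, sampled at a common fixed `rate` starting at time 0.
#' @param rate Sampling rate in Hz.
#' @param class_label,domain_label Binary labels.
#' @return An object of class `force_series`.
#' @export
force_series <- function(id, left, right, rate, class_label = 0L,
                         domain_label = 0L) {
  left <- as.numeric(left); right <- as.numeric(right)
  if (length(left) < 1L || length(right) < 1L)
    stop("both feet need samples", call. = FALSE)
  if (length(left) != length(right))
    stop("feet must be aligned: equal length at one rate", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  check_binary_label(class_label, "class_label")
  check_binary_label(domain_label, "domain_label")
  structure(
    list(id = as.character(id), left = left, right = right,
         rate = as.numeric(rate), class_label = as.integer(class_label),
         domain_label = as.integer(domain_label)),
    class = "force_series")
}

contact_onsets <- function(force, threshold, rate) {
  above <- force > threshold
  onsets <- which(diff(c(FALSE, above)) == 1L)
  (onsets - 1L) / rate
}

#' Convert gait force recordings to a stride-time series
#'
#' Stride time (interval between consecutive contacts of the same foot) is
#' inversely related to walking speed, so the merged stride-time sequence
#' plays the role a speed series plays for free locomotion. Contact onsets
#' are upward crossings of `contact_threshold` in the summed per-foot force;
#' per-foot stride times are merged by sorting on the timestamp of the stride
#' onset.
#'
#' @param f A [force_series()].
#' @param contact_threshold Force threshold for foot contact; defaults to 5%
#'   of the per-foot maximum (heel-strike detection is not standardized).
#' @return An unnormalized [speed_series()] whose values are stride times in
#'   seconds, ordered by stride onset.
#' @export
gait_to_stride_series <- function(f, contact_threshold = NULL) {
  stopifnot(inherits(f, "force_series"))
  feet <- list(f$left, f$right)
  ev <- list()
  for (k in 1:2) {
    thr <- if (is.null(contact_threshold)) 0.05 * max(feet[[k]])
           else contact_threshold
    if (!is.null(contact_threshold) && contact_threshold <= 0)
      stop("contact_threshold must be positive", call. = FALSE)
    on <- contact_onsets(feet[[k]], thr, f$rate)
    if (length(on) < 2L)
      stop("insufficient gait events: fewer than 2 contacts on one foot",
           call. = FALSE)
    ev[[k]] <- data.frame(t = on[-length(on)], stride = diff(on))
  }
  merged <- rbind(ev[[1L]], ev[[2L]])
  merged <- merged[order(merged$t), , drop = FALSE]
  speed_series(f$id, merged$stride, f$class_label, f$domain_label,
               normalized = FALSE)
}
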