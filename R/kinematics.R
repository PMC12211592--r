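# Per-trial locomotor performance measures: speed, tortuosity, yaw, stride
# detection, stance/swing and duty factor, and the allometric helper.

#' Path-level kinematic summary of a trial
#'
#' Computes mean center-of-mass speed (mm/s), relative speed (body lengths
#' per second), path tortuosity and per-frame yaw. Tortuosity is the
#' straightness index `tau = d / D`: net displacement between the first and
#' last COM positions divided by the total distance traveled along the
#' trajectory, at most 1. Yaw is the signed angle (degrees) between the
#' instantaneous COM velocity and the cranial-pointing body axis
#' (cranial minus caudal); positive when the body axis lies
#' counterclockwise of the velocity in dorsal view.
#'
#' @param trial A [tracked_trial()].
#' @param com_velocity Optional n x 2 COM velocity matrix (mm/s); computed
#'   with [local_quadratic_derivative()] over `window_ms` when `NULL`.
#' @param window_ms COM derivative window, default 50 ms.
#' @return An object of class `path_summary`: list with `mean_speed`,
#'   `relative_speed`, `tortuosity`, `yaw` (per frame, degrees),
#'   `mean_abs_yaw`, `speed` (per frame).
#' @export
path_summary <- function(trial, com_velocity = NULL, window_ms = 50) {
  validate_trial(trial)
  if (is.null(com_velocity)) {
    com_velocity <- cbind(
      local_quadratic_derivative(trial$com[, 1], window_ms, trial$frame_rate),
      local_quadratic_derivative(trial$com[, 2], window_ms, trial$frame_rate))
  }
  com_velocity <- as.matrix(com_velocity)
  speed <- sqrt(rowSums(com_velocity^2))
  steps <- sqrt(rowSums(diff(trial$com)^2))
  path_len <- sum(steps)
  if (path_len <= 0)
    stop("zero path length: tortuosity undefined", call. = FALSE)
  displacement <- sqrt(sum((trial$com[nrow(trial$com), ] - trial$com[1, ])^2))
  axis <- trial$cranial - trial$caudal  # cranial-pointing
  cross <- com_velocity[, 1] * axis[, 2] - com_velocity[, 2] * axis[, 1]
  dot <- rowSums(com_velocity * axis)
  yaw <- atan2(cross, dot) * 180 / pi
  structure(list(mean_speed = mean(speed),
                 relative_speed = mean(speed) / trial$body_length,
                 tortuosity = displacement / path_len,
                 yaw = yaw, mean_abs_yaw = mean(abs(yaw)),
                 speed = speed),
            class = "path_summary")
}

#' @export
print.path_summary <- function(x, ...) {
  cat(sprintf("<path_summary> speed %.2f mm/s (%.2f BL/s), tortuosity %.3f, mean |yaw| %.1f deg\n",
              x$mean_speed, x$relative_speed, x$tortuosity, x$mean_abs_yaw))
  invisible(x)
}

# Dominant period (frames) of a zero-mean oscillatory series: lag of the
# first local maximum of the autocorrelation with positive correlation.
dominant_period <- function(x) {
  n <- length(x)
  ac <- stats::acf(x, lag.max = min(n - 2L, 5000L), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  d <- diff(ac)
  # first index where acf turns from rising to falling after the lag-0 peak
  turns <- which(d[-1] <= 0 & d[-length(d)] > 0) + 1L
  turns <- turns[ac[turns + 1L] > 0]
  if (length(turns) == 0L) return(NA_real_)
  turns[1]
}

# Local maxima of a series with prominence- and distance-based selection.
# Plateaus (runs of equal values strictly above both shoulders) count as a
# single peak at the plateau center, so flat-topped velocity profiles give
# stable stride boundaries. Prominence of a peak: height above the higher
# of the two deepest valleys separating it from taller peaks (standard
# topographic definition).
find_peaks <- function(x, min_distance = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  fin <- x[is.finite(x)]
  if (length(fin) < 3L) return(integer(0))
  eps <- 1e-8 * max(diff(range(fin)), .Machine$double.eps)
  flat <- which(x[2:(n - 1L)] >= x[1:(n - 2L)] - eps &
                  x[2:(n - 1L)] >= x[3:n] - eps) + 1L
  if (length(flat) == 0L) return(integer(0))
  runs <- split(flat, cumsum(c(1L, diff(flat) != 1L)))
  cand <- vapply(runs, function(r) {
    a <- r[1]; b <- r[length(r)]
    v <- max(x[a:b])
    left_ok <- a == 1L || x[a - 1L] < v - eps
    right_ok <- b == n || x[b + 1L] < v - eps
    if (left_ok && right_ok) as.integer(floor((a + b) / 2)) else NA_integer_
  }, integer(1))
  cand <- cand[!is.na(cand)]
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    taller_l <- x[1:i] > x[i] + eps
    left <- if (any(taller_l)) min(x[max(which(taller_l)):i]) else min(x[1:i])
    taller_r <- x[i:n] > x[i] + eps
    right <- if (any(taller_r)) min(x[i:(i - 1L + min(which(taller_r)))])
             else min(x[i:n])
    x[i] - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1L) return(keep)
  # enforce minimum spacing, keeping taller peaks first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) if (all(abs(i - sel) >= min_distance)) sel <- c(sel, i)
  sort(sel)
}

#' Detect strides from a tarsus velocity series
#'
#' Stride boundaries are successive peaks of the tarsus velocity along the
#' direction of COM motion; the stride period is the mean inter-peak
#' spacing. By default the minimum peak separation is half the dominant
#' period of the series (from its autocorrelation) and the minimum peak
#' prominence is half the series' standard deviation.
#'
#' @param v Tarsus velocity along the motion direction, per frame (from
#'   [local_quadratic_derivative()] projected on the COM heading).
#' @param frame_rate Frames per second.
#' @param com Optional n x 2 COM position matrix; when supplied, per-stride
#'   length is the COM displacement accumulated over the stride.
#' @param min_distance,min_prominence Peak-selection overrides (frames /
#'   velocity units); computed from the series when `NULL`.
#' @return An object of class `stride_table`: data frame with one row per
#'   stride (`start_time`, `end_time`, `period`, `frequency`, `length`),
#'   with attributes `mean_period`, `mean_frequency`, `mean_length` and
#'   logical `warning` (`TRUE` when fewer than 2 peaks were found and the
#'   table is empty).
#' @export
detect_strides <- function(v, frame_rate, com = NULL, min_distance = NULL,
                           min_prominence = NULL) {
  stopifnot(is.numeric(v), frame_rate > 0)
  empty <- function(warn) {
    out <- data.frame(start_time = numeric(0), end_time = numeric(0),
                      period = numeric(0), frequency = numeric(0),
                      length = numeric(0))
    structure(out, class = c("stride_table", "data.frame"),
              mean_period = NA_real_, mean_frequency = NA_real_,
              mean_length = NA_real_, warning = warn)
  }
  ok <- is.finite(v)
  if (sum(ok) < 3L) {
    warning("too few finite samples for stride detection", call. = FALSE)
    return(empty(TRUE))
  }
  if (is.null(min_distance)) {
    p <- dominant_period(v[ok] - mean(v[ok]))
    min_distance <- if (is.na(p)) 1 else 0.5 * p
  }
  if (is.null(min_prominence)) min_prominence <- 0.5 * stats::sd(v[ok])
  vv <- v
  vv[!ok] <- -Inf
  pk <- find_peaks(vv, min_distance, min_prominence)
  if (length(pk) < 2L) {
    warning("fewer than 2 velocity peaks: no strides detected", call. = FALSE)
    return(empty(TRUE))
  }
  t_pk <- (pk - 1L) / frame_rate
  periods <- diff(t_pk)
  lens <- if (!is.null(com)) {
    com <- as.matrix(com)
    vapply(seq_len(length(pk) - 1L), function(k)
      sqrt(sum((com[pk[k + 1L], ] - com[pk[k], ])^2)), numeric(1))
  } else rep(NA_real_, length(periods))
  out <- data.frame(start_time = t_pk[-length(t_pk)], end_time = t_pk[-1L],
                    period = periods, frequency = 1 / periods, length = lens)
  structure(out, class = c("stride_table", "data.frame"),
            mean_period = mean(periods), mean_frequency = 1 / mean(periods),
            mean_length = mean(lens), warning = FALSE)
}

# Remove state runs shorter than `debounce` frames by flipping them,
# iterating until stable (morphological opening + closing).
debounce_mask <- function(mask, debounce) {
  if (debounce <= 1L || length(mask) == 0L) return(mask)
  repeat {
    r <- rle(mask)
    short <- which(r$lengths < debounce)
    # never flip leading/trailing runs (no neighbor consensus)
    short <- short[short > 1L & short < length(r$lengths)]
    if (length(short) == 0L) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- !r$values[i]
    mask <- inverse.rle(r)
  }
  mask
}

#' Stance/swing classification and duty factor
#'
#' A tarsus is in stance when it moves caudally relative to the COM: its
#' body-frame fore-aft velocity is below `-threshold`. Runs shorter than
#' `debounce` frames are removed. When stride boundaries are supplied, the
#' duty factor of each stride is the fraction of its frames in stance. A
#' dragged tarsus moving with the body (zero velocity relative to the COM)
#' is never in stance, giving duty factor 0 in the limit.
#'
#' @param bft A `body_frame_trial` from [to_body_frame()].
#' @param threshold Caudal-velocity threshold (mm/s), default 2.
#' @param debounce Minimum run length in frames, default 3.
#' @param strides Optional named list of [detect_strides()] tables (per leg
#'   label), used to compute per-stride duty factors.
#' @param window_ms Tarsal derivative window, default 40 ms.
#' @return An object of class `stance_mask`: list with `mask` (logical
#'   frames x legs matrix; `FALSE` on invalid frames) and `duty` (data frame
#'   `leg`, `stride`, `duty`, empty when `strides` is `NULL`).
#' @export
stance_swing <- function(bft, threshold = 2, debounce = 3L, strides = NULL,
                         window_ms = 40) {
  stopifnot(inherits(bft, "body_frame_trial"))
  fr <- bft$source$frame_rate
  legs <- names(bft$tarsi_bf)
  n <- length(bft$valid)
  mask <- matrix(FALSE, n, length(legs), dimnames = list(NULL, legs))
  for (leg in legs) {
    y <- bft$tarsi_bf[[leg]][, "y"]
    ok <- is.finite(y)
    if (sum(ok) < 3L) next
    idx <- range(which(ok))
    span <- idx[1]:idx[2]
    if (!all(is.finite(y[span]))) next
    vy <- local_quadratic_derivative(y[span], window_ms, fr)
    st <- vy < -threshold
    mask[span, leg] <- debounce_mask(st, debounce)
  }
  duty <- data.frame(leg = character(0), stride = integer(0),
                     duty = numeric(0))
  if (!is.null(strides)) {
    # stride times are series-relative: frame 1 is t = 0
    for (leg in intersect(legs, names(strides))) {
      tab <- strides[[leg]]
      if (nrow(tab) == 0L) next
      for (k in seq_len(nrow(tab))) {
        i0 <- round((tab$start_time[k]) * fr) + 1L
        i1 <- round((tab$end_time[k]) * fr)
        i0 <- max(1L, i0); i1 <- min(n, i1)
        if (i1 <= i0) next
        duty <- rbind(duty, data.frame(
          leg = leg, stride = k,
          duty = mean(mask[i0:i1, leg])))
      }
    }
  }
  structure(list(mask = mask, duty = duty), class = "stance_mask")
}

#' Predicted speed-length allometric exponent
#'
#' Combines a speed-mass power-law exponent `a` (speed proportional to
#' mass^a) with a mass-length exponent `b` (mass proportional to length^b)
#' into the predicted speed-length exponent `a * b`, with first-order error
#' propagation `sigma = sqrt(b^2 sigma_a^2 + a^2 sigma_b^2)`.
#'
#' @param a,sigma_a Speed-mass exponent and its standard error.
#' @param b,sigma_b Mass-length exponent and its standard error.
#' @return Named numeric vector `c(exponent = ..., sigma = ...)`.
#' @examples
#' predicted_length_exponent(0.353, 0.08, 2.70, 0.04)  # ~0.95 +/- 0.22
#' @export
predicted_length_exponent <- function(a, sigma_a, b, sigma_b) {
  stopifnot(is.finite(a), is.finite(sigma_a), is.finite(b), is.finite(sigma_b))
  c(exponent = a * b,
    sigma = sqrt(b^2 * sigma_a^2 + a^2 * sigma_b^2))
}

#' Strides for every present leg of a trial
#'
#' Runs [detect_strides()] on each present leg's tarsus velocity projected
#' on the instantaneous COM heading.
#'
#' @param trial A [tracked_trial()].
#' @param window_ms Tarsal derivative window, default 40 ms.
#' @param com_window_ms COM derivative window, default 50 ms.
#' @param ... Passed to [detect_strides()].
#' @return Named list of `stride_table`s, one per present leg.
#' @export
trial_strides <- function(trial, window_ms = 40, com_window_ms = 50, ...) {
  validate_trial(trial)
  fr <- trial$frame_rate
  vcom <- cbind(local_quadratic_derivative(trial$com[, 1], com_window_ms, fr),
                local_quadratic_derivative(trial$com[, 2], com_window_ms, fr))
  sp <- sqrt(rowSums(vcom^2))
  u <- vcom / ifelse(sp > 0, sp, NA_real_)
  out <- list()
  for (leg in present_legs(trial)) {
    m <- trial$tarsi[[leg]]
    vt <- cbind(local_quadratic_derivative(m[, 1], window_ms, fr),
                local_quadratic_derivative(m[, 2], window_ms, fr))
    v_along <- rowSums(vt * u)
    out[[leg]] <- detect_strides(v_along, fr, com = trial$com, ...)
  }
  out
}
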