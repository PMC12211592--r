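# The gait-space core: per-leg phase estimation from standardized tarsus
# kinematics, adjacent-leg phase differences, model gaits, the hypertorus
# quotient metric, and dataset-to-model distances.

#' Ordering of present legs along the canonical circuit
#'
#' Legs are numbered starting from the foremost left leg and running
#' counterclockwise in dorsal view (down the left side, across the rear, up
#' the right side) to the foremost right leg; autotomized legs are skipped.
#'
#' @param present Character vector of present leg labels (subset of
#'   [LEG_LABELS], any order).
#' @return An object of class `leg_ordering`: list with `labels` (ordered)
#'   and `n_legs`.
#' @export
leg_ordering <- function(present) {
  present <- unique(as.character(present))
  bad <- setdiff(present, LEG_LABELS)
  if (length(bad))
    stop("unknown leg labels: ", paste(bad, collapse = ", "), call. = FALSE)
  labels <- LEG_LABELS[LEG_LABELS %in% present]
  if (length(labels) < 2L)
    stop("need at least 2 present legs", call. = FALSE)
  structure(list(labels = labels, n_legs = length(labels)),
            class = "leg_ordering")
}

#' Standardize a series to zero mean and unit variance
#'
#' Phases are estimated from standardized position and velocity so that the
#' oscillator amplitude and angular frequency drop out. Standardization is
#' over the whole trial.
#'
#' @param x Numeric vector.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
standardize <- function(x) {
  ok <- is.finite(x)
  s <- stats::sd(x[ok])
  if (!isTRUE(s > 0))
    stop("constant signal: cannot standardize (zero variance)", call. = FALSE)
  (x - mean(x[ok])) / s
}

#' Effective oscillation phase from standardized position and velocity
#'
#' For a harmonic oscillator `y = A*cos(2*pi*f*t)` the phase is
#' `atan2(-v, y)` once position and velocity are standardized to zero mean
#' and unit variance; the same construction gives an effective phase for any
#' noisy oscillatory signal.
#'
#' @param y_std Standardized fore-aft position per frame.
#' @param v_std Standardized fore-aft velocity per frame.
#' @return Phase per frame in `[0, 1)` cycles; frames where both inputs are
#'   zero (or either is `NA`) are `NA`.
#' @export
estimate_phase <- function(y_std, v_std) {
  stopifnot(length(y_std) == length(v_std))
  phi <- wrap_cycle(atan2(-v_std, y_std) / (2 * pi))
  phi[(y_std == 0 & v_std == 0) | is.na(y_std) | is.na(v_std)] <- NA_real_
  phi
}

#' Adjacent-leg phase differences (gait points)
#'
#' The gait at each frame is the vector of `n_legs - 1` phase differences
#' `(phi[i+1] - phi[i]) mod 1` between angularly adjacent legs along the
#' canonical ordering. Adding a common phase to all legs leaves the gait
#' point unchanged, which is what makes the gait space a quotient of the
#' leg-phase torus.
#'
#' @param phases Matrix of per-frame phases (cycles), one column per leg in
#'   the order of `ordering$labels`.
#' @param ordering A [leg_ordering()] matching the columns of `phases`.
#' @return Matrix of gait points, `n_frames` x `(n_legs - 1)`, columns named
#'   `dphi_1 ...`; frames with any undefined phase are all-`NA` rows.
#' @export
phase_differences <- function(phases, ordering) {
  phases <- as.matrix(phases)
  stopifnot(inherits(ordering, "leg_ordering"),
            ncol(phases) == ordering$n_legs)
  n <- ordering$n_legs
  d <- wrap_cycle(phases[, -1L, drop = FALSE] - phases[, -n, drop = FALSE])
  bad <- rowSums(is.na(phases)) > 0L
  d[bad, ] <- NA_real_
  colnames(d) <- paste0("dphi_", seq_len(n - 1L))
  d
}

#' Construct a model gait
#'
#' @param name Gait name (`"ALT"`, `"ABT"`, `"MT"` or a custom label).
#' @param point Numeric vector of `n_legs - 1` phase differences in cycles.
#' @param n_legs Leg count the gait is defined for.
#' @return An object of class `gait_model`.
#' @export
gait_model <- function(name, point, n_legs) {
  point <- wrap_cycle(as.numeric(point))
  if (length(point) != n_legs - 1L)
    stop("`point` must have n_legs - 1 entries", call. = FALSE)
  structure(list(name = as.character(name), point = point,
                 n_legs = as.integer(n_legs)), class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> %s (%d legs): (%s)\n", x$name, x$n_legs,
              paste(format(x$point), collapse = ", ")))
  invisible(x)
}

#' Named model gaits for a leg count
#'
#' Eight legs: the alternating tetrapod (ALT), two diagonal sets of four
#' legs in antiphase, all seven phase differences 0.5. Six legs (after
#' losing L4 and R1): the modified tripod (MT), all five differences 0.5,
#' and the ablated tetrapod (ABT), whose third difference is 0 instead of
#' 0.5 so the surviving tetrapod alternates with the bipod of remaining
#' legs: `(0.5, 0.5, 0, 0.5, 0.5)`.
#'
#' @param n_legs 6 or 8.
#' @param missing Character vector of missing legs; for `n_legs = 6` only
#'   the `{L4, R1}` autotomy pattern has named models.
#' @return Named list of [gait_model()] objects, in canonical order
#'   (ALT, ABT, MT).
#' @export
model_gaits <- function(n_legs, missing = NULL) {
  if (n_legs == 8L && length(missing) == 0L)
    return(list(ALT = gait_model("ALT", rep(0.5, 7), 8L)))
  if (n_legs == 6L && (is.null(missing) || setequal(missing, c("L4", "R1"))))
    return(list(ABT = gait_model("ABT", c(0.5, 0.5, 0, 0.5, 0.5), 6L),
                MT = gait_model("MT", rep(0.5, 5), 6L)))
  stop(sprintf("no named model gaits for %d legs with missing = {%s}",
               n_legs, paste(missing, collapse = ", ")), call. = FALSE)
}

#' The gait-space metric tensor
#'
#' The space of leg phases is a flat `N`-torus with unit weight per leg.
#' Quotienting out the common phase (which does not change the gait) and
#' expressing the result in successive-difference coordinates induces the
#' quadratic form
#' \deqn{g_{ij} = (N - \max(i,j)) - (N-i)(N-j)/N,}
#' a symmetric positive-definite matrix with all entries positive. The
#' maximum distance between two gaits, attained when every coordinate
#' separation is 0.5 cycles, is `d_max = sqrt(0.25 * sum(g))`.
#'
#' @param n_legs Number of legs, at least 2.
#' @return An object of class `gait_metric`: list with `n_legs`, `g`
#'   (`(n_legs-1)` square matrix) and `d_max` (cycles).
#' @export
metric_tensor <- function(n_legs) {
  n_legs <- as.integer(n_legs)
  if (is.na(n_legs) || n_legs < 2L)
    stop("`n_legs` must be at least 2", call. = FALSE)
  i <- seq_len(n_legs - 1L)
  g <- outer(i, i, function(a, b) (n_legs - pmax(a, b)) -
               (n_legs - a) * (n_legs - b) / n_legs)
  structure(list(n_legs = n_legs, g = g, d_max = sqrt(0.25 * sum(g))),
            class = "gait_metric")
}

#' @export
print.gait_metric <- function(x, ...) {
  cat(sprintf("<gait_metric> %d legs, %dx%d tensor, d_max = %.4f cycles\n",
              x$n_legs, nrow(x$g), ncol(x$g), x$d_max))
  invisible(x)
}

# Coerce a gait point argument (gait_model or numeric vector) to a vector.
as_gait_point <- function(x) {
  if (inherits(x, "gait_model")) x$point else wrap_cycle(as.numeric(x))
}

#' Distance between two gaits on the hypertorus
#'
#' Each coordinate difference is wrapped to its minimal signed
#' representative (magnitude at most 0.5 cycles), then contracted with the
#' metric tensor: `d_AB = sqrt(delta' g delta)`. The normalized distance
#' `Delta_AB = d_AB / d_max` lies in `[0, 1]`, with 1 attained when every
#' coordinate is half a cycle apart. For nearby gaits this equals the exact
#' quotient-torus distance (the minimum over a common phase shift of the
#' leg-phase separation); at large separations it is the standard
#' single-chart approximation.
#'
#' @param a,b Gait points: numeric vectors of phase differences in cycles,
#'   or [gait_model()] objects.
#' @param metric A [metric_tensor()] of matching dimension.
#' @return Named numeric vector `c(d = ..., Delta = ...)` (cycles and
#'   normalized).
#' @examples
#' m <- metric_tensor(6)
#' gm <- model_gaits(6)
#' gait_distance(gm$ABT, gm$MT, m)["Delta"]  # 0.29
#' @export
gait_distance <- function(a, b, metric) {
  stopifnot(inherits(metric, "gait_metric"))
  a <- as_gait_point(a); b <- as_gait_point(b)
  k <- nrow(metric$g)
  if (length(a) != k || length(b) != k)
    stop("gait point dimension does not match the metric", call. = FALSE)
  v <- circular_diff_signed(a, b)
  d <- sqrt(max(0, drop(v %*% metric$g %*% v)))
  c(d = d, Delta = d / metric$d_max)
}

#' Normalized distances from a set of gait points to one model gait
#'
#' Vectorized form of [gait_distance()] for a matrix of gait points.
#'
#' @param points Matrix of gait points (rows) in cycles.
#' @param model A [gait_model()] or numeric gait point.
#' @param metric A [metric_tensor()] of matching dimension.
#' @return Numeric vector of normalized distances, `NA` for all-`NA` rows.
#' @export
model_distances <- function(points, model, metric) {
  stopifnot(inherits(metric, "gait_metric"))
  points <- as.matrix(points)
  mu <- as_gait_point(model)
  if (ncol(points) != nrow(metric$g) || length(mu) != nrow(metric$g))
    stop("gait point dimension does not match the metric", call. = FALSE)
  if (nrow(points) == 0L) return(numeric(0))
  v <- circular_diff_signed(points, matrix(mu, nrow(points), length(mu),
                                           byrow = TRUE))
  sqrt(pmax(0, rowSums((v %*% metric$g) * v))) / metric$d_max
}

#' Mean distance from a dataset to a model gait, with bootstrap CI
#'
#' Computes the mean normalized gait distance between every gait point in a
#' dataset and a model gait, with a percentile bootstrap 95% confidence
#' interval over resampled points.
#'
#' @param points Matrix of gait points (rows, cycles); all-`NA` rows are
#'   dropped.
#' @param model A [gait_model()] or numeric gait point.
#' @param metric A [metric_tensor()].
#' @param n_boot Number of bootstrap resamples (default 1000; at least 100).
#' @param seed Optional integer seed for reproducible resampling.
#' @param conf Confidence level (default 0.95).
#' @return List with `mean`, `ci` (length-2 vector), `n`, `n_boot`.
#' @export
dataset_to_model <- function(points, model, metric, n_boot = 1000L,
                             seed = NULL, conf = 0.95) {
  if (n_boot < 100L) stop("`n_boot` must be at least 100", call. = FALSE)
  d <- model_distances(points, model, metric)
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 1L) stop("empty dataset", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  boots <- vapply(seq_len(n_boot),
                  function(i) mean(d[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  alpha <- (1 - conf) / 2
  list(mean = mean(d),
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n = n, n_boot = as.integer(n_boot))
}

#' Gait points for a whole trial
#'
#' Convenience pipeline from a tracked trial to per-frame gait points:
#' transform to the comoving body frame, standardize each present leg's
#' fore-aft tarsus coordinate and its running-quadratic-fit velocity,
#' estimate per-leg phases, and difference adjacent legs along the canonical
#' ordering. Frames with undefined heading (COM too slow) yield `NA` rows.
#'
#' @param trial A [tracked_trial()].
#' @param window_ms Derivative window for tarsal velocities, default 40 ms.
#' @param com_window_ms Derivative window for the COM, default 50 ms.
#' @param min_speed Body-frame validity threshold (mm/s), default 1.
#' @return List with `points` (matrix of gait points), `phases` (matrix of
#'   per-leg phases), `ordering` ([leg_ordering()]) and `body_frame`
#'   (the intermediate `body_frame_trial`).
#' @export
trial_gait_points <- function(trial, window_ms = 40, com_window_ms = 50,
                              min_speed = 1) {
  bft <- to_body_frame(trial, min_speed = min_speed,
                       window_ms = com_window_ms)
  ordering <- leg_ordering(present_legs(trial))
  fr <- trial$frame_rate
  phases <- sapply(ordering$labels, function(leg) {
    y <- bft$tarsi_bf[[leg]][, "y"]
    ok <- is.finite(y)
    # Derivative needs a finite series; compute on valid span, NA elsewhere.
    v <- rep(NA_real_, length(y))
    if (sum(ok) >= 3L) {
      idx <- range(which(ok))
      span <- idx[1]:idx[2]
      if (all(is.finite(y[span])))
        v[span] <- local_quadratic_derivative(y[span], window_ms, fr)
    }
    estimate_phase(standardize(y), standardize(v))
  })
  list(points = phase_differences(phases, ordering), phases = phases,
       ordering = ordering, body_frame = bft)
}
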