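# Reading, writing and validating tracked-landmark trials, smoothed
# derivatives, and the comoving body-frame transform.

#' Canonical leg labels, counterclockwise in dorsal view
#'
#' Ordered from the foremost left leg, down the left side, around the rear
#' and back up the right side to the foremost right leg.
#' @export
LEG_LABELS <- c("L1", "L2", "L3", "L4", "R4", "R3", "R2", "R1")

#' Recognized treatment codes
#'
#' Controls (`C1`, `C2`), cooled control (`CC`), first and second autotomy on
#' the day of (`1AUT0`, `2AUT0`) and the day after (`1AUT1`, `2AUT1`)
#' treatment, plus `OTHER` for anything else (e.g. synthetic trials).
#' @export
TREATMENTS <- c("C1", "CC", "1AUT0", "1AUT1", "C2", "2AUT0", "2AUT1", "OTHER")

#' Construct a tracked trial
#'
#' Container for one dorsal-view recording: body landmarks (center of mass,
#' cranial and caudal points) and up to eight tarsus-tip trajectories, all in
#' mm at a fixed frame rate. Legs absent from `tarsi` are treated as
#' autotomized.
#'
#' @param specimen_id Character scalar identifying the animal.
#' @param treatment One of [TREATMENTS].
#' @param frame_rate Frames per second, `> 0`.
#' @param body_length Body length in mm, `> 0`.
#' @param time Time per frame in seconds, strictly increasing with spacing
#'   `1/frame_rate` (to tolerance).
#' @param com,cranial,caudal Two-column matrices (x, y) in mm, one row per
#'   frame.
#' @param tarsi Named list of two-column matrices, names a subset of
#'   [LEG_LABELS].
#' @return An object of class `tracked_trial`.
#' @export
tracked_trial <- function(specimen_id, treatment, frame_rate, body_length,
                          time, com, cranial, caudal, tarsi) {
  treatment <- match.arg(treatment, TREATMENTS)
  as_xy <- function(m, what) {
    m <- as.matrix(m)
    if (ncol(m) != 2L) stop(sprintf("`%s` must have two columns", what), call. = FALSE)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    m
  }
  com <- as_xy(com, "com"); cranial <- as_xy(cranial, "cranial")
  caudal <- as_xy(caudal, "caudal")
  tarsi <- lapply(tarsi, as_xy, what = "tarsi")
  trial <- structure(
    list(specimen_id = as.character(specimen_id), treatment = treatment,
         frame_rate = as.numeric(frame_rate),
         body_length = as.numeric(body_length),
         time = as.numeric(time), com = com, cranial = cranial,
         caudal = caudal, tarsi = tarsi),
    class = "tracked_trial")
  validate_trial(trial)
}

#' Validate a tracked trial's invariants
#'
#' Checks series lengths, positivity of rates and body length, strict
#' monotonicity and uniform spacing of the time base, leg-label validity and
#' coordinate finiteness. Called by [tracked_trial()] and [read_tracks()].
#'
#' @param trial A `tracked_trial`.
#' @return The trial, invisibly unchanged, or an error.
#' @export
validate_trial <- function(trial) {
  stopifnot(inherits(trial, "tracked_trial"))
  n <- length(trial$time)
  if (n < 2L) stop("trial must have at least 2 frames", call. = FALSE)
  if (!is.finite(trial$frame_rate) || trial$frame_rate <= 0)
    stop("`frame_rate` must be positive", call. = FALSE)
  if (!is.finite(trial$body_length) || trial$body_length <= 0)
    stop("`body_length` must be positive", call. = FALSE)
  dt <- diff(trial$time)
  if (any(dt <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(abs(dt - 1 / trial$frame_rate) > 1e-6 / trial$frame_rate + 1e-9))
    stop("time spacing must equal 1/frame_rate", call. = FALSE)
  for (nm in c("com", "cranial", "caudal")) {
    m <- trial[[nm]]
    if (nrow(m) != n) stop(sprintf("`%s` length differs from time base", nm), call. = FALSE)
    if (!all(is.finite(m))) stop(sprintf("non-finite coordinates in `%s`", nm), call. = FALSE)
  }
  bad <- setdiff(names(trial$tarsi), LEG_LABELS)
  if (length(bad))
    stop("unknown leg labels: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(trial$tarsi)))
    stop("duplicated leg labels", call. = FALSE)
  for (leg in names(trial$tarsi)) {
    m <- trial$tarsi[[leg]]
    if (nrow(m) != n) stop(sprintf("leg %s length differs from time base", leg), call. = FALSE)
    if (!all(is.finite(m)))
      stop(sprintf("non-finite coordinates in leg %s", leg), call. = FALSE)
  }
  invisible(trial)
}

#' Present legs of a trial, in canonical order
#'
#' @param trial A `tracked_trial` or `body_frame_trial`.
#' @return Character vector of leg labels, a subset of [LEG_LABELS] in the
#'   canonical counterclockwise circuit.
#' @export
present_legs <- function(trial) {
  if (inherits(trial, "body_frame_trial")) trial <- trial$source
  LEG_LABELS[LEG_LABELS %in% names(trial$tarsi)]
}

#' @export
print.tracked_trial <- function(x, ...) {
  cat(sprintf("<tracked_trial> specimen %s, treatment %s\n", x$specimen_id, x$treatment))
  cat(sprintf("  %d frames @ %g Hz (%.3f s), body length %g mm\n",
              length(x$time), x$frame_rate, diff(range(x$time)), x$body_length))
  legs <- present_legs(x)
  cat(sprintf("  legs present (%d): %s\n", length(legs), paste(legs, collapse = " ")))
  absent <- setdiff(LEG_LABELS, legs)
  if (length(absent)) cat("  absent:", paste(absent, collapse = " "), "\n")
  invisible(x)
}

# Default column map of the tracks CSV dialect; a schema overrides entries.
default_schema <- function() {
  base <- c(frame = "frame", time = "time",
            com_x = "com_x", com_y = "com_y",
            cranial_x = "cranial_x", cranial_y = "cranial_y",
            caudal_x = "caudal_x", caudal_y = "caudal_y")
  legs <- as.vector(rbind(paste0(LEG_LABELS, "_x"), paste0(LEG_LABELS, "_y")))
  names(legs) <- legs
  c(base, legs)
}

# Locate the metadata sidecar (same stem, .json/.yaml/.yml extension).
sidecar_path <- function(path) {
  stem <- sub("\\.[^.]*$", "", path)
  for (ext in c(".json", ".yaml", ".yml")) {
    p <- paste0(stem, ext)
    if (file.exists(p)) return(p)
  }
  NULL
}

# Fill interior runs of NA of length <= max_gap by linear interpolation.
# Returns NULL if a longer gap (or a leading/trailing gap beyond max_gap)
# remains, letting the caller raise a leg-specific error.
fill_gaps <- function(x, max_gap) {
  if (!anyNA(x)) return(list(x = x, filled = 0L))
  r <- rle(is.na(x))
  if (any(r$values & r$lengths > max_gap)) return(NULL)
  idx <- which(!is.na(x))
  if (length(idx) < 2L) return(NULL)
  filled <- sum(is.na(x))
  x <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  list(x = x, filled = filled)
}

#' Read a tracked trial from a tracks CSV
#'
#' The canonical on-disk dialect is a CSV with header
#' `frame,time,com_x,com_y,cranial_x,cranial_y,caudal_x,caudal_y` followed by
#' `<LEG>_x,<LEG>_y` pairs for tracked legs. Empty cells are missing samples;
#' whole absent (or all-empty) leg column pairs mark autotomized legs. Trial
#' metadata (specimen id, treatment, frame rate, body length) comes from a
#' JSON/YAML sidecar with the same stem, or the `metadata` argument.
#'
#' Short interior tracking gaps (at most `max_gap` frames) are linearly
#' interpolated with a warning; longer gaps in a present leg are a
#' validation error.
#'
#' @param path Path to the tracks CSV.
#' @param schema Optional named character vector remapping canonical column
#'   names (names) to the file's column names (values), to absorb
#'   tracker-export variants.
#' @param metadata Optional named list overriding the sidecar (fields
#'   `specimen_id`, `treatment`, `frame_rate`, `body_length`,
#'   optionally `px_per_mm`).
#' @param max_gap Longest interior `NA` run, in frames, repaired by linear
#'   interpolation (default 3).
#' @return A validated [tracked_trial()].
#' @seealso [write_tracks()]
#' @export
read_tracks <- function(path, schema = NULL, metadata = NULL, max_gap = 3L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- default_schema()
  if (!is.null(schema)) {
    schema <- unlist(schema)
    unknown <- setdiff(names(schema), names(map))
    if (length(unknown))
      stop("schema remaps unknown canonical columns: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    map[names(schema)] <- schema
  }
  df <- utils::read.csv(path, check.names = FALSE)

  meta <- list()
  sc <- sidecar_path(path)
  if (!is.null(sc)) {
    meta <- if (grepl("\\.json$", sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
            else yaml::read_yaml(sc)
  }
  if (!is.null(metadata)) meta[names(metadata)] <- metadata
  for (fld in c("specimen_id", "treatment", "frame_rate", "body_length"))
    if (is.null(meta[[fld]]))
      stop("missing trial metadata field `", fld,
           "` (no sidecar and no `metadata` entry)", call. = FALSE)

  need <- c("time", "com_x", "com_y", "cranial_x", "cranial_y",
            "caudal_x", "caudal_y")
  missing_cols <- need[!(map[need] %in% names(df))]
  if (length(missing_cols))
    stop("missing mandatory columns: ",
         paste(map[missing_cols], collapse = ", "), call. = FALSE)

  scale <- 1
  if (!is.null(meta$px_per_mm)) scale <- 1 / as.numeric(meta$px_per_mm)
  col <- function(canon) as.numeric(df[[map[canon]]]) * scale
  time <- as.numeric(df[[map["time"]]])
  if (length(time) < 2L || any(diff(time) <= 0))
    stop("time column must be strictly increasing", call. = FALSE)

  grab_xy <- function(prefix) cbind(x = col(paste0(prefix, "_x")),
                                    y = col(paste0(prefix, "_y")))
  tarsi <- list()
  for (leg in LEG_LABELS) {
    cx <- map[paste0(leg, "_x")]; cy <- map[paste0(leg, "_y")]
    if (!(cx %in% names(df)) || !(cy %in% names(df))) next
    m <- cbind(x = as.numeric(df[[cx]]) * scale,
               y = as.numeric(df[[cy]]) * scale)
    if (all(is.na(m))) next  # all-empty columns: autotomized
    total_filled <- 0L
    for (j in 1:2) {
      res <- fill_gaps(m[, j], max_gap)
      if (is.null(res))
        stop(sprintf("leg %s has a tracking gap longer than %d frames",
                     leg, max_gap), call. = FALSE)
      m[, j] <- res$x
      total_filled <- total_filled + res$filled
    }
    if (total_filled > 0L)
      warning(sprintf("leg %s: interpolated %d missing coordinate samples",
                      leg, total_filled), call. = FALSE)
    tarsi[[leg]] <- m
  }
  if (length(tarsi) == 0L)
    stop("no tarsus columns present in file", call. = FALSE)

  tracked_trial(specimen_id = meta$specimen_id, treatment = meta$treatment,
                frame_rate = meta$frame_rate, body_length = meta$body_length,
                time = time, com = grab_xy("com"),
                cranial = grab_xy("cranial"), caudal = grab_xy("caudal"),
                tarsi = tarsi)
}

#' Write a tracked trial to a tracks CSV plus JSON sidecar
#'
#' Inverse of [read_tracks()]: coordinates are written with six decimals, and
#' the trial metadata goes to `<stem>.json`. `write_tracks` followed by
#' `read_tracks` is the identity on valid trials (to the printed precision).
#'
#' @param trial A `tracked_trial`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trial, path) {
  validate_trial(trial)
  n <- length(trial$time)
  df <- data.frame(frame = seq_len(n) - 1L, time = trial$time,
                   check.names = FALSE)
  put_xy <- function(df, prefix, m) {
    df[[paste0(prefix, "_x")]] <- round(m[, 1], 6)
    df[[paste0(prefix, "_y")]] <- round(m[, 2], 6)
    df
  }
  df <- put_xy(df, "com", trial$com)
  df <- put_xy(df, "cranial", trial$cranial)
  df <- put_xy(df, "caudal", trial$caudal)
  for (leg in present_legs(trial)) df <- put_xy(df, leg, trial$tarsi[[leg]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(specimen_id = trial$specimen_id, treatment = trial$treatment,
               frame_rate = trial$frame_rate, body_length = trial$body_length)
  jsonlite::write_json(meta, paste0(sub("\\.[^.]*$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-frame derivative by running quadratic fit
#'
#' Slope of a least-squares quadratic fitted over a centered window of
#' `window_ms` milliseconds around each frame, the standard smoothing
#' derivative for tracked kinematics (50 ms windows for the center of mass,
#' 40 ms for tarsi). Edge frames use truncated one-sided windows (degree
#' reduced when fewer than three samples remain) so the output stays aligned
#' with the input.
#'
#' Exact for polynomials of degree up to 2 on interior frames.
#'
#' @param series Numeric vector, one value per frame; must be finite.
#' @param window_ms Window length in milliseconds; must span at least
#'   3 frames at `frame_rate`.
#' @param frame_rate Frames per second.
#' @return Numeric vector of per-frame derivatives (units of `series` per
#'   second).
#' @export
local_quadratic_derivative <- function(series, window_ms, frame_rate) {
  stopifnot(is.numeric(series), frame_rate > 0)
  if (!all(is.finite(series))) stop("`series` must be finite", call. = FALSE)
  n <- length(series)
  dt <- 1 / frame_rate
  h <- floor((window_ms / 1000) * frame_rate / 2)
  if (2L * h + 1L < 3L)
    stop("window spans fewer than 3 frames", call. = FALSE)
  # Interior: on a symmetric window the quadratic's linear coefficient is the
  # classic Savitzky-Golay first-derivative filter sum(j * y_j) / sum(j^2).
  j <- seq(-h, h)
  w <- j / (sum(j^2) * dt)
  out <- rep(NA_real_, n)
  if (n >= 2L * h + 1L) {
    sm <- stats::filter(series, rev(w), sides = 2)
    out <- as.numeric(sm)
  }
  # Edges (and short series): truncated window, explicit polynomial fit.
  edge <- which(is.na(out))
  for (i in edge) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    idx <- lo:hi
    tt <- (idx - i) * dt
    deg <- min(2L, length(idx) - 1L)
    X <- cbind(1, tt, tt^2)[, seq_len(deg + 1L), drop = FALSE]
    fit <- stats::lm.fit(X, series[idx])
    out[i] <- fit$coefficients[2L]
  }
  out
}

#' Transform a trial to the comoving body frame
#'
#' Each frame is translated so the center of mass (COM) is at the origin and
#' rotated so the instantaneous COM velocity points along +y. Frames where
#' the COM speed falls below `min_speed` have no defined heading and are
#' flagged invalid (their body-frame coordinates are `NA`).
#'
#' The per-frame transform is a rigid motion: pairwise distances among
#' landmarks are preserved.
#'
#' @param trial A `tracked_trial`.
#' @param com_velocity Optional n x 2 matrix of COM velocity (mm/s); computed
#'   with [local_quadratic_derivative()] over `window_ms` when `NULL`.
#' @param min_speed Speed threshold (mm/s) below which frame orientation is
#'   undefined; default 1.
#' @param window_ms Derivative window for the COM, default 50 ms.
#' @return An object of class `body_frame_trial`: list with `source`,
#'   `tarsi_bf` (named list of n x 2 matrices), `com_velocity`, `speed` and
#'   logical `valid` per frame.
#' @export
to_body_frame <- function(trial, com_velocity = NULL, min_speed = 1,
                          window_ms = 50) {
  validate_trial(trial)
  if (is.null(com_velocity)) {
    com_velocity <- cbind(
      local_quadratic_derivative(trial$com[, 1], window_ms, trial$frame_rate),
      local_quadratic_derivative(trial$com[, 2], window_ms, trial$frame_rate))
  }
  com_velocity <- as.matrix(com_velocity)
  stopifnot(nrow(com_velocity) == length(trial$time), ncol(com_velocity) == 2L)
  speed <- sqrt(rowSums(com_velocity^2))
  valid <- speed >= min_speed
  if (!any(valid))
    stop("degenerate trial: COM speed below `min_speed` in every frame",
         call. = FALSE)
  ux <- com_velocity[, 1] / speed
  uy <- com_velocity[, 2] / speed
  ux[!valid] <- NA_real_; uy[!valid] <- NA_real_
  # Rotation taking the unit heading (ux, uy) to (0, 1):
  #   x_bf =  uy*dx - ux*dy ;  y_bf = ux*dx + uy*dy
  tarsi_bf <- lapply(trial$tarsi, function(m) {
    dx <- m[, 1] - trial$com[, 1]
    dy <- m[, 2] - trial$com[, 2]
    cbind(x = uy * dx - ux * dy, y = ux * dx + uy * dy)
  })
  structure(list(source = trial, tarsi_bf = tarsi_bf,
                 com_velocity = com_velocity, speed = speed, valid = valid),
            class = "body_frame_trial")
}

#' @export
print.body_frame_trial <- function(x, ...) {
  cat(sprintf("<body_frame_trial> %d frames (%d valid), %d legs\n",
              length(x$valid), sum(x$valid), length(x$tarsi_bf)))
  invisible(x)
}
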