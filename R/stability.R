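# Static-stability and posture measures: support polygon, stability
# margins, adjacent-leg spacing, tarsal range of motion, leg extension.

# Shoelace signed area of a polygon (rows = vertices, in order).
polygon_area <- function(v) {
  if (is.null(v) || nrow(v) < 3L) return(0)
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

# Area centroid of a polygon; falls back to the vertex mean when the area
# is numerically zero (degenerate hull).
polygon_centroid <- function(v) {
  a <- polygon_area(v)
  if (abs(a) < 1e-12) return(colMeans(v))
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1L)
  cr <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Distance from point p to segment a-b.
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}

# Even-odd ray-casting point-in-polygon test (boundary counts as inside).
point_in_polygon <- function(p, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # on-edge check
    if (point_segment_distance(p, c(xi, yi), c(xj, yj)) < 1e-12) return(TRUE)
    if ((yi > p[2]) != (yj > p[2])) {
      xcross <- xi + (p[2] - yi) / (yj - yi) * (xj - xi)
      if (p[1] < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Support polygon of the tarsi in stance
#'
#' The support polygon is the convex hull of the xy coordinates of all tarsi
#' in stance; `n_support` is the number of stance tarsi (hull interior
#' points included). The hull is degenerate when fewer than three distinct,
#' non-collinear stance positions exist.
#'
#' @param stance_positions Matrix (k x 2) of stance tarsus positions in mm;
#'   may have zero rows.
#' @return An object of class `support_polygon`: list with `vertices`
#'   (hull vertices, counterclockwise; `NULL` when empty), `n_support`,
#'   `area` (mm^2) and logical `degenerate`.
#' @export
support_polygon <- function(stance_positions) {
  m <- as.matrix(stance_positions)
  if (length(m) == 0L || nrow(m) == 0L)
    return(structure(list(vertices = NULL, n_support = 0L, area = 0,
                          degenerate = TRUE), class = "support_polygon"))
  if (ncol(m) != 2L) stop("stance positions must be k x 2", call. = FALSE)
  n_support <- nrow(m)
  u <- unique(round(m, 12))
  if (nrow(u) < 3L) {
    return(structure(list(vertices = u, n_support = n_support, area = 0,
                          degenerate = TRUE), class = "support_polygon"))
  }
  idx <- grDevices::chull(u)      # clockwise order
  v <- u[rev(idx), , drop = FALSE]  # counterclockwise
  a <- polygon_area(v)
  structure(list(vertices = v, n_support = n_support, area = abs(a),
                 degenerate = nrow(v) < 3L || abs(a) < 1e-12),
            class = "support_polygon")
}

#' Static stability margins of a support polygon
#'
#' The static stability margin (SSM) is the minimum distance from the
#' projection of the COM to the support polygon's edges: positive when the
#' COM lies inside the polygon, zero on its boundary (metastable
#' equilibrium), and the negated distance to the hull when the COM is
#' outside or the hull is degenerate (fewer than three supports cannot be
#' statically stable). The ideal margin (ISSM) is the same quantity with
#' the COM placed at the polygon's area centroid, the value attained when
#' the posture is ideally balanced.
#'
#' @param polygon A [support_polygon()].
#' @param com Length-2 numeric, COM projection (mm).
#' @return Named numeric vector `c(ssm = ..., issm = ...)`, mm.
#' @export
stability_margins <- function(polygon, com) {
  stopifnot(inherits(polygon, "support_polygon"))
  com <- as.numeric(com)
  v <- polygon$vertices
  if (is.null(v) || nrow(v) == 0L)
    return(c(ssm = NA_real_, issm = NA_real_))
  margin <- function(p) {
    if (nrow(v) == 1L) return(-sqrt(sum((p - v[1, ])^2)))
    j <- c(2:nrow(v), 1L)
    d <- vapply(seq_len(nrow(v)), function(i)
      point_segment_distance(p, v[i, ], v[j[i], ]), numeric(1))
    dmin <- min(d)
    if (polygon$degenerate) return(-dmin)
    if (point_in_polygon(p, v)) dmin else -dmin
  }
  c(ssm = margin(com), issm = margin(polygon_centroid(v)))
}

#' Angles between adjacent legs about the COM
#'
#' Given mean body-frame leg directions, returns the angular gaps between
#' angularly adjacent legs (summing to 360 degrees) together with the
#' uniform-spacing expectation `360 / n_legs`: 45 degrees for eight legs,
#' 60 degrees for six.
#'
#' @param directions Named numeric vector of mean leg directions in degrees
#'   (any origin/convention, measured about the COM).
#' @return List with `angles` (named by leg pair, degrees, in increasing
#'   direction order), `expected` (degrees) and `mean` (equal to `expected`
#'   by construction).
#' @export
leg_spacing <- function(directions) {
  n <- length(directions)
  if (n < 2L) stop("need at least 2 present legs", call. = FALSE)
  d <- directions %% 360
  if (anyDuplicated(round(d, 9)))
    warning("coincident leg directions: spacing is degenerate", call. = FALSE)
  ord <- order(d)
  d <- d[ord]
  gaps <- diff(c(d, d[1] + 360))
  names(gaps) <- paste(names(d), names(d)[c(2:n, 1L)], sep = "-")
  list(angles = gaps, expected = 360 / n, mean = mean(gaps))
}

#' Tarsal range-of-motion area with MAD outlier removal
#'
#' Removes outlying points before measuring the swept area: a point is an
#' outlier when its radial distance from the coordinate-wise 2-D median
#' exceeds the median of those distances by more than `mad_factor` times
#' their median absolute deviation (MAD, consistency constant 1.4826). The
#' area is the convex hull area of the survivors.
#'
#' @param points Matrix (n x 2) of body-frame tarsus positions, mm.
#' @param mad_factor Outlier cutoff in MAD units, default 3.
#' @return List with `area` (mm^2; `NA` when fewer than 3 points survive),
#'   `kept` (logical per point) and logical `degenerate`.
#' @export
range_of_motion <- function(points, mad_factor = 3) {
  m <- as.matrix(points)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0L)
    return(list(area = NA_real_, kept = logical(0), degenerate = TRUE))
  med <- apply(m, 2, stats::median)
  r <- sqrt(colSums((t(m) - med)^2))
  s <- stats::mad(r)
  kept <- if (s == 0) rep(TRUE, nrow(m))
          else r <= stats::median(r) + mad_factor * s
  mm <- m[kept, , drop = FALSE]
  if (nrow(mm) < 3L)
    return(list(area = NA_real_, kept = kept, degenerate = TRUE))
  hull <- support_polygon(mm)
  list(area = hull$area, kept = kept, degenerate = hull$degenerate)
}

#' Fore-aft and lateral leg extension
#'
#' Distances between each tarsus and the COM along the body axes: in the
#' comoving body frame the COM is the origin, so the fore-aft extension is
#' `|y|` and the lateral extension `|x|`, averaged over valid frames.
#'
#' @param bft A `body_frame_trial` from [to_body_frame()].
#' @return Data frame with one row per present leg: `leg`, `lateral` (mm),
#'   `fore_aft` (mm).
#' @export
leg_extension <- function(bft) {
  stopifnot(inherits(bft, "body_frame_trial"))
  legs <- names(bft$tarsi_bf)
  out <- data.frame(
    leg = legs,
    lateral = vapply(legs, function(l)
      mean(abs(bft$tarsi_bf[[l]][, "x"]), na.rm = TRUE), numeric(1)),
    fore_aft = vapply(legs, function(l)
      mean(abs(bft$tarsi_bf[[l]][, "y"]), na.rm = TRUE), numeric(1)),
    row.names = NULL)
  out
}

#' Per-frame stability trace of a trial
#'
#' For every frame, builds the support polygon from the lab-frame positions
#' of the tarsi in stance and evaluates the static stability margins with
#' respect to the COM projection.
#'
#' @param trial A [tracked_trial()].
#' @param stance A `stance_mask` from [stance_swing()] (its `mask` columns
#'   must be legs of the trial).
#' @return An object of class `stability_trace`: data frame with `frame`,
#'   `time`, `n_support`, `ssm`, `issm`.
#' @export
stability_trace <- function(trial, stance) {
  validate_trial(trial)
  stopifnot(inherits(stance, "stance_mask"))
  mask <- stance$mask
  n <- length(trial$time)
  stopifnot(nrow(mask) == n)
  legs <- colnames(mask)
  ssm <- issm <- rep(NA_real_, n)
  nsup <- integer(n)
  for (i in seq_len(n)) {
    on <- legs[mask[i, ]]
    nsup[i] <- length(on)
    if (length(on) == 0L) next
    pts <- t(vapply(on, function(l) trial$tarsi[[l]][i, ], numeric(2)))
    poly <- support_polygon(pts)
    m <- stability_margins(poly, trial$com[i, ])
    ssm[i] <- m["ssm"]; issm[i] <- m["issm"]
  }
  structure(data.frame(frame = seq_len(n), time = trial$time,
                       n_support = nsup, ssm = ssm, issm = issm),
            class = c("stability_trace", "data.frame"))
}

#' Posture summary of a trial
#'
#' Mean body-frame direction of each leg (circular mean of per-frame tarsus
#' bearings about the COM), adjacent-leg spacing, per-leg range-of-motion
#' hull area after MAD outlier removal, and fore-aft/lateral leg extension.
#'
#' @param bft A `body_frame_trial` from [to_body_frame()].
#' @param mad_factor Outlier cutoff for [range_of_motion()], default 3.
#' @return List with `directions` (degrees per leg), `spacing`
#'   ([leg_spacing()] result), `rom_area` (mm^2 per leg) and `extension`
#'   ([leg_extension()] data frame).
#' @export
posture_summary <- function(bft, mad_factor = 3) {
  stopifnot(inherits(bft, "body_frame_trial"))
  legs <- names(bft$tarsi_bf)
  dirs <- vapply(legs, function(l) {
    m <- bft$tarsi_bf[[l]]
    br <- atan2(m[, "y"], m[, "x"]) / (2 * pi)  # bearings in cycles
    360 * circular_mean(br)
  }, numeric(1))
  rom <- vapply(legs, function(l)
    range_of_motion(bft$tarsi_bf[[l]], mad_factor)$area, numeric(1))
  list(directions = dirs, spacing = leg_spacing(dirs), rom_area = rom,
       extension = leg_extension(bft))
}
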