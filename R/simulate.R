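# Synthetic-data generation: von Mises-perturbed gait points, concentration
# fitting, ideal footfall patterns, and full synthetic tracked trials.

# Run `expr` under a temporary RNG state seeded with `seed` (when not NULL),
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample noisy gait points around a model gait
#'
#' Draws `n` gait points whose coordinates are independent von Mises
#' deviates centered on the model's phase differences (mean direction
#' `2*pi*mu_i`, concentration `kappa`), mapped back to cycles. `kappa = 0`
#' gives uniform phases; large `kappa` concentrates tightly on the model.
#'
#' @param model A [gait_model()] or numeric gait point (cycles).
#' @param kappa von Mises concentration, `>= 0`.
#' @param n Number of samples, `>= 1`.
#' @param seed Optional integer seed.
#' @return Matrix `n x (n_legs - 1)` of gait points in `[0, 1)` cycles.
#' @export
sample_gait_points <- function(model, kappa, n, seed = NULL) {
  mu <- as_gait_point(model)
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  with_seed(seed, {
    X <- vapply(mu, function(m)
      rvonmises(n, 2 * pi * m, kappa) / (2 * pi), numeric(n))
    X <- matrix(X, nrow = n)
    colnames(X) <- paste0("dphi_", seq_along(mu))
    wrap_cycle(X)
  })
}

#' Maximum-likelihood von Mises concentration
#'
#' Estimates `kappa` by inverting the resultant-length equation
#' `A(kappa) = I1(kappa)/I0(kappa) = Rbar` using the standard rational
#' approximation (Banerjee et al. style) refined by Newton steps on the
#' exact Bessel ratio. For a matrix of gait points the fit is per
#' dimension, after centering each at its circular mean, and the mean
#' estimate is returned (with per-dimension values as an attribute).
#'
#' @param samples Numeric vector of circular values in cycles, or a matrix
#'   of gait points (columns = dimensions).
#' @return Estimated concentration `kappa`. `Inf` (with a warning) when all
#'   samples coincide; near 0 for uniform samples. Matrix input returns the
#'   mean across dimensions with attribute `per_dimension`.
#' @export
fit_kappa <- function(samples) {
  if (is.matrix(samples)) {
    ks <- apply(samples, 2, fit_kappa)
    return(structure(mean(ks), per_dimension = ks))
  }
  x <- samples[!is.na(samples)]
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  R <- resultant_length(x)
  if (R >= 1 - 1e-12) {
    warning("all samples identical: infinite concentration", call. = FALSE)
    return(Inf)
  }
  # rational approximation to A^{-1}(R)
  k <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
       else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
       else 1 / (R^3 - 4 * R^2 + 3 * R)
  # Newton refinement on A(k) - R = 0; A'(k) = 1 - A/k - A^2
  for (it in 1:5) {
    A <- bessel_ratio(k)
    dA <- 1 - A / k - A^2
    step <- (A - R) / dA
    k <- max(k - step, 0)
    if (abs(step) < 1e-10) break
  }
  k
}

#' Ideal footfall pattern of a model gait
#'
#' Generates the stance/swing timing of an ideal gait: leg `k` is in stance
#' while `(t * f + phi_k) mod 1 < duty`, where the `phi_k` are the
#' cumulative leg phases implied by the gait's phase differences (first leg
#' at phase 0). At duty factor 0.5 the alternating tetrapod keeps 4 of 8
#' tarsi in stance at every instant, the modified tripod 3 of 6, and the
#' ablated tetrapod alternates between a 2-leg bipod and a 4-leg tetrapod
#' half the time each.
#'
#' @param model A [gait_model()] or numeric gait point (cycles).
#' @param duty Duty factor in (0, 1), default 0.5.
#' @param n_strides Number of strides, default 10.
#' @param samples_per_stride Time samples per stride, default 1000.
#' @return List with `stance` (logical samples x legs matrix), `n_support`
#'   (integer per sample), `t` (time in stride units) and `leg_phases`.
#' @export
footfall_pattern <- function(model, duty = 0.5, n_strides = 10L,
                             samples_per_stride = 1000L) {
  if (!(duty > 0 && duty < 1)) stop("`duty` must be in (0, 1)", call. = FALSE)
  dphi <- as_gait_point(model)
  phi <- wrap_cycle(cumsum(c(0, dphi)))
  ns <- as.integer(n_strides) * as.integer(samples_per_stride)
  t <- (seq_len(ns) - 1L) / samples_per_stride
  stance <- outer(t, phi, function(tt, p) ((tt + p) %% 1) < duty)
  colnames(stance) <- paste0("leg_", seq_along(phi))
  list(stance = stance, n_support = as.integer(rowSums(stance)), t = t,
       leg_phases = phi)
}

# Piecewise-linear fore-aft waveform: linear retraction from +A/2 to -A/2
# over the stance fraction of the cycle, linear protraction back over the
# swing fraction. Makes stance/swing ground truth exact.
sawtooth_wave <- function(phase, amplitude, duty) {
  p <- wrap_cycle(phase)
  ifelse(p < duty,
         amplitude * (0.5 - p / duty),
         amplitude * (-0.5 + (p - duty) / (1 - duty)))
}

# Body-frame anchor points (mm) for the present legs: lateral offset by
# side, fore-aft stations spread along the body.
leg_anchors <- function(body_length, legs) {
  row <- as.integer(substr(legs, 2, 2))        # 1..4 from front
  side <- ifelse(substr(legs, 1, 1) == "L", -1, 1)
  cbind(x = side * 0.35 * body_length,
        y = body_length * c(0.35, 0.12, -0.12, -0.35)[row])
}

#' Generate a synthetic tracked trial
#'
#' Emulates a straight constant-speed run: the COM advances along +y at
#' `speed`; each present leg's tarsus oscillates fore-aft about a
#' leg-specific anchor with the model gait's phase offsets and a
#' duty-factor-asymmetric sawtooth waveform (linear retraction during
#' stance, faster linear protraction during swing). With the default
#' amplitude (`speed * duty / stride_freq`) the tarsus is exactly
#' stationary in the lab frame during stance, so stance/swing ground truth
#' is exact. Optional per-stride von Mises phase jitter and Gaussian
#' tracking noise emulate measurement conditions.
#'
#' @param gait A [gait_model()] (e.g. from [model_gaits()]).
#' @param n_strides Number of strides, default 8.
#' @param stride_freq Stride frequency in Hz, default 6.
#' @param duty Duty factor in (0, 1), default 0.5.
#' @param speed COM speed in mm/s, default 120.
#' @param body_length Body length in mm, default 12.
#' @param frame_rate Frames per second, default 500.
#' @param amplitude Fore-aft tarsus amplitude in mm; default
#'   `speed * duty / stride_freq` (ground-stationary stance).
#' @param tracking_noise_sd Gaussian coordinate noise s.d. in mm, default 0.
#' @param phase_kappa von Mises concentration of per-stride leg phase
#'   jitter; `Inf` (default) disables jitter.
#' @param missing Character vector of absent legs; defaults to the legs
#'   implied by the gait's leg count (none for 8; `L4`, `R1` for 6).
#' @param specimen_id,treatment Metadata for the emitted trial.
#' @param seed Optional integer seed.
#' @return A validated [tracked_trial()].
#' @export
synth_trial <- function(gait, n_strides = 8L, stride_freq = 6, duty = 0.5,
                        speed = 120, body_length = 12, frame_rate = 500,
                        amplitude = NULL, tracking_noise_sd = 0,
                        phase_kappa = Inf, missing = NULL,
                        specimen_id = "synthetic", treatment = "OTHER",
                        seed = NULL) {
  stopifnot(inherits(gait, "gait_model"))
  if (!(duty > 0 && duty < 1)) stop("`duty` must be in (0, 1)", call. = FALSE)
  if (stride_freq <= 0 || speed <= 0 || frame_rate <= 0 || body_length <= 0)
    stop("rates, speed and body length must be positive", call. = FALSE)
  if (tracking_noise_sd < 0) stop("`tracking_noise_sd` must be >= 0", call. = FALSE)
  if (is.null(missing)) {
    missing <- if (gait$n_legs == 8L) character(0)
               else if (gait$n_legs == 6L) c("L4", "R1")
               else stop("specify `missing` for leg counts other than 6 or 8",
                         call. = FALSE)
  }
  legs <- LEG_LABELS[!(LEG_LABELS %in% missing)]
  if (length(legs) != gait$n_legs)
    stop("`missing` inconsistent with the gait's leg count", call. = FALSE)
  if (is.null(amplitude)) amplitude <- speed * duty / stride_freq

  n <- round(n_strides / stride_freq * frame_rate)
  tt <- (seq_len(n) - 1L) / frame_rate
  phi <- wrap_cycle(cumsum(c(0, gait$point)))  # leg phases, first leg 0
  names(phi) <- legs
  anchors <- leg_anchors(body_length, legs)

  with_seed(seed, {
    com <- cbind(x = rep(0, n), y = speed * tt)
    cranial <- com + cbind(0, rep(body_length / 2, n))
    caudal <- com - cbind(0, rep(body_length / 2, n))
    stride_idx <- floor(tt * stride_freq)
    tarsi <- list()
    for (j in seq_along(legs)) {
      jitter <- if (is.finite(phase_kappa)) {
        eps <- rvonmises(max(stride_idx) + 1L, 0, phase_kappa) / (2 * pi)
        circular_diff_signed(eps, 0)[stride_idx + 1L]
      } else 0
      ph <- tt * stride_freq + phi[j] + jitter
      tarsi[[legs[j]]] <- cbind(
        x = anchors[j, "x"] + com[, "x"],
        y = anchors[j, "y"] + com[, "y"] + sawtooth_wave(ph, amplitude, duty))
    }
    if (tracking_noise_sd > 0) {
      noisy <- function(m) m + matrix(stats::rnorm(length(m), 0, tracking_noise_sd),
                                      nrow(m))
      com <- noisy(com); cranial <- noisy(cranial); caudal <- noisy(caudal)
      tarsi <- lapply(tarsi, noisy)
    }
    tracked_trial(specimen_id = specimen_id, treatment = treatment,
                  frame_rate = frame_rate, body_length = body_length,
                  time = tt, com = com, cranial = cranial, caudal = caudal,
                  tarsi = tarsi)
  })
}
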