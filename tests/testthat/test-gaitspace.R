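test_that("standardization centers, scales and rejects constant signals", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_equal(standardize(z), z)  # idempotent on standardized input
  expect_error(standardize(rep(2, 10)), "constant signal")
})

test_that("phase estimation recovers the analytic phase of a harmonic signal", {
  fr <- 500; f <- 6
  tt <- (0:999) / fr  # integer number of cycles
  y <- cos(2 * pi * f * tt)
  v <- -2 * pi * f * sin(2 * pi * f * tt)
  phi <- estimate_phase(standardize(y), standardize(v))
  expect_lt(max(circular_delta(phi, wrap_cycle(f * tt))), 1e-6)
  # shifting the signal by a quarter period shifts the phase by 0.25 cycles
  sh <- 0.25 / f
  y2 <- cos(2 * pi * f * (tt - sh))
  v2 <- -2 * pi * f * sin(2 * pi * f * (tt - sh))
  phi2 <- estimate_phase(standardize(y2), standardize(v2))
  expect_lt(max(circular_delta(phi2, wrap_cycle(phi - 0.25))), 1e-6)
  # degenerate frame flagged
  expect_true(is.na(estimate_phase(c(0, 1), c(0, 0))[1]))
})

test_that("phase estimation is robust to additive Gaussian noise", {
  set.seed(314)
  fr <- 500; f <- 6
  tt <- (0:4999) / fr
  snr_amp <- 10  # amplitude signal-to-noise ratio
  y <- cos(2 * pi * f * tt) + stats::rnorm(5000, 0, 1 / snr_amp)
  v <- -sin(2 * pi * f * tt) + stats::rnorm(5000, 0, 1 / snr_amp)
  phi <- estimate_phase(standardize(y), standardize(v))
  rms_err <- sqrt(mean(circular_delta(phi, wrap_cycle(f * tt))^2))
  expect_lt(rms_err, 0.03)
})

test_that("phase differences follow the canonical ordering and ignore common phase", {
  ord <- leg_ordering(LEG_LABELS)
  expect_identical(ord$labels, LEG_LABELS)
  expect_equal(ord$n_legs, 8)
  # autotomy ordering skips missing legs but keeps the circuit
  ord6 <- leg_ordering(sample(setdiff(LEG_LABELS, c("L4", "R1"))))
  expect_identical(ord6$labels, c("L1", "L2", "L3", "R4", "R3", "R2"))

  ph_same <- matrix(0.3, 5, 8)
  expect_true(all(phase_differences(ph_same, ord) == 0))
  alt <- matrix(rep(c(0, 0.5), length.out = 8), 5, 8, byrow = TRUE)
  expect_true(all(phase_differences(alt, ord) == 0.5))
  ph <- matrix(stats::runif(40), 5, 8)
  expect_equal(phase_differences(wrap_cycle(ph + 0.37), ord),
               phase_differences(ph, ord), tolerance = 1e-9)
  # undefined phases propagate as missing gait points
  ph[2, 4] <- NA
  expect_true(all(is.na(phase_differences(ph, ord)[2, ])))
})

test_that("model gaits match their leg counts", {
  m8 <- model_gaits(8)
  expect_named(m8, "ALT")
  expect_equal(m8$ALT$point, rep(0.5, 7))
  m6 <- model_gaits(6)
  expect_named(m6, c("ABT", "MT"))
  expect_equal(m6$ABT$point, c(0.5, 0.5, 0, 0.5, 0.5))
  expect_equal(m6$MT$point, rep(0.5, 5))
  expect_error(model_gaits(7), "no named model")
  expect_error(model_gaits(6, missing = c("L1", "L2")), "no named model")
})

test_that("circular delta wraps to the shorter arc", {
  expect_equal(circular_delta(0.9, 0.1), 0.2)
  expect_equal(circular_delta(0.25, 0.75), 0.5)
  x <- stats::runif(20)
  expect_equal(circular_delta(x, x), rep(0, 20))
  expect_equal(circular_delta(x, x + 1), rep(0, 20), tolerance = 1e-9)
})

test_that("the metric tensor matches its closed form and is positive definite", {
  m6 <- metric_tensor(6)
  expect_equal(m6$g[3, 3], 1.5)
  expect_equal(sum(m6$g), 17.5)
  expect_equal(m6$d_max, 0.5 * sqrt(17.5))
  m8 <- metric_tensor(8)
  expect_equal(sum(m8$g), 42)
  expect_equal(m8$d_max, 0.5 * sqrt(42))
  for (n in c(2, 4, 6, 8, 10)) {
    g <- metric_tensor(n)$g
    expect_equal(g, t(g))
    expect_true(all(g > 0))
    expect_true(all(eigen(g, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  expect_error(metric_tensor(1), "at least 2")
})

test_that("gait distances hit the printed anchors and stay in [0, 1]", {
  m <- metric_tensor(6)
  gm <- model_gaits(6)
  expect_equal(unname(gait_distance(gm$ABT, gm$ABT, m)["Delta"]), 0)
  expect_equal(round(unname(gait_distance(gm$ABT, gm$MT, m)["Delta"]), 2), 0.29)
  # antipodal in every coordinate: the maximum distance
  a <- rep(0.25, 5); b <- rep(0.75, 5)
  expect_equal(unname(gait_distance(a, b, m)["Delta"]), 1)
  expect_equal(unname(gait_distance(a, b, m)["d"]), m$d_max)
  # symmetry and range over random pairs
  set.seed(99)
  for (i in 1:50) {
    p <- stats::runif(5); q <- stats::runif(5)
    dpq <- gait_distance(p, q, m)["Delta"]
    expect_equal(dpq, gait_distance(q, p, m)["Delta"], tolerance = 1e-12)
    expect_gte(dpq, 0); expect_lte(dpq, 1)
  }
  expect_error(gait_distance(rep(0.5, 4), rep(0.5, 5), m), "dimension")
})

test_that("the quadratic form equals the brute-force quotient distance near-field", {
  set.seed(2024)
  m <- metric_tensor(8)
  for (i in 1:20) {
    phi_a <- stats::runif(8)
    phi_b <- wrap_cycle(phi_a + stats::runif(8, -0.12, 0.12))
    a <- wrap_cycle(diff(phi_a)); b <- wrap_cycle(diff(phi_b))
    d_form <- unname(gait_distance(a, b, m)["d"])
    d_bf <- brute_force_quotient_distance(phi_a, phi_b)
    expect_lt(abs(d_form - d_bf) / d_bf, 1e-3)
  }
})

test_that("the triangle inequality holds for nearby coordinate lifts", {
  set.seed(5)
  m <- metric_tensor(6)
  for (i in 1:30) {
    base <- stats::runif(5)
    a <- wrap_cycle(base + stats::runif(5, 0, 0.1))
    b <- wrap_cycle(base + stats::runif(5, 0, 0.1))
    cc <- wrap_cycle(base + stats::runif(5, 0, 0.1))
    dab <- gait_distance(a, b, m)["d"]
    dbc <- gait_distance(b, cc, m)["d"]
    dac <- gait_distance(a, cc, m)["d"]
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("dataset-to-model distances bootstrap reproducibly", {
  m <- metric_tensor(6)
  gm <- model_gaits(6)
  # dataset consisting of the model point itself
  one <- matrix(gm$MT$point, 1)
  b <- dataset_to_model(one, gm$MT, m, n_boot = 200, seed = 1)
  expect_equal(b$mean, 0)
  expect_equal(b$ci, c(0, 0))
  # von Mises cloud around the model: small mean, CI brackets it
  pts <- sample_gait_points(gm$MT, kappa = 8, n = 1000, seed = 2)
  b1 <- dataset_to_model(pts, gm$MT, m, n_boot = 500, seed = 3)
  expect_lt(b1$mean, 0.2)
  expect_gte(b1$mean, b1$ci[1]); expect_lte(b1$mean, b1$ci[2])
  b2 <- dataset_to_model(pts, gm$MT, m, n_boot = 500, seed = 3)
  expect_identical(b1$ci, b2$ci)
  expect_error(dataset_to_model(pts[0, , drop = FALSE], gm$MT, m), "empty")
  expect_error(dataset_to_model(pts, gm$MT, m, n_boot = 10), "at least 100")
})

test_that("noiseless synthetic trials round-trip through the phase pipeline", {
  cases <- list(list(gm = model_gaits(8)$ALT),
                list(gm = model_gaits(6)$ABT),
                list(gm = model_gaits(6)$MT))
  for (cs in cases) {
    trial <- synth_trial(cs$gm, n_strides = 6)
    gp <- trial_gait_points(trial)
    rec <- apply(gp$points, 2, circular_mean)
    expect_lt(max(circular_delta(rec, cs$gm$point)), 0.02,
              label = paste("round trip", cs$gm$name))
  }
})
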