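test_that("tracks CSV round-trips through write_tracks and read_tracks", {
  trial <- synth_trial(model_gaits(8)$ALT, n_strides = 2, seed = 11,
                       tracking_noise_sd = 0.4)
  path <- tempfile(fileext = ".csv")
  write_tracks(trial, path)
  back <- read_tracks(path)
  expect_identical(back$specimen_id, trial$specimen_id)
  expect_identical(back$treatment, trial$treatment)
  expect_equal(back$frame_rate, trial$frame_rate)
  expect_equal(back$body_length, trial$body_length)
  expect_equal(back$time, trial$time, tolerance = 1e-9)
  expect_equal(back$com, trial$com, tolerance = 1e-6)
  expect_identical(present_legs(back), present_legs(trial))
  for (leg in present_legs(trial))
    expect_equal(back$tarsi[[leg]], trial$tarsi[[leg]], tolerance = 1e-6)
  # second round trip is bit-stable
  path2 <- tempfile(fileext = ".csv")
  write_tracks(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("absent leg columns and all-empty columns are recorded as autotomized", {
  legs6 <- setdiff(LEG_LABELS, c("L4", "R1"))
  path <- write_fixture_csv(fixture_frame(3, legs = legs6))
  trial <- read_tracks(path)
  expect_setequal(present_legs(trial), legs6)
  expect_identical(present_legs(trial),
                   LEG_LABELS[LEG_LABELS %in% legs6])  # canonical order

  df <- fixture_frame(3, legs = LEG_LABELS)
  df$L4_x <- NA; df$L4_y <- NA
  path <- write_fixture_csv(df)
  trial <- read_tracks(path)
  expect_false("L4" %in% present_legs(trial))
  expect_equal(length(present_legs(trial)), 7)
})

test_that("schema remapping, gap policy and format errors behave as specified", {
  # non-monotonic time
  df <- fixture_frame(3)
  df$time <- c(0, 0.002, 0.001)
  expect_error(read_tracks(write_fixture_csv(df)), "increasing")
  # missing mandatory column
  df <- fixture_frame(3)
  df$com_x <- NULL
  expect_error(read_tracks(write_fixture_csv(df)), "mandatory")
  # schema remap absorbs a tracker-export variant
  df <- fixture_frame(3)
  names(df)[names(df) == "com_x"] <- "body_cx"
  p <- write_fixture_csv(df)
  expect_error(read_tracks(p), "mandatory")
  trial <- read_tracks(p, schema = c(com_x = "body_cx"))
  expect_equal(trial$com[, "x"], fixture_frame(3)$com_x)
  # short gap interpolated with warning; long gap is an error
  df <- fixture_frame(12)
  df$L1_x[5:6] <- NA
  expect_warning(trial <- read_tracks(write_fixture_csv(df)), "interpolated")
  expect_equal(trial$tarsi$L1[5:6, "x"],
               fixture_frame(12)$L1_x[5:6], tolerance = 1e-9)
  df$L1_x[4:8] <- NA
  expect_error(suppressWarnings(read_tracks(write_fixture_csv(df))),
               "gap longer")
})

test_that("pixel calibration in metadata converts coordinates to mm", {
  df <- fixture_frame(3)
  p <- write_fixture_csv(df, meta = list(specimen_id = "s1", treatment = "C1",
                                         frame_rate = 500, body_length = 12,
                                         px_per_mm = 3.67))
  trial <- read_tracks(p)
  expect_equal(trial$com[, "x"], df$com_x / 3.67)
})

test_that("running quadratic derivative is exact on polynomials up to degree 2", {
  fr <- 500
  tt <- (0:199) / fr
  expect_equal(local_quadratic_derivative(3 * tt, 40, fr),
               rep(3, 200), tolerance = 1e-9)
  d <- local_quadratic_derivative(tt^2, 40, fr)
  h <- floor(0.040 * fr / 2)
  interior <- (h + 1):(200 - h)
  expect_equal(d[interior], 2 * tt[interior], tolerance = 1e-9)
  # truncated edge windows still fit the quadratic exactly
  expect_equal(d, 2 * tt, tolerance = 1e-8)
  expect_error(local_quadratic_derivative(tt, 2, fr), "3 frames")
})

test_that("sine derivative error matches the closed-form quadratic-fit attenuation", {
  fr <- 500; f <- 6
  tt <- (0:999) / fr
  y <- sin(2 * pi * f * tt)
  est <- local_quadratic_derivative(y, 40, fr)
  truth <- 2 * pi * f * cos(2 * pi * f * tt)
  # Interior filter response on a sinusoid: the symmetric-window slope
  # filter sum(j*y_j)/(dt*sum(j^2)) has gain G = sum(j*sin(j*w*dt)) /
  # (w*dt*sum(j^2)) relative to the true derivative, so the worst-case
  # interior error is |w|*(1 - G).
  h <- floor(0.040 * fr / 2)
  j <- seq(-h, h); w <- 2 * pi * f; dt <- 1 / fr
  G <- sum(j * sin(j * w * dt)) / (w * dt * sum(j^2))
  tol <- w * (1 - G) * 1.01 + 1e-9
  interior <- (h + 1):(1000 - h)
  expect_lt(max(abs(est[interior] - truth[interior])), tol)
  expect_gt(G, 0.9)  # 40 ms window passes a 6 Hz signal with mild attenuation
})

test_that("body-frame transform orients the heading to +y and is an isometry", {
  n <- 100; fr <- 500; v <- 100
  tt <- (0:(n - 1)) / fr
  com <- cbind(v * tt, 0)  # moving along +x
  tarsi <- list(L1 = shift_xy(com, c(5, 0)),   # 5 mm ahead of COM along motion
                R1 = shift_xy(com, c(2, 3)))
  trial <- tracked_trial("s", "OTHER", fr, 10, tt, com,
                         shift_xy(com, c(5, 0)), shift_xy(com, c(-5, 0)), tarsi)
  bft <- to_body_frame(trial)
  i <- 50
  expect_equal(unname(bft$tarsi_bf$L1[i, ]), c(0, 5), tolerance = 1e-9)
  # isometry: pairwise distance between the two tarsi preserved frame-by-frame
  lab <- sqrt(rowSums((tarsi$L1 - tarsi$R1)^2))
  bf <- sqrt(rowSums((bft$tarsi_bf$L1 - bft$tarsi_bf$R1)^2))
  expect_equal(bf, lab, tolerance = 1e-9)
  # inverse transform recovers lab-frame coordinates
  u <- bft$com_velocity / bft$speed
  x_bf <- bft$tarsi_bf$R1[, 1]; y_bf <- bft$tarsi_bf$R1[, 2]
  back_x <- u[, 2] * x_bf + u[, 1] * y_bf + trial$com[, 1]
  back_y <- -u[, 1] * x_bf + u[, 2] * y_bf + trial$com[, 2]
  expect_equal(cbind(back_x, back_y), unname(tarsi$R1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a stationary COM makes the body frame degenerate", {
  n <- 50; fr <- 500
  tt <- (0:(n - 1)) / fr
  com <- cbind(rep(0, n), rep(0, n))
  trial <- tracked_trial("s", "OTHER", fr, 10, tt, com,
                         shift_xy(com, c(0, 5)), shift_xy(com, c(0, -5)),
                         list(L1 = shift_xy(com, c(1, 1))))
  expect_error(to_body_frame(trial), "degenerate")
})

test_that("trial validation enforces the core invariants", {
  n <- 10; fr <- 500
  tt <- (0:(n - 1)) / fr
  com <- cbind(tt, tt)
  ok <- list(L1 = com + 1)
  expect_error(tracked_trial("s", "OTHER", -1, 10, tt, com, com, com, ok),
               "frame_rate")
  expect_error(tracked_trial("s", "OTHER", fr, 0, tt, com, com, com, ok),
               "body_length")
  expect_error(tracked_trial("s", "OTHER", fr, 10, tt * 2, com, com, com, ok),
               "spacing")
  expect_error(tracked_trial("s", "OTHER", fr, 10, tt, com, com, com,
                             list(Z9 = com)), "unknown leg")
  bad <- ok; bad$L1[3, 1] <- NA
  expect_error(tracked_trial("s", "OTHER", fr, 10, tt, com, com, com, bad),
               "non-finite")
})
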