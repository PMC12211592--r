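# Shared fixtures and independent oracles for the test suite.

# Brute-force quotient distance between two full leg-phase vectors:
# minimum over a fine grid of common phase offsets c of the Euclidean
# norm of per-leg minimal circular separations. This is the independent
# derivation of the gait metric tensor; it never calls the package's
# quadratic-form code path.
brute_force_quotient_distance <- function(phi_a, phi_b, n_grid = 200000L) {
  cs <- seq(0, 1, length.out = n_grid + 1L)[-(n_grid + 1L)]
  shifted <- outer(phi_b, cs, "+")
  d <- abs(phi_a - shifted) %% 1
  d <- pmin(d, 1 - d)
  min(sqrt(colSums(d^2)))
}

# Write a minimal hand-built tracks CSV (+ JSON sidecar) and return its path.
write_fixture_csv <- function(df, meta = list(specimen_id = "s1",
                                              treatment = "C1",
                                              frame_rate = 500,
                                              body_length = 12)) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  path
}

# Data frame skeleton for n frames at 500 Hz with COM/cranial/caudal and
# the requested legs placed at fixed offsets.
fixture_frame <- function(n = 3L, legs = LEG_LABELS, frame_rate = 500) {
  tt <- (seq_len(n) - 1L) / frame_rate
  df <- data.frame(frame = seq_len(n) - 1L, time = tt,
                   com_x = seq_len(n) * 0.1, com_y = seq_len(n) * 0.2,
                   cranial_x = seq_len(n) * 0.1, cranial_y = seq_len(n) * 0.2 + 6,
                   caudal_x = seq_len(n) * 0.1, caudal_y = seq_len(n) * 0.2 - 6)
  for (i in seq_along(legs)) {
    df[[paste0(legs[i], "_x")]] <- seq_len(n) * 0.1 + i
    df[[paste0(legs[i], "_y")]] <- seq_len(n) * 0.2 - i
  }
  df
}

# Add a constant xy offset to an n x 2 coordinate matrix.
shift_xy <- function(m, v) sweep(m, 2, v, "+")

# A hand-built straight-running trial: COM advances along +y at `speed`,
# with the given tarsus trajectories (list of n x 2 matrices).
straight_trial <- function(n, speed, tarsi, frame_rate = 500,
                           body_length = 12) {
  tt <- (seq_len(n) - 1L) / frame_rate
  com <- cbind(0, speed * tt)
  tracked_trial("fix", "OTHER", frame_rate, body_length, tt, com,
                com + cbind(0, body_length / 2),
                com - cbind(0, body_length / 2), tarsi)
}
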