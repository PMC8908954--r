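fake_stream <- function(acc, mag = NULL, fs = 40) {
  n <- nrow(acc)
  if (is.null(mag)) mag <- matrix(rep(c(1, 0, 0.5), each = n), ncol = 3)
  list(time_s = (seq_len(n) - 1) / fs, acc = acc, mag = mag, fs = fs)
}

test_that("static/dynamic split is exact for constant input", {
  acc <- matrix(rep(c(0, 0, 1), each = 400), ncol = 3)
  d <- split_static_dynamic(fake_stream(acc), 2)
  expect_equal(d$static, acc)
  expect_equal(d$dynamic, matrix(0, 400, 3))
  # the split always reconstructs the raw signal exactly
  expect_equal(d$static + d$dynamic, acc)
})

test_that("window equal to the record length returns the global mean", {
  set.seed(2)
  acc <- matrix(rnorm(303), ncol = 3)
  d <- split_static_dynamic(fake_stream(acc, fs = 1), window_s = 101)
  for (j in 1:3) expect_equal(d$static[51, j], mean(acc[, j]))
  expect_error(split_static_dynamic(fake_stream(acc, fs = 1), 500),
               "longer than the record")
})

test_that("VeDBA is the dynamic vector magnitude (3-4-5 check)", {
  expect_equal(compute_vedba(matrix(c(0.06, 0, 0.08), 1)), 0.10)
  expect_equal(compute_vedba(matrix(0, 5, 3)), rep(0, 5))
})

test_that("VeDBA is invariant to axis permutation and sign flips", {
  set.seed(3)
  d <- matrix(rnorm(300), ncol = 3)
  v <- compute_vedba(d)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(compute_vedba(d[, perm]), v)
  }
  expect_equal(compute_vedba(-d), v)
  expect_equal(compute_vedba(d %*% diag(c(1, -1, 1))), v)
})

test_that("level-body headings follow the stated axis convention", {
  level <- matrix(c(0, 0, 1), 1)
  expect_equal(compute_heading(level, matrix(c(1, 0, 0.5), 1))$heading_deg, 0)
  # facing east puts magnetic north on the left (+y) side of the collar
  expect_equal(compute_heading(level, matrix(c(0, 1, -0.5), 1))$heading_deg, 90)
  expect_equal(compute_heading(level, matrix(c(-1, 0, 0.5), 1))$heading_deg, 180)
})

test_that("a known body rotation is inverted to 0.1 degree", {
  incl <- 67 * pi / 180
  Bw <- c(cos(incl), 0, -sin(incl))
  for (case in list(c(137, 20, 10), c(12, -8, 25), c(301, 14, -14))) {
    R <- rot_body_to_world(case[1], case[2], case[3])
    acc <- t(R) %*% c(0, 0, 1)
    mag <- t(R) %*% Bw
    hd <- compute_heading(matrix(acc, 1, 3), matrix(mag, 1, 3))
    expect_equal(hd$heading_deg, case[1], tolerance = 0.1)
    expect_equal(hd$pitch_deg, case[2], tolerance = 0.1)
    expect_equal(hd$roll_deg, case[3], tolerance = 0.1)
  }
})

test_that("heading is invariant to uniform magnetometer scaling", {
  set.seed(4)
  static <- matrix(rep(c(0.1, 0.05, 0.99), each = 50), ncol = 3)
  mag <- matrix(rnorm(150), ncol = 3)
  h1 <- compute_heading(static, mag)$heading_deg
  h2 <- compute_heading(static, mag * 37.5)$heading_deg
  expect_equal(h1, h2)
})

test_that("zero static magnitude is flagged and interpolated", {
  static <- rbind(c(0, 0, 1), c(0, 0, 0), c(0, 0, 1))
  mag <- rbind(c(1, 0, 0.5), c(0, 1, 0.5), c(1, 0, 0.5))
  hd <- compute_heading(static, mag)
  expect_identical(hd$valid, c(TRUE, FALSE, TRUE))
  expect_equal(hd$heading_deg[2], 0)
})

test_that("constant activity yields a single above-ground bout", {
  fs <- 40
  v <- rep(0.25, 20 * 60 * fs)
  b <- detect_sett_occupancy(v, rep(10, length(v)), fs = fs)
  expect_equal(nrow(b), 1)
  expect_equal(b$state, "above_ground")
})

test_that("a VeDBA step with a temperature ramp is detected as entry with both evidence", {
  fs <- 40
  n1 <- 30 * 60 * fs
  n2 <- 40 * 60 * fs
  set.seed(5)
  v <- c(rep(0.25, n1), rep(0.05, n2)) + rnorm(n1 + n2, 0, 0.01)
  t0 <- n1 / fs
  tt <- (seq_len(n1 + n2) - 1) / fs
  temp <- 10 + 4 * pmin(1, pmax(0, (tt - t0) / 1800))
  b <- detect_sett_occupancy(v, temp, fs = fs)
  expect_equal(nrow(b), 2)
  expect_equal(b$state, c("above_ground", "below_ground"))
  expect_lt(abs(b$start_s[2] - t0), 60)
  expect_equal(b$evidence[2], "both")
  # without temperature the bout stands on VeDBA alone
  b2 <- detect_sett_occupancy(v, NULL, fs = fs)
  expect_equal(b2$evidence[2], "vedba")
})

test_that("bouts tile the record with alternating states", {
  nt <- quick_night()
  b <- detect_sett_occupancy(nt$signals$vedba, nt$stream$temp_c,
                             fs = nt$stream$fs, time_s = nt$stream$time_s)
  expect_equal(b$start_s[1], nt$stream$time_s[1])
  expect_equal(b$end_s[nrow(b)],
               nt$stream$time_s[length(nt$stream$time_s)] + 1 / nt$stream$fs)
  if (nrow(b) > 1) {
    expect_true(all(abs(b$start_s[-1] - b$end_s[-nrow(b)]) < 1e-6))
    expect_true(all(b$state[-1] != b$state[-nrow(b)]))
  }
  # every bout respects the minimum duration
  expect_true(all(b$end_s - b$start_s >= 300 - 1e-6))
})
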