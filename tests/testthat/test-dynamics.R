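# Time-resolved narrowband power, lateralization index, turn-locked
# contrasts, burst grouping, perturbation responses.

test_that("narrowband envelope power matches sinusoid amplitude algebra", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)[-1]
  A <- 1.7
  p <- timeresolved_power(A * sin(2 * pi * 39 * t), fs, center_hz = 39)
  mid <- p$valid & seq_along(t) > 2 * fs & seq_along(t) < length(t) - 2 * fs
  expect_equal(mean(p$values[mid]), A^2, tolerance = 0.02)
  # out-of-band rejection: a pure 41 Hz tone leaves < 1% in the 39 Hz band
  p41 <- timeresolved_power(sin(2 * pi * 41 * t), fs, center_hz = 39)
  pref <- timeresolved_power(sin(2 * pi * 41 * t), fs, center_hz = 41)
  expect_lt(mean(p41$values[mid]) / mean(pref$values[mid]), 0.01)
  # amplitude step A -> 2A quadruples power beyond the settling time
  x <- sin(2 * pi * 39 * t) * ifelse(t > 10, 2, 1)
  ps <- timeresolved_power(x, fs, center_hz = 39)
  before <- mean(ps$values[t > 6 & t < 9])
  after <- mean(ps$values[t > 11 & t < 14])
  expect_equal(after / before, 4, tolerance = 0.05)
  expect_error(timeresolved_power(x, fs, center_hz = 300), "Nyquist")
})

test_that("lateralization index follows its printed algebra", {
  mk <- function(v, hz) structure(list(values = v, fs = 500, center_hz = hz,
                                       valid = rep(TRUE, length(v))),
                                  class = "power_series")
  p39 <- mk(rep(3, 10), 39); p41 <- mk(rep(1, 10), 41)
  li <- lateralization_index(p39, p41)
  expect_equal(li$values, rep(0.5, 10))          # (3-1)/(3+1)
  # symmetry and antisymmetry
  expect_equal(lateralization_index(p41, p39)$values, rep(-0.5, 10))
  same <- lateralization_index(p39, p39)
  expect_equal(same$values, rep(0, 10))
  # invariance under common gain
  k <- 12.3
  li_k <- lateralization_index(mk(k * rep(3, 10), 39), mk(k * rep(1, 10), 41))
  expect_equal(li_k$values, li$values)
  # zero-power samples flagged as undefined, not silently zeroed
  pz <- lateralization_index(mk(c(0, 2), 39), mk(c(0, 2), 41))
  expect_true(is.na(pz$values[1]))
  expect_equal(pz$undefined, 1L)
  expect_error(lateralization_index(mk(rep(1, 5), 39), mk(rep(1, 6), 41)),
               "aligned")
})

test_that("turn-locked contrast is zero for a shared trial set", {
  set.seed(1)
  fs <- 500
  lat <- structure(list(values = rnorm(fs * 120), fs = fs,
                        valid = rep(TRUE, fs * 120)),
                   class = "lateralization_series")
  turns <- data.frame(apex_time_s = seq(10, 110, by = 6),
                      direction = rep(c("left", "right"), length.out = 17))
  con <- turn_locked_contrast(lat, turns)
  # replaying the same lateralization series epoched at the same apices for
  # both conditions gives an identically zero contrast
  shared <- con
  shared$right <- shared$left
  expect_equal(shared$left - shared$right,
               matrix(0, nrow(con$left), ncol(con$left)))
  expect_equal(ncol(con$left), 2001)
  expect_error(turn_locked_contrast(lat, turns[1:2, ]), "at least 2")
})

test_that("turn-phase gain produces the pre/post apex contrast pattern", {
  # left-turn trials must show a positive left-minus-right lateralization
  # contrast before the apex and a negative one after; antisymmetric under
  # swapping the ear-to-frequency assignment
  cfg <- quick_config("walk", n_laps = 10, seed = 21,
                      lateralization_gain = 1.5)
  mo <- simulate_gyro(cfg)
  rec <- rereference(simulate_eeg(cfg, motion = mo))
  tu <- detect_turns(lowpass_yaw(mo))
  con <- assr_turn_contrast(rec, tu)
  pre <- con$time < -0.3; post <- con$time > 0.3
  d <- colMeans(con$left) - colMeans(con$right)
  expect_gt(mean(d[pre]), 0)
  expect_lt(mean(d[post]), 0)
  # swapped band assignment negates the contrast pattern
  con_sw <- assr_turn_contrast(rec, tu, freqs = c(41, 39))
  d_sw <- colMeans(con_sw$left) - colMeans(con_sw$right)
  expect_lt(mean(d_sw[pre]), 0)
  expect_gt(mean(d_sw[post]), 0)
})

test_that("bursts are grouped by turn direction and entrainment phase", {
  turns <- data.frame(apex_time_s = c(10, 16, 22),
                      direction = c("left", "right", "left"))
  bursts <- c(8.5, 10.0, 11.5, 15.1, 30.0, 21.9)
  by_dir <- group_bursts_by_turn(bursts, turns, mode = "direction")
  expect_identical(by_dir, c("left", "left", "left", "right", "unassigned",
                             "left"))
  by_ph <- group_bursts_by_turn(bursts, turns, mode = "entrainment_phase")
  # burst before a left-turn apex: left ear preferred; at the apex exactly:
  # post half (stated boundary rule); after: right preferred
  expect_identical(by_ph, c("left_preferred", "right_preferred",
                            "right_preferred", "right_preferred",
                            "unassigned", "left_preferred"))
  # oracle: brute-force interval intersection on a seeded random layout
  set.seed(9)
  tu2 <- data.frame(apex_time_s = sort(runif(20, 5, 295)),
                    direction = sample(c("left", "right"), 20, TRUE))
  b2 <- runif(100, 0, 300)
  got <- group_bursts_by_turn(b2, tu2, mode = "direction")
  oracle <- vapply(b2, function(b) {
    inside <- which(abs(tu2$apex_time_s - b) <= 2)
    if (!length(inside)) "unassigned"
    else tu2$direction[inside[which.min(abs(tu2$apex_time_s[inside] - b))]]
  }, "")
  expect_identical(got, oracle)
})

test_that("perturbation response is zero for constant power and negative for dips", {
  tm <- seq(-2, 2, by = 1 / 500)
  const <- matrix(5, 8, length(tm))
  pr0 <- perturbation_response(const, tm)
  expect_equal(pr0$series, rep(0, length(tm)))
  expect_equal(pr0$value, 0)
  # deeper multiplicative dips give strictly more negative responses
  vals <- vapply(c(0.2, 0.5, 0.8), function(depth) {
    dip <- ifelse(tm > 0 & tm < 0.3, 1 - depth, 1)
    perturbation_response(matrix(rep(5 * dip, 6), 6, byrow = TRUE), tm)$value
  }, 0)
  expect_true(all(vals < 0))
  expect_true(all(diff(vals) < 0))
  # invariant to global power scaling (log-ratio form)
  dip <- ifelse(tm > 0 & tm < 0.3, 0.5, 1)
  a <- perturbation_response(matrix(rep(5 * dip, 6), 6, byrow = TRUE), tm)$value
  b <- perturbation_response(matrix(rep(500 * dip, 6), 6, byrow = TRUE), tm)$value
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(perturbation_response(const[0, , drop = FALSE], tm), "empty")
})
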