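# Synthetic-data generator: stimulus, schedules, gyroscope, forward-mixed EEG.

test_that("amplitude-modulated tone has the stated envelope algebra", {
  cfg0 <- stimulus_config(depth = 0)
  s0 <- generate_am_tone(cfg0, "left", duration = 0.2)
  # depth 0: envelope constant -> pure carrier, |s| bounded by 1
  expect_lte(max(abs(s0$samples)), 1 + 1e-12)
  amp_spec <- Mod(fft(s0$samples))
  f <- (seq_along(s0$samples) - 1) / length(s0$samples) * s0$fs
  expect_equal(f[which.max(amp_spec[f < s0$fs / 2])], 1000, tolerance = 1e-6)

  cfg1 <- stimulus_config(depth = 1)
  s1 <- generate_am_tone(cfg1, "left", duration = 1)
  # depth 1: envelope range [0, 2] x carrier amplitude
  expect_lte(max(abs(s1$samples)), 2 + 1e-9)
  expect_gt(max(abs(s1$samples)), 1.95)

  # envelope of the rectified signal peaks at the left-ear modulation rate
  env <- abs(s1$samples)
  n <- length(env)
  sp <- Mod(fft(env - mean(env)))[2:(n %/% 2)]
  fgrid <- (1:(n %/% 2 - 1)) / n * s1$fs
  expect_equal(fgrid[which.max(sp)], 39, tolerance = 1e-6)

  s2 <- generate_am_tone(cfg1, "right", duration = 1)
  env2 <- abs(s2$samples)
  sp2 <- Mod(fft(env2 - mean(env2)))[2:(n %/% 2)]
  expect_equal(fgrid[which.max(sp2)], 41, tolerance = 1e-6)

  expect_error(generate_am_tone(cfg1, "left", duration = -1), "positive")
})

test_that("burst schedules respect counts, gap bounds and the seed", {
  sch <- schedule_bursts(60, 8, seed = 7)
  ev <- sch$events
  expect_equal(unname(table(ev$kind)[c("central", "left", "right")]),
               c(8L, 8L, 8L), ignore_attr = TRUE)
  for (k in unique(ev$kind)) {
    gaps <- diff(ev$onset_s[ev$kind == k])
    expect_true(all(gaps >= 3 & gaps <= 7))
  }
  sch2 <- schedule_bursts(60, 8, seed = 7)
  expect_identical(sch, sch2)
  expect_error(schedule_bursts(10, 8, seed = 1), "too short")
})

test_that("scheduled gaps are uniform on [3, 7] (Monte-Carlo mean)", {
  # mean of Uniform(3, 7) is 5; 10,000 gaps pin the empirical mean tightly
  gaps <- c()
  i <- 0L
  while (length(gaps) < 10000) {
    i <- i + 1L
    sch <- schedule_bursts(600, 80, kinds = "central", seed = i)
    gaps <- c(gaps, diff(sch$events$onset_s))
  }
  expect_gt(mean(gaps), 4.9)
  expect_lt(mean(gaps), 5.1)
})

test_that("noiseless gyroscope yaw has apices at the analytic times", {
  cfg <- quick_config("walk", n_laps = 4, seed = 2, gyro_noise_dps = 0,
                      step_ripple_dps = 0)
  mo <- simulate_gyro(cfg)
  tu <- detect_turns(mo, magnitude_threshold = 20)
  expect_equal(nrow(tu), 8)
  expect_equal(sum(tu$direction == "left"), 4)
  truth <- attr(mo, "truth")
  expect_equal(tu$apex_time_s, truth$apex_time_s, tolerance = 1.5 / mo$fs)
  expect_identical(tu$direction, truth$direction)
  # apex spacing is half a lap
  expect_equal(diff(tu$apex_time_s), rep(6, 7), tolerance = 0.02)
})

test_that("standing yaw stays below the turn-detection threshold", {
  cfg <- quick_config("stand", duration_s = 60, seed = 3)
  mo <- lowpass_yaw(simulate_gyro(cfg))
  expect_lt(max(abs(mo$gyro[3, ])), 10)
  expect_equal(nrow(detect_turns(mo)), 0)
})

test_that("default-noise gyro turns are recovered by detect_turns", {
  cfg <- quick_config("walk", n_laps = 6, seed = 4)
  mo <- lowpass_yaw(simulate_gyro(cfg))
  tu <- detect_turns(mo)
  truth <- attr(mo, "truth")
  expect_equal(nrow(tu), nrow(truth))
  matched <- vapply(truth$apex_time_s, function(a)
    min(abs(tu$apex_time_s - a)) <= 0.25, TRUE)
  expect_true(all(matched))
})

test_that("simulated EEG is seed-deterministic and embeds every burst", {
  cfg <- quick_config(seed = 11, duration_s = 25)
  sch <- schedule_bursts(25, 3, seed = 5)
  r1 <- simulate_eeg(cfg, schedule = sch)
  r2 <- simulate_eeg(cfg, schedule = sch)
  expect_identical(r1$data, r2$data)
  bursts <- r1$events[startsWith(r1$events$label, "burst_"), ]
  expect_equal(nrow(bursts), nrow(sch$events))
  expect_equal(bursts$sample, as.integer(round(sch$events$onset_s * 500)))
})

test_that("noiseless ASSR source power matches the sinusoid closed form", {
  amp <- 0.9
  cfg <- quick_config(duration_s = 30, seed = 6,
                      assr_amp = list(stand = c(amp, 0)),
                      alpha_amp = c(stand = 0),
                      aperiodic = c(offset = -20, exponent = 1),
                      sensor_noise_uV = 0)
  rec <- simulate_eeg(cfg)
  avg <- channel_average(rec)
  w <- welch_psd(avg, rec$fs)
  band <- w$freqs >= 36 & w$freqs <= 42
  measured <- sum(w$power[band]) * 1          # 1 Hz bins -> band power
  topo <- attr(rec, "truth")$topo_assr[, "f39"]
  a_eff <- amp * mean(topo[frontocentral_channels()])
  expect_equal(measured, a_eff^2 / 2, tolerance = 0.05)
})

test_that("zero ASSR amplitude leaves no parameterized peak at 39/41 Hz", {
  cfg <- quick_config(duration_s = 40, seed = 7,
                      assr_amp = list(stand = c(0, 0)))
  rec <- simulate_eeg(cfg)
  w <- welch_psd(channel_average(rec), rec$fs)
  ps <- fit_parameterized(w)
  expect_equal(parameterized_power(ps, 39, tol = 0.5), 0)
  expect_equal(parameterized_power(ps, 41, tol = 0.5), 0)
})

test_that("configured alpha-power state ordering propagates to O1/O2", {
  # stand > walk in configured alpha amplitude must show in measured Welch
  # alpha power; sign correct in at least 95% of seeds
  ok <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    p <- vapply(c("stand", "walk"), function(st) {
      cfg <- session_config(movement_state = st, duration_s = 20,
                            n_laps = 2, seed = 300L + s)
      rec <- simulate_eeg(cfg)
      w <- welch_psd(channel_average(rec, occipital_channels()), rec$fs)
      sum(w$power[w$freqs >= 8 & w$freqs <= 14])
    }, 0)
    ok <- ok + (p["stand"] > p["walk"])
  }
  expect_gte(ok / n_seeds, 0.95)
})

test_that("session fixtures round-trip through the CSV+JSON writer", {
  cfg <- quick_config(duration_s = 5, seed = 13)
  sch <- schedule_bursts(5, 1, seed = 2)
  rec <- simulate_eeg(cfg, schedule = sch)
  mo <- simulate_gyro(cfg)
  dir <- withr::local_tempdir()
  write_session(rec, mo, dir, meta = list(note = "fixture"))
  back <- read_session(dir)
  expect_equal(back$recording$data, rec$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$recording$labels, rec$labels)
  expect_equal(back$recording$events$sample, rec$events$sample)
  expect_equal(back$motion$gyro, mo$gyro, tolerance = 1e-6,
               ignore_attr = TRUE)
})
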