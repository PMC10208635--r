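test_that("calibration recovers the stereotyped amplitude of noiseless pulses", {
  s <- make_session(times = seq(500, 5300, by = 600), heights = rep(2, 9),
                    rate = 10)
  cal <- calibrate_height(global_dff(s))
  expect_equal(cal$stereotyped_height, 2, tolerance = 0.01)
  expect_equal(cal$n_contributing, 5)
})

test_that("narrow pulses are gated out of calibration by the 10 s FWHM rule", {
  narrow <- make_session(times = seq(500, 2300, by = 450), heights = rep(1, 5),
                         rate = 20, shape = "triangle", fwhm = 8)
  expect_error(calibrate_height(global_dff(narrow)),
               class = "arcpulse_calibration_error")
  # wide pulses (FWHM 12 s) qualify
  wide <- make_session(times = seq(500, 2300, by = 450), heights = rep(1, 5),
                       rate = 20, shape = "triangle", fwhm = 12)
  cal <- calibrate_height(global_dff(wide))
  expect_gt(cal$n_contributing, 0)
  # in a mixed trace only the wide pulses contribute
  mixed <- make_session(times = seq(500, 4550, by = 450),
                        heights = rep(1, 10), rate = 20, duration = 5200,
                        shape = "triangle", fwhm = 12)
  nar <- make_session(times = seq(500, 4550, by = 450) + 225,
                      heights = rep(1, 10), rate = 20, duration = 5200,
                      shape = "triangle", fwhm = 8)
  mixed$samples <- mixed$samples + nar$samples - 100
  cal <- calibrate_height(global_dff(mixed))
  wide_times <- seq(500, 4550, by = 450)
  expect_true(all(vapply(cal$peaks$peak_time, function(t) {
    min(abs(t - wide_times)) < min(abs(t - (wide_times + 225)))
  }, logical(1))))
})

test_that("calibration picks the prominent stereotyped peaks, not small ones", {
  tms <- seq(500, 5900, by = 600)
  s <- make_session(times = tms, heights = c(rep(1, 5), rep(0.2, 5)),
                    rate = 10)
  cal <- calibrate_height(global_dff(s), k = 5)
  expect_equal(cal$stereotyped_height, 1, tolerance = 0.02)
})

test_that("the 40% threshold separates 0.41H from 0.39H pulses", {
  tms <- seq(500, 2900, by = 600)
  s <- make_session(times = c(tms, 3500, 4100),
                    heights = c(rep(1, 5), 0.41, 0.39), rate = 10)
  d <- global_dff(s)
  cal <- calibrate_height(d)
  ev <- detect_pulses(d, cal)
  hit <- function(t0) any(abs(ev$peak_time - t0) < 30)
  expect_true(hit(3500))    # 0.41 H detected
  expect_false(hit(4100))   # 0.39 H rejected
  expect_equal(nrow(ev), 6)
})

test_that("a flat trace yields zero events without error", {
  d <- make_dff(rep(0, 5000), rate = 10)
  cal <- structure(list(animal_id = "fix", stereotyped_height = 1,
                        n_contributing = 1, fwhm_min = 10),
                   class = "calibration_result")
  ev <- detect_pulses(d, cal)
  expect_equal(nrow(ev), 0)
})

test_that("noiseless simulated sessions are detected exactly against ground truth", {
  rt <- default_rate_table(); rt["proestrus", "light"] <- 45
  cfg <- generator_config(stage_rate_table = rt, sampling_rate = 20,
                          noise_sd = 0, drift_amplitude = 0)
  s <- simulate_session(cfg, "proestrus", "light", seed = 21)
  d <- global_dff(s)
  cal <- calibrate_height(d)
  ev <- detect_pulses(d, cal)
  expect_equal(nrow(ev), length(s$truth$times))
  expect_true(all(abs(ev$peak_time - s$truth$times) < 0.2))
})

test_that("detection count is monotone non-increasing in the threshold", {
  cfg <- test_config()
  s <- simulate_session(cfg, "metestrus", "dark", seed = 31)
  d <- global_dff(s)
  cal <- calibrate_height(d)
  cand <- session_candidates(d)
  counts <- vapply(seq(0.1, 1.5, by = 0.1), function(f) {
    nrow(detect_pulses(d, cal, threshold_frac = f, candidates = cand))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("calibration and detection are equivariant to delta-F/F scaling", {
  v <- rep(0, 60000)
  tp <- se_kernel_peak_time(20, 60)
  t <- (seq_along(v) - 1) / 10
  for (tm in seq(500, 5500, by = 1200)) {
    v <- v + se_kernel(t - (tm - tp), 20, 60)
  }
  d1 <- make_dff(v, rate = 10)
  d2 <- make_dff(3 * v, rate = 10)
  c1 <- calibrate_height(d1); c2 <- calibrate_height(d2)
  expect_equal(c2$stereotyped_height, 3 * c1$stereotyped_height,
               tolerance = 1e-6)
  e1 <- detect_pulses(d1, c1); e2 <- detect_pulses(d2, c2)
  expect_equal(e1$peak_time, e2$peak_time)
})

test_that("inter-peak intervals are formed within sessions only", {
  ev <- data.frame(peak_time = c(0, 600, 1800), animal_id = "a",
                   day_index = 1L, period = "light")
  expect_equal(interpeak_intervals(ev), c(10, 20))
  # one event per session never forms an interval
  ev2 <- data.frame(peak_time = c(100, 200, 300), animal_id = "a",
                    day_index = 1:3, period = "light")
  expect_equal(interpeak_intervals(ev2), numeric(0))
  # no cross-session interval between day 1 and day 2
  ev3 <- rbind(ev, transform(ev, day_index = 2L))
  expect_equal(sort(interpeak_intervals(ev3)), c(10, 10, 20, 20))
})

test_that("simulated inter-peak intervals match the generative mean", {
  rt <- default_rate_table(); rt["diestrus", "dark"] <- 45
  cfg <- generator_config(stage_rate_table = rt, sampling_rate = 1,
                          noise_sd = 0, drift_amplitude = 0)
  iv <- unlist(lapply(1:80, function(s) {
    tt <- simulate_session(cfg, "diestrus", "dark", seed = s)$truth$times
    if (length(tt) > 1) diff(tt) / 60 else numeric(0)
  }))
  expect_gt(length(iv), 400)
  expect_lt(abs(mean(iv) - 45), 4.5)
})
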