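test_that("a forced noiseless event adds exactly one kernel at its analytic peak", {
  cfg <- generator_config(sampling_rate = 10, noise_sd = 0, drift_amplitude = 0)
  s <- simulate_session(cfg, "proestrus", "light", seed = 1,
                        event_times = 5000)
  expect_equal(length(s$samples), 21600 * 10)
  imax <- which.max(s$samples)
  expect_lt(abs((imax - 1) / 10 - 5000), 0.11)   # one sample at 10 Hz
  expect_equal(max(s$samples), cfg$baseline_level * 2, tolerance = 1e-6)
  expect_equal(min(s$samples), cfg$baseline_level)
  # far from the pulse the trace is exactly baseline
  expect_equal(s$samples[1:100], rep(cfg$baseline_level, 100))
})

test_that("renewal event counts match the configured mean interval", {
  rt <- default_rate_table(); rt["proestrus", "light"] <- 45
  cfg <- generator_config(stage_rate_table = rt, sampling_rate = 1,
                          noise_sd = 0, drift_amplitude = 0)
  counts <- vapply(1:200, function(s) {
    length(simulate_session(cfg, "proestrus", "light", seed = s)$truth$times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 8), 0.15 * 8)
})

test_that("identical seed and config give bit-identical sessions", {
  cfg <- test_config()
  s1 <- simulate_session(cfg, "estrus", "dark", seed = 7)
  s2 <- simulate_session(cfg, "estrus", "dark", seed = 7)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_session(cfg, "estrus", "dark", seed = 8)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("generator configuration is validated", {
  expect_error(generator_config(noise_sd = -1), class = "arcpulse_config_error")
  expect_error(generator_config(kernel_rise_tau = 80),
               class = "arcpulse_config_error")
  amp <- default_amplitude_table(); amp["proestrus", "light"] <- 1.2
  expect_error(generator_config(stage_amplitude_table = amp),
               class = "arcpulse_config_error")
  rt <- default_rate_table(); rt["diestrus", "dark"] <- 0
  expect_error(generator_config(stage_rate_table = rt),
               class = "arcpulse_config_error")
  expect_error(generator_config(session_duration = 100.5, sampling_rate = 1.3),
               class = "arcpulse_config_error")
  expect_error(simulate_session(generator_config(session_duration = 120,
                                                 sampling_rate = 10),
                                "proestrus", "light", seed = 1),
               class = "arcpulse_config_error")
})

test_that("default generator keeps the printed qualitative orderings", {
  cfg <- generator_config()
  rates <- cfg$stage_rate_table
  # rarest cell (longest interval) is the proestrus dark period
  expect_equal(which.max(rates), which(rownames(rates) == "proestrus") +
                 nrow(rates) * (which(colnames(rates) == "dark") - 1))
  # most frequent cells are metestrus/diestrus dark
  expect_equal(min(rates), rates["metestrus", "dark"])
  expect_equal(min(rates), rates["diestrus", "dark"])
  amps <- cfg$stage_amplitude_table
  expect_equal(amps["proestrus", "light"], 1.0)
  expect_equal(max(amps), amps["metestrus", "light"])  # light, 2 d after P
})

test_that("regular timelines hold at least three complete cycles per 25 days", {
  for (s in 1:10) {
    tl <- simulate_timeline(phase = "regular", n_days = 25, seed = s,
                            misread_prob = 0)
    cc <- count_cycles(tl$true_stage)
    expect_gte(cc$cycles_per_25_days, 3)
  }
})

test_that("acyclic timelines never complete a cycle", {
  for (s in 1:5) {
    tl <- simulate_timeline(phase = "acyclic", n_days = 40, seed = s)
    expect_equal(nrow(cycle_spans <- count_cycles(tl$true_stage)$spans), 0)
  }
})

test_that("cytology staging recovers the generated stage on >= 95% of days", {
  tl <- simulate_timeline(phase = "regular", n_days = 700, seed = 42)
  tl2 <- simulate_timeline(phase = "irregular", n_days = 300, seed = 43)
  truth <- c(tl$true_stage, tl2$true_stage)
  staged <- c(stage_smears(tl), stage_smears(tl2))
  expect_gte(mean(staged == truth), 0.95)
})

test_that("simulated Ct tables round-trip through the ddCt chain", {
  # identity: all folds 1, no noise
  ct <- simulate_ct_table(c(Kiss1 = 1), n_samples = 4, ct_noise_sd = 0, seed = 1)
  out <- relative_expression(ct, "Kiss1")
  expect_equal(out$relative_expression, rep(1, nrow(out)), tolerance = 1e-12)
  # a known fold change is recovered exactly without noise
  ct <- simulate_ct_table(c(Kiss1 = 0.5), n_samples = 4, ct_noise_sd = 0, seed = 2)
  out <- relative_expression(ct, "Kiss1")
  expect_equal(unique(round(out$relative_expression[out$phase == "acyclic"], 12)),
               0.5)
  # with noise the mean recovered fold stays within 10%
  folds <- vapply(1:100, function(s) {
    ct <- simulate_ct_table(c(Kiss1 = 0.5), n_samples = 8,
                            ct_noise_sd = 0.2, seed = s)
    out <- relative_expression(ct, "Kiss1")
    mean(out$relative_expression[out$phase == "acyclic"])
  }, numeric(1))
  expect_lt(abs(mean(folds) - 0.5), 0.05)
  # configuration errors
  expect_error(simulate_ct_table(c(Kiss1 = -1)), class = "arcpulse_config_error")
  expect_error(simulate_ct_table(c(Foo = 1)), class = "arcpulse_config_error")
})
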