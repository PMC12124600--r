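test_that("rate binning is conservative over half-open bins", {
  # 10 spikes inside one 5-s bin -> 2 Hz there, 0 elsewhere
  tr <- spike_train("u", seq(5.1, 9.6, by = 0.5))
  rs <- bin_rates(tr, 5, t_start = 0, t_end = 15)
  expect_equal(rs$rates, c(0, 2, 0))
  # boundary spike belongs to the later bin
  tb <- spike_train("u", c(4.9, 5.0))
  expect_equal(bin_rates(tb, 5, 0, 10)$rates, c(0.2, 0.2))
  # empty train: all-zero series
  expect_equal(bin_rates(spike_train("u"), 300, 0, 1200)$rates, rep(0, 4))
  # conservation for random trains and bin widths dividing the span
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    tr <- spike_train("u", sort(runif(n, 0, 600)))
    dlt <- sample(c(5, 10, 30, 60, 300), 1)
    rs <- bin_rates(tr, dlt, 0, 600)
    expect_equal(sum(rs$rates) * dlt, n)
  }
})

test_that("stage summary gives mean and SEM across recordings", {
  df <- data.frame(stage = rep("proestrus", 3), rate_hz = c(5, 5, 5))
  s <- suppressWarnings(stage_summary(df))
  expect_equal(s$mean_rate, 5)
  expect_equal(s$sem_rate, 0)
  expect_equal(s$n_recordings, 3)
  # two-point arithmetic: 4 and 6 Hz -> mean 5, SEM 1
  s2 <- suppressWarnings(stage_summary(
    data.frame(stage = "estrus", rate_hz = c(4, 6))))
  expect_equal(s2$mean_rate, 5)
  expect_equal(s2$sem_rate, 1)
  # empty stages are omitted with a warning; neuron/mouse counts kept
  df3 <- data.frame(stage = c("proestrus", "proestrus"), rate_hz = c(8, 10),
                    neuron_id = c("n1", "n1"), mouse_id = c("m1", "m1"))
  expect_warning(s3 <- stage_summary(df3), "no recordings")
  expect_equal(s3$n_neurons, 1)
  expect_equal(s3$n_mice, 1)
  expect_error(suppressWarnings(stage_summary(
    data.frame(stage = "luteal", rate_hz = 1))), "unknown stage")
})

test_that("stage-basal cohorts recover the generating rate", {
  cfg <- cohort_config(n_units = 11, stage = "proestrus", seed = 41)
  coh <- generate_cohort(cfg, "stage_basal")
  df <- data.frame(stage = "proestrus",
                   rate_hz = vapply(coh$sessions, session_mean_rate,
                                    numeric(1)))
  s <- suppressWarnings(stage_summary(df))
  expect_lt(abs(s$mean_rate - stage_baselines()[["proestrus"]]),
            3 * s$sem_rate)
})

test_that("elevation index behaves as a calibrated ratio", {
  clk <- session_clock("14:00")
  # constant series -> EI = 1
  flat <- rate_series(rep(8, 20), 3600, 0)
  expect_equal(surge_index(flat, clk), 1)
  # one 3-h block at exactly twice the first-hour rate -> EI = 2
  r <- rep(4, 20)
  r[10:12] <- 8
  expect_equal(surge_index(rate_series(r, 3600, 0), clk), 2)
  # shorter sessions are an error
  expect_error(surge_index(rate_series(rep(1, 10), 3600, 0), clk), "20-h")
  expect_error(surge_index(rate_series(rep(1, 20), 300, 0), clk), "3600")
  # zero anchor rate: undefined with warning
  z <- rate_series(c(0, rep(2, 19)), 3600, 0)
  expect_warning(ei <- surge_index(z, clk), "undefined")
  expect_true(is.na(ei))
  # scale invariance: EI is a ratio
  r2 <- rate_series(r * 7.3, 3600, 0)
  expect_equal(surge_index(r2, clk), 2)
})

test_that("surge classifier separates profile shapes, not rate scale", {
  clk <- session_clock("14:00")
  flat <- rate_series(rep(8, 20), 3600, 0)
  expect_equal(classify_surge(flat, flat, clk)$subtype, "basal_rhythmic")
  # generator surge unit against a flat diestrus day
  ev <- session_events("proestrus", NULL, 72000, clk)
  f <- build_rate_function(rate_profile(8.54, surge = surge_defaults()), ev)
  tr <- sample_spike_train(f, 72000, seed = 51)
  pro <- bin_rates(tr, 3600, 0, 72000)
  cls <- classify_surge(pro, flat, clk)
  expect_equal(cls$subtype, "surge_like")
  expect_gt(cls$EI_proestrus, 1.5)
  # uniform scaling of both series never flips the verdict
  scaled <- classify_surge(rate_series(pro$rates * 0.2, 3600, 0),
                           rate_series(flat$rates * 0.2, 3600, 0), clk)
  expect_equal(scaled$subtype, cls$subtype)
})

test_that("subtype recovery holds across generator seeds", {
  clk <- session_clock("14:00")
  correct <- vapply(1:6, function(sd) {
    coh <- generate_cohort(cohort_config(n_surge = 7, n_basal = 8,
                                         seed = 1000 + sd), "surge_pair")
    pred <- vapply(coh$sessions, function(p) {
      classify_surge(bin_rates(p$proestrus$trains[[1]], 3600, 0, 72000),
                     bin_rates(p$diestrus$trains[[1]], 3600, 0, 72000),
                     clk)$subtype
    }, character(1))
    sum(pred == coh$truth$subtype)
  }, numeric(1))
  expect_true(all(correct >= 14))
})

test_that("hourly profile summary aggregates recordings element-wise", {
  clk <- session_clock("14:00")
  one <- rate_series(rep(6, 20), 3600, 0)
  s1 <- surge_profile_summary(list(one), clk)
  expect_equal(s1$profile$mean_hz, rep(6, 20))
  expect_equal(s1$profile$sem_hz, rep(0, 20))
  # two identical series: SEM 0 everywhere
  s2 <- surge_profile_summary(list(one, one), clk)
  expect_equal(max(s2$profile$sem_hz), 0)
  expect_equal(s2$peak_hz, 6)
  # length mismatch is an error
  expect_error(surge_profile_summary(list(one, rate_series(rep(6, 10),
                                                           3600, 0))),
               "share")
  # clock labels follow the 14:00 anchor
  expect_equal(s1$profile$clock[1], "14:00")
  expect_equal(s1$profile$clock[11], "00:00")
})

test_that("waveform features match a brute-force scan oracle", {
  # symmetric triangular biphasic waveform, exact agreement
  v <- c(0, 20, 40, 20, 0, -40, -80, -120, -80, -40, 0, 20, 40, 20, 0)
  got <- waveform_features(v, 30000)
  orc <- waveform_oracle(v, 30000)
  expect_equal(got$left_peak_to_trough_ms, orc$left_peak_to_trough_ms)
  expect_equal(got$trough_to_right_peak_ms, orc$trough_to_right_peak_ms)
  expect_equal(got$half_width_ms, orc$half_width_ms, tolerance = 1e-2)

  # 100 random valid biphasic templates
  set.seed(8)
  for (i in 1:100) {
    cfg <- template_config(
      left_peak_uv = runif(1, 20, 80),
      trough_uv = -runif(1, 90, 300),
      right_peak_uv = runif(1, 30, 120),
      left_peak_to_trough_ms = runif(1, 0.2, 0.6),
      trough_to_right_peak_ms = runif(1, 0.2, 0.6),
      half_width_ms = runif(1, 0.05, 0.18))
    tpl <- render_template(calibrate_template(config = cfg))
    got <- waveform_features(tpl$samples, tpl$sample_rate)
    orc <- waveform_oracle(tpl$samples, tpl$sample_rate)
    expect_equal(got$left_peak_to_trough_ms, orc$left_peak_to_trough_ms)
    expect_equal(got$trough_to_right_peak_ms, orc$trough_to_right_peak_ms)
    expect_equal(got$half_width_ms, orc$half_width_ms, tolerance = 1e-2)
  }

  # degenerate inputs
  expect_error(waveform_features(rep(0, 30), 30000), "flat")
  expect_error(waveform_features(c(0, -50, -100, -50, 0), 30000),
               "biphasic")
})
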