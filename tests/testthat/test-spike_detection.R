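fs <- 30000

test_that("high-pass filter rejects DC, keeps spike-band content", {
  t <- seq(0, 1, by = 1 / fs)
  mid <- seq(round(0.2 * fs), round(0.8 * fs))  # avoid edge transients
  # constant input is removed entirely
  dc <- highpass(rep(100, length(t)), 300, fs)
  expect_lt(max(abs(dc[mid])), 1)
  # 1 kHz content retained (f/fc = 3.33, squared 4th-order response)
  s1k <- highpass(sin(2 * pi * 1000 * t), 300, fs)
  expect_gte(max(abs(s1k[mid])), 0.95)
  # 10 Hz content attenuated by >= 60 dB
  s10 <- highpass(sin(2 * pi * 10 * t), 300, fs)
  expect_lte(max(abs(s10[mid])), 10^(-60 / 20))
  # linearity
  x <- rnorm(fs)
  expect_equal(highpass(3.7 * x, 300, fs), 3.7 * highpass(x, 300, fs),
               tolerance = 1e-8)
  expect_error(highpass(x, 2e4, fs), "Nyquist")
})

test_that("robust noise estimate is consistent and spike-insensitive", {
  set.seed(42)
  x <- rnorm(10 * fs, sd = 5)
  expect_true(estimate_noise(x) > 4.7 && estimate_noise(x) < 5.3)
  expect_equal(estimate_noise(numeric(100)), 0)
  expect_error(estimate_noise(numeric(0)), "empty")
  # sparse large spikes barely move the estimate
  y <- x
  y[sample(length(y), 300)] <- -500
  expect_lt(abs(estimate_noise(y) - estimate_noise(x)) / estimate_noise(x),
            0.1)
})

test_that("threshold detection finds embedded spikes and merges doublets", {
  tpl <- render_template(test_templates()$small)  # -120 uV trough
  truth <- spike_train("u", c(0.1, 0.25, 0.4))
  syn <- synthesize_trace(list(truth), list(tpl), noise_sd_uv = 5,
                          sample_rate = fs, duration = 0.5, seed = 9)
  x <- highpass(syn$trace, 300)$samples[, 1]
  ev <- detect_events(x, fs)
  expect_length(ev, 3)
  expect_true(all(vapply(truth$timestamps, function(t)
    min(abs(ev - t)) < 1e-3, logical(1))))
  # sub-threshold activity yields no events
  expect_length(detect_events(rnorm(fs, sd = 5), fs), 0)
  # two crossings 0.5 ms apart collapse to the larger event
  z <- numeric(fs / 10)
  z[1000] <- -100
  z[1015] <- -80   # 0.5 ms later
  expect_length(detect_events(z, fs), 1)
  # detection count is monotone non-increasing in the threshold
  counts <- vapply(c(32, 64, 100, 150, 250), function(th)
    length(detect_events(x, fs,
                         detection_params(threshold_uv = th))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("snippets are trough-aligned with the stated geometry", {
  tpl <- render_template(test_templates()$small)
  truth <- spike_train("u", seq(0.1, 0.9, by = 0.1))
  syn <- synthesize_trace(list(truth), list(tpl), noise_sd_uv = 0,
                          sample_rate = fs, duration = 1)
  x <- syn$trace$samples[, 1]
  sn <- extract_align(x, fs, detect_events(x, fs))
  expect_equal(ncol(sn), round(1.2e-3 * fs))
  # every row has its minimum at the fixed trough index
  expect_true(all(apply(sn, 1, which.min) == attr(sn, "trough_index")))
  # noiseless snippets reproduce the template (zero-padded to the window)
  ti <- attr(sn, "trough_index")
  seg <- numeric(ncol(sn))
  src <- (tpl$trough_index - ti + 1):(tpl$trough_index - ti + ncol(sn))
  ok <- src >= 1 & src <= length(tpl$samples)
  seg[ok] <- tpl$samples[src[ok]]
  expect_equal(unname(sn[1, ]), seg)
  # events at the trace edge are dropped, not errors
  sn_edge <- extract_align(x, fs, c(0, 0.5))
  expect_equal(attr(sn_edge, "dropped"), 1L)
})

test_that("feature matrix behaves as specified", {
  tpl <- render_template(test_templates()$small)
  idcl <- matrix(rep(tpl$samples, 5), nrow = 5, byrow = TRUE)
  fe <- snippet_features(idcl, fs)
  # identical snippets: zero variance, PC coordinates all zero
  expect_equal(max(abs(fe[, 1:3])), 0)
  expect_equal(unname(fe[1, "amplitude_uv"]),
               max(tpl$samples) - min(tpl$samples))
  expect_true(all(fe[, "energy_uv2ms"] > 0))

  # PC scores agree with an eigendecomposition oracle on a random instance
  set.seed(11)
  X <- matrix(rnorm(10 * 12), 10, 12)
  fe2 <- snippet_features(X, fs)
  Xc <- scale(X, scale = FALSE)
  eg <- eigen(crossprod(Xc) / (nrow(X) - 1))
  oracle <- Xc %*% eg$vectors[, 1:3]
  for (j in 1:3)  # sign of each component is arbitrary
    expect_equal(abs(fe2[, j]), abs(oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("clustering separates distinct templates and respects QC", {
  tpls <- test_templates()
  trA <- sample_spike_train(flat_rate(3), 60, seed = 1, unit_id = "A")
  trB <- sample_spike_train(flat_rate(3), 60, seed = 2, unit_id = "B")
  syn <- synthesize_trace(list(trA, trB),
                          list(render_template(tpls$small),
                               render_template(tpls$large)),
                          noise_sd_uv = 5, sample_rate = fs, duration = 60,
                          seed = 3)
  x <- highpass(syn$trace, 300)$samples[, 1]
  ev <- detect_events(x, fs)
  sn <- extract_align(x, fs, ev)
  fe <- snippet_features(sn, fs)
  clu <- cluster_units(fe, 1:5, seed = 4, times = attr(sn, "times"))
  expect_equal(clu$k, 2)
  # ground-truth labels by nearest template trough amplitude
  truth_lab <- ifelse(vapply(attr(sn, "times"), function(t)
    min(abs(trA$timestamps - t)), numeric(1)) < 1e-3, "A", "B")
  expect_equal(adjusted_rand(clu$assignments, truth_lab), 1.0)
  # determinism
  clu2 <- cluster_units(fe, 1:5, seed = 4, times = attr(sn, "times"))
  expect_identical(clu$assignments, clu2$assignments)

  # single template: one cluster retained
  syn1 <- synthesize_trace(list(trA), list(render_template(tpls$small)),
                           noise_sd_uv = 5, sample_rate = fs,
                           duration = 60, seed = 5)
  x1 <- highpass(syn1$trace, 300)$samples[, 1]
  sn1 <- extract_align(x1, fs, detect_events(x1, fs))
  clu1 <- cluster_units(snippet_features(sn1, fs), 1:5, seed = 6,
                        times = attr(sn1, "times"))
  expect_equal(clu1$k, 1)
  expect_true(all(clu1$assignments == 1))

  # clusters below the snippet minimum are discarded as noise
  few <- matrix(rnorm(10 * 8), 10, 8)
  expect_warning(res <- cluster_units(snippet_features(few, fs), 1,
                                      seed = 1),
                 "quality control")
  expect_true(all(is.na(res$assignments)))
})

test_that("end-to-end sorting recovers ground truth at high SNR", {
  tpls <- test_templates()
  trA <- sample_spike_train(flat_rate(3), 60, seed = 21, unit_id = "A")
  trB <- sample_spike_train(flat_rate(3), 60, seed = 22, unit_id = "B")
  syn <- synthesize_trace(list(trA, trB),
                          list(render_template(tpls$small),
                               render_template(tpls$large)),
                          noise_sd_uv = 5, sample_rate = fs, duration = 60,
                          seed = 23)
  srt <- sort_trace(syn$trace, seed = 24)
  expect_length(srt$trains, 2)
  # match each truth unit to its best cluster
  hits <- sapply(srt$trains, function(u)
    c(A = match_fraction(trA$timestamps, u$timestamps),
      B = match_fraction(trB$timestamps, u$timestamps)))
  best <- apply(hits, 1, max)
  expect_gte(best[["A"]], 0.95)
  expect_gte(best[["B"]], 0.95)
  # false positives: every detected spike near some truth spike
  all_truth <- sort(c(trA$timestamps, trB$timestamps))
  for (u in srt$trains) {
    fp <- mean(vapply(u$timestamps, function(t)
      min(abs(all_truth - t)) > 1e-3, logical(1)))
    expect_lte(fp, 0.05)
  }
})
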