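# Independent oracles and small fixtures used across the suite.

# Deterministic evenly spaced spike train segment: exactly
# `rate * (t1 - t0)` spikes at bin midpoints, so any window with edges at
# t0/t1 counts them all regardless of open/closed conventions
regular_spikes <- function(rate, t0, t1) {
  if (rate <= 0) return(numeric())
  n <- round(rate * (t1 - t0))
  t0 + (seq_len(n) - 0.5) / rate
}

# Brute-force one-way ANOVA from raw sums of squares
anova_F_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(all_v) - length(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# Brute-force waveform feature scan, written independently of the package
# implementation: dense linear-interpolation resampling and direct search
# for the half-amplitude crossings.
waveform_oracle <- function(v, fs, upsample = 200L) {
  n <- length(v)
  i_tr <- which.min(v)
  i_lp <- which.max(v[seq_len(i_tr - 1L)])
  i_rp <- i_tr + which.max(v[(i_tr + 1L):n])
  level <- v[i_tr] + (max(v) - v[i_tr]) / 2
  tt <- seq(1, n, by = 1 / upsample)
  vv <- approx(seq_len(n), v, xout = tt)$y
  j_tr <- which.min(abs(tt - i_tr))
  left <- max(which(vv[seq_len(j_tr)] >= level))
  right <- j_tr - 1L + min(which(vv[j_tr:length(vv)] >= level))
  list(left_peak_to_trough_ms = (i_tr - i_lp) * 1000 / fs,
       trough_to_right_peak_ms = (i_rp - i_tr) * 1000 / fs,
       half_width_ms = (tt[right] - tt[left]) * 1000 / fs)
}

# Adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Fraction of truth spikes matched by a detected train within `tol` s
match_fraction <- function(truth_times, detected_times, tol = 1e-3) {
  if (!length(truth_times)) return(NA_real_)
  mean(vapply(truth_times, function(t)
    any(abs(detected_times - t) < tol), logical(1)))
}

# A standard pair of well-separated templates for sorting tests
test_templates <- function() {
  list(small = calibrate_template(config = template_config(trough_uv = -120)),
       large = calibrate_template(config = template_config(
         trough_uv = -300, left_peak_uv = 100, right_peak_uv = 150)))
}

flat_rate <- function(hz) function(t) rep(hz, length(t))
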