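#' Bin spike timestamps into a firing-rate series
#'
#' Counts spikes in half-open bins `[t_start + i*bin_width,
#' t_start + (i+1)*bin_width)` and divides by the bin width. Spans outside
#' the train's range simply produce zero bins.
#'
#' @param train a [spike_train()]
#' @param bin_width seconds (5, 300 and 3600 s are the conventional sizes)
#' @param t_start,t_end span to bin; defaults to `[0, ceiling(last spike))`
#'   aligned up to a whole number of bins
#' @return a [rate_series()]
#' @export
bin_rates <- function(train, bin_width, t_start = 0, t_end = NULL) {
  stopifnot(inherits(train, "spike_train"), bin_width > 0)
  if (is.null(t_end)) {
    last <- if (n_spikes(train)) max(train$timestamps) else 0
    t_end <- t_start + bin_width * max(1, ceiling((last - t_start) /
                                                    bin_width + 1e-12))
  }
  stopifnot(t_end > t_start)
  nbins <- as.integer(ceiling((t_end - t_start) / bin_width - 1e-12))
  ts <- train$timestamps
  ts <- ts[ts >= t_start & ts < t_end]
  counts <- tabulate(floor((ts - t_start) / bin_width) + 1L, nbins = nbins)
  rate_series(counts / bin_width, bin_width, t_start)
}

#' Per-stage summary of basal firing rates
#'
#' Takes one mean rate per 2-h basal recording and summarises by estrous
#' stage as mean and SEM (sd / sqrt(n recordings)) across recordings.
#'
#' @param recordings data.frame with columns `stage` and `rate_hz` (one row
#'   per recording); optional `neuron_id` and `mouse_id` columns are
#'   counted into `n_neurons` / `n_mice`
#' @return data.frame with columns `stage`, `mean_rate`, `sem_rate`,
#'   `n_recordings` (and counts when available), one row per non-empty
#'   stage in cycle order
#' @export
stage_summary <- function(recordings) {
  stopifnot(is.data.frame(recordings),
            all(c("stage", "rate_hz") %in% names(recordings)))
  seen <- intersect(STAGES, unique(recordings$stage))
  missing <- setdiff(unique(recordings$stage), STAGES)
  if (length(missing)) stop("unknown stage: ", missing[1L])
  empty <- setdiff(STAGES, seen)
  if (length(empty))
    warning("no recordings for stage(s): ", paste(empty, collapse = ", "))
  rows <- lapply(seen, function(st) {
    r <- recordings[recordings$stage == st, , drop = FALSE]
    out <- data.frame(stage = st, mean_rate = mean(r$rate_hz),
                      sem_rate = if (nrow(r) > 1L)
                        stats::sd(r$rate_hz) / sqrt(nrow(r)) else 0,
                      n_recordings = nrow(r))
    if ("neuron_id" %in% names(r))
      out$n_neurons <- length(unique(r$neuron_id))
    if ("mouse_id" %in% names(r))
      out$n_mice <- length(unique(r$mouse_id))
    out
  })
  do.call(rbind, rows)
}

#' Mean rate of a session's single unit over the basal window
#'
#' Convenience for [stage_summary()]: mean firing rate of the first unit
#' over the whole session span.
#'
#' @param session a [gnrh_session()]
#' @return rate in Hz
#' @export
session_mean_rate <- function(session) {
  stopifnot(inherits(session, "gnrh_session"))
  mean_rate(session$trains[[1L]], 0, session$events$duration)
}

#' Elevation index of a 20-h hourly rate series
#'
#' Operationalises "surge-like" activity: the maximum mean rate over any
#' contiguous `window_bins`-hour block, divided by the rate in the
#' early-afternoon anchor hour (14:00-15:00). An index near 1 indicates a
#' flat day; the surge envelope's peak/baseline ratio is about 2.
#'
#' @param rs a [rate_series()] with 3600-s bins spanning >= 20 h
#' @param clock the session's [session_clock()] (used to locate the anchor
#'   hour)
#' @param window_bins width of the sliding maximum window, in hourly bins
#' @param anchor_clock "HH:MM" start of the denominator hour
#' @return the elevation index (ratio), or NA with a warning when the
#'   anchor-hour rate is zero
#' @export
surge_index <- function(rs, clock, window_bins = 3L,
                        anchor_clock = "14:00") {
  stopifnot(inherits(rs, "rate_series"), inherits(clock, "session_clock"))
  if (rs$bin_width != 3600)
    stop("surge_index expects hourly (3600 s) bins")
  if (length(rs$rates) < 20L)
    stop("surge_index needs a full 20-h session (>= 20 hourly bins)")
  anchor_s <- rs$t_start +
    (clock_to_session(anchor_clock, clock) - rs$t_start) %% 86400
  i0 <- (anchor_s - rs$t_start) / 3600 + 1
  if (abs(i0 - round(i0)) > 1e-9 || round(i0) > length(rs$rates))
    stop("anchor hour ", anchor_clock, " does not align with a bin")
  denom <- rs$rates[round(i0)]
  if (denom == 0) {
    warning("anchor-hour rate is zero; elevation index undefined")
    return(NA_real_)
  }
  n <- length(rs$rates)
  w <- as.integer(window_bins)
  stopifnot(w >= 1L, w <= n)
  csum <- cumsum(c(0, rs$rates))
  win_means <- (csum[(w + 1L):(n + 1L)] - csum[1L:(n - w + 1L)]) / w
  max(win_means) / denom
}

#' Classify a unit as surge-like or basal-rhythmic from a 20-h pair
#'
#' A unit is surge-like when its proestrus elevation index reaches the
#' threshold `kappa` while its diestrus index stays below it; everything
#' else is basal-rhythmic. Both series must span 20 h at 3600-s bins.
#'
#' @param proestrus_rs,diestrus_rs hourly [rate_series()] for the paired
#'   proestrus and diestrus recordings of one unit
#' @param clock the shared [session_clock()] (sessions anchored 14:00)
#' @param kappa elevation-index threshold (default 1.5, below the ~2.0
#'   peak/baseline ratio of the surge envelope)
#' @param ... passed to [surge_index()]
#' @return list with `subtype` ("surge_like" | "basal_rhythmic" | NA),
#'   `EI_proestrus`, `EI_diestrus`, `kappa`
#' @export
classify_surge <- function(proestrus_rs, diestrus_rs,
                           clock = session_clock("14:00"), kappa = 1.5,
                           ...) {
  ei_p <- surge_index(proestrus_rs, clock, ...)
  ei_d <- surge_index(diestrus_rs, clock, ...)
  subtype <- if (is.na(ei_p) || is.na(ei_d)) {
    warning("elevation index undefined; unit unclassifiable")
    NA_character_
  } else if (ei_p >= kappa && ei_d < kappa) "surge_like" else
    "basal_rhythmic"
  list(subtype = subtype, EI_proestrus = ei_p, EI_diestrus = ei_d,
       kappa = kappa)
}

#' Hourly mean +/- SEM profile across surge-unit recordings
#'
#' Element-wise mean and SEM of a set of equal-length hourly rate series,
#' with the peak of the mean profile and its clock hour.
#'
#' @param series_list list of [rate_series()] with identical bin width,
#'   start and length
#' @param clock a [session_clock()] used to label bins with clock time
#' @return list with `profile` (data.frame: t_s, clock, mean_hz, sem_hz),
#'   `peak_hz`, `peak_clock`, `n`
#' @export
surge_profile_summary <- function(series_list,
                                  clock = session_clock("14:00")) {
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, TRUE, "rate_series")))
  lens <- vapply(series_list, function(s) length(s$rates), integer(1L))
  bws <- vapply(series_list, `[[`, numeric(1L), "bin_width")
  starts <- vapply(series_list, `[[`, numeric(1L), "t_start")
  if (length(unique(lens)) != 1L || length(unique(bws)) != 1L ||
      length(unique(starts)) != 1L)
    stop("all rate series must share length, bin width and start time")
  m <- do.call(rbind, lapply(series_list, `[[`, "rates"))
  mu <- colMeans(m)
  sem <- if (nrow(m) > 1L) apply(m, 2L, stats::sd) / sqrt(nrow(m)) else
    rep(0, ncol(m))
  t_s <- starts[1L] + (seq_along(mu) - 1L) * bws[1L]
  peak_i <- which.max(mu)
  list(profile = data.frame(t_s = t_s,
                            clock = session_to_clock(t_s, clock),
                            mean_hz = mu, sem_hz = sem),
       peak_hz = mu[peak_i],
       peak_clock = session_to_clock(t_s[peak_i], clock),
       n = nrow(m))
}

#' Duration features of a biphasic spike waveform
#'
#' Locates the global trough, the left peak (maximum before the trough)
#' and the right peak (maximum after it), and measures three durations:
#' left peak to trough, trough to right peak, and the half-width - the
#' time between the two points on the trough lobe whose amplitude equals
#' the trough plus half the maximum peak-to-peak amplitude, with linear
#' interpolation between samples.
#'
#' @param samples numeric waveform, uV
#' @param sample_rate Hz
#' @return list with `left_peak_to_trough_ms`, `trough_to_right_peak_ms`,
#'   `half_width_ms`
#' @export
waveform_features <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  n <- length(samples)
  stopifnot(sample_rate > 0)
  if (n < 3L || diff(range(samples)) == 0)
    stop("waveform is flat or too short to be biphasic")
  i_tr <- which.min(samples)
  if (i_tr <= 1L || i_tr >= n)
    stop("waveform trough at the edge: not a biphasic spike")
  i_lp <- which.max(samples[1:(i_tr - 1L)])
  i_rp <- i_tr + which.max(samples[(i_tr + 1L):n])
  if (samples[i_tr] >= 0 || samples[i_lp] <= 0 || samples[i_rp] <= 0)
    stop("waveform is not biphasic (needs positive peaks flanking a ",
         "negative trough)")
  p2p <- max(samples) - samples[i_tr]
  level <- samples[i_tr] + p2p / 2

  # left crossing: walk from the trough toward the left peak
  j <- i_tr - 1L
  while (j >= i_lp && samples[j] < level) j <- j - 1L
  if (j < i_lp) stop("half-amplitude level not crossed on the left lobe")
  t_left <- if (samples[j] == level) j else
    j + (samples[j] - level) / (samples[j] - samples[j + 1L])

  # right crossing: walk from the trough toward the right peak
  j <- i_tr + 1L
  while (j <= i_rp && samples[j] < level) j <- j + 1L
  if (j > i_rp) stop("half-amplitude level not crossed on the right lobe")
  t_right <- if (samples[j] == level) j else
    (j - 1L) + (level - samples[j - 1L]) / (samples[j] - samples[j - 1L])

  ms_per_sample <- 1000 / sample_rate
  list(left_peak_to_trough_ms = (i_tr - i_lp) * ms_per_sample,
       trough_to_right_peak_ms = (i_rp - i_tr) * ms_per_sample,
       half_width_ms = (t_right - t_left) * ms_per_sample)
}
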