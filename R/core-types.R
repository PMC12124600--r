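STAGES <- c("metestrus", "diestrus", "proestrus", "estrus")
DRUGS  <- c("Kiss10", "Kiss54", "CNO", "Kiss10+CNO", "saline")

#' Parse a "HH:MM" clock string to seconds after midnight
#' @param x character, e.g. "14:00"
#' @return numeric seconds in [0, 86400)
#' @keywords internal
parse_clock <- function(x) {
  if (!is.character(x) || length(x) != 1L || !grepl("^\\d{1,2}:\\d{2}$", x))
    stop("clock time must be a single \"HH:MM\" string, got: ", deparse(x))
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1L]])
  if (parts[1L] > 23L || parts[2L] > 59L)
    stop("clock time out of range: ", x)
  parts[1L] * 3600 + parts[2L] * 60
}

format_clock <- function(sec) {
  sec <- as.integer(round(sec)) %% 86400L
  sprintf("%02d:%02d", sec %/% 3600L, (sec %% 3600L) %/% 60L)
}

#' Session clock: anchor session time 0 to a time of day
#'
#' All analysis windows are offsets in seconds from the start of a recording
#' session; the clock maps those offsets back to wall-clock time so that
#' circadian anchors (lights-off, the midnight surge peak) can be located.
#' Mice are housed with lights on 07:00--19:00.
#'
#' @param t0_clock time of day of session second 0, "HH:MM"
#' @param lights_on,lights_off light-cycle boundaries, "HH:MM"
#' @return a `session_clock` object
#' @export
#' @examples
#' clk <- session_clock("14:00")
#' clock_to_session("19:00", clk)  # lights-off, 5 h in -> 18000
session_clock <- function(t0_clock = "14:00", lights_on = "07:00",
                          lights_off = "19:00") {
  for (x in c(t0_clock, lights_on, lights_off)) parse_clock(x)
  if (parse_clock(lights_on) == parse_clock(lights_off))
    stop("lights_on and lights_off must differ")
  structure(list(t0_clock = t0_clock, lights_on = lights_on,
                 lights_off = lights_off),
            class = "session_clock")
}

#' Convert a time of day to seconds from session start
#'
#' The mapping wraps past midnight, so for a session anchored at 14:00 a
#' query of "10:00" refers to 10:00 the next morning (72000 s), matching the
#' 20-h overnight recording convention (14:00 until 10:00 the following day).
#'
#' @param clock_time "HH:MM" time of day
#' @param clock a [session_clock()]
#' @return seconds from session start in [0, 86400)
#' @export
clock_to_session <- function(clock_time, clock) {
  stopifnot(inherits(clock, "session_clock"))
  (parse_clock(clock_time) - parse_clock(clock$t0_clock)) %% 86400
}

#' Convert seconds from session start to a time of day
#' @param t seconds from session start (t >= 0)
#' @param clock a [session_clock()]
#' @return "HH:MM" string
#' @export
session_to_clock <- function(t, clock) {
  stopifnot(inherits(clock, "session_clock"), all(t >= 0))
  vapply(t, function(ti) format_clock(parse_clock(clock$t0_clock) + ti),
         character(1L))
}

#' Spike train of one sorted unit
#'
#' Timestamps are seconds from session start, strictly increasing. An
#' optional snippet matrix stores the per-spike voltage waveform (uV), one
#' row per spike, trough-aligned; `sample_rate` is required with snippets.
#'
#' @param unit_id character label (typically channel-derived, e.g. "ch05")
#' @param timestamps numeric vector, seconds, strictly increasing, >= 0
#' @param snippets optional numeric matrix, `length(timestamps)` rows
#' @param sample_rate snippet sampling rate in Hz (snippets only)
#' @return a `spike_train` object
#' @export
spike_train <- function(unit_id, timestamps = numeric(), snippets = NULL,
                        sample_rate = NULL) {
  timestamps <- as.numeric(timestamps)
  if (any(!is.finite(timestamps)))
    stop("unit ", unit_id, ": non-finite timestamps")
  if (length(timestamps) && any(timestamps < 0))
    stop("unit ", unit_id, ": negative timestamps")
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("unit ", unit_id, ": timestamps must be strictly increasing")
  if (!is.null(snippets)) {
    snippets <- as.matrix(snippets)
    if (nrow(snippets) != length(timestamps))
      stop("unit ", unit_id, ": snippets must have one row per timestamp")
    if (is.null(sample_rate) || sample_rate <= 0)
      stop("unit ", unit_id, ": sample_rate required with snippets")
  }
  structure(list(unit_id = as.character(unit_id), timestamps = timestamps,
                 snippets = snippets, sample_rate = sample_rate),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes%s>\n", x$unit_id,
              length(x$timestamps),
              if (is.null(x$snippets)) "" else ", with snippets"))
  invisible(x)
}

#' Number of spikes in a train
#' @param train a [spike_train()]
#' @return integer count
#' @export
n_spikes <- function(train) length(train$timestamps)

#' Mean firing rate of a train over a window
#' @param train a [spike_train()]
#' @param t_start,t_end window in session seconds; spikes are counted in
#'   the half-open interval `[t_start, t_end)`
#' @return rate in Hz
#' @export
mean_rate <- function(train, t_start, t_end) {
  stopifnot(t_end > t_start)
  sum(train$timestamps >= t_start & train$timestamps < t_end) /
    (t_end - t_start)
}

#' Session protocol events
#'
#' Clock-anchored description of one recording session: estrous stage,
#' intraperitoneal injections, and total duration.
#'
#' @param stage one of "metestrus", "diestrus", "proestrus", "estrus"
#' @param injections data.frame with columns `drug` (one of "Kiss10",
#'   "Kiss54", "CNO", "Kiss10+CNO", "saline") and `t_s` (session seconds)
#' @param duration session length in seconds
#' @param clock a [session_clock()]
#' @return a `session_events` object
#' @export
session_events <- function(stage, injections = NULL, duration,
                           clock = session_clock()) {
  stage <- match.arg(stage, STAGES)
  if (is.null(injections))
    injections <- data.frame(drug = character(), t_s = numeric())
  stopifnot(is.data.frame(injections),
            all(c("drug", "t_s") %in% names(injections)),
            inherits(clock, "session_clock"), duration > 0)
  if (nrow(injections)) {
    bad <- !(injections$drug %in% DRUGS)
    if (any(bad)) stop("unknown drug: ", injections$drug[bad][1L])
    if (any(injections$t_s < 0 | injections$t_s > duration))
      stop("injection time outside [0, duration]")
  }
  structure(list(stage = stage,
                 injections = injections[order(injections$t_s), ,
                                         drop = FALSE],
                 duration = as.numeric(duration), clock = clock),
            class = "session_events")
}

#' Continuous extracellular voltage trace
#'
#' @param samples numeric matrix, one column per channel (a vector is
#'   treated as a single channel), values in uV
#' @param sample_rate sampling rate in Hz
#' @param channel_ids character vector, one per channel
#' @return a `continuous_trace` object
#' @export
continuous_trace <- function(samples, sample_rate, channel_ids = NULL) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  if (any(!is.finite(samples))) stop("trace contains non-finite samples")
  stopifnot(sample_rate > 0)
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(ncol(samples)))
  stopifnot(length(channel_ids) == ncol(samples))
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 channel_ids = as.character(channel_ids)),
            class = "continuous_trace")
}

#' Binned firing-rate series
#'
#' Bins are half-open `[t, t + bin_width)`: a spike exactly on a boundary
#' belongs to the later bin, which makes the count-conservation identity
#' `sum(rates) * bin_width == n_spikes` exact for integer-aligned spans.
#'
#' @param rates numeric vector of rates in Hz, all >= 0
#' @param bin_width bin width in seconds (5, 300 and 3600 s are the
#'   conventional choices)
#' @param t_start session time of the first bin's left edge, seconds
#' @return a `rate_series` object
#' @export
rate_series <- function(rates, bin_width, t_start = 0) {
  rates <- as.numeric(rates)
  stopifnot(bin_width > 0, all(is.finite(rates)), all(rates >= 0))
  structure(list(rates = rates, bin_width = as.numeric(bin_width),
                 t_start = as.numeric(t_start)),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series: %d bins of %gs from t=%gs, mean %.3f Hz>\n",
              length(x$rates), x$bin_width, x$t_start, mean(x$rates)))
  invisible(x)
}

#' Bundle spike trains, events and an optional raw trace into a session
#'
#' @param trains list of [spike_train()] objects
#' @param events a [session_events()]
#' @param trace optional [continuous_trace()]
#' @param seed RNG seed recorded in the manifest for generated sessions
#' @return a `gnrh_session` object
#' @export
gnrh_session <- function(trains, events, trace = NULL, seed = NULL) {
  stopifnot(is.list(trains), all(vapply(trains, inherits, TRUE, "spike_train")),
            inherits(events, "session_events"))
  if (!is.null(trace)) stopifnot(inherits(trace, "continuous_trace"))
  ids <- vapply(trains, `[[`, character(1L), "unit_id")
  if (anyDuplicated(ids)) stop("duplicate unit_id in session")
  names(trains) <- ids
  structure(list(trains = trains, events = events, trace = trace,
                 seed = seed),
            class = "gnrh_session")
}

#' @export
print.gnrh_session <- function(x, ...) {
  cat(sprintf("<gnrh_session: %d unit(s), stage %s, %.0f s%s>\n",
              length(x$trains), x$events$stage, x$events$duration,
              if (is.null(x$trace)) "" else ", raw trace"))
  invisible(x)
}
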