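# Biphasic waveform templates. A template is a piecewise-linear breakpoint
# curve (time in ms relative to the trough, amplitude in uV); the
# half-amplitude crossings are themselves breakpoints, so the calibrated
# durations survive sampling and linear-interpolation feature measurement.

#' Biphasic spike-template configuration
#'
#' Extracellular GnRH-neuron spikes are biphasic: a small positive left
#' peak, a dominant negative trough, and a positive right peak, ~1 ms
#' overall.
#'
#' @param left_peak_uv,trough_uv,right_peak_uv amplitudes in uV
#'   (`trough_uv < 0 < left_peak_uv, right_peak_uv`)
#' @param left_peak_to_trough_ms,trough_to_right_peak_ms,half_width_ms
#'   target duration features in ms (see [waveform_features()])
#' @param sample_rate rendering rate, Hz (default 30 kHz, the rate implied
#'   by the 1/30 ms quantum of the reported durations)
#' @param lead_ms,tail_ms flat-zero margins before the left peak onset and
#'   after the right peak return
#' @return a `template_config` object
#' @export
template_config <- function(left_peak_uv = 40, trough_uv = -120,
                            right_peak_uv = 60,
                            left_peak_to_trough_ms = 0.3667,
                            trough_to_right_peak_ms = 0.4,
                            half_width_ms = 0.2,
                            sample_rate = 30000,
                            lead_ms = 0.2, tail_ms = 0.2) {
  stopifnot(trough_uv < 0, left_peak_uv > 0, right_peak_uv > 0,
            sample_rate > 0, lead_ms > 0, tail_ms > 0)
  structure(list(left_peak_uv = left_peak_uv, trough_uv = trough_uv,
                 right_peak_uv = right_peak_uv,
                 left_peak_to_trough_ms = left_peak_to_trough_ms,
                 trough_to_right_peak_ms = trough_to_right_peak_ms,
                 half_width_ms = half_width_ms,
                 sample_rate = sample_rate,
                 lead_ms = lead_ms, tail_ms = tail_ms,
                 breakpoints = NULL),
            class = "template_config")
}

template_breakpoints <- function(config) {
  lp <- config$left_peak_to_trough_ms
  rp <- config$trough_to_right_peak_ms
  hw <- config$half_width_ms
  if (hw <= 0) stop("half-width target must be positive")
  if (hw / 2 >= min(lp, rp))
    stop("infeasible targets: half-width exceeds the peak separation")
  p2p_max <- max(config$left_peak_uv, config$right_peak_uv)
  level <- config$trough_uv + (p2p_max - config$trough_uv) / 2
  if (level >= min(config$left_peak_uv, config$right_peak_uv))
    stop("infeasible amplitudes: half-amplitude level above a peak")
  # snap breakpoints to the sample grid so peaks and half-amplitude
  # crossings land exactly on rendered samples (error <= half a sample)
  fs_ms <- config$sample_rate / 1000
  snap <- function(t) round(t * fs_ms) / fs_ms
  t_ms <- c(snap(-lp) - config$lead_ms, snap(-lp), snap(-hw / 2), 0,
            snap(hw / 2), snap(rp), snap(rp) + config$tail_ms)
  if (is.unsorted(t_ms, strictly = TRUE))
    stop("infeasible targets: breakpoints collapse at this sample rate")
  data.frame(t_ms = t_ms,
             uv = c(0, config$left_peak_uv, level, config$trough_uv, level,
                    config$right_peak_uv, 0))
}

#' Calibrate a template so its measured duration features hit targets
#'
#' Constructs the piecewise-linear breakpoint curve whose rendered waveform
#' reproduces the target left-peak-to-trough, trough-to-right-peak and
#' half-width durations under [waveform_features()] to within one sample
#' period. A config whose existing breakpoints already conform is returned
#' unchanged (fixed point).
#'
#' @param targets optional list/vector with elements `left_peak_to_trough_ms`,
#'   `trough_to_right_peak_ms`, `half_width_ms`; defaults to the targets
#'   already in `config`
#' @param config a [template_config()]
#' @return the calibrated `template_config` (with `$breakpoints` set)
#' @export
calibrate_template <- function(targets = NULL, config = template_config()) {
  stopifnot(inherits(config, "template_config"))
  if (!is.null(targets)) {
    targets <- as.list(targets)
    for (f in c("left_peak_to_trough_ms", "trough_to_right_peak_ms",
                "half_width_ms"))
      if (!is.null(targets[[f]])) config[[f]] <- targets[[f]]
  }
  tol <- 1000 / config$sample_rate  # one sample period, ms
  if (!is.null(config$breakpoints)) {
    got <- waveform_features(render_template(config)$samples,
                             config$sample_rate)
    if (abs(got$left_peak_to_trough_ms - config$left_peak_to_trough_ms) <= tol &&
        abs(got$trough_to_right_peak_ms - config$trough_to_right_peak_ms) <= tol &&
        abs(got$half_width_ms - config$half_width_ms) <= tol)
      return(config)
  }
  config$breakpoints <- template_breakpoints(config)
  got <- waveform_features(render_template(config)$samples,
                           config$sample_rate)
  if (abs(got$left_peak_to_trough_ms - config$left_peak_to_trough_ms) > tol ||
      abs(got$trough_to_right_peak_ms - config$trough_to_right_peak_ms) > tol ||
      abs(got$half_width_ms - config$half_width_ms) > tol)
    stop("template calibration failed to reach targets at this sample rate")
  config
}

#' Render a template configuration to voltage samples
#'
#' Samples the breakpoint curve on a grid aligned so the trough falls
#' exactly on a sample.
#'
#' @param config a calibrated [template_config()] (uncalibrated configs are
#'   calibrated on the fly)
#' @return list with `samples` (uV), `sample_rate` (Hz) and `trough_index`
#' @export
render_template <- function(config) {
  stopifnot(inherits(config, "template_config"))
  bp <- config$breakpoints
  if (is.null(bp)) bp <- template_breakpoints(config)
  fs_ms <- config$sample_rate / 1000  # samples per ms
  k <- seq.int(floor(bp$t_ms[1L] * fs_ms), ceiling(bp$t_ms[nrow(bp)] * fs_ms))
  v <- stats::approx(bp$t_ms, bp$uv, xout = k / fs_ms, yleft = 0,
                     yright = 0)$y
  list(samples = v, sample_rate = config$sample_rate,
       trough_index = which(k == 0L))
}
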