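# Rate model: lambda(t) = base(t) * oscillation(t) * prod(drug kernels)
# base(t) is the stage baseline (flat) or, for surge-subtype proestrus
# sessions, an absolute piecewise-cosine surge envelope.

#' Default basal firing rates by estrous stage (Hz)
#'
#' Mean basal rates of identified GnRH neurons recorded 10:00-12:00 across
#' the cycle: highest on proestrus, lowest on estrus.
#'
#' @return named numeric vector (metestrus, diestrus, proestrus, estrus)
#' @export
stage_baselines <- function() {
  c(metestrus = 5.76, diestrus = 6.05, proestrus = 9.10, estrus = 4.55)
}

#' Default proestrus surge envelope parameters
#'
#' A gradual rise in firing starting around 15:00 (4 h before lights-off),
#' peaking near midnight, and returning to a lower baseline by 08:00.
#'
#' @return list of clock anchors and rates (Hz)
#' @export
surge_defaults <- function() {
  list(onset_clock = "15:00", peak_clock = "00:00", end_clock = "08:00",
       baseline_hz = 8.54, peak_hz = 17.12, return_hz = 6.59)
}

#' Default multiplicative drug-response kernels
#'
#' Trapezoidal envelopes on the baseline rate. Kiss-10 produces a short
#' robust excitation (rise 60 s, plateau 600 s, decay 1200 s); CNO in the
#' hM3D(Gq) model a prolonged excitation (plateau 5400 s); in the hM4D(Gi)
#' model prior CNO attenuates the second Kiss-10 response, modelled as the
#' Kiss-10 gain scaled by `(1 + cno_gi_gain)` with `cno_gi_gain = -0.8`.
#'
#' @param kiss10_gain peak fractional rate increase for Kiss-10 (2 = +200%)
#' @param cno_gq_gain peak fractional increase for CNO under hM3D(Gq)
#' @param cno_gi_gain fractional suppression applied to the Kiss-10 gain
#'   when CNO precedes it under hM4D(Gi); must be > -1
#' @return named list of kernels (one per drug label)
#' @export
drug_kernel_defaults <- function(kiss10_gain = 2.0, cno_gq_gain = 1.0,
                                 cno_gi_gain = -0.8) {
  stopifnot(cno_gi_gain > -1)
  list(
    "Kiss10" = list(latency_s = 0, rise_s = 60, plateau_s = 600,
                    decay_s = 1200, gain = kiss10_gain),
    "CNO" = list(latency_s = 0, rise_s = 60, plateau_s = 5400,
                 decay_s = 1200, gain = cno_gq_gain),
    "Kiss10+CNO" = list(latency_s = 0, rise_s = 60, plateau_s = 600,
                        decay_s = 1200,
                        gain = kiss10_gain * (1 + cno_gi_gain)),
    "saline" = list(latency_s = 0, rise_s = 60, plateau_s = 600,
                    decay_s = 1200, gain = 0)
  )
}

#' Rate profile of one simulated unit
#'
#' @param baseline_hz flat baseline rate (Hz); ignored when `surge` is set
#'   except as the oscillation reference
#' @param surge NULL, or a list as returned by [surge_defaults()]; when
#'   present the base rate follows the absolute surge envelope
#' @param oscillation NULL, or `list(amplitude_hz, period_s, phase)` for
#'   basal-rhythmic units (sinusoidal modulation)
#' @param kernels named list of drug kernels (subset of
#'   [drug_kernel_defaults()]); empty for non-responders
#' @return a `rate_profile` object
#' @export
rate_profile <- function(baseline_hz, surge = NULL, oscillation = NULL,
                         kernels = list()) {
  stopifnot(baseline_hz >= 0)
  if (!is.null(surge)) {
    stopifnot(surge$peak_hz >= surge$baseline_hz,
              surge$baseline_hz >= 0, surge$return_hz >= 0)
  }
  if (!is.null(oscillation)) {
    oscillation$phase <- oscillation$phase %||% 0
    stopifnot(oscillation$amplitude_hz >= 0, oscillation$period_s > 0)
  }
  for (k in kernels) stopifnot(k$gain > -1)
  structure(list(baseline_hz = baseline_hz, surge = surge,
                 oscillation = oscillation, kernels = kernels),
            class = "rate_profile")
}

# trapezoidal envelope in [0,1]; u is time since (injection + latency)
trapezoid_env <- function(u, rise, plateau, decay) {
  out <- numeric(length(u))
  if (rise > 0) {
    i <- u >= 0 & u < rise
    out[i] <- u[i] / rise
  }
  i <- u >= rise & u < rise + plateau
  out[i] <- 1
  if (decay > 0) {
    i <- u >= rise + plateau & u < rise + plateau + decay
    out[i] <- 1 - (u[i] - rise - plateau) / decay
  }
  out
}

# half-cosine ramp from a to b as s goes 0 -> 1
cos_ramp <- function(s, a, b) a + (b - a) * (1 - cos(pi * pmin(pmax(s, 0), 1))) / 2

#' Build the firing-intensity function lambda(t) of a unit
#'
#' Composes baseline (or surge envelope), sinusoidal oscillation, and the
#' multiplicative drug kernels attached to the session's injections into a
#' vectorised intensity function in Hz. With no modulation the function is
#' identically the baseline.
#'
#' @param profile a [rate_profile()]
#' @param events a [session_events()]; injection times and the session
#'   clock come from here
#' @return function of session time t (vectorised), returning Hz (>= 0)
#' @export
build_rate_function <- function(profile, events) {
  stopifnot(inherits(profile, "rate_profile"),
            inherits(events, "session_events"))
  clk <- events$clock
  dur <- events$duration

  if (!is.null(profile$surge)) {
    sg <- profile$surge
    t_on <- clock_to_session(sg$onset_clock, clk)
    t_pk <- clock_to_session(sg$peak_clock, clk)
    t_end <- clock_to_session(sg$end_clock, clk)
    if (!(t_on < t_pk && t_pk < t_end))
      stop("surge clock anchors must be ordered onset < peak < end ",
           "within the session")
    if (t_pk > dur)
      stop("surge peak falls outside the session span")
    base_fn <- function(t) {
      out <- numeric(length(t))
      out[t < t_on] <- sg$baseline_hz
      i <- t >= t_on & t < t_pk
      out[i] <- cos_ramp((t[i] - t_on) / (t_pk - t_on),
                         sg$baseline_hz, sg$peak_hz)
      i <- t >= t_pk & t < t_end
      out[i] <- cos_ramp((t[i] - t_pk) / (t_end - t_pk),
                         sg$peak_hz, sg$return_hz)
      out[t >= t_end] <- sg$return_hz
      out
    }
  } else {
    base_fn <- function(t) rep(profile$baseline_hz, length(t))
  }

  osc <- profile$oscillation
  ref <- if (!is.null(profile$surge)) profile$surge$baseline_hz else
    profile$baseline_hz
  osc_fn <- if (is.null(osc) || ref <= 0) function(t) 1 else
    function(t) 1 + (osc$amplitude_hz / ref) *
      sin(2 * pi * t / osc$period_s + osc$phase)

  inj <- events$injections
  kern_fn <- function(t) {
    f <- rep(1, length(t))
    if (!nrow(inj) || !length(profile$kernels)) return(f)
    for (i in seq_len(nrow(inj))) {
      k <- profile$kernels[[inj$drug[i]]]
      if (is.null(k)) next
      f <- f * (1 + k$gain *
                  trapezoid_env(t - inj$t_s[i] - k$latency_s,
                                k$rise_s, k$plateau_s, k$decay_s))
    }
    f
  }

  function(t) pmax(0, base_fn(t) * osc_fn(t) * kern_fn(t))
}
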