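#' Sample a spike train from an intensity function
#'
#' Inhomogeneous Poisson process by thinning, followed by an absolute dead
#' time (greedy censoring: any spike closer than `refractory_s` to the last
#' kept spike is removed). The intensity is rescaled as
#' `lambda = f / (1 - f * refractory_s)` so that `rate_fn` specifies the
#' *observed* firing rate after dead-time censoring; with `refractory_s = 0`
#' the process is exactly Poisson with intensity `rate_fn`.
#'
#' @param rate_fn vectorised intensity function of session time (Hz),
#'   e.g. from [build_rate_function()]
#' @param duration session length, seconds
#' @param refractory_s absolute dead time, seconds (default 2 ms)
#' @param seed integer RNG seed; NULL leaves the RNG state alone
#' @param unit_id label for the resulting train
#' @return a [spike_train()]
#' @export
sample_spike_train <- function(rate_fn, duration, refractory_s = 0.002,
                               seed = NULL, unit_id = "u01") {
  stopifnot(duration > 0, refractory_s >= 0)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, duration, length.out = min(50001L, max(1001L,
                                                        ceiling(duration) + 1L)))
  lam_obs <- rate_fn(grid)
  if (any(!is.finite(lam_obs)) || any(lam_obs < 0))
    stop("rate function must be finite and non-negative on [0, duration]")
  if (max(lam_obs) <= 0)
    return(spike_train(unit_id, numeric()))
  if (refractory_s > 0 && max(lam_obs) * refractory_s >= 1)
    warning("refractory period >= 1 / sup(rate): rate saturation, ",
            "requested rate cannot be attained")
  comp <- function(l) if (refractory_s > 0)
    l / (1 - pmin(l * refractory_s, 0.99)) else l
  lam_max <- max(comp(lam_obs)) * 1.05
  n_cand <- stats::rpois(1L, lam_max * duration)
  if (n_cand == 0L) return(spike_train(unit_id, numeric()))
  tc <- sort(stats::runif(n_cand, 0, duration))
  keep <- stats::runif(n_cand) < comp(rate_fn(tc)) / lam_max
  t <- unique(tc[keep])
  if (refractory_s > 0 && length(t) > 1L) {
    repeat {
      d <- diff(t)
      bad <- which(d < refractory_s)
      if (!length(bad)) break
      bad <- bad[c(TRUE, diff(bad) > 1L)]  # first offender of each run
      t <- t[-(bad + 1L)]
    }
  }
  spike_train(unit_id, t)
}

#' Synthesize a raw extracellular trace from spike trains
#'
#' Inserts a per-unit waveform template (trough-aligned) at every spike
#' time on a single channel and adds white Gaussian noise. The input trains
#' are the ground truth for testing the detection/sorting stages.
#'
#' @param trains list of [spike_train()] ground-truth trains
#' @param templates list (same length) of rendered templates from
#'   [render_template()], or numeric sample vectors with a `trough_index`
#'   attribute
#' @param noise_sd_uv white-noise standard deviation, uV
#' @param sample_rate Hz
#' @param duration trace length, seconds
#' @param seed integer RNG seed for the noise
#' @return list with `trace` (a [continuous_trace()]) and `truth` (the
#'   input trains)
#' @export
synthesize_trace <- function(trains, templates, noise_sd_uv = 5,
                             sample_rate = 30000, duration, seed = NULL) {
  stopifnot(length(trains) == length(templates), duration > 0,
            noise_sd_uv >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sample_rate)
  v <- if (noise_sd_uv > 0) stats::rnorm(n, 0, noise_sd_uv) else numeric(n)
  for (u in seq_along(trains)) {
    tpl <- templates[[u]]
    samp <- if (is.list(tpl)) tpl$samples else as.numeric(tpl)
    trough <- if (is.list(tpl)) tpl$trough_index else attr(tpl, "trough_index")
    if (is.null(trough)) trough <- which.min(samp)
    ts <- trains[[u]]$timestamps
    if (length(ts) > 1L &&
        min(diff(ts)) < (length(samp) - 1) / sample_rate)
      stop("unit ", trains[[u]]$unit_id,
           ": inter-spike interval shorter than template; ",
           "insertions would overlap")
    centre <- round(ts * sample_rate) + 1L
    offs <- seq_along(samp) - trough
    for (ci in centre) {
      idx <- ci + offs
      ok <- idx >= 1L & idx <= n
      if (!all(ok)) next  # spike too close to the trace edge
      v[idx] <- v[idx] + samp
    }
  }
  list(trace = continuous_trace(v, sample_rate), truth = trains)
}

#' Cohort configuration for the synthetic generator
#'
#' @param n_units number of recorded units (or recordings, for the
#'   stage-basal protocol)
#' @param n_responders number of ground-truth GnRH responders (gi/gq
#'   protocols)
#' @param n_surge,n_basal subtype split for the surge-pair protocol;
#'   `n_surge + n_basal` units are generated
#' @param stage estrous stage for the stage-basal protocol
#' @param rate_cv between-recording lognormal coefficient of variation on
#'   unit rates (mean-preserving); 0 disables
#' @param seed integer seed; cohort generation is a pure function of
#'   (config, seed)
#' @param baselines named stage-baseline vector, default [stage_baselines()]
#' @param surge surge envelope list, default [surge_defaults()]
#' @param kernels drug-kernel list, default [drug_kernel_defaults()]
#' @param osc_period_s,osc_amp_frac basal-rhythmic oscillation period and
#'   relative amplitude
#' @return a `cohort_config` object
#' @export
cohort_config <- function(n_units = 0L, n_responders = 0L,
                          n_surge = 0L, n_basal = 0L,
                          stage = "diestrus", rate_cv = 0.1, seed = 1L,
                          baselines = stage_baselines(),
                          surge = surge_defaults(),
                          kernels = drug_kernel_defaults(),
                          osc_period_s = 7200, osc_amp_frac = 0.3) {
  stopifnot(n_responders <= n_units, n_units >= 0, n_surge >= 0,
            n_basal >= 0, rate_cv >= 0)
  structure(list(n_units = as.integer(n_units),
                 n_responders = as.integer(n_responders),
                 n_surge = as.integer(n_surge),
                 n_basal = as.integer(n_basal),
                 stage = match.arg(stage, STAGES),
                 rate_cv = rate_cv, seed = as.integer(seed),
                 baselines = baselines, surge = surge, kernels = kernels,
                 osc_period_s = osc_period_s, osc_amp_frac = osc_amp_frac),
            class = "cohort_config")
}

# mean-preserving lognormal multiplier with coefficient of variation cv
rate_jitter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Generate a synthetic cohort with ground-truth labels
#'
#' Protocols:
#' \describe{
#'   \item{gi}{hM4D(Gi) identification sessions: Kiss-10 at 1800 s, then
#'     Kiss-10+CNO 60 min later. Responders carry the Kiss-10 kernel and a
#'     CNO-attenuated second kernel; non-responders carry none.}
#'   \item{gq}{hM3D(Gq) sessions: Kiss-10 at 1800 s, CNO 60 min later;
#'     responders are excited by both.}
#'   \item{surge_pair}{paired 20-h proestrus + diestrus sessions anchored
#'     at 14:00; surge-subtype units follow the surge envelope on
#'     proestrus, basal-rhythmic units oscillate identically on both days.}
#'   \item{stage_basal}{independent 2-h basal recordings (10:00-12:00) at
#'     the configured stage's baseline rate.}
#' }
#'
#' Ground truth is always emitted alongside the sessions and never
#' inferred from the data.
#'
#' @param config a [cohort_config()]
#' @param protocol one of "gi", "gq", "surge_pair", "stage_basal"
#' @return list with `sessions` (for surge_pair a list of
#'   `list(proestrus=, diestrus=)` pairs, otherwise a list of
#'   [gnrh_session()]), `truth` (data.frame), and `protocol`
#' @export
generate_cohort <- function(config,
                            protocol = c("gi", "gq", "surge_pair",
                                         "stage_basal")) {
  stopifnot(inherits(config, "cohort_config"))
  protocol <- match.arg(protocol)
  set.seed(config$seed)

  if (protocol %in% c("gi", "gq")) {
    n <- config$n_units
    if (n == 0L)
      return(list(sessions = list(),
                  truth = data.frame(unit_id = character(),
                                     is_responder = logical()),
                  protocol = protocol))
    responder <- rep(FALSE, n)
    if (config$n_responders > 0L)
      responder[sample.int(n, config$n_responders)] <- TRUE
    second_drug <- if (protocol == "gi") "Kiss10+CNO" else "CNO"
    inj <- data.frame(drug = c("Kiss10", second_drug), t_s = c(1800, 5400))
    duration <- 9000
    base <- config$baselines[[config$stage]] * rate_jitter(n, config$rate_cv)
    ids <- sprintf("u%03d", seq_len(n))
    kern_resp <- config$kernels[c("Kiss10", second_drug)]
    seeds <- sample.int(.Machine$integer.max, n)
    sessions <- lapply(seq_len(n), function(i) {
      ev <- session_events(config$stage, inj, duration,
                           session_clock("10:00"))
      prof <- rate_profile(base[i],
                           kernels = if (responder[i]) kern_resp else list())
      train <- sample_spike_train(build_rate_function(prof, ev), duration,
                                  seed = seeds[i], unit_id = ids[i])
      gnrh_session(list(train), ev, seed = seeds[i])
    })
    return(list(sessions = sessions,
                truth = data.frame(unit_id = ids, is_responder = responder),
                protocol = protocol))
  }

  if (protocol == "surge_pair") {
    n <- config$n_surge + config$n_basal
    if (n == 0L)
      return(list(sessions = list(),
                  truth = data.frame(unit_id = character(),
                                     subtype = character()),
                  protocol = protocol))
    subtype <- sample(c(rep("surge_like", config$n_surge),
                        rep("basal_rhythmic", config$n_basal)))
    ids <- sprintf("u%03d", seq_len(n))
    clk <- session_clock("14:00")
    duration <- 72000  # 14:00 -> 10:00 next day
    jit <- rate_jitter(n, config$rate_cv)
    phases <- stats::runif(n, 0, 2 * pi)
    seeds <- matrix(sample.int(.Machine$integer.max, 2L * n), ncol = 2L)
    di_base <- config$baselines[["diestrus"]]
    sessions <- lapply(seq_len(n), function(i) {
      if (subtype[i] == "surge_like") {
        sg <- config$surge
        sg$baseline_hz <- sg$baseline_hz * jit[i]
        sg$peak_hz <- sg$peak_hz * jit[i]
        sg$return_hz <- sg$return_hz * jit[i]
        prof_pro <- rate_profile(sg$baseline_hz, surge = sg)
        prof_di <- rate_profile(di_base * jit[i])
      } else {
        osc <- function(b) list(amplitude_hz = config$osc_amp_frac * b,
                                period_s = config$osc_period_s,
                                phase = phases[i])
        b <- di_base * jit[i]
        prof_pro <- rate_profile(b, oscillation = osc(b))
        prof_di <- prof_pro
      }
      ev_pro <- session_events("proestrus", NULL, duration, clk)
      ev_di <- session_events("diestrus", NULL, duration, clk)
      list(proestrus = gnrh_session(
             list(sample_spike_train(build_rate_function(prof_pro, ev_pro),
                                     duration, seed = seeds[i, 1L],
                                     unit_id = ids[i])),
             ev_pro, seed = seeds[i, 1L]),
           diestrus = gnrh_session(
             list(sample_spike_train(build_rate_function(prof_di, ev_di),
                                     duration, seed = seeds[i, 2L],
                                     unit_id = ids[i])),
             ev_di, seed = seeds[i, 2L]))
    })
    return(list(sessions = sessions,
                truth = data.frame(unit_id = ids, subtype = subtype),
                protocol = protocol))
  }

  # stage_basal: n_units independent 2-h recordings at the stage baseline
  n <- config$n_units
  if (n == 0L)
    return(list(sessions = list(),
                truth = data.frame(unit_id = character(),
                                   rate_hz = numeric()),
                protocol = protocol))
  ids <- sprintf("u%03d", seq_len(n))
  base <- config$baselines[[config$stage]] * rate_jitter(n, config$rate_cv)
  seeds <- sample.int(.Machine$integer.max, n)
  duration <- 7200  # 10:00 -> 12:00
  clk <- session_clock("10:00")
  sessions <- lapply(seq_len(n), function(i) {
    ev <- session_events(config$stage, NULL, duration, clk)
    train <- sample_spike_train(build_rate_function(rate_profile(base[i]),
                                                    ev),
                                duration, seed = seeds[i], unit_id = ids[i])
    gnrh_session(list(train), ev, seed = seeds[i])
  })
  list(sessions = sessions,
       truth = data.frame(unit_id = ids, rate_hz = base),
       protocol = protocol)
}
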