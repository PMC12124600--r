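# Spike detection and sorting: 300 Hz high-pass -> amplitude threshold
# (fixed 64 uV or 2x robust noise) -> trough alignment -> PCA + amplitude /
# width / energy features -> k-means with silhouette model selection ->
# cluster quality control.

#' Detection and sorting parameters
#'
#' @param highpass_hz high-pass cutoff, Hz (default 300)
#' @param threshold_uv fixed amplitude threshold, uV (default 64); used
#'   when `threshold_mode = "fixed"`
#' @param threshold_mode "fixed" (64 uV convention) or "2x_noise" (twice
#'   the robust background-noise estimate)
#' @param pre_ms,post_ms snippet window before/after the trough, ms
#' @param merge_ms refractory merge window: threshold crossings closer
#'   than this collapse to the largest-amplitude event
#' @param min_snippets,max_isi_violation,isi_floor_s cluster QC: minimum
#'   snippet count and maximum fraction of inter-spike intervals below the
#'   refractory floor
#' @param min_silhouette smallest average silhouette at which a multi-
#'   cluster solution is preferred over a single cluster
#' @return a `detection_params` object
#' @export
detection_params <- function(highpass_hz = 300, threshold_uv = 64,
                             threshold_mode = c("fixed", "2x_noise"),
                             pre_ms = 0.4, post_ms = 0.8, merge_ms = 1.0,
                             min_snippets = 50L, max_isi_violation = 0.01,
                             isi_floor_s = 0.002, min_silhouette = 0.6) {
  stopifnot(highpass_hz > 0, threshold_uv > 0, pre_ms > 0, post_ms > 0,
            merge_ms >= 0)
  structure(list(highpass_hz = highpass_hz, threshold_uv = threshold_uv,
                 threshold_mode = match.arg(threshold_mode),
                 pre_ms = pre_ms, post_ms = post_ms, merge_ms = merge_ms,
                 min_snippets = as.integer(min_snippets),
                 max_isi_violation = max_isi_violation,
                 isi_floor_s = isi_floor_s,
                 min_silhouette = min_silhouette),
            class = "detection_params")
}

as_trace_matrix <- function(trace) {
  if (inherits(trace, "continuous_trace"))
    list(x = trace$samples, fs = trace$sample_rate)
  else stop("expected a continuous_trace")
}

#' Zero-phase 4th-order Butterworth high-pass filter
#'
#' Forward-backward filtering (zero phase distortion, squared magnitude
#' response); length-preserving. Applied per channel.
#'
#' @param trace a [continuous_trace()], or a numeric vector with
#'   `sample_rate` given
#' @param f_c cutoff frequency, Hz (default 300)
#' @param sample_rate required when `trace` is a bare vector
#' @return filtered object of the same type
#' @export
highpass <- function(trace, f_c = 300, sample_rate = NULL) {
  if (is.numeric(trace)) {
    stopifnot(!is.null(sample_rate))
    trace <- continuous_trace(trace, sample_rate)
    bare <- TRUE
  } else bare <- FALSE
  tm <- as_trace_matrix(trace)
  if (f_c >= tm$fs / 2)
    stop("high-pass cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, f_c / (tm$fs / 2), type = "high")
  out <- apply(tm$x, 2L, function(ch) signal::filtfilt(bf, ch))
  res <- continuous_trace(matrix(out, ncol = ncol(tm$x)), tm$fs,
                          trace$channel_ids)
  if (bare) as.vector(res$samples) else res
}

#' Robust background-noise estimate
#'
#' `sigma = median(|v|) / 0.6745`, the median-based estimator that is
#' insensitive to sparse large spikes riding on the noise floor. Intended
#' for high-passed traces with at least ~1 s of data.
#'
#' @param x numeric vector (one channel, uV)
#' @return noise SD estimate, uV
#' @export
estimate_noise <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("cannot estimate noise from an empty trace")
  stats::median(abs(x)) / 0.6745
}

#' Detect spike events by amplitude threshold
#'
#' Finds negative-going local minima below `-theta` (extracellular troughs)
#' on a high-passed channel, where `theta` is the fixed 64 uV threshold or
#' twice the robust noise estimate in `2x_noise` mode. Candidates within
#' the refractory merge window collapse to the single largest-amplitude
#' event (most negative trough first).
#'
#' @param x numeric high-passed channel, uV
#' @param sample_rate Hz
#' @param params a [detection_params()]
#' @return numeric vector of event (trough) times in seconds; empty when
#'   nothing crosses threshold
#' @export
detect_events <- function(x, sample_rate, params = detection_params()) {
  x <- as.numeric(x)
  n <- length(x)
  theta <- if (params$threshold_mode == "2x_noise")
    2 * estimate_noise(x) else params$threshold_uv
  if (n < 3L) return(numeric())
  below <- x < -theta
  is_min <- c(FALSE, x[2:(n - 1L)] <= x[1:(n - 2L)] &
                x[2:(n - 1L)] < x[3:n], FALSE)
  cand <- which(below & is_min)
  if (!length(cand)) return(numeric())
  merge_n <- params$merge_ms / 1000 * sample_rate
  keep <- logical(length(cand))
  ord <- order(x[cand])  # most negative first
  kept_idx <- numeric(0)
  for (i in ord) {
    if (!length(kept_idx) || all(abs(kept_idx - cand[i]) >= merge_n)) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, cand[i])
    }
  }
  sort((cand[keep] - 1L)) / sample_rate
}

#' Extract trough-aligned snippets around detected events
#'
#' Each snippet spans `[-pre_ms, +post_ms)` around its trough sample, with
#' the trough re-localised to the minimum within +/-0.2 ms of the event
#' and placed at a fixed row index. Events too close to the trace edge are
#' dropped (recorded in the `dropped` attribute).
#'
#' @param x numeric high-passed channel, uV
#' @param sample_rate Hz
#' @param event_times event times in seconds, e.g. from [detect_events()]
#' @param params a [detection_params()]
#' @return matrix (events x samples) with attributes `trough_index`,
#'   `times` (aligned trough times, s) and `dropped` (count)
#' @export
extract_align <- function(x, sample_rate, event_times,
                          params = detection_params()) {
  x <- as.numeric(x)
  n <- length(x)
  n_pre <- round(params$pre_ms / 1000 * sample_rate)
  n_post <- round(params$post_ms / 1000 * sample_rate)
  len <- n_pre + n_post
  r <- round(0.2 / 1000 * sample_rate)
  rows <- list()
  times <- numeric()
  dropped <- 0L
  for (t in event_times) {
    i <- round(t * sample_rate) + 1L
    lo <- max(1L, i - r)
    hi <- min(n, i + r)
    i <- lo + which.min(x[lo:hi]) - 1L
    a <- i - n_pre + 1L
    b <- i + n_post
    if (a < 1L || b > n) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- x[a:b]
    times <- c(times, (i - 1L) / sample_rate)
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0L, len)
  structure(m, trough_index = n_pre, times = times, dropped = dropped)
}

#' Feature matrix for spike sorting
#'
#' First `n_pc` principal-component scores of the mean-centred snippets,
#' concatenated with peak-to-peak amplitude (uV), width (trough to right
#' peak, ms) and energy (sum of squared voltage x sample period,
#' uV^2 ms). Missing components (fewer snippets than components) are
#' zero-padded.
#'
#' @param snippets matrix from [extract_align()] (events x samples)
#' @param sample_rate Hz
#' @param n_pc number of principal components (default 3)
#' @return numeric matrix (events x (n_pc + 3)) with named columns
#' @export
snippet_features <- function(snippets, sample_rate, n_pc = 3L) {
  snippets <- as.matrix(snippets)
  n <- nrow(snippets)
  if (n < 2L) stop("need at least 2 snippets to build features")
  pcs <- matrix(0, n, n_pc)
  pr <- stats::prcomp(snippets, center = TRUE, scale. = FALSE)
  k <- min(n_pc, ncol(pr$x))
  if (k > 0L) pcs[, seq_len(k)] <- pr$x[, seq_len(k)]
  trough_i <- attr(snippets, "trough_index")
  width_ms <- apply(snippets, 1L, function(v) {
    ti <- if (!is.null(trough_i)) trough_i else which.min(v)
    if (ti >= length(v)) return(0)
    (which.max(v[(ti + 1L):length(v)])) * 1000 / sample_rate
  })
  amp <- apply(snippets, 1L, function(v) max(v) - min(v))
  energy <- rowSums(snippets^2) * 1000 / sample_rate
  out <- cbind(pcs, amp, width_ms, energy)
  colnames(out) <- c(paste0("PC", seq_len(n_pc)), "amplitude_uv",
                     "width_ms", "energy_uv2ms")
  if (any(!is.finite(out))) stop("non-finite feature values")
  out
}

#' Cluster snippets into putative units
#'
#' k-means over `k_range` on standardised features, with k chosen by the
#' largest average silhouette; a single cluster is retained when no
#' multi-cluster solution reaches `min_silhouette`. Clusters failing QC
#' (fewer than `min_snippets` members, or more than `max_isi_violation`
#' of inter-event intervals under `isi_floor_s`) are discarded as noise
#' (assignment NA).
#'
#' @param features matrix from [snippet_features()]
#' @param k_range candidate cluster counts (default 1:5)
#' @param seed integer seed; the result is deterministic for a fixed seed
#' @param times optional event times (s) enabling the ISI QC rule
#' @param params a [detection_params()] carrying the QC thresholds
#' @return list with `assignments` (integer vector, NA = discarded),
#'   `k`, `silhouette`, `qc` (per-cluster data.frame)
#' @export
cluster_units <- function(features, k_range = 1:5, seed = 1L,
                          times = NULL, params = detection_params()) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 1L) stop("no feature rows to cluster")
  set.seed(seed)
  # raw feature scales carry the separation signal (amplitude, energy);
  # standardising would inflate pure-noise dimensions
  X <- features
  ks <- k_range[k_range >= 2L & k_range < n]
  best <- list(k = 1L, sil = NA_real_,
               cl = rep(1L, n))
  if (length(ks) && n >= 3L) {
    d <- stats::dist(X)
    sil_best <- -Inf
    for (k in ks) {
      km <- stats::kmeans(X, centers = k, nstart = 10L, iter.max = 100L)
      if (min(km$size) < params$min_snippets) next  # would fail QC anyway
      s <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
      if (s > sil_best) {
        sil_best <- s
        best <- list(k = k, sil = s, cl = km$cluster)
      }
    }
    if ((1L %in% k_range) && sil_best < params$min_silhouette)
      best <- list(k = 1L, sil = sil_best, cl = rep(1L, n))
  }
  cl <- best$cl
  qc <- do.call(rbind, lapply(sort(unique(cl)), function(g) {
    idx <- which(cl == g)
    isi_viol <- if (!is.null(times) && length(idx) > 1L)
      mean(diff(sort(times[idx])) < params$isi_floor_s) else 0
    data.frame(cluster = g, n_snippets = length(idx),
               isi_violation = isi_viol,
               pass = length(idx) >= params$min_snippets &&
                 isi_viol <= params$max_isi_violation)
  }))
  assignments <- cl
  assignments[cl %in% qc$cluster[!qc$pass]] <- NA_integer_
  if (all(is.na(assignments)))
    warning("all clusters failed quality control; no units retained")
  list(assignments = assignments, k = best$k, silhouette = best$sil,
       qc = qc)
}

#' End-to-end sorting of a raw trace into spike trains
#'
#' Runs the full chain (high-pass, threshold detection, alignment,
#' features, clustering, QC) on each channel and returns one
#' [spike_train()] per retained cluster, with snippets attached, plus a
#' per-channel sorting report.
#'
#' @param trace a [continuous_trace()]
#' @param params a [detection_params()]
#' @param k_range,seed passed to [cluster_units()]
#' @return list with `trains` and `report` (per-cluster counts,
#'   silhouette, QC verdicts, threshold mode used)
#' @export
sort_trace <- function(trace, params = detection_params(), k_range = 1:5,
                       seed = 1L) {
  tm <- as_trace_matrix(trace)
  filt <- highpass(trace, params$highpass_hz)
  trains <- list()
  report <- list()
  for (ch in seq_len(ncol(tm$x))) {
    x <- filt$samples[, ch]
    ev <- detect_events(x, tm$fs, params)
    if (length(ev) < 2L) next
    sn <- extract_align(x, tm$fs, ev, params)
    if (nrow(sn) < 2L) next
    fe <- snippet_features(sn, tm$fs)
    clu <- cluster_units(fe, k_range, seed, times = attr(sn, "times"),
                         params = params)
    times <- attr(sn, "times")
    for (g in sort(unique(stats::na.omit(clu$assignments)))) {
      idx <- which(clu$assignments == g)
      uid <- sprintf("%s_c%d", trace$channel_ids[ch], g)
      trains[[uid]] <- spike_train(uid, times[idx],
                                   snippets = sn[idx, , drop = FALSE],
                                   sample_rate = tm$fs)
    }
    report[[trace$channel_ids[ch]]] <-
      list(n_events = length(ev), k = clu$k, silhouette = clu$silhouette,
           qc = clu$qc, threshold_mode = params$threshold_mode)
  }
  list(trains = trains, report = report)
}
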