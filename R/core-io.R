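# Session directory layout:
#   events.json    stage, t0_clock, lights, duration_s, injections, unit roster
#   spikes.csv     unit_id,timestamp_s            (full float precision)
#   snippets.csv   unit_id,spike_index,sample_index,uv   (optional)
#   trace.bin      little-endian float32, channel-major  (optional)
#   trace.json     sidecar: sample_rate_hz, n_channels, channel_ids, units
#   manifest.json  file list + RNG seed

fmt_num <- function(x) sprintf("%.17g", x)

write_json_file <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(txt, path)
}

#' Save a session to a directory
#'
#' Writes plain-text CSV/JSON (and a raw float32 binary for the trace) in a
#' deterministic byte-stable form: saving the same session twice yields
#' byte-identical files, and timestamps survive a save/load round trip
#' bit-exactly.
#'
#' @param session a [gnrh_session()]
#' @param path directory to create/write into
#' @return the manifest (list of files written plus the recorded seed),
#'   invisibly
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "gnrh_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)
  files <- character()

  ev <- session$events
  snip_rate <- NULL
  for (tr in session$trains)
    if (!is.null(tr$snippets)) snip_rate <- tr$sample_rate
  ev_list <- list(stage = ev$stage,
                  t0_clock = ev$clock$t0_clock,
                  lights_on = ev$clock$lights_on,
                  lights_off = ev$clock$lights_off,
                  duration_s = ev$duration,
                  injections = ev$injections,
                  units = I(names(session$trains)))
  if (!is.null(snip_rate)) ev_list$snippet_sample_rate_hz <- snip_rate
  write_json_file(ev_list, file.path(path, "events.json"))
  files <- c(files, "events.json")

  sp <- do.call(rbind, lapply(session$trains, function(tr) {
    if (!length(tr$timestamps)) return(NULL)
    data.frame(unit_id = tr$unit_id, timestamp_s = fmt_num(tr$timestamps))
  }))
  con <- file(file.path(path, "spikes.csv"), "wb")
  writeLines("unit_id,timestamp_s", con)
  if (!is.null(sp)) writeLines(paste(sp$unit_id, sp$timestamp_s, sep = ","), con)
  close(con)
  files <- c(files, "spikes.csv")

  snip_rows <- lapply(session$trains, function(tr) {
    if (is.null(tr$snippets) || !nrow(tr$snippets)) return(NULL)
    s <- tr$snippets
    data.frame(unit_id = tr$unit_id,
               spike_index = rep(seq_len(nrow(s)), each = ncol(s)),
               sample_index = rep(seq_len(ncol(s)), times = nrow(s)),
               uv = fmt_num(as.vector(t(s))))
  })
  snip_rows <- snip_rows[!vapply(snip_rows, is.null, TRUE)]
  if (length(snip_rows)) {
    sn <- do.call(rbind, snip_rows)
    con <- file(file.path(path, "snippets.csv"), "wb")
    writeLines("unit_id,spike_index,sample_index,uv", con)
    writeLines(paste(sn$unit_id, sn$spike_index, sn$sample_index, sn$uv,
                     sep = ","), con)
    close(con)
    files <- c(files, "snippets.csv")
  }

  if (!is.null(session$trace)) {
    tr <- session$trace
    con <- file(file.path(path, "trace.bin"), "wb")
    writeBin(as.vector(tr$samples), con, size = 4L, endian = "little")
    close(con)
    write_json_file(list(sample_rate_hz = tr$sample_rate,
                         n_channels = ncol(tr$samples),
                         n_samples = nrow(tr$samples),
                         channel_ids = I(tr$channel_ids),
                         units = "uV"),
                    file.path(path, "trace.json"))
    files <- c(files, "trace.bin", "trace.json")
  }

  manifest <- list(files = I(sort(files)), seed = session$seed)
  write_json_file(manifest, file.path(path, "manifest.json"))
  invisible(manifest)
}

#' Load a session from a directory
#'
#' Inverse of [save_session()]. The directory must contain `events.json`
#' and at least one of `spikes.csv` or `trace.bin` (the latter with its
#' JSON sidecar). All type invariants are re-validated on load; unsorted
#' timestamps raise an error naming the offending unit.
#'
#' @param path session directory
#' @return a [gnrh_session()]
#' @export
load_session <- function(path) {
  ev_path <- file.path(path, "events.json")
  if (!file.exists(ev_path)) stop("missing events.json in ", path)
  ev <- jsonlite::fromJSON(readLines(ev_path, warn = FALSE))
  inj <- ev$injections
  if (is.null(inj) || !length(inj))
    inj <- data.frame(drug = character(), t_s = numeric())
  events <- session_events(stage = ev$stage, injections = inj,
                           duration = ev$duration_s,
                           clock = session_clock(ev$t0_clock,
                                                 ev$lights_on %||% "07:00",
                                                 ev$lights_off %||% "19:00"))

  sp_path <- file.path(path, "spikes.csv")
  tr_path <- file.path(path, "trace.bin")
  if (!file.exists(sp_path) && !file.exists(tr_path))
    stop("session at ", path, " has neither spikes.csv nor trace.bin")

  trains <- list()
  if (file.exists(sp_path)) {
    sp <- utils::read.csv(sp_path, colClasses = c("character", "numeric"))
    roster <- as.character(ev$units %||% unique(sp$unit_id))
    snips <- NULL
    sn_path <- file.path(path, "snippets.csv")
    if (file.exists(sn_path))
      snips <- utils::read.csv(sn_path,
                               colClasses = c("character", "integer",
                                              "integer", "numeric"))
    trains <- lapply(roster, function(uid) {
      ts <- sp$timestamp_s[sp$unit_id == uid]
      sm <- NULL
      rate <- NULL
      if (!is.null(snips) && any(snips$unit_id == uid)) {
        su <- snips[snips$unit_id == uid, ]
        sm <- matrix(su$uv[order(su$spike_index, su$sample_index)],
                     nrow = max(su$spike_index), byrow = TRUE)
        rate <- ev$snippet_sample_rate_hz
      }
      spike_train(uid, ts, snippets = sm, sample_rate = rate)
    })
  }

  trace <- NULL
  if (file.exists(tr_path)) {
    side_path <- file.path(path, "trace.json")
    if (!file.exists(side_path))
      stop("trace.bin present without trace.json sidecar in ", path)
    side <- jsonlite::fromJSON(readLines(side_path, warn = FALSE))
    n_total <- side$n_channels * side$n_samples
    con <- file(tr_path, "rb")
    v <- readBin(con, "numeric", n = n_total, size = 4L, endian = "little")
    close(con)
    if (length(v) != n_total) stop("trace.bin truncated in ", path)
    trace <- continuous_trace(matrix(v, ncol = side$n_channels),
                              side$sample_rate_hz,
                              as.character(side$channel_ids))
  }

  seed <- NULL
  mf_path <- file.path(path, "manifest.json")
  if (file.exists(mf_path))
    seed <- jsonlite::fromJSON(readLines(mf_path, warn = FALSE))$seed
  gnrh_session(trains, events, trace = trace, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
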