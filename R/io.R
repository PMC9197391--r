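# On-disk format: one directory per recording containing a JSON sidecar
# (recording.json) plus one CSV per sweep.  Current-clamp sweep files carry
# the header "time_ms,voltage_mV,command_pA"; voltage-clamp files carry
# "time_ms,current_pA,command_mV" (the measured channel is current).  Plain
# text throughout, so fixtures are diffable and dependency-free.

sidecar_name <- "recording.json"

signal_header <- function(clamp_mode) {
  if (clamp_mode == "current_clamp") c("time_ms", "voltage_mV", "command_pA")
  else c("time_ms", "current_pA", "command_mV")
}

#' Write a recording to a sweep directory
#'
#' Lays out one CSV per sweep plus a `recording.json` sidecar naming cell id,
#' clamp mode, condition, dt, opsin flag, leak/seal metadata, and the sweep
#' files in order.  Numeric fields are serialized at full precision so a
#' read-back equals the original to better than 1e-9 relative.
#'
#' @param rec an `ephys_recording`.
#' @param path directory to create (must not be an existing non-empty
#'   recording unless `overwrite = TRUE`).
#' @param overwrite replace an existing directory.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, overwrite = FALSE) {
  stopifnot(inherits(rec, "ephys_recording"))
  if (dir.exists(path)) {
    if (!overwrite && length(dir(path)) > 0)
      stop("write_recording: '", path, "' exists and is non-empty")
  } else if (!dir.create(path, recursive = TRUE)) {
    stop("write_recording: cannot create '", path, "'")
  }
  nsw <- length(rec$sweeps)
  files <- sprintf("sweep_%03d.csv", seq_len(nsw))
  hdr <- signal_header(rec$clamp_mode)
  for (i in seq_len(nsw)) {
    sw <- rec$sweeps[[i]]
    dt <- data.table::data.table(t = trace_times(sw$signal),
                                 s = sw$signal$samples,
                                 c = sw$command$samples)
    data.table::setnames(dt, hdr)
    data.table::fwrite(dt, file.path(path, files[i]))
  }
  meta <- list(
    cell_id = rec$cell_id,
    clamp_mode = rec$clamp_mode,
    condition = rec$condition,
    dt_ms = recording_dt(rec),
    opsin = rec$opsin_expressing,
    leak_pA = rec$leak_pA,
    seal_Gohm = rec$seal_Gohm,
    sweeps = lapply(seq_len(nsw), function(i) {
      sw <- rec$sweeps[[i]]
      list(file = files[i], protocol_tag = sw$protocol_tag,
           step_amplitude_pA = sw$step_amplitude,
           t0_ms = sw$signal$t0)
    }))
  jsonlite::write_json(meta, file.path(path, sidecar_name),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a recording from a sweep directory
#'
#' Inverse of [write_recording()].  Sweep order follows the sidecar.
#'
#' @param path directory holding `recording.json` and sweep CSVs.
#' @return An `ephys_recording`.
#' @export
read_recording <- function(path) {
  sc <- file.path(path, sidecar_name)
  if (!file.exists(sc))
    stop("read_recording: missing sidecar '", sc, "' (format error)")
  meta <- jsonlite::read_json(sc, simplifyVector = FALSE)
  dt_ms <- as.numeric(meta$dt_ms)
  kind <- if (meta$clamp_mode == "current_clamp") "voltage" else "current"
  cmd_kind <- if (meta$clamp_mode == "current_clamp") "current" else "voltage"
  sweeps <- lapply(meta$sweeps, function(sm) {
    f <- file.path(path, sm$file)
    if (!file.exists(f)) stop("read_recording: missing sweep file '", f, "'")
    tab <- data.table::fread(f)
    if (ncol(tab) != 3L)
      stop("read_recording: '", f, "' must have 3 columns")
    sig <- tab[[2]]; cmd <- tab[[3]]
    if (anyNA(sig) || !all(is.finite(sig)))
      stop(sprintf("read_recording: non-finite sample in '%s' row %d",
                   f, which(!is.finite(sig))[1L]))
    if (nrow(tab) >= 2L) {
      dt_obs <- (tab[[1]][nrow(tab)] - tab[[1]][1L]) / (nrow(tab) - 1L)
      if (abs(dt_obs - dt_ms) > 1e-6 * max(dt_ms, 1))
        stop(sprintf(paste0("read_recording: sweep '%s' sampled at %g ms but ",
                            "sidecar declares dt %g ms (consistency error)"),
                     f, dt_obs, dt_ms))
    }
    t0 <- if (!is.null(sm$t0_ms)) as.numeric(sm$t0_ms) else tab[[1]][1L]
    sweep(trace(sig, dt_ms, kind, t0 = t0),
          trace(cmd, dt_ms, cmd_kind, t0 = t0),
          protocol_tag = sm$protocol_tag,
          step_amplitude = if (is.null(sm$step_amplitude_pA)) NA_real_
                           else as.numeric(sm$step_amplitude_pA))
  })
  recording(meta$cell_id, meta$clamp_mode, meta$condition, sweeps,
            opsin_expressing = isTRUE(meta$opsin),
            leak_pA = if (is.null(meta$leak_pA)) NA_real_ else as.numeric(meta$leak_pA),
            seal_Gohm = if (is.null(meta$seal_Gohm)) NA_real_ else as.numeric(meta$seal_Gohm))
}

#' Write a recorded pair (pre/post subdirectories plus pair.json)
#' @param pair an `ephys_pair`.
#' @param path directory to create.
#' @param overwrite replace an existing directory.
#' @return `path`, invisibly.
#' @export
write_pair_recording <- function(pair, path, overwrite = FALSE) {
  stopifnot(inherits(pair, "ephys_pair"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("write_pair_recording: cannot create '", path, "'")
  write_recording(pair$pre, file.path(path, "pre"), overwrite = overwrite)
  write_recording(pair$post, file.path(path, "post"), overwrite = overwrite)
  jsonlite::write_json(list(pair_id = pair$pair_id,
                            alignment_offset_ms = pair$alignment_offset),
                       file.path(path, "pair.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a recorded pair written by [write_pair_recording()]
#' @param path pair directory.
#' @return An `ephys_pair`.
#' @export
read_pair_recording <- function(path) {
  pj <- file.path(path, "pair.json")
  if (!file.exists(pj))
    stop("read_pair_recording: missing '", pj, "' (format error)")
  meta <- jsonlite::read_json(pj, simplifyVector = TRUE)
  pair_recording(read_recording(file.path(path, "pre")),
                 read_recording(file.path(path, "post")),
                 alignment_offset = as.numeric(meta$alignment_offset_ms),
                 pair_id = meta$pair_id)
}
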