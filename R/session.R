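#' Recording-session container
#'
#' Ties together multichannel LFP, channel metadata, sorted spike units, head
#' accelerometer traces and session metadata (drug, injection time). All times
#' are seconds from recording start (float); LFP is microvolts; accelerometer
#' is g.
#'
#' @param lfp numeric matrix, channels x samples, microvolts.
#' @param fs_lfp LFP sampling rate, Hz.
#' @param channels data.frame with columns `channel_id` (unique integers),
#'   `structure` (anatomical label, e.g. "vStr", "mPFC", "OB"), `hemisphere`
#'   ("left"/"right"), `electrode_group` (integer bundle id) and optional
#'   stereotaxic coordinates `ap`, `ml`, `dv` in mm.
#' @param units list of spike units as returned by [spike_unit()]; may be
#'   empty.
#' @param accel optional 3 x samples matrix in g (rows AP, ML, DV).
#' @param fs_accel accelerometer sampling rate, Hz (required when `accel`
#'   given).
#' @param injection_time drug injection time in seconds from recording start,
#'   or `NA` for baseline-only sessions.
#' @param drug one of "LSD", "DOI", "ketamine", "PCP", "amphetamine", "none".
#' @param drug_class one of "5HT2A", "NMDA", "amphetamine", "baseline-only".
#' @return object of class `hfo_session`.
#' @export
session <- function(lfp, fs_lfp, channels, units = list(), accel = NULL,
                    fs_accel = NULL, injection_time = NA_real_,
                    drug = "none", drug_class = "baseline-only") {
  s <- structure(
    list(lfp = lfp, fs_lfp = fs_lfp, channels = channels, units = units,
         accel = accel, fs_accel = fs_accel,
         injection_time = injection_time, drug = drug,
         drug_class = drug_class),
    class = "hfo_session"
  )
  validate_session(s)
  s
}

#' Construct a spike unit
#'
#' @param unit_id unit identifier (string or integer).
#' @param spike_times sorted spike times, seconds from recording start.
#' @param electrode `channel_id` of the electrode the unit was sorted on.
#' @param waveform optional mean extracellular waveform, microvolts
#'   (negative-first convention).
#' @param wf_fs waveform sampling rate, Hz.
#' @param cell_type "PC", "IN", "X" or "unset".
#' @return object of class `spike_unit`.
#' @export
spike_unit <- function(unit_id, spike_times, electrode, waveform = NULL,
                       wf_fs = NULL, cell_type = "unset") {
  stopifnot(!is.unsorted(spike_times))
  structure(
    list(unit_id = as.character(unit_id), spike_times = as.numeric(spike_times),
         electrode = electrode, waveform = waveform, wf_fs = wf_fs,
         cell_type = cell_type),
    class = "spike_unit"
  )
}

#' Validate a session object
#'
#' Checks the structural invariants: LFP row count matches the channel table,
#' channel ids are unique, sampling rates are positive, spike times and the
#' injection time fall inside the recording.
#'
#' @param s an `hfo_session`.
#' @return `s`, invisibly; stops with a validation error otherwise.
#' @export
validate_session <- function(s) {
  if (!is.matrix(s$lfp)) stop("session validation: lfp must be a matrix")
  if (!is.numeric(s$fs_lfp) || length(s$fs_lfp) != 1L || s$fs_lfp <= 0)
    stop("session validation: fs_lfp must be a positive scalar")
  if (nrow(s$lfp) != nrow(s$channels))
    stop(sprintf("session validation: lfp has %d rows but channel table lists %d channels",
                 nrow(s$lfp), nrow(s$channels)))
  if (anyDuplicated(s$channels$channel_id))
    stop("session validation: duplicate channel_id")
  dur <- ncol(s$lfp) / s$fs_lfp
  for (u in s$units) {
    if (length(u$spike_times) && (min(u$spike_times) < 0 ||
                                  max(u$spike_times) > dur))
      stop(sprintf("session validation: unit %s has spike times outside the recording",
                   u$unit_id))
  }
  if (!is.na(s$injection_time) &&
      (s$injection_time < 0 || s$injection_time > dur))
    stop("session validation: injection_time outside the recording")
  if (!is.null(s$accel)) {
    if (is.null(s$fs_accel) || s$fs_accel <= 0)
      stop("session validation: accel present but fs_accel missing or <= 0")
    if (nrow(s$accel) != 3L)
      stop("session validation: accel must have 3 rows (AP, ML, DV)")
  }
  invisible(s)
}

#' Session duration in seconds
#' @param s an `hfo_session`.
#' @return duration, seconds.
#' @export
session_duration <- function(s) ncol(s$lfp) / s$fs_lfp

#' @export
print.hfo_session <- function(x, ...) {
  cat(sprintf("<hfo_session> %d channels x %.0f s @ %g Hz | %d units | drug=%s (%s) | injection=%s s\n",
              nrow(x$lfp), session_duration(x), x$fs_lfp, length(x$units),
              x$drug, x$drug_class,
              ifelse(is.na(x$injection_time), "NA",
                     format(x$injection_time))))
  cat("structures:", paste(unique(x$channels$structure), collapse = ", "), "\n")
  invisible(x)
}

#' Write a session to an on-disk container
#'
#' The container is a directory holding plain-text blocks mirroring a
#' hierarchical layout: `meta.json` (fs, drug, drug_class, injection_time,
#' accelerometer axis names), `channels.csv`, `lfp.csv` (samples x channels,
#' one column per channel id), optional `accel.csv`, and `units.json` (spike
#' times, electrode, waveform per unit). Numeric values are stored with 15
#' significant digits, so round trips are lossless well beyond single
#' precision.
#'
#' @param s an `hfo_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "hfosync-session", version = 1L,
               fs_lfp = s$fs_lfp, fs_accel = s$fs_accel,
               injection_time = s$injection_time,
               drug = s$drug, drug_class = s$drug_class,
               accel_axes = c("AP", "ML", "DV"))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  data.table::fwrite(s$channels, file.path(path, "channels.csv"))
  lfp_dt <- data.table::as.data.table(t(s$lfp))
  data.table::setnames(lfp_dt, paste0("ch", s$channels$channel_id))
  data.table::fwrite(lfp_dt, file.path(path, "lfp.csv"))
  if (!is.null(s$accel)) {
    acc_dt <- data.table::as.data.table(t(s$accel))
    data.table::setnames(acc_dt, c("AP", "ML", "DV"))
    data.table::fwrite(acc_dt, file.path(path, "accel.csv"))
  }
  units <- lapply(s$units, function(u) {
    list(unit_id = u$unit_id, electrode = u$electrode,
         cell_type = u$cell_type, wf_fs = u$wf_fs,
         spike_times = u$spike_times, waveform = u$waveform)
  })
  jsonlite::write_json(units, file.path(path, "units.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a session container
#'
#' Inverse of [write_session()]. Optional blocks (`accel.csv`, units) may be
#' absent; a malformed container raises a format error naming the missing
#' dataset.
#'
#' @param path container directory.
#' @return an `hfo_session`.
#' @export
read_session <- function(path) {
  need <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p))
      stop(sprintf("read_session: malformed container, missing dataset '%s'", f))
    p
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  if (is.null(meta$fs_lfp) || !is.numeric(meta$fs_lfp) || meta$fs_lfp <= 0)
    stop("read_session: validation error, fs_lfp missing or <= 0")
  channels <- as.data.frame(data.table::fread(need("channels.csv")))
  lfp <- t(as.matrix(data.table::fread(need("lfp.csv"))))
  dimnames(lfp) <- NULL
  accel <- NULL
  fs_accel <- NULL
  if (file.exists(file.path(path, "accel.csv"))) {
    accel <- t(as.matrix(data.table::fread(file.path(path, "accel.csv"))))
    dimnames(accel) <- NULL
    fs_accel <- meta$fs_accel
    if (is.null(fs_accel) || is.na(fs_accel) || fs_accel <= 0)
      stop("read_session: validation error, accel present but fs_accel invalid")
  }
  units <- list()
  up <- file.path(path, "units.json")
  if (file.exists(up)) {
    raw <- jsonlite::read_json(up, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    units <- lapply(raw, function(u) {
      spike_unit(u$unit_id, unlist(u$spike_times), u$electrode,
                 waveform = if (length(u$waveform)) unlist(u$waveform) else NULL,
                 wf_fs = u$wf_fs,
                 cell_type = if (is.null(u$cell_type)) "unset" else u$cell_type)
    })
  }
  inj <- meta$injection_time
  session(lfp, meta$fs_lfp, channels, units = units, accel = accel,
          fs_accel = fs_accel,
          injection_time = if (is.null(inj) || is.na(inj)) NA_real_ else inj,
          drug = meta$drug, drug_class = meta$drug_class)
}

#' Bipolar derivation within a structure
#'
#' Forms all unique pairs of same-structure electrodes and returns the
#' difference series (lower `channel_id` minus higher). Bipolar referencing
#' cancels common-mode (distant/volume-conducted) signal, so surviving
#' activity is locally generated.
#'
#' @param s an `hfo_session`.
#' @param structure structure label to pair within.
#' @return list of `bipolar_series` objects (fields `pair`, `structure`,
#'   `series`, `fs`); empty list when the structure has fewer than 2 channels.
#' @export
make_bipolar <- function(s, structure) {
  ids <- sort(s$channels$channel_id[s$channels$structure == structure])
  if (length(ids) < 2L) return(list())
  rows <- match(ids, s$channels$channel_id)
  prs <- utils::combn(seq_along(ids), 2)
  lapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    structure(
      list(pair = c(ids[i], ids[j]), structure = structure,
           series = s$lfp[rows[i], ] - s$lfp[rows[j], ], fs = s$fs_lfp),
      class = "bipolar_series"
    )
  })
}

#' Analysis epoch definition
#'
#' Windows are seconds relative to the injection time. Defaults follow the
#' study convention: baseline -35 to -5 min, drug +30 to +60 min.
#'
#' @param name "baseline" or "drug".
#' @param start,end window bounds in seconds relative to injection; defaults
#'   depend on `name`.
#' @return object of class `epoch`.
#' @export
epoch <- function(name = c("baseline", "drug"), start = NULL, end = NULL) {
  name <- match.arg(name)
  if (is.null(start)) start <- if (name == "baseline") -35 * 60 else 30 * 60
  if (is.null(end))   end   <- if (name == "baseline")  -5 * 60 else 60 * 60
  stopifnot(start < end)
  structure(list(name = name, start = start, end = end), class = "epoch")
}

#' Restrict a series or spike train to an epoch
#'
#' For numeric vectors interpreted as spike times (seconds from recording
#' start), returns the times inside `[injection_time + start,
#' injection_time + end)`. For sample series (vector or channels x samples
#' matrix with a sampling rate), returns the sample slice in the window; the
#' absolute start time of the slice is kept in attribute `t0`, which makes
#' slicing idempotent. Zero overlap with the recording yields an empty result
#' with a warning.
#'
#' @param x numeric vector of spike times, or a sample series (numeric vector
#'   or matrix) when `fs` is supplied.
#' @param injection_time injection time, seconds from recording start.
#' @param ep an [epoch()].
#' @param fs sampling rate of `x` in Hz; `NULL` means `x` holds spike times.
#' @return sliced object of the same kind.
#' @export
slice_epoch <- function(x, injection_time, ep, fs = NULL) {
  lo <- injection_time + ep$start
  hi <- injection_time + ep$end
  if (is.null(fs)) {
    out <- x[x >= lo & x < hi]
    if (!length(out) && (length(x) || hi <= 0))
      warning("slice_epoch: epoch has no overlap with the data")
    return(out)
  }
  n <- if (is.matrix(x)) ncol(x) else length(x)
  t0 <- attr(x, "t0"); if (is.null(t0)) t0 <- 0
  tt <- t0 + (seq_len(n) - 1) / fs
  keep <- tt >= lo & tt < hi
  if (!any(keep)) {
    warning("slice_epoch: epoch has no overlap with the recording")
    out <- if (is.matrix(x)) x[, integer(0), drop = FALSE] else x[integer(0)]
  } else {
    out <- if (is.matrix(x)) x[, keep, drop = FALSE] else x[keep]
    attr(out, "t0") <- tt[which(keep)[1]]
  }
  out
}
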