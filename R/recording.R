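# Recording container and signal / table I/O.
#
# Conventions used throughout the package: sample indices are 0-based,
# event intervals are half-open [onset, offset), and all times are seconds
# from recording start.

MIN_RATE_HZ <- 1250  # Nyquist must cover the 250-600 Hz fast-ripple band

#' Construct a multichannel iEEG recording
#'
#' @param samples numeric matrix, channels x timepoints, microvolts
#' @param rate_hz sampling rate in Hz; must exceed 1250 Hz so the 250-600 Hz
#'   fast-ripple band is resolvable
#' @param channel_ids unique channel names, one per row of `samples`
#' @param condition `"intraop"` or `"sleep"`
#' @param patient_id patient identifier
#' @param start_time_s recording start offset in seconds
#' @return object of class `Recording`
#' @export
recording <- function(samples, rate_hz = 2000, channel_ids = rownames(samples),
                      condition = c("intraop", "sleep"), patient_id = "P?",
                      start_time_s = 0) {
  condition <- match.arg(condition)
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  if (is.null(channel_ids))
    channel_ids <- paste0("ch", seq_len(nrow(samples)))
  channel_ids <- as.character(channel_ids)
  if (anyDuplicated(channel_ids))
    stop("duplicate channel ids: ",
         paste(unique(channel_ids[duplicated(channel_ids)]), collapse = ", "))
  if (length(channel_ids) != nrow(samples))
    stop("channel_ids length (", length(channel_ids),
         ") does not match sample rows (", nrow(samples), ")")
  if (!is.numeric(rate_hz) || rate_hz < MIN_RATE_HZ)
    stop("sampling rate insufficient for 250-600 Hz band (need > ",
         MIN_RATE_HZ, " Hz, got ", rate_hz, ")")
  rownames(samples) <- channel_ids
  structure(list(samples = samples, rate_hz = rate_hz,
                 channel_ids = channel_ids, condition = condition,
                 patient_id = patient_id, start_time_s = start_time_s),
            class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, x$condition, nrow(x$samples), ncol(x$samples),
              x$rate_hz, ncol(x$samples) / x$rate_hz))
  invisible(x)
}

#' Duration of a recording in seconds / minutes
#' @param rec a `Recording`
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$rate_hz

# ---------------------------------------------------------------- raw binary

#' Write / read a recording
#'
#' Two on-disk formats are supported. `"raw-binary"` stores samples as
#' little-endian float64 (channel-major) next to a JSON sidecar
#' (`<path>.json`) holding rate, channel ids, condition and patient; it is
#' lossless. `"edf"` writes a minimal continuous EDF file (16-bit, one
#' 1-second data record per block), lossy to the int16 quantization of the
#' per-channel physical range.
#'
#' @param rec a `Recording`
#' @param path output file
#' @param format `"raw-binary"` or `"edf"`
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `Recording`.
#' @export
write_recording <- function(rec, path, format = c("raw-binary", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "Recording"))
  if (format == "raw-binary") {
    meta <- list(rate_hz = rec$rate_hz, channel_ids = rec$channel_ids,
                 condition = rec$condition, patient_id = rec$patient_id,
                 start_time_s = rec$start_time_s,
                 n_channels = nrow(rec$samples), n_samples = ncol(rec$samples))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(t(rec$samples)), con, size = 8, endian = "little")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("raw-binary", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (format == "raw-binary") {
    meta_path <- paste0(path, ".json")
    if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (meta$rate_hz < MIN_RATE_HZ)
      stop("sampling rate insufficient for 250-600 Hz band (", meta$rate_hz,
           " Hz)")
    n <- meta$n_channels * meta$n_samples
    con <- file(path, "rb")
    on.exit(close(con))
    x <- readBin(con, "double", n = n, size = 8, endian = "little")
    if (length(x) != n)
      stop("channel-count/header mismatch: expected ", n,
           " samples, file holds ", length(x))
    samples <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
    recording(samples, meta$rate_hz, meta$channel_ids, meta$condition,
              meta$patient_id, meta$start_time_s %||% 0)
  } else {
    read_edf(path)
  }
}

# ------------------------------------------------------------------ EDF
# Minimal continuous EDF: one signal per channel, equal rates, 1-s records.
# Header layout per the EDF specification (ASCII fixed-width fields).

pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  spr <- as.integer(rec$rate_hz)           # samples per 1-s record
  if (abs(rec$rate_hz - spr) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  n_rec <- floor(ncol(rec$samples) / spr)
  if (n_rec < 1L) stop("recording shorter than one 1-s EDF data record")
  x <- rec$samples[, seq_len(n_rec * spr), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  # physical range must fit the 8-char ASCII header field; re-parse the
  # written representation so encode/decode use identical scaling
  num8 <- function(v) {
    s <- sprintf("%.6g", v)
    long <- nchar(s) > 8L
    s[long] <- sprintf("%.0f", v[long])
    if (any(nchar(s) > 8L)) stop("physical range too large for EDF header")
    s
  }
  smin <- num8(pmin_); pmin_ <- as.numeric(smin)
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  smax <- num8(pmax_); pmax_ <- as.numeric(smax)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(paste("pt", rec$patient_id, rec$condition), 80),
    pad("hfoseeg", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + 256 * ns, 8), pad("", 44),
    pad(n_rec, 8), pad(format(1), 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste0(vapply(
    vals, pad, "", w = w), collapse = ""), con, eos = NULL)
  field(rec$channel_ids, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)
  field(smin, 8)
  field(smax, 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                       # reserved
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, idx] - pmin_[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                        # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports equal per-channel rates only")
  rate <- spr[1L] / rec_dur
  if (rate < MIN_RATE_HZ)
    stop("sampling rate insufficient for 250-600 Hz band (", rate, " Hz)")
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  samples <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) != spr[ch]) stop("channel-count/header mismatch in EDF")
      samples[ch, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  pieces <- strsplit(patient, " +")[[1]]
  cond <- if (length(pieces) >= 3 && pieces[3] %in% c("intraop", "sleep"))
    pieces[3] else "intraop"
  pid <- if (length(pieces) >= 2) pieces[2] else "P?"
  recording(samples, rate, labels, cond, pid)
}

# --------------------------------------------------------------- tables

#' Read a per-contact channel metadata table
#'
#' Expects a delimited table with columns `channel`, `patient`, `soz`,
#' `resected`, `lobe` and optionally `matched`, `montage_partner`,
#' `anesthesia`. Blank / NA `resected` entries encode "resection status
#' unknown" (the contact was not sampled post-operatively), distinct from
#' FALSE.
#'
#' @param path CSV path
#' @return data.frame of class `ChannelInfo`, one row per contact, with
#'   logical `soz`, logical-or-NA `resected`, factor `lobe`
#' @export
read_channel_table <- function(path) {
  if (!file.exists(path)) stop("channel table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("channel", "patient", "soz", "resected", "lobe")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("channel table missing column(s): ", paste(miss, collapse = ", "))
  dup <- unique(df$channel[duplicated(df$channel)])
  if (length(dup))
    stop("duplicate channel id(s): ", paste(dup, collapse = ", "))
  as_tristate <- function(x) {
    x <- trimws(tolower(x))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1", "yes")] <- TRUE
    out[x %in% c("false", "f", "0", "no")] <- FALSE
    out
  }
  out <- data.frame(
    channel_id = df$channel,
    patient_id = df$patient,
    lobe = factor(df$lobe,
                  levels = c("frontal", "parietal", "temporal", "occipital",
                             "other")),
    soz = as_tristate(df$soz) %in% TRUE,
    resected = as_tristate(df$resected),
    matched = if ("matched" %in% names(df)) as_tristate(df$matched) %in% TRUE
              else TRUE,
    montage_partner = if ("montage_partner" %in% names(df)) {
      p <- df$montage_partner; p[!nzchar(trimws(p))] <- NA; p
    } else NA_character_,
    anesthesia = if ("anesthesia" %in% names(df)) df$anesthesia
                 else NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("ChannelInfo", "data.frame")
  out
}

#' Write a channel metadata table
#' @param channels a `ChannelInfo` data.frame
#' @param path CSV path
#' @export
write_channel_table <- function(channels, path) {
  df <- data.frame(channel = channels$channel_id,
                   patient = channels$patient_id,
                   soz = channels$soz,
                   resected = ifelse(is.na(channels$resected), "",
                                     as.character(channels$resected)),
                   lobe = as.character(channels$lobe),
                   matched = channels$matched,
                   montage_partner = ifelse(is.na(channels$montage_partner),
                                            "", channels$montage_partner),
                   anesthesia = channels$anesthesia %||% NA_character_)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write patient outcomes
#'
#' Engel class is ordinal (`I < IIa < IIb < III < IV`); surgical failure is
#' Engel IIa or worse.
#' @param path CSV path with columns `patient`, `engel_class`, `postop_mri`
#' @return data.frame of class `PatientOutcome`
#' @export
read_outcome_table <- function(path) {
  if (!file.exists(path)) stop("outcome table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient", "engel_class", "postop_mri")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("outcome table missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    patient_id = as.character(df$patient),
    engel_class = factor(df$engel_class,
                         levels = c("I", "IIa", "IIb", "III", "IV"),
                         ordered = TRUE),
    postop_mri = as.logical(df$postop_mri),
    stringsAsFactors = FALSE)
  if (anyNA(out$engel_class))
    stop("invalid Engel class value(s) in outcome table")
  class(out) <- c("PatientOutcome", "data.frame")
  out
}

#' @rdname read_outcome_table
#' @param outcomes a `PatientOutcome` data.frame
#' @export
write_outcome_table <- function(outcomes, path) {
  utils::write.csv(
    data.frame(patient = outcomes$patient_id,
               engel_class = as.character(outcomes$engel_class),
               postop_mri = outcomes$postop_mri),
    path, row.names = FALSE)
  invisible(path)
}

#' Is an Engel class a surgical failure?
#' @param engel_class ordered factor or character of Engel classes
#' @return logical; TRUE for Engel IIa or worse
#' @export
is_failure <- function(engel_class) {
  lev <- c("I", "IIa", "IIb", "III", "IV")
  factor(as.character(engel_class), levels = lev, ordered = TRUE) >= "IIa"
}

# ------------------------------------------------------------ event catalog

#' Write / read an event catalog
#'
#' One event per row; timestamps in seconds at microsecond precision, so the
#' catalog round-trips losslessly at any sampling rate in scope. Rows with
#' `offset <= onset` are rejected with a warning, never written.
#'
#' @param events data.frame with at least `channel_id`, `onset_s`,
#'   `offset_s` and (for classified catalogs) `category`
#' @param path CSV path
#' @export
write_event_catalog <- function(events, path) {
  cols <- c("channel_id", "band", "montage", "onset_s", "offset_s",
            "peak_envelope_z", "category", "power", "spectral_freq_hz",
            "duration_ms", "has_spike", "tf_island")
  if (is.null(events) || nrow(events) == 0L) {
    empty <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    utils::write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  bad <- events$onset_s >= events$offset_s
  if (any(bad)) {
    warning(sum(bad), " event(s) with offset <= onset rejected")
    events <- events[!bad, , drop = FALSE]
  }
  for (col in cols) if (is.null(events[[col]])) events[[col]] <- NA
  out <- events[, cols]
  out$onset_s <- sprintf("%.6f", out$onset_s)
  out$offset_s <- sprintf("%.6f", out$offset_s)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_catalog
#' @export
read_event_catalog <- function(path) {
  if (!file.exists(path)) stop("event catalog not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("onset_s", "offset_s", "peak_envelope_z", "power",
           "spectral_freq_hz", "duration_ms")
  for (col in num) if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  for (col in c("has_spike", "tf_island"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}
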