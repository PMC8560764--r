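# Hilbert HFO detector.
#
# Chain per channel, montage, and band: 1000th-order symmetric FIR band-pass
# (windowed-sinc, Hamming) -> analytic-signal envelope -> 40 ms moving
# average -> whole-series z-scoring -> skewness-adapted threshold ->
# maximal above-threshold runs walked out to the half-threshold crossing,
# gap-merged and duration-filtered.

#' Design a symmetric (linear-phase) FIR band-pass filter
#'
#' Windowed-sinc design with a Hamming window; `order` taps + 1
#' coefficients, symmetric, hence exactly linear phase with group delay
#' `order/2` samples. Passband gain is unity at band centre; stopband
#' attenuation exceeds 40 dB beyond ~13 Hz from the edges at 2 kHz.
#'
#' @param band numeric length-2, Hz
#' @param rate_hz sampling rate
#' @param order filter order (even; default 1000)
#' @return numeric vector of `order + 1` coefficients
#' @export
fir_bandpass <- function(band, rate_hz, order = 1000L) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[2] >= rate_hz / 2)
    stop("band edge ", band[2], " Hz >= Nyquist (", rate_hz / 2, " Hz)")
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L
  m <- -(order / 2):(order / 2)
  sinc <- function(fc) {
    x <- 2 * fc / rate_hz
    out <- x * sin(pi * x * m) / (pi * x * m)
    out[m == 0] <- x
    out
  }
  h <- sinc(band[2]) - sinc(band[1])
  w <- 0.54 + 0.46 * cos(2 * pi * m / order)   # Hamming
  h <- h * w
  h <- h - sum(h) / length(h)                  # exact DC rejection
  # normalize passband gain to unity at the geometric band centre
  fc <- sqrt(prod(band))
  gain <- Mod(sum(h * exp(-2i * pi * fc / rate_hz * seq_along(h))))
  h / gain
}

#' Zero-phase band-pass filtering
#'
#' Applies the symmetric FIR by FFT convolution and realigns by the group
#' delay, so features keep their temporal position.
#'
#' @param signal numeric vector (length > filter order)
#' @param rate_hz sampling rate
#' @param band `"broad_hfo"` (80-600 Hz), `"fast_ripple"` (250-600 Hz), or a
#'   numeric length-2 band in Hz
#' @param order FIR order
#' @return filtered signal, same length
#' @export
bandpass_fir <- function(signal, rate_hz, band = "broad_hfo", order = 1000L) {
  edges <- band_edges(band)
  if (length(signal) <= order)
    stop("signal length (", length(signal), ") must exceed filter order (",
         order, ")")
  h <- fir_bandpass(edges, rate_hz, order)
  fft_conv_same(signal, h)
}

#' @keywords internal
band_edges <- function(band, config = hfo_config()) {
  if (is.numeric(band)) return(band)
  b <- config$detector$bands[[band]]
  if (is.null(b)) stop("unknown band: ", band)
  as.numeric(b)
}

#' Analytic envelope of a filtered signal
#'
#' The analytic signal z(t) = a(t) exp(i phi(t)) is obtained by the
#' frequency-domain Hilbert transform; `a_t` is its modulus (instantaneous
#' amplitude, same units as input), `phi_t` its argument.
#'
#' @param filtered zero-mean band-passed signal
#' @param rate_hz sampling rate
#' @param band band label carried along for downstream rules
#' @return object of class `AnalyticEnvelope` with `a_t`, `phi_t`, `band`,
#'   `rate_hz`, `group_delay_samples`
#' @export
analytic_envelope <- function(filtered, rate_hz, band = "broad_hfo") {
  z <- analytic_signal(filtered)
  structure(list(a_t = Mod(z), phi_t = Arg(z), band = band,
                 rate_hz = rate_hz, group_delay_samples = 0L),
            class = "AnalyticEnvelope")
}

#' Smooth and z-score an envelope
#'
#' Centered moving-average smoothing (default 40 ms) followed by z-scoring
#' with the whole-series mean and SD. A constant envelope (zero SD) yields
#' an all-zero series with a warning.
#'
#' @param envelope an `AnalyticEnvelope` or numeric envelope series
#' @param window_ms smoothing window, milliseconds
#' @param rate_hz sampling rate (taken from the envelope object if given)
#' @return numeric z-scored series (mean 0, SD 1 unless degenerate)
#' @export
smooth_normalize <- function(envelope, window_ms = 40, rate_hz = NULL) {
  a <- if (inherits(envelope, "AnalyticEnvelope")) envelope$a_t else envelope
  rate_hz <- rate_hz %||%
    if (inherits(envelope, "AnalyticEnvelope")) envelope$rate_hz else
      stop("rate_hz required for a bare numeric envelope")
  stopifnot(window_ms > 0)
  width <- max(1L, round(window_ms / 1000 * rate_hz))
  if (width %% 2L == 0L) width <- width + 1L
  if (width > length(a)) stop("smoothing window longer than series")
  sm <- moving_average(a, width)
  s <- stats::sd(sm)
  if (!is.finite(s) || s < .Machine$double.eps * max(abs(sm), 1)) {
    warning("degenerate (constant) envelope; returning zero series")
    return(numeric(length(sm)))
  }
  (sm - mean(sm)) / s
}

#' Skewness-adapted detection threshold
#'
#' `clamp(base + gain * max(0, skewness), floor, ceiling)` in SD units of
#' the normalized envelope. A symmetric series yields the base threshold;
#' heavier right tails (more transient activity) raise it, monotonically,
#' up to the ceiling.
#'
#' @param normalized z-scored envelope series (>= 10 s of samples advised)
#' @param base,gain,floor_,ceiling_ mapping parameters
#' @return threshold in SD units
#' @export
skewness_threshold <- function(normalized, base = 3.0, gain = 0.5,
                               floor_ = 3.0, ceiling_ = 6.0) {
  sk <- sample_skewness(normalized)
  min(max(base + gain * max(0, sk), floor_), ceiling_)
}

#' Extract candidate events from a normalized envelope
#'
#' Maximal runs above `threshold`; each run's onset/offset is walked out to
#' the nearest crossing of `boundary_fraction * threshold`; runs separated
#' by less than `merge_gap_ms` are merged; events shorter than the band's
#' minimum duration are discarded.
#'
#' @param normalized z-scored envelope
#' @param threshold detection threshold (SD units)
#' @param band `"broad_hfo"` or `"fast_ripple"` (sets minimum duration)
#' @param rate_hz sampling rate
#' @param config `hfo_config`
#' @param channel_id,montage labels stamped on the events
#' @return data.frame of `CandidateEvent`s: `channel_id`, `band`, `montage`,
#'   `onset_s`, `offset_s`, `peak_envelope_z`
#' @export
extract_events <- function(normalized, threshold, band = "broad_hfo",
                           rate_hz = 2000, config = hfo_config(),
                           channel_id = "ch", montage = "referential") {
  stopifnot(threshold > 0)
  det <- config$detector
  above <- normalized > threshold
  if (!any(above)) return(empty_candidates())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  half <- det$boundary_fraction * threshold
  below <- normalized <= half
  n <- length(normalized)
  # walk out to the nearest half-threshold crossing
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, 1]
    while (s > 1L && !below[s - 1L]) s <- s - 1L
    e <- runs[i, 2]
    while (e < n && !below[e + 1L]) e <- e + 1L
    runs[i, ] <- c(s, e)
  }
  runs <- runs[order(runs[, 1]), , drop = FALSE]
  # merge runs separated by < merge_gap (walk-out can also make them touch)
  gap <- det$merge_gap_ms / 1000 * rate_hz
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    last <- nrow(merged)
    if (runs[i, 1] - merged[last, 2] < gap)
      merged[last, 2] <- max(merged[last, 2], runs[i, 2])
    else merged <- rbind(merged, runs[i, ])
  }
  min_dur <- det$min_duration_ms[[band]] %||% 20
  out <- data.frame(
    channel_id = channel_id, band = band, montage = montage,
    onset_s = (merged[, 1] - 1L) / rate_hz,          # 0-based half-open
    offset_s = merged[, 2] / rate_hz,
    peak_envelope_z = vapply(seq_len(nrow(merged)), function(i)
      max(normalized[merged[i, 1]:merged[i, 2]]), 0),
    stringsAsFactors = FALSE)
  out <- out[(out$offset_s - out$onset_s) * 1000 >= min_dur, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
empty_candidates <- function() {
  data.frame(channel_id = character(), band = character(),
             montage = character(), onset_s = numeric(),
             offset_s = numeric(), peak_envelope_z = numeric(),
             stringsAsFactors = FALSE)
}

#' Run the detector chain on one signal
#' @keywords internal
detect_channel <- function(signal, rate_hz, band, config, channel_id,
                           montage) {
  filt <- bandpass_fir(signal - mean(signal), rate_hz,
                       band_edges(band, config),
                       config$detector$filter_order)
  env <- analytic_envelope(filt, rate_hz, band)
  nrm <- smooth_normalize(env, config$detector$smooth_window_ms)
  thr <- skewness_threshold(nrm,
                            base = config$detector$threshold_base,
                            gain = config$detector$threshold_gain,
                            floor_ = config$detector$threshold_floor,
                            ceiling_ = config$detector$threshold_ceiling)
  extract_events(nrm, thr, band, rate_hz, config, channel_id, montage)
}

#' Detect candidate events across montages and bands
#'
#' Runs the Hilbert chain per contact in the referential and (where
#' `montage_partner` pairs are declared) bipolar montage, in the broad
#' 80-600 Hz pass and the dedicated 250-600 Hz fast-ripple pass, then
#' deduplicates: candidates on the same contact whose intervals overlap by
#' >= 50% of the shorter interval are collapsed, keeping the referential
#' over the bipolar instance and the broad-band over the fast-ripple
#' instance (ripple vs fast-ripple is assigned later from classifier
#' spectral frequency). Deterministic for fixed input and config.
#'
#' @param rec a `Recording` (referential montage)
#' @param channels `ChannelInfo` (for bipolar pairing); may be NULL for
#'   referential-only detection
#' @param config `hfo_config`
#' @return data.frame of `CandidateEvent`s
#' @export
detect_all <- function(rec, channels = NULL, config = hfo_config()) {
  det <- config$detector
  views <- list(referential = rec)
  if ("bipolar" %in% det$montages && !is.null(channels)) {
    # only pairs with both contacts present in this recording's montage
    pairs <- channels[!is.na(channels$montage_partner) &
                        channels$channel_id %in% rec$channel_ids &
                        channels$montage_partner %in% rec$channel_ids, ,
                      drop = FALSE]
    if (nrow(pairs)) views$bipolar <- to_bipolar(rec, pairs)
  }
  out <- list()
  for (mname in names(views)) {
    v <- views[[mname]]
    for (band in names(det$bands)) {
      for (ch_i in seq_along(v$channel_ids)) {
        sig <- v$samples[ch_i, ]
        if (all(sig == 0)) next
        cand <- detect_channel(sig, v$rate_hz, band, config,
                               v$channel_ids[ch_i], mname)
        if (nrow(cand)) out[[length(out) + 1L]] <- cand
      }
    }
  }
  if (!length(out)) return(empty_candidates())
  cands <- do.call(rbind, out)
  # map bipolar derivations back to their source (first-named) contact so
  # dedup and rates are per referential contact
  src <- sub("-.*$", "", cands$channel_id)
  cands$source_channel <- src
  dedup_candidates(cands, det$dedup_overlap)
}

#' Collapse overlapping candidates on the same source contact
#'
#' Preference order: referential before bipolar, broad band before
#' fast-ripple, then higher peak envelope. A bipolar trace `a-b` carries
#' activity from both contacts, so a bipolar candidate is suppressed when it
#' overlaps a kept candidate on either source contact; if kept, it is
#' attributed to the first-named contact.
#' @keywords internal
dedup_candidates <- function(cands, min_overlap = 0.5) {
  if (nrow(cands) == 0L) return(cands)
  if (is.null(cands$source_channel)) cands$source_channel <- cands$channel_id
  pref <- order(match(cands$montage, c("referential", "bipolar")),
                cands$source_channel,
                match(cands$band, c("broad_hfo", "fast_ripple")),
                -cands$peak_envelope_z)
  cands <- cands[pref, , drop = FALSE]
  keep <- rep(TRUE, nrow(cands))
  kept <- list()   # per contact: matrix of kept intervals
  overlaps <- function(ch, iv) {
    prev <- kept[[ch]]
    if (is.null(prev)) return(FALSE)
    ov <- pmin(prev[, 2], iv[2]) - pmax(prev[, 1], iv[1])
    shorter <- pmin(prev[, 2] - prev[, 1], iv[2] - iv[1])
    any(ov >= min_overlap * shorter)
  }
  for (i in seq_len(nrow(cands))) {
    iv <- c(cands$onset_s[i], cands$offset_s[i])
    src <- if (cands$montage[i] == "bipolar")
      strsplit(cands$channel_id[i], "-", fixed = TRUE)[[1]]
    else cands$source_channel[i]
    if (any(vapply(src, overlaps, TRUE, iv = iv))) { keep[i] <- FALSE; next }
    kept[[src[1]]] <- rbind(kept[[src[1]]], iv)
    if (length(src) > 1)                  # block the partner contact too
      kept[[src[2]]] <- rbind(kept[[src[2]]], iv)
  }
  out <- cands[keep, , drop = FALSE]
  out$channel_id <- out$source_channel
  out$source_channel <- NULL
  out <- out[order(out$channel_id, out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
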