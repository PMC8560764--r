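# Time-frequency topographic classifier.
#
# A candidate from the Hilbert detector can be (i) an authentic oscillation
# -- a closed above-threshold "island" in the time-frequency plane, isolated
# from low frequencies; (ii) Gibbs ringing of a band-passed sharp transient
# -- power that ridges continuously down to the lowest frequencies with no
# isolated island; or a mixture. The decision table:
#   island & !spike -> RonO / fRonO   (by spectral peak frequency)
#   island &  spike -> RonS / fRonS
#  !island &  spike -> SharpSpike
#  !island & !spike -> Artifact       (kept for audit, excluded from rates)

#' Morlet wavelet time-frequency power map
#'
#' Complex Morlet transform (default 7 cycles) on a log-spaced frequency
#' grid 32-600 Hz. Computed by FFT per frequency.
#'
#' @param excerpt signal excerpt covering the event +/- context
#' @param rate_hz sampling rate
#' @param freqs frequency grid (Hz); default log-spaced per config
#' @param n_cycles wavelet cycles
#' @return list of class `tf_map`: `power` (freq x time, uV^2), `freqs`,
#'   `times` (s, relative to excerpt start)
#' @export
tf_map <- function(excerpt, rate_hz, freqs = NULL, n_cycles = 7) {
  cfg <- hfo_config()$classifier
  if (is.null(freqs))
    freqs <- exp(seq(log(cfg$tf_freqs_min), log(cfg$tf_freqs_max),
                     length.out = cfg$tf_n_freqs))
  n <- length(excerpt)
  min_len <- 2 * n_cycles / min(freqs) * rate_hz
  if (n < min_len)
    stop("excerpt too short for the lowest frequency (need >= ",
         ceiling(min_len), " samples, got ", n, ")")
  nfft <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(excerpt, numeric(nfft - n)))
  f_axis <- (seq_len(nfft) - 1) / nfft * rate_hz
  f_axis[f_axis > rate_hz / 2] <- f_axis[f_axis > rate_hz / 2] - rate_hz
  power <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sigma_f <- f0 / n_cycles
    # analytic Morlet in the frequency domain: Gaussian at f0, unity peak
    # gain, negative frequencies zeroed. A sinusoid A*cos(2 pi f0 t) maps to
    # Mod(z) = A/2, so 2*Mod(z)^2 = A^2/2, the sinusoid's mean power.
    H <- exp(-(f_axis - f0)^2 / (2 * sigma_f^2))
    H[f_axis < 0] <- 0
    z <- stats::fft(X * H, inverse = TRUE)[seq_len(n)] / nfft
    power[k, ] <- 2 * Mod(z)^2
  }
  structure(list(power = power, freqs = freqs,
                 times = (seq_len(n) - 1) / rate_hz),
            class = "tf_map")
}

#' Detect a coincident low-frequency sharp transient
#'
#' A spike is declared when the < `spike_lowpass_hz` component of the
#' excerpt has both amplitude and slope exceeding robust (MAD-based)
#' z-thresholds within +/- `spike_window_ms` of the candidate interval.
#'
#' @param excerpt signal excerpt
#' @param rate_hz sampling rate
#' @param cand_rel candidate interval (s) relative to excerpt start,
#'   length-2; default the middle of the excerpt
#' @param config `hfo_config`
#' @param lf_scale optional robust scale (MAD) of the channel's low-passed
#'   signal computed over the whole recording; if NULL, computed from the
#'   excerpt (less stable)
#' @param lf_slope_scale analogous robust scale for the slope series
#' @return list: `has_spike` (logical), `spike_interval` (s, or NULL)
#' @export
detect_spike <- function(excerpt, rate_hz, cand_rel = NULL,
                         config = hfo_config(), lf_scale = NULL,
                         lf_slope_scale = NULL) {
  cls <- config$classifier
  lf <- spike_band(excerpt, rate_hz, cls)
  slope <- c(0, diff(lf)) * rate_hz
  sc_a <- lf_scale %||% stats::mad(lf)
  sc_s <- lf_slope_scale %||% stats::mad(slope)
  if (sc_a <= 0 || sc_s <= 0)
    return(list(has_spike = FALSE, spike_interval = NULL))
  hot <- abs(lf) / sc_a > cls$spike_amp_z & abs(slope) / sc_s > cls$spike_slope_z
  if (!any(hot)) return(list(has_spike = FALSE, spike_interval = NULL))
  t <- (seq_along(excerpt) - 1) / rate_hz
  if (is.null(cand_rel)) {
    mid <- t[length(t)] / 2
    cand_rel <- c(mid, mid)
  }
  win <- cls$spike_window_ms / 1000
  in_win <- hot & t >= cand_rel[1] - win & t <= cand_rel[2] + win
  if (!any(in_win)) return(list(has_spike = FALSE, spike_interval = NULL))
  list(has_spike = TRUE, spike_interval = range(t[in_win]))
}

# spike-band signal: 4-30 Hz by default. The high-pass removes delta/slow
# waves whose amplitude would otherwise dominate the robust scale during
# non-REM sleep and mask genuine spikes.
#' @keywords internal
spike_band <- function(x, rate_hz, cls) {
  lo <- lowpass_fir(x, rate_hz, cls$spike_lowpass_hz)
  hp <- cls$spike_highpass_hz %||% 0
  if (hp > 0) lo <- lo - lowpass_fir(x, rate_hz, hp, order = 400L)
  lo
}

#' @keywords internal
lowpass_fir <- function(x, rate_hz, cutoff_hz, order = 200L) {
  m <- -(order / 2):(order / 2)
  fc <- 2 * cutoff_hz / rate_hz
  h <- fc * sin(pi * fc * m) / (pi * fc * m)
  h[m == 0] <- fc
  h <- h * (0.54 + 0.46 * cos(2 * pi * m / order))
  h <- h / sum(h)
  fft_conv_same(x, h)
}

#' Island test: is the time-frequency peak an isolated closed contour?
#'
#' Thresholds the map at `contour` x (peak power inside the event window,
#' in-band), takes the 4-connected component containing that peak, and
#' requires it to be closed within the map and not extend below 80 Hz.
#' Filter ringing of a sharp transient fails: its power ridges continuously
#' down to the lowest frequencies.
#'
#' @param tf a `tf_map`
#' @param band `"broad_hfo"` or `"fast_ripple"` (in-band peak search range)
#' @param event_window length-2 time window (s, excerpt-relative) of the
#'   candidate; default whole map
#' @param contour contour fraction of peak power (default 0.5)
#' @param low_floor_hz lowest frequency an authentic island may reach. The
#'   default 65 Hz is 80 Hz minus the half-power bandwidth of a 7-cycle
#'   Morlet at the 80 Hz band edge: an authentic 80-100 Hz ripple's contour
#'   necessarily smears that far, while spike ringing ridges all the way to
#'   the bottom of the map.
#' @return list: `island` (logical), `peak_freq_hz`, `peak_time_s`,
#'   `island_power` (summed power inside the component), `island_trange`
#' @export
island_test <- function(tf, band = "broad_hfo", event_window = NULL,
                        contour = 0.5, low_floor_hz = 65) {
  edges <- band_edges(band)
  fidx <- which(tf$freqs >= edges[1] & tf$freqs <= edges[2])
  tidx <- if (is.null(event_window)) seq_along(tf$times) else
    which(tf$times >= event_window[1] & tf$times <= event_window[2])
  if (!length(tidx) || !length(fidx))
    return(list(island = FALSE, peak_freq_hz = NA_real_,
                peak_time_s = NA_real_, island_power = 0,
                island_trange = NULL))
  sub <- tf$power[fidx, tidx, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  peak_power <- sub[pk[1], pk[2]]
  if (peak_power <= 0)
    return(list(island = FALSE, peak_freq_hz = NA_real_,
                peak_time_s = NA_real_, island_power = 0,
                island_trange = NULL))
  peak_f <- fidx[pk[1]]; peak_t <- tidx[pk[2]]
  thr <- contour * peak_power
  above <- tf$power >= thr
  comp <- flood_fill(above, peak_f, peak_t)
  comp_f <- range(which(rowSums(comp) > 0))
  lowest_f <- tf$freqs[comp_f[1]]
  island <- lowest_f >= low_floor_hz && comp_f[1] > 1  # closed: must not
                                     # touch the map's lowest frequency row
  comp_t <- range(which(colSums(comp) > 0))
  list(island = island,
       peak_freq_hz = tf$freqs[peak_f],
       peak_time_s = tf$times[peak_t],
       island_power = sum(tf$power[comp]),
       island_trange = tf$times[comp_t])
}

# iterative 4-connected flood fill on a logical matrix
#' @keywords internal
flood_fill <- function(mask, r0, c0) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  if (!mask[r0, c0]) return(comp)
  stack <- matrix(c(r0, c0), ncol = 2)
  comp[r0, c0] <- TRUE
  while (nrow(stack)) {
    r <- stack[1, 1]; cc <- stack[1, 2]
    stack <- stack[-1, , drop = FALSE]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
          mask[rr, c2] && !comp[rr, c2]) {
        comp[rr, c2] <- TRUE
        stack <- rbind(stack, c(rr, c2))
      }
    }
  }
  comp
}

#' Classify one candidate event
#'
#' Extracts the event +/- 250 ms excerpt, computes the wavelet map, the
#' island test and the spike test, and applies the decision table. Power is
#' the summed time-frequency power inside the island (for SharpSpike: the
#' in-band power inside the candidate window); duration is the island's
#' temporal extent (candidate duration otherwise); spectral frequency is the
#' in-band TF peak.
#'
#' @param cand one-row candidate data.frame
#' @param rec the `Recording` the candidate came from
#' @param config `hfo_config`
#' @param lf_scales optional list(amp, slope) of channel-level robust scales
#'   for the spike test
#' @return one-row `ClassifiedEvent` data.frame
#' @export
classify_event <- function(cand, rec, config = hfo_config(),
                           lf_scales = NULL) {
  cls <- config$classifier
  rate <- rec$rate_hz
  ch_i <- match(cand$channel_id, rec$channel_ids)
  if (is.na(ch_i)) stop("candidate references unknown channel ",
                        cand$channel_id)
  n <- ncol(rec$samples)
  i0 <- max(1L, floor(cand$onset_s * rate) - round(cls$context_s * rate))
  i1 <- min(n, ceiling(cand$offset_s * rate) + round(cls$context_s * rate))
  # near recording edges, extend inward so the excerpt still covers two
  # wavelet lengths at the lowest analysis frequency
  needed <- ceiling(2 * cls$wavelet_cycles / cls$tf_freqs_min * rate) + 2L
  if (i1 - i0 + 1L < needed) {
    i1 <- min(n, i0 + needed - 1L)
    i0 <- max(1L, i1 - needed + 1L)
  }
  excerpt <- rec$samples[ch_i, i0:i1]
  t0 <- (i0 - 1L) / rate
  cand_rel <- c(cand$onset_s, cand$offset_s) - t0
  freqs <- exp(seq(log(cls$tf_freqs_min), log(cls$tf_freqs_max),
                   length.out = cls$tf_n_freqs))
  tf <- tf_map(excerpt, rate, freqs = freqs, n_cycles = cls$wavelet_cycles)
  isl <- island_test(tf, cand$band, event_window = cand_rel,
                     contour = cls$island_contour,
                     low_floor_hz = cls$island_low_floor_hz %||% 65)
  sp <- detect_spike(excerpt, rate, cand_rel, config,
                     lf_scale = lf_scales$amp, lf_slope_scale = lf_scales$slope)
  has_spike <- sp$has_spike
  island <- isl$island
  if (island) {
    fast <- isl$peak_freq_hz >= cls$ripple_split_hz
    category <- if (has_spike) { if (fast) "fRonS" else "RonS" }
      else { if (fast) "fRonO" else "RonO" }
    power <- isl$island_power
    duration_ms <- 1000 * (isl$island_trange[2] - isl$island_trange[1])
    spectral_freq <- isl$peak_freq_hz
  } else if (has_spike) {
    category <- "SharpSpike"
    fidx <- which(tf$freqs >= 80 & tf$freqs <= 600)
    tidx <- which(tf$times >= cand_rel[1] & tf$times <= cand_rel[2])
    power <- sum(tf$power[fidx, tidx])
    duration_ms <- 1000 * (cand$offset_s - cand$onset_s)
    spectral_freq <- isl$peak_freq_hz
  } else {
    category <- "Artifact"
    power <- isl$island_power
    duration_ms <- 1000 * (cand$offset_s - cand$onset_s)
    spectral_freq <- isl$peak_freq_hz
  }
  out <- cand[, c("channel_id", "band", "montage", "onset_s", "offset_s",
                  "peak_envelope_z")]
  out$category <- category
  out$power <- power
  out$spectral_freq_hz <- spectral_freq
  out$duration_ms <- duration_ms
  out$has_spike <- has_spike
  out$tf_island <- island
  out
}

#' Classify a candidate catalog
#'
#' Batch wrapper over [classify_event()]: channel-level robust scales for
#' the spike test are computed once per channel from the whole low-passed
#' trace, which stabilizes the spike criterion on short excerpts.
#'
#' @param cands candidate data.frame from [detect_all()]
#' @param rec the `Recording`
#' @param config `hfo_config`
#' @return `ClassifiedEvent` data.frame, one row per candidate
#' @export
classify_all <- function(cands, rec, config = hfo_config()) {
  if (nrow(cands) == 0L) {
    out <- cands
    for (col in c("category")) out[[col]] <- character(0)
    for (col in c("power", "spectral_freq_hz", "duration_ms"))
      out[[col]] <- numeric(0)
    for (col in c("has_spike", "tf_island")) out[[col]] <- logical(0)
    return(out)
  }
  scales <- list()
  for (ch in unique(cands$channel_id)) {
    ch_i <- match(ch, rec$channel_ids)
    lf <- spike_band(rec$samples[ch_i, ], rec$rate_hz, config$classifier)
    scales[[ch]] <- list(amp = stats::mad(lf),
                         slope = stats::mad(c(0, diff(lf)) * rec$rate_hz))
  }
  rows <- lapply(seq_len(nrow(cands)), function(i)
    classify_event(cands[i, , drop = FALSE], rec, config,
                   lf_scales = scales[[cands$channel_id[i]]]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Audit per-channel artifact fractions
#'
#' Flags channels whose fraction of Artifact-classified detections exceeds
#' the cap (default 5%). Nothing is deleted; the report is for review.
#'
#' @param classified `ClassifiedEvent` data.frame
#' @param cap maximum tolerated artifact fraction
#' @return data.frame of flagged channels with `n_events`, `n_artifact`,
#'   `fraction` (empty when nothing exceeds the cap)
#' @export
screen_artifact_rate <- function(classified, cap = 0.05) {
  if (nrow(classified) == 0L)
    return(data.frame(channel_id = character(), n_events = integer(),
                      n_artifact = integer(), fraction = numeric()))
  tab <- stats::aggregate(
    list(n_events = classified$category),
    by = list(channel_id = classified$channel_id),
    FUN = length)
  art <- stats::aggregate(
    list(n_artifact = classified$category == "Artifact"),
    by = list(channel_id = classified$channel_id),
    FUN = sum)
  rep_ <- merge(tab, art, by = "channel_id")
  rep_$fraction <- rep_$n_artifact / rep_$n_events
  out <- rep_[rep_$fraction > cap, , drop = FALSE]
  rownames(out) <- NULL
  out
}
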