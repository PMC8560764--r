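# Shared fixtures and oracles, built in code at test time.

# minimal ChannelInfo constructor
make_channels <- function(n, soz = seq_len(n) <= ceiling(n / 4),
                          patient = "P01", matched = TRUE,
                          resected = NA, partner = TRUE) {
  ids <- sprintf("%s_ch%02d", patient, seq_len(n))
  mp <- rep(NA_character_, n)
  if (partner && n >= 2) {
    mp <- c(ids[-1], NA)
    mp[seq(2, n, by = 2)] <- NA
  }
  d <- data.frame(channel_id = ids, patient_id = patient,
                  lobe = factor("other",
                                levels = c("frontal", "parietal", "temporal",
                                           "occipital", "other")),
                  soz = soz, resected = resected,
                  matched = matched, montage_partner = mp,
                  anesthesia = "sevo2", stringsAsFactors = FALSE)
  class(d) <- c("ChannelInfo", "data.frame")
  d
}

# one-row rate-table builder
make_rates <- function(channel_ids, rates, condition = "sleep",
                       category = "RonO", patient = "P01", minutes = 10) {
  data.frame(patient_id = patient, channel_id = channel_ids,
             condition = condition, category = category,
             n_events = rates * minutes, minutes_analyzed = minutes,
             rate_per_min = rates, stringsAsFactors = FALSE)
}

# greedy one-to-one interval-overlap matching of candidates to ground truth
match_events <- function(truth, cands) {
  hit <- logical(nrow(truth))
  used <- logical(max(nrow(cands), 1L))
  pred <- rep(NA_character_, nrow(truth))
  if (nrow(cands)) {
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      ov <- pmin(cands$offset_s, tr$offset_s) -
        pmax(cands$onset_s, tr$onset_s)
      j <- which(ov > 0 & cands$channel_id == tr$channel_id & !used)
      if (length(j)) {
        jj <- j[which.max(ov[j])]
        hit[i] <- TRUE
        used[jj] <- TRUE
        if (!is.null(cands$category)) pred[i] <- cands$category[jj]
      }
    }
  }
  list(recall = mean(hit), precision = if (nrow(cands)) mean(used) else NA,
       hit = hit, used = used, pred = pred)
}

# Welch PSD oracle (segment-averaged periodogram, Hann window)
welch_psd <- function(x, rate_hz, seg_s = 4) {
  nseg <- floor(seg_s * rate_hz)
  nwin <- floor(length(x) / nseg)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  acc <- 0
  for (k in seq_len(nwin)) {
    seg <- x[((k - 1) * nseg + 1):(k * nseg)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / nwin / sum(w^2) / rate_hz
  f <- (seq_len(nseg) - 1) / nseg * rate_hz
  keep <- f > 0 & f < rate_hz / 2
  data.frame(freq = f[keep], psd = p[keep])
}

# small synthetic cohort shared by the detector/classifier acceptance suite;
# built once per test session (scaled down from the full-scale default in
# channel count and duration only -- rates, SNR and thresholds untouched)
.cohort_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    spec <- sim_spec(n_patients = 2L, channels_per_patient = 8L,
                     matched_fraction = 0.75, duration_s = 600,
                     failure_patients = 1L, mri_fraction = 1, seed = 101L)
    .cohort_cache$cohort <- simulate_cohort(spec)
  }
  .cohort_cache$cohort
}

acceptance_detections <- function() {
  if (is.null(.cohort_cache$detections)) {
    co <- acceptance_cohort()
    cfg <- hfo_config()
    out <- list()
    for (key in names(co$recordings)) {
      rec <- co$recordings[[key]]
      cands <- detect_all(rec, co$channels, cfg)
      cl <- classify_all(cands, rec, cfg)
      if (nrow(cl)) {
        cl$patient_id <- rec$patient_id
        cl$condition <- rec$condition
      }
      out[[key]] <- cl
    }
    .cohort_cache$detections <- do.call(rbind, out)
  }
  .cohort_cache$detections
}
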