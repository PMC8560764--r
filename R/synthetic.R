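# Synthetic stereo-EEG cohort generator.
#
# The generator plants ground-truth-labeled events on a 1/f background so
# that detector recall/precision and every downstream statistic can be
# scored exactly. Oscillatory events are Gabor atoms (Gaussian-windowed
# sinusoids); epileptiform spikes are biphasic difference-of-Gaussians
# transients, which produce genuine Gibbs ringing when band-passed -- the
# classifier's hard case.

#' Simulation specification for the synthetic cohort
#'
#' Defaults emulate the study design the analysis assumes: 16 patients
#' recorded at 2 kHz in two conditions (10-min anesthetized intraoperative
#' recording, 10-min non-REM-sleep recording), roughly 33 matched contacts
#' per patient (530 cohort-wide), a minority of contacts in the seizure-onset
#' zone with elevated Poisson event rates, and condition effects on planted
#' event power/frequency applied on the natural-log scale with the signs of
#' the clinical mixed-model estimates (sleep ripples larger and slightly
#' faster; fast ripples slower in sleep).
#'
#' @param n_patients number of patients
#' @param channels_per_patient contacts per patient
#' @param matched_fraction fraction of contacts recorded in both conditions
#' @param soz_fraction fraction of contacts in the SOZ
#' @param duration_s recording duration per condition, seconds
#' @param rate_hz sampling rate
#' @param base_rates named events/min Poisson rates on non-SOZ contacts
#' @param soz_multiplier named SOZ rate multipliers per category
#' @param cond_log_power named natural-log power offsets (sleep minus
#'   intraop) applied to planted amplitudes as `exp(offset/2)`
#' @param cond_log_freq named natural-log frequency offsets (sleep minus
#'   intraop)
#' @param background_sd background 1/f noise SD, microvolts
#' @param pink_alpha PSD exponent of the background
#' @param slow_amp_uv amplitude of the 0.5-2 Hz slow oscillation added in
#'   the sleep condition
#' @param snr amplitude of planted oscillations in units of background SD
#' @param spike_amp_snr amplitude of planted spikes in background-SD units
#' @param failure_patients how many patients are surgical failures (Engel
#'   >= IIa) simulated as SOZ contacts left unresected
#' @param mri_fraction fraction of patients with post-operative MRI
#' @param failure_extra_boost extra fast-ripple rate multiplier on the one
#'   unresected SOZ contact of failure patients, making the residual
#'   epileptogenic tissue the top-rate region
#' @param seed master seed; fully determines all output
#' @return object of class `sim_spec`
#' @export
sim_spec <- function(n_patients = 16L,
                     channels_per_patient = 164L,
                     matched_fraction = 0.2,
                     soz_fraction = 0.25,
                     duration_s = 600,
                     rate_hz = 2000,
                     base_rates = c(RonO = 2, RonS = 0.5, fRonO = 0.3,
                                    fRonS = 0.2, SharpSpike = 1),
                     soz_multiplier = c(RonO = 2, RonS = 3, fRonO = 4,
                                        fRonS = 4, SharpSpike = 2),
                     cond_log_power = c(RonO = 1.291, RonS = 0.97,
                                        fRonO = 0.3, fRonS = 1.208),
                     cond_log_freq = c(RonO = 0.03, RonS = 0.022,
                                       fRonO = -0.1877, fRonS = -0.115),
                     background_sd = 10,
                     pink_alpha = 1,
                     slow_amp_uv = 30,
                     snr = 6,
                     spike_amp_snr = 10,
                     failure_patients = 4L,
                     mri_fraction = 0.5,
                     failure_extra_boost = 2,
                     seed = 1L) {
  stopifnot(all(base_rates >= 0), all(soz_multiplier >= 0),
            soz_fraction > 0, soz_fraction < 1,
            matched_fraction > 0, matched_fraction <= 1,
            duration_s >= 10)
  spec <- as.list(environment())
  structure(spec, class = "sim_spec")
}

# -------------------------------------------------------------- background

#' Simulate multichannel 1/f background iEEG
#'
#' Pink noise with PSD proportional to 1/f^alpha; the sleep condition adds a
#' large-amplitude 0.5-2 Hz slow oscillation (randomly phased, slowly
#' frequency-wandering) emulating non-REM delta activity. Zero-mean per
#' channel.
#'
#' @param duration_s seconds (>= 10)
#' @param rate_hz sampling rate
#' @param condition `"intraop"` or `"sleep"`
#' @param spec a `sim_spec`
#' @param n_channels number of channels
#' @param channel_ids optional channel names
#' @param patient_id patient label
#' @return a `Recording`
#' @export
simulate_background <- function(duration_s, rate_hz,
                                condition = c("intraop", "sleep"),
                                spec = sim_spec(), n_channels = 1L,
                                channel_ids = NULL, patient_id = "SIM") {
  condition <- match.arg(condition)
  stopifnot(duration_s >= 10)
  n <- round(duration_s * rate_hz)
  samples <- matrix(0, n_channels, n)
  t <- seq_len(n) / rate_hz
  for (ch in seq_len(n_channels)) {
    x <- if (spec$background_sd > 0)
      pink_noise(n, spec$pink_alpha, spec$background_sd) else numeric(n)
    if (condition == "sleep" && spec$slow_amp_uv > 0) {
      f0 <- stats::runif(1, 0.5, 2)
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + spec$slow_amp_uv * sin(2 * pi * f0 * t + phase)
      x <- x - mean(x)
    }
    samples[ch, ] <- x
  }
  recording(samples, rate_hz, channel_ids, condition, patient_id)
}

# ------------------------------------------------------------- event shapes

#' Gabor atom: Gaussian-windowed sinusoid
#'
#' `n_cycles` counts cycles within +/- 2 sigma of the envelope, giving a
#' burst whose effective duration is `n_cycles / freq_hz` seconds.
#' @keywords internal
gabor_atom <- function(freq_hz, n_cycles, amplitude, rate_hz) {
  dur <- n_cycles / freq_hz
  sigma <- dur / 4
  half <- ceiling(3 * sigma * rate_hz)
  t <- (-half:half) / rate_hz
  amplitude * exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * freq_hz * t)
}

#' Biphasic spike transient (difference of two offset Gaussians)
#'
#' A sharp millisecond-scale first phase followed by a slower opposite
#' after-wave. The sharp phase is what gives an epileptiform spike its
#' 80-600 Hz content when band-passed (Gibbs ringing); the overall biphasic
#' complex spans `width_ms` (30-60 ms).
#' @keywords internal
spike_transient <- function(width_ms, amplitude, rate_hz) {
  w <- width_ms / 1000
  sigma_sharp <- 0.002           # ~2 ms apex: sharpness does not scale with
                                 # the complex duration
  sigma_slow <- w / 4
  half <- ceiling(4 * sigma_slow * rate_hz)
  t <- (-half:half) / rate_hz
  shape <- exp(-t^2 / (2 * sigma_sharp^2)) -
    0.6 * exp(-(t - 1.5 * sigma_slow)^2 / (2 * sigma_slow^2))
  amplitude * shape / max(abs(shape))
}

# -------------------------------------------------------------- planting

#' Plant ground-truth events into a recording
#'
#' Per-channel event counts are Poisson(lambda * minutes) per category, with
#' lambda multiplied by the SOZ multiplier on SOZ channels. Events are
#' placed uniformly with rejection so that no two events on a channel
#' overlap (including a guard gap); after `max_attempts` rejections the
#' requested density is declared infeasible.
#'
#' Oscillatory events are Gabor atoms of 4-12 cycles with frequency drawn
#' uniformly in-band (ripple 80-250 Hz, fast ripple 250-600 Hz); RonS/fRonS
#' superimpose the atom on a biphasic spike; SharpSpike plants the spike
#' alone. `amp_scale`/`freq_scale` apply the condition effects.
#'
#' @param rec a `Recording`
#' @param spec a `sim_spec`
#' @param soz_channels channel ids with SOZ rate elevation
#' @param amp_scale multiplicative amplitude scale (condition effect);
#'   scalar or named per-category vector
#' @param freq_scale multiplicative frequency scale (condition effect);
#'   scalar or named per-category vector
#' @param boost_channels channels receiving an extra rate boost for
#'   `boost_category` (residual-epileptogenic-tissue emulation)
#' @param boost_category,boost_factor the boosted category and factor
#' @param max_attempts rejection-sampling bound per event
#' @return list with elements `recording` (events added) and `truth`
#'   (data.frame of `GroundTruthEvent`s sorted by channel then onset)
#' @export
plant_events <- function(rec, spec, soz_channels = character(),
                         amp_scale = 1, freq_scale = 1,
                         boost_channels = character(),
                         boost_category = "fRonO", boost_factor = 1,
                         max_attempts = 200L) {
  scale_of <- function(scales, cat) {
    if (length(scales) == 1L && is.null(names(scales))) return(scales[[1L]])
    if (!is.null(names(scales)) && cat %in% names(scales))
      return(scales[[cat]])
    1
  }
  rate_hz <- rec$rate_hz
  n <- ncol(rec$samples)
  minutes <- n / rate_hz / 60
  truth <- list()
  guard_s <- 0.15
  edge_s <- 0.5
  for (ch_i in seq_along(rec$channel_ids)) {
    ch <- rec$channel_ids[ch_i]
    chan_sig <- rec$samples[ch_i, ]          # work on a vector: writing into
                                             # the big matrix per event would
                                             # copy it each time
    mult <- if (ch %in% soz_channels) spec$soz_multiplier else
      stats::setNames(rep(1, length(EVENT_CATEGORIES)), EVENT_CATEGORIES)
    placed <- matrix(numeric(0), ncol = 2)   # occupied [onset, offset]
    for (cat in EVENT_CATEGORIES) {
      lambda <- spec$base_rates[[cat]] * (mult[[cat]] %||% 1)
      if (ch %in% boost_channels && cat == boost_category)
        lambda <- lambda * boost_factor
      if (is.na(lambda) || lambda <= 0) next
      a_sc <- scale_of(amp_scale, cat)
      f_sc <- scale_of(freq_scale, cat)
      k <- stats::rpois(1, lambda * minutes)
      if (k == 0) next
      for (i in seq_len(k)) {
        if (cat == "SharpSpike") {
          freq <- NA_real_
          width_ms <- stats::runif(1, 30, 60)
          wave <- spike_transient(width_ms,
                                  spec$spike_amp_snr * spec$background_sd *
                                    a_sc, rate_hz)
        } else {
          band <- if (cat %in% c("RonO", "RonS")) c(80, 250) else c(250, 600)
          freq <- stats::runif(1, band[1], band[2]) * f_sc
          freq <- min(max(freq, band[1]), band[2] - 1e-9)
          cycles <- stats::runif(1, 4, 12)
          amp <- spec$snr * spec$background_sd * a_sc
          wave <- gabor_atom(freq, cycles, amp, rate_hz)
          if (cat %in% c("RonS", "fRonS")) {
            sp <- spike_transient(stats::runif(1, 30, 60),
                                  spec$spike_amp_snr * spec$background_sd *
                                    a_sc, rate_hz)
            m <- max(length(wave), length(sp))
            pad2 <- function(v) {
              extra <- m - length(v)
              c(numeric(floor(extra / 2)), v, numeric(ceiling(extra / 2)))
            }
            wave <- pad2(wave) + pad2(sp)
          }
        }
        len_s <- length(wave) / rate_hz
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          onset <- stats::runif(1, edge_s, n / rate_hz - edge_s - len_s)
          if (nrow(placed) == 0 ||
              all(onset > placed[, 2] + guard_s |
                  onset + len_s < placed[, 1] - guard_s)) {
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("event density infeasible: could not place a ", cat,
               " on channel ", ch, " after ", max_attempts, " attempts")
        i0 <- round(onset * rate_hz) + 1L
        idx <- i0:(i0 + length(wave) - 1L)
        chan_sig[idx] <- chan_sig[idx] + wave
        placed <- rbind(placed, c(onset, onset + len_s))
        truth[[length(truth) + 1L]] <- data.frame(
          channel_id = ch, category = cat,
          onset_s = onset, offset_s = onset + len_s,
          amplitude_uv = max(abs(wave)),
          osc_freq_hz = freq, stringsAsFactors = FALSE)
      }
    }
    rec$samples[ch_i, ] <- chan_sig
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(channel_id = character(), category = character(),
               onset_s = numeric(), offset_s = numeric(),
               amplitude_uv = numeric(), osc_freq_hz = numeric())
  truth <- truth[order(truth$channel_id, truth$onset_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(recording = rec, truth = truth)
}

# --------------------------------------------------------------- cohort

#' Simulate a full two-condition cohort
#'
#' For each patient, generates an intraop and a sleep recording over the
#' same contacts (a `matched_fraction` subset flagged matched and present in
#' both; unmatched contacts appear only in the sleep recording, mirroring
#' the limited intraoperative montage), plants events with the condition
#' log-power/log-frequency offsets applied to the sleep condition, and
#' assigns outcomes: `failure_patients` patients are Engel IIIA-style
#' failures whose SOZ contacts are partially left unresected; the remaining
#' MRI patients are Engel I with their SOZ fully resected.
#'
#' @param spec a `sim_spec`
#' @return list with `recordings` (list of `Recording`, two per patient),
#'   `channels` (`ChannelInfo`), `outcomes` (`PatientOutcome`), `truth`
#'   (ground-truth events with patient and condition columns)
#' @export
simulate_cohort <- function(spec = sim_spec()) {
  set.seed(derive_seed(spec$seed, "simulate"))
  recordings <- list()
  channels <- list()
  outcomes <- list()
  truth <- list()
  n_mri <- max(spec$failure_patients,
               round(spec$mri_fraction * spec$n_patients))
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%02d", p)
    n_ch <- spec$channels_per_patient
    ch_ids <- sprintf("%s_ch%02d", pid, seq_len(n_ch))
    n_soz <- max(1L, round(spec$soz_fraction * n_ch))
    soz <- rep(FALSE, n_ch)
    soz[sample.int(n_ch, n_soz)] <- TRUE
    n_matched <- max(3L, round(spec$matched_fraction * n_ch))
    # matched subset always includes at least one SOZ contact (the
    # intraoperative montage targeted the suspected focus)
    soz_idx <- which(soz)
    matched_idx <- unique(c(soz_idx[sample.int(length(soz_idx), 1L)],
                            sample.int(n_ch, n_matched)))[seq_len(n_matched)]
    matched <- seq_len(n_ch) %in% matched_idx
    # adjacent contacts on the same electrode form bipolar pairs
    partner <- c(ch_ids[-1], NA)
    partner[seq(2, n_ch, by = 2)] <- NA
    is_failure_pt <- p <= spec$failure_patients
    has_mri <- p <= n_mri
    resected <- rep(NA, n_ch)
    residual_ch <- character()
    if (has_mri) {
      resected <- rep(FALSE, n_ch)
      resected[soz] <- TRUE
      if (is_failure_pt) {
        # leave one SOZ contact (the highest-fast-ripple-rate tissue,
        # enforced by the planting boost) outside the resection
        leave <- soz_idx[sample.int(length(soz_idx), 1L)]
        resected[leave] <- FALSE
        residual_ch <- ch_ids[leave]
      }
    }
    lobes <- sample(c("frontal", "parietal", "temporal", "occipital"),
                    n_ch, replace = TRUE)
    channels[[p]] <- data.frame(
      channel_id = ch_ids, patient_id = pid,
      lobe = factor(lobes, levels = c("frontal", "parietal", "temporal",
                                      "occipital", "other")),
      soz = soz, resected = resected, matched = matched,
      montage_partner = partner,
      anesthesia = sample(c("sevo1", "sevo2", "propofol"), 1),
      stringsAsFactors = FALSE)
    engel <- if (is_failure_pt) sample(c("IIa", "III", "IV"), 1) else "I"
    outcomes[[p]] <- data.frame(patient_id = pid, engel_class = engel,
                                postop_mri = has_mri,
                                stringsAsFactors = FALSE)
    for (cond in c("intraop", "sleep")) {
      keep <- if (cond == "intraop") which(matched) else seq_len(n_ch)
      bg <- simulate_background(spec$duration_s, spec$rate_hz, cond, spec,
                                n_channels = length(keep),
                                channel_ids = ch_ids[keep], patient_id = pid)
      amp_scale <- freq_scale <- stats::setNames(
        rep(1, length(EVENT_CATEGORIES)), EVENT_CATEGORIES)
      if (cond == "sleep") {
        for (cat in HFO_CATEGORIES) {
          amp_scale[cat] <- exp((spec$cond_log_power[[cat]] %||% 0) / 2)
          freq_scale[cat] <- exp(spec$cond_log_freq[[cat]] %||% 0)
        }
      }
      planted <- plant_events(bg, spec,
                              soz_channels = ch_ids[intersect(keep,
                                                              which(soz))],
                              amp_scale = amp_scale,
                              freq_scale = freq_scale,
                              boost_channels = residual_ch,
                              boost_category = "fRonO",
                              boost_factor = spec$failure_extra_boost %||% 1)
      planted$truth$patient_id <- pid
      planted$truth$condition <- cond
      recordings[[paste(pid, cond, sep = "_")]] <- planted$recording
      truth[[paste(pid, cond, sep = "_")]] <- planted$truth
    }
  }
  channels <- do.call(rbind, channels)
  class(channels) <- c("ChannelInfo", "data.frame")
  outcomes <- do.call(rbind, outcomes)
  outcomes$engel_class <- factor(outcomes$engel_class,
                                 levels = c("I", "IIa", "IIb", "III", "IV"),
                                 ordered = TRUE)
  class(outcomes) <- c("PatientOutcome", "data.frame")
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(recordings = recordings, channels = channels, outcomes = outcomes,
       truth = truth, spec = spec)
}

#' Write / read a ground-truth event table
#' @param truth data.frame of ground-truth events
#' @param path CSV path
#' @export
write_truth_table <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Simulate per-event responses under the mixed-model generative process
#'
#' Generates `log(response) = intercept + condition_effect * I(sleep) +
#' soz_effect * I(SOZ) + u_contact + noise`, with one random intercept per
#' contact, for parameter-recovery and coverage studies of
#' [fit_power_frequency_model()].
#'
#' @param n_contacts number of contacts
#' @param events_per_contact events per contact (split evenly across the
#'   two conditions)
#' @param intercept,condition_effect,soz_effect fixed effects on the
#'   natural-log scale
#' @param ranef_sd random-intercept SD
#' @param resid_sd residual SD on the log scale
#' @param soz_fraction fraction of SOZ contacts
#' @param category category label stamped on events
#' @param seed RNG seed
#' @return list: `events` (data.frame usable by
#'   [fit_power_frequency_model()]), `channels` (`ChannelInfo`)
#' @export
simulate_mixed_model_events <- function(n_contacts = 500L,
                                        events_per_contact = 40L,
                                        intercept = 12.287,
                                        condition_effect = 1.291,
                                        soz_effect = 0.263,
                                        ranef_sd = 0.5, resid_sd = 1.5,
                                        soz_fraction = 0.25,
                                        category = "RonO", seed = 1L) {
  set.seed(seed)
  n_soz <- round(soz_fraction * n_contacts)
  half <- max(1L, events_per_contact %/% 2L)
  rows <- vector("list", n_contacts)
  for (i in seq_len(n_contacts)) {
    soz <- i <= n_soz
    u <- stats::rnorm(1, 0, ranef_sd)
    cond <- rep(c(0L, 1L), c(half, half))
    y <- intercept + condition_effect * cond + soz_effect * soz + u +
      stats::rnorm(length(cond), 0, resid_sd)
    rows[[i]] <- data.frame(
      channel_id = sprintf("c%04d", i),
      condition = ifelse(cond == 1L, "sleep", "intraop"),
      category = category, power = exp(y), spectral_freq_hz = exp(y),
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, rows)
  channels <- data.frame(
    channel_id = sprintf("c%04d", seq_len(n_contacts)),
    patient_id = "SIM",
    lobe = factor("other", levels = c("frontal", "parietal", "temporal",
                                      "occipital", "other")),
    soz = seq_len(n_contacts) <= n_soz,
    resected = NA, matched = TRUE, montage_partner = NA_character_,
    anesthesia = NA_character_, stringsAsFactors = FALSE)
  class(channels) <- c("ChannelInfo", "data.frame")
  list(events = events, channels = channels)
}
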