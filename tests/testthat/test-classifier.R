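# classifier: wavelet map, spike coincidence, island topography, decision
# table, artifact audit

rate <- 2000

# 0.7 s excerpt with an optional atom and/or spike at its centre
make_excerpt <- function(atom_hz = NULL, atom_amp = 60, spike = FALSE,
                         spike_amp = 100, noise_sd = 0, n = 1400,
                         atom_cycles = 8, seed = 1) {
  set.seed(seed)
  x <- if (noise_sd > 0) hfoseeg:::pink_noise(n, 1, noise_sd) else numeric(n)
  centre <- n %/% 2
  if (!is.null(atom_hz)) {
    a <- hfoseeg:::gabor_atom(atom_hz, atom_cycles, atom_amp, rate)
    idx <- centre + seq_along(a) - length(a) %/% 2
    x[idx] <- x[idx] + a
  }
  if (spike) {
    s <- hfoseeg:::spike_transient(40, spike_amp, rate)
    idx <- centre + seq_along(s) - length(s) %/% 2
    x[idx] <- x[idx] + s
  }
  x
}

test_that("tf_map localizes frequency and respects amplitude", {
  x <- make_excerpt(atom_hz = 140)
  tf <- tf_map(x, rate)
  pk <- which(tf$power == max(tf$power), arr.ind = TRUE)
  expect_lt(abs(tf$freqs[pk[1]] - 140), 10)
  # unit-amplitude sinusoid maps to its mean power A^2/2 within 10%
  tone <- 4 * cos(2 * pi * 200 * seq_len(2000) / rate)
  tft <- tf_map(tone, rate, freqs = c(150, 200, 260))
  expect_lt(abs(max(tft$power[2, 500:1500]) - 8) / 8, 0.1)

  expect_true(all(tf_map(numeric(1400), rate)$power == 0))
  expect_error(tf_map(numeric(300), rate), "too short")

  # two-component input -> two distinct local maxima
  x2 <- make_excerpt(atom_hz = 100) + make_excerpt(atom_hz = 300)
  tf2 <- tf_map(x2, rate)
  centre_t <- 600:800
  prof <- apply(tf2$power[, centre_t], 1, max)
  i100 <- which.min(abs(tf2$freqs - 100)); i300 <- which.min(abs(tf2$freqs - 300))
  i200 <- which.min(abs(tf2$freqs - 200))
  expect_gt(prof[i100], 2 * prof[i200])
  expect_gt(prof[i300], 2 * prof[i200])
})

test_that("detect_spike requires a coincident sharp transient", {
  cfg <- hfo_config()
  x <- make_excerpt(spike = TRUE, noise_sd = 10, seed = 2)
  r <- detect_spike(x, rate, cand_rel = c(0.33, 0.37), config = cfg)
  expect_true(r$has_spike)

  x2 <- make_excerpt(atom_hz = 140, noise_sd = 10, seed = 3)
  r2 <- detect_spike(x2, rate, cand_rel = c(0.33, 0.37), config = cfg)
  expect_false(r2$has_spike)

  # spike 80 ms away from the candidate window -> no coincidence
  r3 <- detect_spike(x, rate, cand_rel = c(0.20, 0.22), config = cfg)
  expect_false(r3$has_spike)
})

test_that("island test separates oscillations from filter ringing", {
  x <- make_excerpt(atom_hz = 200)
  expect_true(island_test(tf_map(x, rate), "broad_hfo",
                          event_window = c(0.3, 0.4))$island)
  # band-passed pure spike: ringing has no isolated island
  sp <- make_excerpt(spike = TRUE)
  expect_false(island_test(tf_map(sp, rate), "broad_hfo",
                           event_window = c(0.3, 0.4))$island)
  expect_false(island_test(tf_map(numeric(1400), rate), "broad_hfo")$island)
})

test_that("classify_event applies the decision table", {
  ch <- make_channels(1, partner = FALSE)
  base <- hfoseeg:::pink_noise(rate * 20, 1, 10)
  mk_rec <- function(wave, at = 10) {
    x <- base
    idx <- at * rate + seq_along(wave)
    x[idx] <- x[idx] + wave
    recording(matrix(x, 1), rate, ch$channel_id)
  }
  cfg <- hfo_config()
  run1 <- function(rec) {
    cands <- detect_all(rec, NULL, cfg)
    cands <- cands[order(-cands$peak_envelope_z), ][1, , drop = FALSE]
    classify_event(cands, rec, cfg)
  }
  # fRonS: 320 Hz atom + spike
  atom <- hfoseeg:::gabor_atom(320, 10, 80, rate)
  spk <- hfoseeg:::spike_transient(40, 100, rate)
  m <- max(length(atom), length(spk))
  pad2 <- function(v) c(numeric((m - length(v)) %/% 2), v,
                        numeric(m - length(v) - (m - length(v)) %/% 2))
  ev <- run1(mk_rec(pad2(atom) + pad2(spk)))
  expect_equal(ev$category, "fRonS")
  expect_lt(abs(ev$spectral_freq_hz - 320), 35)
  expect_true(ev$has_spike && ev$tf_island)

  # spike alone -> SharpSpike
  ev2 <- run1(mk_rec(spk))
  expect_equal(ev2$category, "SharpSpike")
  expect_true(ev2$has_spike)
  expect_false(ev2$tf_island)

  # 140 Hz atom alone -> RonO; duration = half-power extent of the island.
  # Closed form for a Gaussian burst seen through a 7-cycle Morlet:
  # 2*sqrt(ln 2)*sqrt(sigma_atom^2 + sigma_wavelet^2)
  atom3 <- hfoseeg:::gabor_atom(140, 12, 80, rate)
  ev3 <- run1(mk_rec(atom3))
  expect_equal(ev3$category, "RonO")
  sigma_atom <- (12 / 140) / 4
  sigma_wav <- 7 / (2 * pi * 140)
  expected_ms <- 1000 * 2 * sqrt(log(2)) * sqrt(sigma_atom^2 + sigma_wav^2)
  expect_lt(abs(ev3$duration_ms - expected_ms) / expected_ms, 0.20)
})

test_that("classified power scales as the square of the signal", {
  ch <- make_channels(1, partner = FALSE)
  x <- hfoseeg:::pink_noise(rate * 20, 1, 10)
  atom <- hfoseeg:::gabor_atom(150, 10, 80, rate)
  x[10 * rate + seq_along(atom)] <- x[10 * rate + seq_along(atom)] + atom
  cfg <- hfo_config()
  rec1 <- recording(matrix(x, 1), rate, ch$channel_id)
  rec2 <- recording(matrix(3 * x, 1), rate, ch$channel_id)
  c1 <- detect_all(rec1, NULL, cfg)
  c2 <- detect_all(rec2, NULL, cfg)
  e1 <- classify_all(c1, rec1, cfg)
  e2 <- classify_all(c2, rec2, cfg)
  expect_equal(e2$power / e1$power, rep(9, nrow(e1)), tolerance = 1e-6)
  expect_true(all(e1$power >= 0))
})

test_that("every candidate maps to exactly one valid category", {
  set.seed(21)
  spec <- sim_spec(duration_s = 60)
  rec <- simulate_background(60, rate, "intraop", spec, n_channels = 2)
  out <- plant_events(rec, spec, soz_channels = "ch1")
  cfg <- hfo_config()
  cl <- classify_all(detect_all(out$recording, NULL, cfg), out$recording, cfg)
  expect_true(all(cl$category %in% c(EVENT_CATEGORIES, "Artifact")))
  ripple <- cl$category %in% c("RonO", "RonS")
  fast <- cl$category %in% c("fRonO", "fRonS")
  expect_true(all(cl$spectral_freq_hz[ripple] < 250))
  expect_true(all(cl$spectral_freq_hz[fast] >= 250))
  expect_true(all((cl$category %in% c("RonS", "fRonS")) ==
                    (cl$has_spike & cl$tf_island)))
  expect_true(all((cl$category == "SharpSpike") ==
                    (cl$has_spike & !cl$tf_island)))
})

test_that("artifact-rate audit flags only channels over the cap", {
  cl <- data.frame(channel_id = c(rep("a", 93), rep("b", 7)),
                   category = c(rep("RonO", 93), rep("Artifact", 7)))
  rep1 <- screen_artifact_rate(cl, cap = 0.05)
  expect_equal(rep1$channel_id, "b")
  expect_equal(rep1$fraction, 1.0)
  expect_equal(nrow(screen_artifact_rate(cl, cap = 1.0)), 0L)
  clean <- data.frame(channel_id = "a", category = "RonO")
  expect_equal(nrow(screen_artifact_rate(clean)), 0L)
})
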