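# detector: FIR band-pass, analytic envelope, normalization, skewness
# threshold, event extraction, full-chain properties

rate <- 2000
tt <- seq_len(20 * rate) / rate

test_that("FIR band-pass has unit passband, deep stopband, DC rejection", {
  mid <- 4000:36000
  f <- bandpass_fir(sin(2 * pi * 120 * tt), rate, "broad_hfo")
  amp <- max(Mod(analytic_signal(f))[mid])
  expect_lt(abs(amp - 1), 0.05)                   # 120 Hz within 5% of unity

  f2 <- bandpass_fir(sin(2 * pi * 20 * tt), rate, "broad_hfo")
  expect_lt(max(abs(f2[mid])), 0.01)              # 20 Hz residual < 1%

  f3 <- bandpass_fir(rep(2.5, length(tt)), rate, "broad_hfo")
  expect_lt(max(abs(f3[mid])), 1e-8)              # DC rejected

  expect_error(bandpass_fir(tt, rate, c(250, 1100)), "Nyquist")
  expect_error(bandpass_fir(rnorm(500), rate, "broad_hfo"), "filter order")
})

test_that("stopband attenuation exceeds 40 dB at band edges +/- 20 Hz", {
  h <- fir_bandpass(c(80, 600), rate, 1000)
  H <- function(fq) Mod(sum(h * exp(-2i * pi * fq / rate * seq_along(h))))
  expect_lt(20 * log10(H(60)), -40)
  expect_lt(20 * log10(H(620)), -40)
  expect_gt(H(300), 0.95)
})

test_that("analytic envelope matches closed forms", {
  expect_equal(analytic_envelope(numeric(1000), rate)$a_t, numeric(1000))

  x <- 10 * cos(2 * pi * 140 * tt)
  env <- analytic_envelope(bandpass_fir(x, rate, "broad_hfo"), rate)
  expect_lt(abs(median(env$a_t[4000:36000]) - 10) / 10, 0.02)

  # Gabor atom: envelope peak ~ amplitude at atom centre
  atom <- 7 * exp(-(tt - 10)^2 / (2 * 0.02^2)) * cos(2 * pi * 140 * (tt - 10))
  enva <- analytic_envelope(atom - mean(atom), rate)
  expect_lt(abs(max(enva$a_t) - 7) / 7, 0.03)
  expect_equal(which.max(enva$a_t), which.min(abs(tt - 10)), tolerance = 3)
})

test_that("smooth_normalize z-scores and handles degenerate input", {
  set.seed(1)
  x <- abs(rnorm(rate * 20))
  nrm <- smooth_normalize(x, 20, rate_hz = rate)
  expect_lt(abs(mean(nrm)), 1e-9)
  expect_equal(sd(nrm), 1, tolerance = 1e-9)

  expect_warning(out <- smooth_normalize(rep(3, 1000), 10, rate_hz = rate),
                 "degenerate")
  expect_equal(out, numeric(1000))
  expect_error(smooth_normalize(rnorm(10), 40, rate_hz = rate), "longer")
})

test_that("moving average reduces white-noise variance by the window length", {
  set.seed(2)
  x <- rnorm(rate * 60)
  w <- round(0.040 * rate) + 1             # 40 ms at 2 kHz -> 81 samples
  sm <- hfoseeg:::moving_average(x, w)
  interior <- sm[w:(length(sm) - w)]
  expect_equal(var(x) / var(interior), w, tolerance = 0.12)
})

test_that("skewness threshold follows the affine-clamped mapping", {
  set.seed(3)
  expect_equal(skewness_threshold(rnorm(30000)), 3.0, tolerance = 0.05)
  # synthetic series with skewness exactly 2 via the mapping arithmetic:
  # threshold = base + gain * skew
  x <- rexp(200000)                         # skewness ~ 2
  sk <- hfoseeg:::sample_skewness(x)
  expect_equal(skewness_threshold(x), 3 + 0.5 * sk, tolerance = 1e-12)
  expect_lte(skewness_threshold(x), 6.0)
  # monotone non-decreasing in skewness; ceiling clamps
  expect_equal(skewness_threshold(c(rep(0, 1000), 1e6)), 6.0)

  # Rayleigh envelope of band-passed Gaussian noise: closed-form skewness
  # 2*sqrt(pi)*(pi-3)/(4-pi)^1.5 = 0.6311, threshold ~ 3.316
  set.seed(42)
  env <- analytic_envelope(bandpass_fir(rnorm(100 * rate), rate,
                                        "broad_hfo"), rate)
  z <- (env$a_t - mean(env$a_t)) / sd(env$a_t)
  expect_equal(skewness_threshold(z), 3 + 0.5 * 2 * sqrt(pi) * (pi - 3) /
                 (4 - pi)^1.5, tolerance = 0.05)
})

test_that("extract_events finds, merges and filters threshold runs", {
  cfg <- hfo_config()
  expect_equal(nrow(extract_events(rnorm(20000) * 0.1, 3, "broad_hfo", rate,
                                   cfg)), 0L)
  # two bumps 5 ms apart with merge gap 10 ms -> one merged event
  env <- numeric(4000)
  env[1000:1060] <- 5            # 30 ms above threshold
  env[1071:1131] <- 5            # 5 ms gap
  ev <- extract_events(env, 3, "broad_hfo", rate, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 0.4995)   # walk-out stops at the step edge
  expect_gte(ev$offset_s, 1131 / rate)  # spans both bumps
  # shorter than 20 ms -> discarded
  env2 <- numeric(4000); env2[2000:2020] <- 5
  expect_equal(nrow(extract_events(env2, 3, "broad_hfo", rate, cfg)), 0L)
  # but a 10-ms fast-ripple run survives in the fast band
  env3 <- numeric(4000); env3[2000:2024] <- 5
  expect_equal(nrow(extract_events(env3, 3, "fast_ripple", rate, cfg)), 1L)
})

test_that("a planted high-SNR Gabor atom yields exactly one accurate event", {
  set.seed(7)
  noise <- rnorm(60 * rate)
  onset_true <- 30
  atom <- hfoseeg:::gabor_atom(140, 8, 12, rate)   # 12x unit background SD
  i0 <- onset_true * rate + 1
  sig <- noise
  sig[i0:(i0 + length(atom) - 1)] <- sig[i0:(i0 + length(atom) - 1)] + atom
  cand <- hfoseeg:::detect_channel(sig, rate, "broad_hfo", hfo_config(),
                                   "c1", "referential")
  expect_equal(nrow(cand), 1L)
  centre_true <- onset_true + length(atom) / 2 / rate
  centre_det <- (cand$onset_s + cand$offset_s) / 2
  expect_lt(abs(centre_det - centre_true), 0.010)
})

test_that("detection is amplitude-equivariant and deterministic", {
  set.seed(8)
  spec <- sim_spec(duration_s = 30)
  rec <- simulate_background(30, rate, "intraop", spec, n_channels = 1)
  out <- plant_events(rec, spec, soz_channels = "ch1")
  cfg <- hfo_config()
  c1 <- detect_all(out$recording, NULL, cfg)
  rec_k <- out$recording
  rec_k$samples <- rec_k$samples * 7.3
  c2 <- detect_all(rec_k, NULL, cfg)
  expect_equal(c1$onset_s, c2$onset_s)
  expect_equal(c1$offset_s, c2$offset_s)
  expect_equal(c1$peak_envelope_z, c2$peak_envelope_z, tolerance = 1e-9)
  c3 <- detect_all(out$recording, NULL, cfg)
  expect_identical(c1, c3)
  expect_equal(nrow(detect_all(recording(matrix(0, 2, rate * 20), rate),
                               NULL, cfg)), 0L)
})

test_that("bipolar montage subtracts partner signals exactly", {
  set.seed(9)
  x <- matrix(rnorm(6 * 5000), 6)
  ch <- make_channels(6)
  rec <- recording(x, rate, ch$channel_id)
  bp <- to_bipolar(rec, ch)
  expect_equal(nrow(bp$samples), 3L)
  # direct subtraction oracle
  for (i in seq_len(3)) {
    a <- match(ch$channel_id[!is.na(ch$montage_partner)][i], rec$channel_ids)
    b <- match(ch$montage_partner[!is.na(ch$montage_partner)][i],
               rec$channel_ids)
    expect_identical(bp$samples[i, ], unname(x[a, ] - x[b, ]))
  }
  # identical pair -> zero trace; pure-sine difference preserved
  x2 <- x
  x2[2, ] <- x2[1, ]
  sine <- sin(2 * pi * 100 * seq_len(5000) / rate)
  x2[4, ] <- x2[3, ] + sine
  bp2 <- to_bipolar(recording(x2, rate, ch$channel_id), ch)
  expect_true(all(bp2$samples[1, ] == 0))
  expect_equal(bp2$samples[2, ], -sine, tolerance = 1e-12)
  ch_bad <- ch
  ch_bad$montage_partner[1] <- "nope"
  expect_error(to_bipolar(recording(x, rate, ch$channel_id), ch_bad), "nope")
})
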