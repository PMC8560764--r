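# rate_stats: rate tables, mixed models, repeated-measures rate tests, ROC

test_that("compute_rates does the arithmetic and fills zero rows", {
  ch <- make_channels(5, partner = FALSE)
  ev <- data.frame(channel_id = rep(ch$channel_id[1], 12),
                   category = "RonO", condition = "sleep",
                   onset_s = 1:12, offset_s = (1:12) + 0.05,
                   stringsAsFactors = FALSE)
  rt <- compute_rates(ev, ch, durations = 10)
  r1 <- rt[rt$channel_id == ch$channel_id[1] & rt$category == "RonO", ]
  expect_equal(r1$rate_per_min, 1.2)
  expect_equal(r1$n_events, 12L)
  # invariant: rate * minutes = n
  expect_true(all(abs(rt$rate_per_min * rt$minutes_analyzed - rt$n_events)
                  < 1e-9))
  # empty catalog: all channels x categories present with rate zero
  rt0 <- compute_rates(ev[0, ], ch, durations = 10, condition = "sleep")
  expect_equal(nrow(rt0), 5L * length(EVENT_CATEGORIES))
  expect_true(all(rt0$rate_per_min == 0))
  # unknown channel
  bad <- ev; bad$channel_id[1] <- "ghost"
  expect_error(compute_rates(bad, ch, 10), "ghost")
  # Artifact events never counted
  ev2 <- ev; ev2$category <- "Artifact"
  expect_true(all(compute_rates(ev2, ch, 10)$n_events == 0))
})

test_that("planted Poisson rates are recovered within sampling error", {
  spec <- sim_spec(base_rates = c(RonO = 2, RonS = 0, fRonO = 0, fRonS = 0,
                                  SharpSpike = 0))
  rec <- recording(matrix(0, 4, 2000 * 600), 2000, sprintf("c%d", 1:4))
  set.seed(31)
  tr <- plant_events(rec, spec)$truth
  tr$condition <- "sleep"
  ch <- make_channels(4, partner = FALSE)
  ch$channel_id <- sprintf("c%d", 1:4)
  rt <- compute_rates(tr, ch, durations = 10)
  r <- rt$rate_per_min[rt$category == "RonO"]
  # mean of 4 channels x Poisson(20)/10: SE = sqrt(2/40) ~ 0.22
  expect_lt(abs(mean(r) - 2), 3 * sqrt(2 / 40))
})

test_that("mixed model recovers planted effects and needs >= 2 contacts", {
  sim <- simulate_mixed_model_events(n_contacts = 200, seed = 7)
  fit <- fit_power_frequency_model(sim$events, sim$channels, "log_power",
                                   "RonO")
  expect_lt(abs(fit$estimates["condition"] - 1.291),
            3 * fit$se["condition"])
  expect_lt(abs(fit$estimates["intercept"] - 12.287),
            3 * fit$se["intercept"])
  expect_true(all(fit$ci_low <= fit$estimates & fit$estimates <= fit$ci_high))

  one <- sim$events[sim$events$channel_id == "c0001", ]
  expect_error(fit_power_frequency_model(one, sim$channels, "log_power",
                                         "RonO"), ">= 2 contacts")
})

test_that("condition-effect CI covers a planted zero in >= 93% of seeds", {
  hits <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    sim <- simulate_mixed_model_events(n_contacts = 40,
                                       events_per_contact = 10,
                                       condition_effect = 0, seed = 1000 + s)
    fit <- suppressWarnings(
      fit_power_frequency_model(sim$events, sim$channels, "log_power",
                                "RonO"))
    if (fit$ci_low["condition"] <= 0 && fit$ci_high["condition"] >= 0)
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("rmANOVA-style rate test: errors, dropping, planted effects", {
  ch <- make_channels(30, partner = FALSE)
  mk <- function(int_rates, slp_rates) {
    rbind(make_rates(ch$channel_id, int_rates, "intraop"),
          make_rates(ch$channel_id, slp_rates, "sleep"))
  }
  set.seed(41)
  u <- rnorm(30)
  d <- mk(2 + u + rnorm(30), 4 + u + rnorm(30) + 2 * ch$soz)
  r <- condition_soz_rate_test(d, ch, "soz")
  expect_setequal(r$table$term, c("soz", "condition", "soz:condition"))
  expect_lt(r$table$p[r$table$term == "condition"], 0.01)
  expect_equal(r$n_dropped, 0L)
  # unbalanced contact dropped with count
  d2 <- d[-1, ]
  r2 <- condition_soz_rate_test(d2, ch, "soz")
  expect_equal(r2$n_dropped, 1L)
  expect_equal(r2$n_contacts, 29L)
  # one contact -> error
  expect_error(condition_soz_rate_test(d[d$channel_id == ch$channel_id[1], ],
                                       ch), ">= 2 matched")
  # mixed categories rejected
  dbad <- d; dbad$category[1] <- "fRonO"
  expect_error(condition_soz_rate_test(dbad, ch), "one category")
})

test_that("AUROC equals the brute-force pair count and rank oracle", {
  ch <- make_channels(4, soz = c(TRUE, TRUE, FALSE, FALSE), partner = FALSE)
  rt <- make_rates(ch$channel_id, c(3, 5, 1, 4))
  r <- soz_roc(rt, ch, "RonO", "sleep", n_boot = 50, seed = 1)
  expect_equal(r$auroc, 0.75)                    # 3 of 4 pairs concordant
  # perfectly separated and all-tied scores
  expect_equal(soz_roc(make_rates(ch$channel_id, c(9, 8, 1, 2)), ch,
                       n_boot = 10, seed = 1)$auroc, 1.0)
  expect_equal(soz_roc(make_rates(ch$channel_id, rep(2, 4)), ch,
                       n_boot = 10, seed = 1)$auroc, 0.5)
  # single class errors
  ch1 <- make_channels(4, soz = rep(TRUE, 4), partner = FALSE)
  expect_error(soz_roc(make_rates(ch1$channel_id, 1:4), ch1,
                       n_boot = 10, seed = 1), "both")
})

test_that("curve-integrated AUROC matches the rank statistic to 1e-12", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n)                            # tie-free
    curve <- hfoseeg:::roc_curve(scores, labels)
    auc_curve <- hfoseeg:::trapezoid(curve$fpr, curve$tpr)
    auc_rank <- hfoseeg:::auroc_rank(scores, labels)
    expect_lt(abs(auc_curve - auc_rank), 1e-12)
    # invariance under strictly monotone transform
    expect_equal(hfoseeg:::auroc_rank(exp(scores), labels), auc_rank)
  }
})

test_that("partial AUROC covers the high-specificity segment", {
  ch <- make_channels(40, soz = seq_len(40) <= 10, partner = FALSE)
  set.seed(6)
  rt <- make_rates(ch$channel_id, c(rnorm(10, 5), rnorm(30, 1)))
  r <- soz_roc(rt, ch, "RonO", "sleep", n_boot = 100, seed = 2)
  expect_gte(r$partial_auroc, 0)
  expect_lte(r$partial_auroc, 1)
  expect_gt(r$auroc, 0.9)
  expect_true(r$auroc_ci_95[1] <= r$auroc & r$auroc <= r$auroc_ci_95[2])
  # bootstrap reproducible under fixed seed
  r2 <- soz_roc(rt, ch, "RonO", "sleep", n_boot = 100, seed = 2)
  expect_identical(r$auroc_ci_95, r2$auroc_ci_95)
})

test_that("compare_auroc: identity, validation, and paired power", {
  ch <- make_channels(40, soz = seq_len(40) <= 10, partner = FALSE)
  set.seed(61)
  rt <- make_rates(ch$channel_id, c(rnorm(10, 3), rnorm(30, 1)))
  rA <- soz_roc(rt, ch, "RonO", "sleep", n_boot = 50, seed = 3)
  cmp <- compare_auroc(rA, rA, n_boot = 200, seed = 4)
  expect_equal(cmp$delta, 0)
  expect_gt(cmp$p_value, 0.5)
  expect_error(compare_auroc(rA, rA, n_boot = 0), "positive")

  # sleep-boosted SOZ rates: delta detected in >= 80% of seeds
  detected <- 0L
  for (s in 1:10) {
    set.seed(300 + s)
    base <- c(rnorm(10, 1.5, 0.8), rnorm(30, 1, 0.8))
    sleep_rt <- make_rates(ch$channel_id,
                           pmax(base + c(rep(2.5, 10), rep(0, 30)) +
                                  rnorm(40, 0, 0.3), 0), "sleep")
    intra_rt <- make_rates(ch$channel_id, pmax(base + rnorm(40, 0, 0.3), 0),
                           "intraop")
    rS <- soz_roc(sleep_rt, ch, "RonO", "sleep", n_boot = 20, seed = s)
    rI <- soz_roc(intra_rt, ch, "RonO", "intraop", n_boot = 20, seed = s)
    cmp2 <- compare_auroc(rS, rI, n_boot = 400, seed = s)
    if (cmp2$delta > 0 && cmp2$p_value < 0.05) detected <- detected + 1L
  }
  expect_gte(detected, 8L)

  rB <- soz_roc(rt[-1, ], ch, "RonO", "sleep", n_boot = 50, seed = 3)
  expect_error(compare_auroc(rA, rB), "different channel sets")
})
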