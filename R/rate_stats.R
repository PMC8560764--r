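# Per-contact rates and group statistics: mixed-effects models of event
# power/frequency, condition x SOZ repeated-measures rate comparisons, and
# SOZ-classification ROC with bootstrap confidence intervals.

RATE_CATEGORIES <- EVENT_CATEGORIES  # Artifact never enters rate statistics

#' Per-contact event rates
#'
#' Counts events per channel x category and divides by analyzed minutes.
#' Every channel present in `channels` for the recording's patient appears
#' in every category, with rate 0 when no events occurred (zero-rate
#' contacts carry real information for ROC and reliability). Artifact-class
#' events are excluded.
#'
#' @param classified `ClassifiedEvent` data.frame (may span recordings if a
#'   `condition` and `patient_id` column is present)
#' @param channels `ChannelInfo`
#' @param durations named vector: minutes analyzed per `patient_id:condition`
#'   key, or a single number applying to all
#' @param condition condition label for the catalog if not a column
#' @return data.frame of class `RateTable`: `patient_id`, `channel_id`,
#'   `condition`, `category`, `n_events`, `minutes_analyzed`, `rate_per_min`
#' @export
compute_rates <- function(classified, channels, durations,
                          condition = NULL) {
  ev <- classified
  if (!is.null(condition) && is.null(ev$condition)) ev$condition <- condition
  if (nrow(ev)) {
    unknown <- setdiff(unique(ev$channel_id), channels$channel_id)
    if (length(unknown))
      stop("event(s) reference unknown channel(s): ",
           paste(unknown, collapse = ", "))
    ev <- ev[ev$category != "Artifact", , drop = FALSE]
  }
  conds <- unique(c(ev$condition,
                    if (is.null(condition)) character() else condition))
  if (!length(conds)) conds <- c("intraop", "sleep")
  grid <- expand.grid(channel_id = channels$channel_id,
                      condition = conds,
                      category = RATE_CATEGORIES,
                      stringsAsFactors = FALSE)
  grid$patient_id <- channels$patient_id[
    match(grid$channel_id, channels$channel_id)]
  key <- paste(grid$patient_id, grid$condition, sep = ":")
  if (length(durations) == 1L && is.null(names(durations))) {
    grid$minutes_analyzed <- as.numeric(durations)
  } else {
    grid$minutes_analyzed <- as.numeric(durations[key])
    if (anyNA(grid$minutes_analyzed))
      stop("missing duration for key(s): ",
           paste(unique(key[is.na(grid$minutes_analyzed)]), collapse = ", "))
  }
  cnt <- if (nrow(ev)) {
    stats::aggregate(list(n_events = rep(1L, nrow(ev))),
                     by = list(channel_id = ev$channel_id,
                               condition = ev$condition,
                               category = ev$category), FUN = sum)
  } else NULL
  grid$n_events <- 0L
  if (!is.null(cnt)) {
    k1 <- paste(grid$channel_id, grid$condition, grid$category)
    k2 <- paste(cnt$channel_id, cnt$condition, cnt$category)
    hit <- match(k1, k2)
    grid$n_events[!is.na(hit)] <- cnt$n_events[hit[!is.na(hit)]]
  }
  grid$rate_per_min <- grid$n_events / grid$minutes_analyzed
  out <- grid[, c("patient_id", "channel_id", "condition", "category",
                  "n_events", "minutes_analyzed", "rate_per_min")]
  out <- out[order(out$patient_id, out$channel_id, out$condition,
                   out$category), ]
  rownames(out) <- NULL
  class(out) <- c("RateTable", "data.frame")
  out
}

#' Mixed-effects model of event power or frequency
#'
#' Fits `log(response) ~ condition + soz + (1 | channel)` by maximum
#' likelihood (lme4), the random intercept absorbing inter-contact
#' differences. Power and spectral frequency are modeled on the natural-log
#' scale. Condition is coded 0 = intraop, 1 = sleep; SOZ 0/1.
#'
#' @param events `ClassifiedEvent` data.frame with `condition` and `power` /
#'   `spectral_freq_hz` columns
#' @param channels `ChannelInfo` (for the SOZ flag)
#' @param response `"log_power"` or `"log_frequency"`
#' @param category event category to model
#' @return object of class `MixedModelFit`: estimates, Wald 95% CIs,
#'   p-values for intercept / condition / SOZ, random-intercept SD,
#'   `n_events`, `singular` flag
#' @export
fit_power_frequency_model <- function(events, channels,
                                      response = c("log_power",
                                                   "log_frequency"),
                                      category = "RonO") {
  response <- match.arg(response)
  ev <- events[events$category == category, , drop = FALSE]
  raw <- if (response == "log_power") ev$power else ev$spectral_freq_hz
  ok <- is.finite(raw) & raw > 0
  ev <- ev[ok, , drop = FALSE]
  ev$y <- log(raw[ok])
  ev$soz <- channels$soz[match(ev$channel_id, channels$channel_id)]
  ev$cond01 <- as.integer(ev$condition == "sleep")
  tab <- table(ev$channel_id)
  if (sum(tab >= 2) < 2)
    stop("need >= 2 contacts with >= 2 events each for category ", category)
  fit <- lme4::lmer(y ~ cond01 + soz + (1 | channel_id), data = ev,
                    REML = FALSE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular mixed-model fit for ", category, " ", response)
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  terms <- c("intercept", "condition", "soz")
  structure(list(
    response = response, category = category,
    estimates = stats::setNames(est, terms),
    se = stats::setNames(se, terms),
    ci_low = stats::setNames(est - 1.96 * se, terms),
    ci_high = stats::setNames(est + 1.96 * se, terms),
    p_values = stats::setNames(p, terms),
    ranef_sd = sqrt(unname(lme4::VarCorr(fit)$channel_id[1])),
    n_events = nrow(ev), singular = singular),
    class = "MixedModelFit")
}

#' @export
print.MixedModelFit <- function(x, ...) {
  cat(sprintf("<MixedModelFit> %s %s (n = %d events)\n", x$category,
              x$response, x$n_events))
  for (t in names(x$estimates))
    cat(sprintf("  %-10s %8.4f [%6.3f, %6.3f]  p = %.3g\n", t,
                x$estimates[t], x$ci_low[t], x$ci_high[t], x$p_values[t]))
  invisible(x)
}

#' Repeated-measures comparison of rates: condition x between-factor
#'
#' Two-way repeated-measures decomposition on matched contacts (those with
#' both conditions): within-contact factor `condition`, between-contact
#' factor `soz` (or `lobe` / `anesthesia`). Estimated with `aov` error
#' strata (`Error(channel)`), the classical univariate rmANOVA, which for
#' two within levels is sphericity-exempt and equivalent to the
#' corresponding mixed model. Contacts missing either condition are dropped
#' and counted.
#'
#' @param rates a `RateTable` restricted to one category
#' @param channels `ChannelInfo`
#' @param between between-contact factor: `"soz"`, `"lobe"`, `"anesthesia"`
#' @return list: `table` (term, F, df1, df2, p), `n_contacts`, `n_dropped`
#' @export
condition_soz_rate_test <- function(rates, channels, between = "soz") {
  stopifnot(between %in% c("soz", "lobe", "anesthesia"))
  d <- as.data.frame(rates)
  if (length(unique(d$category)) > 1L)
    stop("restrict the rate table to one category first")
  cnt <- table(d$channel_id)
  full <- names(cnt)[cnt == 2L]
  n_dropped <- sum(cnt != 2L)
  d <- d[d$channel_id %in% full, , drop = FALSE]
  if (length(full) < 2L)
    stop("need >= 2 matched contacts with both conditions")
  d$between <- factor(channels[[between]][
    match(d$channel_id, channels$channel_id)])
  d$condition <- factor(d$condition)
  d$channel_id <- factor(d$channel_id)
  fit <- stats::aov(rate_per_min ~ between * condition +
                      Error(channel_id / condition), data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    for (i in seq_len(nrow(tab))) {
      term <- trimws(rownames(tab)[i])
      if (term == "Residuals") next
      rows[[length(rows) + 1L]] <- data.frame(
        term = sub("between", between, term),
        F = tab[i, "F value"],
        df1 = tab[i, "Df"],
        df2 = tab[nrow(tab), "Df"],
        p = tab[i, "Pr(>F)"], stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), n_contacts = length(full),
       n_dropped = n_dropped)
}

# ------------------------------------------------------------------- ROC

#' @keywords internal
auroc_rank <- function(scores, labels) {
  # Mann-Whitney with the 1/2 tie convention
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("need both classes for AUROC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
roc_curve <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels); n0 <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n0, 0)
  data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
}

#' @keywords internal
trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                             utils::tail(y, -1)) / 2)

#' @keywords internal
partial_auc <- function(curve, fpr_max = 0.2) {
  x <- curve$fpr; y <- curve$tpr
  if (!any(x <= fpr_max)) return(0)
  keep <- x <= fpr_max
  xs <- x[keep]; ys <- y[keep]
  if (max(xs) < fpr_max) {           # interpolate the segment boundary
    i <- which(!keep)[1]
    if (!is.na(i)) {
      x0 <- x[i - 1]; x1 <- x[i]
      y0 <- y[i - 1]; y1 <- y[i]
      yb <- y0 + (y1 - y0) * (fpr_max - x0) / max(x1 - x0, 1e-300)
      xs <- c(xs, fpr_max); ys <- c(ys, yb)
    }
  }
  trapezoid(xs, ys) / fpr_max
}

#' ROC analysis of SOZ classification by event rate
#'
#' Rate is the score, SOZ membership the positive class. AUROC equals the
#' Mann-Whitney U statistic normalized by n1*n0 (ties counted 1/2);
#' bootstrap over channels gives the percentile 95% CI; partial AUROC is
#' computed over specificity in (0.8, 1], normalized by the segment width.
#'
#' @param rates `RateTable`
#' @param channels `ChannelInfo`
#' @param category event category
#' @param condition recording condition to analyze
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed RNG seed
#' @param scope `"all"` or `"matched"` contacts
#' @return object of class `RocResult`
#' @export
soz_roc <- function(rates, channels, category = "RonO",
                    condition = "sleep", n_boot = 1000L, seed = 1L,
                    scope = c("all", "matched")) {
  scope <- match.arg(scope)
  d <- as.data.frame(rates)
  d <- d[d$category == category & d$condition == condition, , drop = FALSE]
  if (scope == "matched") {
    m <- channels$channel_id[channels$matched]
    d <- d[d$channel_id %in% m, , drop = FALSE]
  }
  labels <- channels$soz[match(d$channel_id, channels$channel_id)]
  if (length(unique(labels)) < 2L)
    stop("need both SOZ and non-SOZ channels")
  scores <- d$rate_per_min
  auc <- auroc_rank(scores, labels)
  curve <- roc_curve(scores, labels)
  pauc <- partial_auc(curve, fpr_max = 1 - 0.8)
  set.seed(seed)
  boots <- replicate(n_boot, {
    idx <- sample(length(scores), replace = TRUE)
    if (length(unique(labels[idx])) < 2L) NA_real_
    else auroc_rank(scores[idx], labels[idx])
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(category = category, condition = condition,
                 scope = scope, curve = curve, auroc = auc,
                 auroc_ci_95 = ci, partial_auroc = pauc,
                 n_bootstrap = n_boot, n_channels = length(scores),
                 scores = scores, labels = labels,
                 channel_ids = d$channel_id),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf(
    "<RocResult> %s / %s (%s, n = %d): AUROC %.3f [%.3f, %.3f], pAUROC %.3f\n",
    x$category, x$condition, x$scope, x$n_channels, x$auroc,
    x$auroc_ci_95[1], x$auroc_ci_95[2], x$partial_auroc))
  invisible(x)
}

#' Paired bootstrap comparison of two AUROCs
#'
#' Both ROC results must come from the same channels (e.g. the same matched
#' contacts in the two conditions). Channels are resampled jointly; the
#' two-sided p-value tests Delta-AUROC != 0 by the bootstrap percentile
#' method with add-one smoothing.
#'
#' @param rocA,rocB `RocResult`s over identical channel sets
#' @param n_boot paired bootstrap replicates (> 0)
#' @param seed RNG seed
#' @return list: `delta` (A minus B), `ci_95`, `p_value`, `n_boot`
#' @export
compare_auroc <- function(rocA, rocB, n_boot = 1000L, seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be positive")
  if (length(rocA$channel_ids) != length(rocB$channel_ids) ||
      !setequal(rocA$channel_ids, rocB$channel_ids))
    stop("ROC results cover different channel sets")
  ord <- match(rocA$channel_ids, rocB$channel_ids)
  sB <- rocB$scores[ord]
  sA <- rocA$scores
  labels <- rocA$labels
  delta <- rocA$auroc - rocB$auroc
  set.seed(seed)
  n <- length(sA)
  deltas <- replicate(n_boot, {
    idx <- sample(n, replace = TRUE)
    if (length(unique(labels[idx])) < 2L) return(NA_real_)
    auroc_rank(sA[idx], labels[idx]) - auroc_rank(sB[idx], labels[idx])
  })
  deltas <- deltas[is.finite(deltas)]
  ci <- stats::quantile(deltas, c(0.025, 0.975), names = FALSE)
  p_lo <- (1 + sum(deltas <= 0)) / (1 + length(deltas))
  p_hi <- (1 + sum(deltas >= 0)) / (1 + length(deltas))
  list(delta = delta, ci_95 = ci, p_value = min(1, 2 * min(p_lo, p_hi)),
       n_boot = n_boot)
}
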