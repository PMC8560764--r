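# Epileptogenic-zone proxy and resection-outcome scoring.
#
# The putative EZ for a patient is the set of contacts whose event rate
# exceeds the 95th percentile of the pooled contact-rate distribution for
# the chosen scope. A patient is predicted to fail surgery when some EZ
# contact was left unresected; the actual outcome is failure when the Engel
# class is IIa or worse. Patient-level labels are cross-tabulated into
# sensitivity / specificity / PPV / NPV / accuracy with exact binomial CIs.

#' Define the putative EZ per patient
#'
#' The rate threshold is the `percentile` (default 95th) of the pooled
#' rates of all in-scope contacts of that patient's recording, computed by
#' linear interpolation (R quantile type 7); contacts strictly exceeding it
#' form the EZ.
#'
#' @param rates `RateTable`
#' @param channels `ChannelInfo`
#' @param category event category
#' @param scope `"intraop"` (matched contacts, intraop rates),
#'   `"sleep_matched"` (matched contacts, sleep rates) or `"sleep_all"`
#'   (all contacts, sleep rates)
#' @param percentile pooled-rate percentile (default 0.95)
#' @return data.frame of class `EZDefinition`: one row per patient with
#'   `threshold_rate`, `ez_channels` (list column), `n_contacts`
#' @export
define_ez <- function(rates, channels, category = "fRonO",
                      scope = c("intraop", "sleep_matched", "sleep_all"),
                      percentile = 0.95) {
  scope <- match.arg(scope)
  d <- as.data.frame(rates)
  cond <- if (scope == "intraop") "intraop" else "sleep"
  d <- d[d$category == category & d$condition == cond, , drop = FALSE]
  if (scope != "sleep_all") {
    m <- channels$channel_id[channels$matched]
    d <- d[d$channel_id %in% m, , drop = FALSE]
  }
  if (nrow(d) == 0L) stop("empty scope: no contacts with rates for ",
                          category, " / ", scope)
  out <- list()
  for (pid in unique(d$patient_id)) {
    dp <- d[d$patient_id == pid, , drop = FALSE]
    if (nrow(dp) < 20L)
      warning("patient ", pid, ": only ", nrow(dp),
              " contacts in scope; 95th percentile is unstable")
    thr <- unname(stats::quantile(dp$rate_per_min, percentile, type = 7))
    ez <- dp$channel_id[dp$rate_per_min > thr]
    if (all(dp$rate_per_min == 0))
      warning("patient ", pid, ": all rates zero; EZ empty")
    out[[pid]] <- data.frame(patient_id = pid, category = category,
                             condition_scope = scope, threshold_rate = thr,
                             n_contacts = nrow(dp),
                             stringsAsFactors = FALSE)
    out[[pid]]$ez_channels <- list(ez)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("EZDefinition", "data.frame")
  res
}

#' Score one patient's EZ-resection prediction against outcome
#'
#' Positive prediction: some EZ contact was left unresected. Actual
#' positive: Engel IIa or worse. Excluded when the outcome is missing, the
#' patient has no post-op MRI, or the resection status of an EZ contact is
#' unknown (resected region not sampled). An empty EZ is a negative
#' prediction.
#'
#' @param ez one-row `EZDefinition` for the patient
#' @param channels `ChannelInfo`
#' @param outcome one-row `PatientOutcome` (or NULL when missing)
#' @return one of `"TP"`, `"FP"`, `"TN"`, `"FN"`, `"excluded"`
#' @export
score_patient <- function(ez, channels, outcome) {
  if (is.null(outcome) || nrow(outcome) == 0L || is.na(outcome$engel_class))
    return("excluded")
  if (!isTRUE(outcome$postop_mri)) return("excluded")
  ez_ch <- ez$ez_channels[[1]]
  res <- channels$resected[match(ez_ch, channels$channel_id)]
  if (length(ez_ch) && anyNA(res)) return("excluded")
  predicted_pos <- length(ez_ch) > 0 && any(!res)
  actual_pos <- isTRUE(is_failure(outcome$engel_class))
  if (predicted_pos && actual_pos) "TP"
  else if (predicted_pos && !actual_pos) "FP"
  else if (!predicted_pos && actual_pos) "FN"
  else "TN"
}

#' Aggregate per-patient labels into contingency metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), accuracy = (TP+TN)/N. A 0/0 ratio is reported as 0.0
#' and flagged degenerate. 95% CIs are Clopper-Pearson.
#'
#' @param labels character vector of `"TP"/"FP"/"TN"/"FN"/"excluded"`
#' @return object of class `ContingencyMetrics`
#' @export
aggregate_metrics <- function(labels) {
  labels <- labels[labels != "excluded"]
  if (!length(labels)) stop("all patients excluded")
  tp <- sum(labels == "TP"); fp <- sum(labels == "FP")
  tn <- sum(labels == "TN"); fn <- sum(labels == "FN")
  ratio <- function(num, den) if (den == 0) 0.0 else num / den
  ci <- function(num, den) if (den == 0) c(0, 0) else binomial_ci(num, den)
  metrics <- list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = ratio(tp + tn, tp + fp + tn + fn))
  cis <- list(
    sensitivity = ci(tp, tp + fn),
    specificity = ci(tn, tn + fp),
    ppv = ci(tp, tp + fp),
    npv = ci(tn, tn + fn),
    accuracy = ci(tp + tn, tp + fp + tn + fn))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 metrics = metrics, ci_95 = cis,
                 degenerate = vapply(
                   list(c(tp, fn), c(tn, fp), c(tp, fp), c(tn, fn)),
                   function(x) sum(x) == 0, TRUE) |>
                   stats::setNames(c("sensitivity", "specificity", "ppv",
                                     "npv")),
                 n = tp + fp + tn + fn),
            class = "ContingencyMetrics")
}

#' @export
print.ContingencyMetrics <- function(x, ...) {
  cat(sprintf("<ContingencyMetrics> TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n))
  for (m in names(x$metrics))
    cat(sprintf("  %-12s %.2f [%.2f-%.2f]%s\n", m, x$metrics[[m]],
                x$ci_95[[m]][1], x$ci_95[[m]][2],
                if (isTRUE(x$degenerate[m])) " (degenerate 0/0)" else ""))
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Beta-quantile form: lower = qbeta(alpha/2, s, n-s+1), upper =
#' qbeta(1-alpha/2, s+1, n-s), with 0 successes giving lower 0 and s = n
#' giving upper 1.
#'
#' @param successes,n integer counts, 0 <= successes <= n, n >= 1
#' @param level confidence level
#' @return numeric length-2 (low, high)
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  if (n < 1L) stop("n must be >= 1")
  stopifnot(successes >= 0, successes <= n)
  alpha <- 1 - level
  lo <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lo, hi)
}

#' Cohort outcome analysis for one category and scope
#'
#' Defines the EZ per patient, scores each against outcome, aggregates.
#'
#' @param rates `RateTable`
#' @param channels `ChannelInfo`
#' @param outcomes `PatientOutcome`
#' @param category event category
#' @param scope see [define_ez()]
#' @return list: `metrics` (`ContingencyMetrics`), `labels` (named per
#'   patient), `ez` (`EZDefinition`)
#' @export
outcome_analysis <- function(rates, channels, outcomes, category = "fRonO",
                             scope = "sleep_all") {
  ez <- define_ez(rates, channels, category, scope)
  labels <- vapply(seq_len(nrow(ez)), function(i) {
    pid <- ez$patient_id[i]
    score_patient(ez[i, , drop = FALSE], channels,
                  outcomes[outcomes$patient_id == pid, , drop = FALSE])
  }, "")
  names(labels) <- ez$patient_id
  list(metrics = aggregate_metrics(labels), labels = labels, ez = ez)
}
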