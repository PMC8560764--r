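# Spatial reliability of per-contact rate maps across conditions:
# normalized scalar product with a channel-permutation null.

#' Normalized scalar product of two rate vectors
#'
#' `dot(v1, v2) / (||v1|| * ||v2||)`. Equals 1 iff the vectors are positive
#' scalar multiples; 0 for disjoint support. A zero vector has no direction,
#' so the result is flagged `undefined` (NA), distinct from 0.
#'
#' @param v1,v2 equal-length numeric vectors (length >= 2)
#' @return scalar in [-1, 1], or NA with attribute `undefined = TRUE`
#' @export
scalar_product <- function(v1, v2) {
  stopifnot(length(v1) == length(v2), length(v1) >= 2L)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    return(structure(NA_real_, undefined = TRUE))
  sum(v1 * v2) / (n1 * n2)
}

#' Permutation test of spatial rate reliability
#'
#' The observed normalized scalar product is compared with a null built by
#' independently permuting the channel order of each vector in every
#' replicate (N = 2000 by default). One-sided (alignment larger than
#' chance): `p = (1 + #(s_perm >= s_obs)) / (1 + n_perm)`, so p is always
#' positive and in (0, 1].
#'
#' @param v1,v2 rate vectors over the same matched channels (length >= 3)
#' @param n_perm permutation replicates
#' @param seed RNG seed (deterministic output for fixed seed)
#' @param patient_id,category labels carried into the result
#' @return object of class `ReliabilityResult`: `s_obs`, `p_value`,
#'   `n_perm`, `null_mean`, `null_q95`, `undefined` flag
#' @export
permutation_reliability <- function(v1, v2, n_perm = 2000L, seed = 1L,
                                    patient_id = NA_character_,
                                    category = NA_character_) {
  stopifnot(length(v1) == length(v2))
  if (length(v1) < 3L)
    stop("need >= 3 channels for a non-degenerate permutation null")
  if (n_perm < 100L)
    warning("n_perm < 100 gives a coarse p-value resolution")
  s_obs <- scalar_product(v1, v2)
  undefined <- isTRUE(attr(s_obs, "undefined")) ||
    stats::var(v1) == 0 || stats::var(v2) == 0
  if (undefined) {
    return(structure(list(patient_id = patient_id, category = category,
                          s_obs = as.numeric(s_obs), p_value = NA_real_,
                          n_perm = n_perm, null_mean = NA_real_,
                          null_q95 = NA_real_, undefined = TRUE),
                     class = "ReliabilityResult"))
  }
  set.seed(seed)
  n <- length(v1)
  s_null <- replicate(n_perm,
                      scalar_product(v1[sample.int(n)], v2[sample.int(n)]))
  p <- (1 + sum(s_null >= s_obs)) / (1 + n_perm)
  structure(list(patient_id = patient_id, category = category,
                 s_obs = as.numeric(s_obs), p_value = p, n_perm = n_perm,
                 null_mean = mean(s_null),
                 null_q95 = unname(stats::quantile(s_null, 0.95)),
                 undefined = FALSE),
            class = "ReliabilityResult")
}

#' @export
print.ReliabilityResult <- function(x, ...) {
  cat(sprintf("<ReliabilityResult> %s %s: s = %.4f, p = %s (n_perm = %d)\n",
              x$patient_id, x$category, x$s_obs,
              if (is.na(x$p_value)) "undefined" else format(x$p_value),
              x$n_perm))
  invisible(x)
}

#' Exact permutation p-value by full enumeration (small-n oracle)
#'
#' Enumerates all n!^2 channel-order pairs (feasible for n <= 6 by fixing
#' one vector: the scalar-product null depends only on the relative order,
#' so enumerating n! permutations of one vector is exhaustive).
#'
#' @param v1,v2 vectors, length <= 7
#' @return exact one-sided p with add-one smoothing over the n! null
#' @export
exhaustive_reliability_p <- function(v1, v2) {
  n <- length(v1)
  stopifnot(n == length(v2), n >= 3L, n <= 7L)
  s_obs <- scalar_product(v1, v2)
  perms <- all_permutations(n)
  s_null <- apply(perms, 1, function(p) scalar_product(v1, v2[p]))
  (1 + sum(s_null >= as.numeric(s_obs))) / (1 + nrow(perms))
}

#' @keywords internal
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Cohort-wide reliability analysis
#'
#' One permutation test per patient x category on the matched contacts'
#' intraop vs sleep rate vectors. Patients with fewer than 3 matched
#' contacts (both conditions present) are skipped and listed.
#'
#' @param rates a `RateTable` over matched contacts, both conditions
#' @param channels `ChannelInfo`
#' @param categories categories to test
#' @param n_perm,seed passed to [permutation_reliability()]
#' @return list: `results` (data.frame with s_obs, p per patient x
#'   category), `skipped` (patient ids with < 3 matched contacts)
#' @export
cohort_reliability <- function(rates, channels,
                               categories = EVENT_CATEGORIES,
                               n_perm = 2000L, seed = 1L) {
  d <- as.data.frame(rates)
  matched_ids <- channels$channel_id[channels$matched]
  d <- d[d$channel_id %in% matched_ids, , drop = FALSE]
  out <- list(); skipped <- character()
  for (pid in unique(d$patient_id)) {
    dp <- d[d$patient_id == pid, , drop = FALSE]
    chs <- intersect(unique(dp$channel_id[dp$condition == "intraop"]),
                     unique(dp$channel_id[dp$condition == "sleep"]))
    if (length(chs) < 3L) { skipped <- c(skipped, pid); next }
    for (cat in categories) {
      s1 <- dp[dp$condition == "intraop" & dp$category == cat, , drop = FALSE]
      s2 <- dp[dp$condition == "sleep" & dp$category == cat, , drop = FALSE]
      v1 <- s1$rate_per_min[match(chs, s1$channel_id)]
      v2 <- s2$rate_per_min[match(chs, s2$channel_id)]
      r <- permutation_reliability(v1, v2, n_perm,
                                   seed = derive_seed(seed, "reliability") +
                                     match(cat, categories),
                                   patient_id = pid, category = cat)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, category = cat, s_obs = r$s_obs,
        p_value = r$p_value, n_perm = n_perm,
        significant = !is.na(r$p_value) && r$p_value < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  list(results = if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(), category = character(),
               s_obs = numeric(), p_value = numeric(),
               n_perm = integer(), significant = logical()),
    skipped = skipped)
}
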