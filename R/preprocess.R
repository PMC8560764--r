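# Montage construction and component-based artifact attenuation.

#' Derive a bipolar montage
#'
#' Each bipolar trace is the sample-wise difference between a contact and
#' its declared `montage_partner` (adjacent contact on the same electrode).
#' Channels without a partner are dropped from the bipolar view.
#'
#' @param rec a `Recording` (referential)
#' @param channels `ChannelInfo` with `montage_partner` declared for
#'   participating contacts
#' @return a `Recording` whose channel ids are `"<a>-<b>"`
#' @export
to_bipolar <- function(rec, channels) {
  pairs <- channels[!is.na(channels$montage_partner) &
                      channels$channel_id %in% rec$channel_ids, ,
                    drop = FALSE]
  if (nrow(pairs) == 0L) stop("no montage_partner pairs declared")
  missing <- setdiff(pairs$montage_partner, rec$channel_ids)
  if (length(missing))
    stop("montage partner(s) missing from recording: ",
         paste(missing, collapse = ", "))
  a <- match(pairs$channel_id, rec$channel_ids)
  b <- match(pairs$montage_partner, rec$channel_ids)
  samples <- rec$samples[a, , drop = FALSE] - rec$samples[b, , drop = FALSE]
  recording(samples, rec$rate_hz,
            paste0(pairs$channel_id, "-", pairs$montage_partner),
            rec$condition, rec$patient_id, rec$start_time_s)
}

# ---- FastICA (symmetric, tanh contrast) --------------------------------
# No ICA package ships with the supported stack, so the standard fixed-point
# algorithm is implemented here: PCA whitening followed by symmetric
# orthogonalized updates of W with the tanh nonlinearity.

#' @keywords internal
fast_ica <- function(X, n_comp = nrow(X), max_iter = 200L, tol = 1e-6) {
  # X: channels x samples, rows will be centered
  X <- X - rowMeans(X)
  n <- ncol(X)
  C <- X %*% t(X) / n
  eig <- eigen(C, symmetric = TRUE)
  keep <- seq_len(n_comp)
  d <- eig$values[keep]
  if (any(d < 1e-12 * max(d)))
    stop("ICA whitening failed: rank-deficient covariance")
  K <- diag(1 / sqrt(d), n_comp) %*% t(eig$vectors[, keep, drop = FALSE])
  Z <- K %*% X                                   # whitened
  W <- matrix(stats::rnorm(n_comp^2), n_comp)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- 1 - G^2
    W_new <- (G %*% t(Z)) / n - diag(rowMeans(gprime)) %*% W
    W_new <- sym_orth(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    # near-Gaussian data has no identifiable rotation: the fixed point
    # wanders harmlessly. Proceed with the last iterate; any strongly
    # non-Gaussian (artifact) direction has already stabilized.
    warning("ICA did not fully converge after ", max_iter,
            " iterations (last delta = ", signif(delta, 3),
            "); using last iterate", call. = FALSE)
  if (anyNA(W)) stop("ICA diverged: non-finite unmixing matrix")
  S <- W %*% Z                                   # sources x samples
  A <- MASS_ginv(K) %*% t(W)                     # mixing: X ~ A %*% S
  list(S = S, A = A, W = W, K = K)
}

# minimal Moore-Penrose pseudoinverse (avoids a MASS dependency)
#' @keywords internal
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Component-based artifact reduction
#'
#' Decomposes the recording into independent components and flags as
#' artifact any component whose high-band (> `highband_hz`) power fraction
#' AND excess kurtosis both exceed their thresholds -- the signature of
#' bursty broadband muscle / electrode noise, as opposed to brief
#' physiological HFOs which contribute little to a whole-recording
#' component's power. Flagged components are removed globally and the
#' recording reconstructed. With no flagged component the output equals the
#' input up to numerical precision.
#'
#' @param rec a `Recording` with >= 8 channels and >= 60 s
#' @param config an `hfo_config` (uses `$preprocess`)
#' @param n_comp number of components (default: channel count)
#' @return list: `recording` (cleaned), `report` (flagged components,
#'   per-component metrics, variance removed)
#' @export
reduce_artifacts_ica <- function(rec, config = hfo_config(),
                                 n_comp = nrow(rec$samples)) {
  opt <- config$preprocess
  if (!isTRUE(opt$ica_enabled)) {
    return(list(recording = rec,
                report = list(enabled = FALSE, flagged = integer(),
                              variance_removed = 0)))
  }
  n_ch <- nrow(rec$samples)
  if (n_ch < 8L) stop("ICA requires >= 8 channels, got ", n_ch)
  if (duration_s(rec) < 60) stop("ICA requires >= 60 s of signal")
  if (n_comp > n_ch)
    stop("requested ", n_comp, " components from ", n_ch, " channels")
  set.seed(derive_seed(config$seed, "preprocess"))
  fit <- fast_ica(rec$samples, n_comp, opt$ica_max_iter, opt$ica_tol)
  rate <- rec$rate_hz
  metrics <- t(apply(fit$S, 1, function(s) {
    sp <- Mod(stats::fft(s))^2
    nf <- length(sp)
    f <- (seq_len(nf) - 1) / nf * rate
    f <- pmin(f, rate - f)
    hb <- sum(sp[f > opt$highband_hz]) / sum(sp)
    c(highband_fraction = hb, kurtosis = sample_kurtosis(s))
  }))
  flagged <- which(metrics[, "highband_fraction"] >
                     opt$highband_fraction_threshold &
                   metrics[, "kurtosis"] > opt$kurtosis_threshold)
  cleaned <- rec
  variance_removed <- 0
  if (length(flagged)) {
    S2 <- fit$S
    S2[flagged, ] <- 0
    means <- rowMeans(rec$samples)
    recon <- fit$A %*% S2 + means
    variance_removed <- 1 - sum(apply(recon, 1, stats::var)) /
      sum(apply(rec$samples, 1, stats::var))
    cleaned$samples <- recon
    rownames(cleaned$samples) <- rec$channel_ids
  }
  list(recording = cleaned,
       report = list(enabled = TRUE, n_components = n_comp,
                     flagged = as.integer(flagged),
                     metrics = as.data.frame(metrics),
                     variance_removed = variance_removed,
                     removal_scope = "global"))
}
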