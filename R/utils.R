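# ---- small numeric helpers shared across modules ----

#' Sample skewness (method-of-moments, g1)
#'
#' @param x numeric vector
#' @return scalar skewness; 0 for degenerate (constant) input
#' @keywords internal
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Sample excess kurtosis (g2)
#' @keywords internal
sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

#' FFT-based linear convolution of a long signal with a short kernel
#'
#' Returns the "same" part: output has length(x), aligned so that a
#' symmetric kernel introduces no shift (centre tap at each sample).
#' @keywords internal
fft_conv_same <- function(x, kernel) {
  nx <- length(x)
  nk <- length(kernel)
  nfull <- nx + nk - 1L
  n <- stats::nextn(nfull, c(2, 3, 5))   # smallest 5-smooth length
  X <- stats::fft(c(x, numeric(n - nx)))
  K <- stats::fft(c(kernel, numeric(n - nk)))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / n
  offset <- (nk - 1L) %/% 2L
  full[(offset + 1L):(offset + nx)]
}

#' Analytic signal via frequency-domain Hilbert transform
#'
#' @param x real, zero-mean vector
#' @return complex vector z(t) = a(t) exp(i phi(t))
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Centered moving average with edge renormalization
#'
#' Each output sample is the mean of the kernel samples that fall inside the
#' series, so edges are partial means rather than zero-padded.
#' @keywords internal
moving_average <- function(x, width) {
  width <- as.integer(width)
  stopifnot(width >= 1L)
  if (width == 1L) return(x)
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' 1/f^alpha ("pink") Gaussian noise via spectral shaping
#'
#' @param n samples
#' @param alpha PSD exponent (power ~ 1/f^alpha)
#' @param sd target standard deviation of the output
#' @keywords internal
pink_noise <- function(n, alpha = 1, sd = 1) {
  if (n < 2L) return(numeric(n))
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1L))            # avoid the DC singularity
  f <- pmin(f, n - f + 1)               # two-sided frequency index
  X <- X * (1 / f^(alpha / 2))
  X[1L] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x - mean(x)
}

#' Deterministic per-stage seed derivation
#'
#' One user-facing seed is expanded into independent stage seeds by a fixed
#' affine scheme, kept below 2^31.
#' @param seed integer master seed
#' @param stage character stage name
#' @keywords internal
derive_seed <- function(seed, stage) {
  stages <- c("simulate", "preprocess", "detect", "classify",
              "rates", "roc", "reliability", "outcome", "misc")
  idx <- match(stage, stages)
  if (is.na(idx)) idx <- 9L
  as.integer((as.numeric(seed) * 131L + idx * 7919L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
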