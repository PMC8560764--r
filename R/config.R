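# Pipeline configuration: every tunable of the detector, classifier and
# statistics stages lives here so each run can log its full parameterization.

#' Default pipeline configuration
#'
#' Returns the full set of tunables with their defaults. Detector values
#' follow the Hilbert-detector design: 1000th-order symmetric FIR band-pass
#' (80-600 Hz broad pass, 250-600 Hz fast-ripple pass), 40 ms envelope
#' smoothing, whole-series z-scoring, and a skewness-adapted threshold
#' `clamp(base + gain * max(0, skewness), floor, ceiling)`.
#'
#' @param ... named overrides of any default value (nested lists merged one
#'   level deep).
#' @return object of class `hfo_config` (a named list)
#' @export
#' @examples
#' cfg <- hfo_config(detector = list(smooth_window_ms = 30))
#' cfg$detector$smooth_window_ms
hfo_config <- function(...) {
  cfg <- list(
    seed = 1L,
    detector = list(
      filter_order = 1000L,
      bands = list(broad_hfo = c(80, 600), fast_ripple = c(250, 600)),
      smooth_window_ms = 20,
      threshold_base = 3.0,
      threshold_gain = 0.5,
      threshold_floor = 3.0,
      threshold_ceiling = 6.0,
      merge_gap_ms = 10,
      min_duration_ms = list(broad_hfo = 20, fast_ripple = 10),
      boundary_fraction = 0.5,       # walk-out to half-threshold crossing
      dedup_overlap = 0.5,
      montages = c("referential", "bipolar")
    ),
    classifier = list(
      tf_freqs_min = 32, tf_freqs_max = 600, tf_n_freqs = 40L,
      wavelet_cycles = 7,
      context_s = 0.25,              # excerpt = event +/- context
      island_contour = 0.5,          # fraction of event-window peak power
      island_low_floor_hz = 65,      # 80 Hz minus the 7-cycle Morlet
                                     # half-power bandwidth at the band edge
      ripple_split_hz = 250,         # ripple vs fast-ripple boundary
      spike_highpass_hz = 4,         # exclude delta/slow-wave activity from
      spike_lowpass_hz = 30,         # the spike-band amplitude scale
      spike_amp_z = 5, spike_slope_z = 5,
      spike_window_ms = 50,
      artifact_rate_cap = 0.05
    ),
    preprocess = list(
      ica_enabled = TRUE,
      ica_max_iter = 200L, ica_tol = 1e-6,
      highband_hz = 80,
      highband_fraction_threshold = 0.6,
      kurtosis_threshold = 5
    ),
    stats = list(
      n_boot = 1000L,
      n_perm = 2000L,
      ez_percentile = 0.95,
      partial_spec_min = 0.8
    )
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(overrides[[nm]])) cfg[[nm]][[k]] <- overrides[[nm]][[k]]
    } else cfg[[nm]] <- overrides[[nm]]
  }
  structure(cfg, class = "hfo_config")
}

#' Write / read a configuration as JSON
#'
#' Round-trips losslessly: `read_config(write_config(cfg, f))` equals `cfg`.
#' @param config an `hfo_config`
#' @param path file path
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   configuration.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "hfo_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(hfo_config())
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(hfo_config, raw)
}

#' @export
print.hfo_config <- function(x, ...) {
  cat("<hfo_config> seed =", x$seed, "\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
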