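# Shared constants (this file collates first).

#' Event categories
#'
#' The five ground-truth / classified event categories: ripple on
#' oscillation, ripple on spike, fast-ripple analogs, and sharp-spike.
#' Classified catalogs may additionally contain `"Artifact"`, which never
#' enters rate statistics.
#' @export
EVENT_CATEGORIES <- c("RonO", "RonS", "fRonO", "fRonS", "SharpSpike")

#' @rdname EVENT_CATEGORIES
#' @export
HFO_CATEGORIES <- c("RonO", "RonS", "fRonO", "fRonS")
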