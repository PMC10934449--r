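#' Mono waveform container
#'
#' The unit every stage of the pipeline consumes and produces: a mono audio
#' signal with its sample rate and a free-text provenance tag.
#'
#' @param samples numeric vector of samples in \[-1, 1\].
#' @param rate sample rate in Hz (> 0).
#' @param source_id free-text provenance (file name, synthesis spec, ...).
#' @return An object of class `waveform`: a list with elements `samples`,
#'   `rate`, `source_id`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000, "a4")
#' wave_duration(w)
#' @export
waveform <- function(samples, rate, source_id = "") {
  stopifnot_scalar(rate, "rate", positive = TRUE)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("waveform samples must all be finite")
  if (any(abs(samples) > 1 + 1e-6))
    stop("waveform samples must lie in [-1, 1]")
  structure(list(samples = samples, rate = rate,
                 source_id = as.character(source_id)[1L]),
            class = "waveform")
}

#' @rdname waveform
#' @param w a `waveform`.
#' @return `wave_duration()`: duration in seconds.
#' @export
wave_duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)  source: %s\n",
              length(x$samples), x$rate, wave_duration(x),
              if (nzchar(x$source_id)) x$source_id else "<unset>"))
  invisible(x)
}
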