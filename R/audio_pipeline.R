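#' Pre-emphasis filter
#'
#' First-order high-pass difference `y[n] = x[n] - alpha * x[n-1]` (with
#' `y[1] = x[1]`), the conventional spectral-tilt compensation applied before
#' short-time analysis of speech.
#'
#' @param w a [waveform].
#' @param alpha filter coefficient in \[0, 1).
#' @return A [waveform] of the same length.
#' @export
pre_emphasis <- function(w, alpha = 0.97) {
  stopifnot(inherits(w, "waveform"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("`alpha` must lie in [0, 1)")
  x <- w$samples
  y <- c(x[1L], x[-1L] - alpha * x[-length(x)])
  out <- w
  out$samples <- y
  out
}

window_vector <- function(n, window = c("hamming", "hann", "rectangular")) {
  window <- match.arg(window)
  k <- seq_len(n) - 1L
  switch(window,
    hamming     = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
    hann        = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
    rectangular = rep(1, n))
}

#' Slice a waveform into windowed analysis frames
#'
#' Produces `1 + floor((N - frame_len) / hop)` frames; a trailing remainder
#' shorter than one frame is discarded. The window is applied
#' multiplicatively.
#'
#' @param w a [waveform].
#' @param frame_len_s frame length in seconds (default 25 ms).
#' @param hop_s hop between frame starts in seconds (default 10 ms).
#' @param window window shape: `"hamming"` (default), `"hann"` or
#'   `"rectangular"`.
#' @return A `frame_matrix`: list with `frames` (n_frames x frame_len
#'   matrix), `frame_len`, `hop` (samples), `window`, `rate`.
#' @export
frame_signal <- function(w, frame_len_s = 0.025, hop_s = 0.010,
                         window = c("hamming", "hann", "rectangular")) {
  stopifnot(inherits(w, "waveform"))
  window <- match.arg(window)
  stopifnot_scalar(frame_len_s, "frame_len_s", positive = TRUE)
  stopifnot_scalar(hop_s, "hop_s", positive = TRUE)
  frame_len <- as.integer(round(frame_len_s * w$rate))
  hop <- max(1L, as.integer(round(hop_s * w$rate)))
  n <- length(w$samples)
  if (n < frame_len)
    stop(sprintf("signal (%d samples) shorter than one frame (%d)", n, frame_len))
  n_frames <- 1L + (n - frame_len) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(starts, seq_len(frame_len), `+`)
  frames <- matrix(w$samples[idx], nrow = n_frames)
  frames <- sweep(frames, 2L, window_vector(frame_len, window), `*`)
  structure(list(frames = frames, frame_len = frame_len, hop = hop,
                 window = window, rate = w$rate),
            class = "frame_matrix")
}

#' Partition a recording into non-overlapping fixed-length samples
#'
#' Cuts consecutive, disjoint, equal-length chunks; the final remainder
#' shorter than `sample_len_s` is discarded. Each chunk's `source_id`
#' records the parent id and the 1-based chunk index as
#' `"<source_id>#<index>"`.
#'
#' @param w a [waveform].
#' @param sample_len_s chunk length in seconds (default 1.0).
#' @return A list of [waveform] chunks (empty, with a warning, when the
#'   recording is shorter than one chunk).
#' @export
partition_samples <- function(w, sample_len_s = 1.0) {
  stopifnot(inherits(w, "waveform"))
  stopifnot_scalar(sample_len_s, "sample_len_s", positive = TRUE)
  len <- as.integer(round(sample_len_s * w$rate))
  n_chunks <- length(w$samples) %/% len
  if (n_chunks == 0L) {
    warning(sprintf("recording %s (%.3f s) shorter than one sample length (%g s)",
                    w$source_id, wave_duration(w), sample_len_s))
    return(list())
  }
  lapply(seq_len(n_chunks), function(i) {
    out <- w
    out$samples <- w$samples[((i - 1L) * len + 1L):(i * len)]
    out$source_id <- sprintf("%s#%d", w$source_id, i)
    out
  })
}
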