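#' Cepstral front-end configuration
#'
#' Settings shared by the MFCC and GTCC extractors. Defaults follow common
#' speech-analysis practice: 13 coefficients (including the 0th), 40 filters
#' per bank, 25 ms Hamming frames with 10 ms hop, pre-emphasis 0.97.
#'
#' @param n_coeffs number of cepstral coefficients kept per bank (default 13).
#' @param n_mel_filters,n_gammatone_filters filters per bank (default 40).
#' @param fmin,fmax filterbank frequency range in Hz; `fmax = NULL` means
#'   half the sample rate.
#' @param include_c0 keep the 0th (log-energy) coefficient? Default `TRUE`,
#'   so the 13 coefficients are c0..c12.
#' @param log_floor positive floor applied to filterbank energies before the
#'   logarithm, guarding silent frames.
#' @param mel_variant `"htk"` (2595 log10(1 + f/700), default) or `"slaney"`
#'   (linear below 1 kHz, logarithmic above).
#' @param frame_len_s,hop_s,window framing parameters (see [frame_signal]).
#' @param preemph_alpha pre-emphasis coefficient (see [pre_emphasis]).
#' @param aggregate how per-frame coefficients are pooled into one vector per
#'   audio sample: `"mean"` (default), `"median"`, or `"mean_sd"` (mean and
#'   standard deviation, doubling the dimension).
#' @return An object of class `cepstral_config`.
#' @export
cepstral_config <- function(n_coeffs = 13L, n_mel_filters = 40L,
                            n_gammatone_filters = 40L, fmin = 50,
                            fmax = NULL, include_c0 = TRUE,
                            log_floor = 1e-10,
                            mel_variant = c("htk", "slaney"),
                            frame_len_s = 0.025, hop_s = 0.010,
                            window = "hamming", preemph_alpha = 0.97,
                            aggregate = c("mean", "median", "mean_sd")) {
  mel_variant <- match.arg(mel_variant)
  aggregate <- match.arg(aggregate)
  if (n_coeffs > n_mel_filters || n_coeffs > n_gammatone_filters)
    stop("n_coeffs must not exceed the number of filters")
  if (log_floor <= 0) stop("log_floor must be positive")
  structure(list(n_coeffs = as.integer(n_coeffs),
                 n_mel_filters = as.integer(n_mel_filters),
                 n_gammatone_filters = as.integer(n_gammatone_filters),
                 fmin = fmin, fmax = fmax, include_c0 = isTRUE(include_c0),
                 log_floor = log_floor, mel_variant = mel_variant,
                 frame_len_s = frame_len_s, hop_s = hop_s, window = window,
                 preemph_alpha = preemph_alpha, aggregate = aggregate),
            class = "cepstral_config")
}

resolve_fmax <- function(cfg, rate) {
  fmax <- if (is.null(cfg$fmax)) rate / 2 else cfg$fmax
  if (!(cfg$fmin < fmax && fmax <= rate / 2))
    stop("need fmin < fmax <= rate/2")
  fmax
}

#' Mel and ERB-rate frequency scales
#'
#' `hz_to_mel`/`mel_to_hz` implement the HTK mel curve
#' `2595 log10(1 + f/700)` (and the Slaney variant: linear below 1 kHz,
#' logarithmic above). `erb_bandwidth` is the equivalent rectangular
#' bandwidth `24.7 (4.37 f/1000 + 1)` of the cochlear filter centred at `f`;
#' `hz_to_erb_rate`/`erb_rate_to_hz` integrate it into the ERB-rate scale
#' `21.4 log10(1 + 0.00437 f)`.
#'
#' @param f frequency in Hz (vectorized, must be >= 0).
#' @param m mel value (vectorized).
#' @param e ERB-rate value (vectorized).
#' @param variant `"htk"` or `"slaney"`.
#' @return Numeric vector on the target scale.
#' @export
hz_to_mel <- function(f, variant = c("htk", "slaney")) {
  variant <- match.arg(variant)
  if (any(f < 0)) stop("frequency must be >= 0")
  if (variant == "htk") return(2595 * log10(1 + f / 700))
  ## Slaney: 3 f / 200 below 1 kHz, then log steps of 27/log(6.4) per octave
  brk <- 1000; lin <- 3 / 200
  ifelse(f < brk, f * lin, brk * lin + log(f / brk) * 27 / log(6.4))
}

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m, variant = c("htk", "slaney")) {
  variant <- match.arg(variant)
  if (variant == "htk") return(700 * (10^(m / 2595) - 1))
  brk <- 1000; lin <- 3 / 200
  ifelse(m < brk * lin, m / lin, brk * exp((m - brk * lin) * log(6.4) / 27))
}

#' @rdname hz_to_mel
#' @export
erb_bandwidth <- function(f) {
  if (any(f < 0)) stop("frequency must be >= 0")
  24.7 * (4.37 * f / 1000 + 1)
}

#' @rdname hz_to_mel
#' @export
hz_to_erb_rate <- function(f) {
  if (any(f < 0)) stop("frequency must be >= 0")
  21.4 * log10(1 + 0.00437 * f)
}

#' @rdname hz_to_mel
#' @export
erb_rate_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Orthonormal type-II DCT matrix
#'
#' Rows are the DCT-II basis vectors scaled so `D %*% t(D) = I`.
#'
#' @param n transform size.
#' @return An `n x n` matrix.
#' @export
dct_matrix <- function(n) {
  k <- seq_len(n) - 1L
  D <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  D[1L, ] <- D[1L, ] / sqrt(2)
  D
}

fft_bin_freqs <- function(n_fft, rate) (0:(n_fft %/% 2L)) * rate / n_fft

#' Build a triangular mel filterbank
#'
#' `n_mel_filters` triangular filters whose apexes are equally spaced on the
#' mel scale strictly inside (`fmin`, `fmax`); each filter rises from its
#' lower neighbour's apex and falls to its upper neighbour's, with unit peak.
#'
#' @param cfg a [cepstral_config].
#' @param n_fft FFT size (gives `n_fft/2 + 1` bins).
#' @param rate sample rate in Hz.
#' @return A `filterbank`: list with `weights` (n_filters x n_bins),
#'   `center_freqs`, `kind`.
#' @export
build_mel_filterbank <- function(cfg, n_fft, rate) {
  fmax <- resolve_fmax(cfg, rate)
  n_bins <- n_fft %/% 2L + 1L
  if (n_bins < cfg$n_mel_filters + 2L)
    stop("fewer FFT bins than filters")
  pts <- mel_to_hz(seq(hz_to_mel(cfg$fmin, cfg$mel_variant),
                       hz_to_mel(fmax, cfg$mel_variant),
                       length.out = cfg$n_mel_filters + 2L), cfg$mel_variant)
  triangular_bank(pts, n_fft, rate, "mel_triangular",
                  function(f) hz_to_mel(f, cfg$mel_variant))
}

triangular_bank <- function(pts, n_fft, rate, kind, to_scale) {
  n_filters <- length(pts) - 2L
  freqs <- fft_bin_freqs(n_fft, rate)
  sf <- to_scale(freqs)
  sp <- to_scale(pts)
  W <- matrix(0, n_filters, length(freqs))
  for (k in seq_len(n_filters)) {
    lo <- sp[k]; ce <- sp[k + 1L]; hi <- sp[k + 2L]
    up <- (sf - lo) / (ce - lo)
    dn <- (hi - sf) / (hi - ce)
    W[k, ] <- pmax(0, pmin(up, dn))
  }
  structure(list(weights = W, center_freqs = pts[2:(n_filters + 1L)],
                 kind = kind), class = "filterbank")
}

#' Build a gammatone filterbank (frequency-domain magnitude responses)
#'
#' `n_gammatone_filters` 4th-order gammatone magnitude responses,
#' `(1 + ((f - fc)/b)^2)^-2` with `b = 1.019 ERB(fc)`, centred at points
#' equally spaced on the ERB-rate scale strictly inside (`fmin`, `fmax`) and
#' sampled on the FFT bin grid, so GTCC shares the MFCC pipeline shape. The
#' 3 dB bandwidth of this response is 0.886 ERB(fc).
#'
#' @inheritParams build_mel_filterbank
#' @return A `filterbank` (see [build_mel_filterbank]).
#' @export
build_gammatone_filterbank <- function(cfg, n_fft, rate) {
  fmax <- resolve_fmax(cfg, rate)
  n_bins <- n_fft %/% 2L + 1L
  if (n_bins < cfg$n_gammatone_filters + 2L)
    stop("fewer FFT bins than filters")
  grid <- erb_rate_to_hz(seq(hz_to_erb_rate(cfg$fmin), hz_to_erb_rate(fmax),
                             length.out = cfg$n_gammatone_filters + 2L))
  centers <- grid[2:(cfg$n_gammatone_filters + 1L)]
  freqs <- fft_bin_freqs(n_fft, rate)
  W <- t(vapply(centers, function(fc) {
    b <- 1.019 * erb_bandwidth(fc)
    (1 + ((freqs - fc) / b)^2)^(-2)
  }, numeric(length(freqs))))
  structure(list(weights = W, center_freqs = centers, kind = "gammatone"),
            class = "filterbank")
}

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

frame_power_spectrum <- function(fm, n_fft) {
  n_bins <- n_fft %/% 2L + 1L
  padded <- cbind(fm$frames,
                  matrix(0, nrow(fm$frames), n_fft - fm$frame_len))
  spec <- stats::mvfft(t(padded))[seq_len(n_bins), , drop = FALSE]
  t(Mod(spec)^2)   # n_frames x n_bins
}

cepstra_from_bank <- function(fm, bank, cfg) {
  n_fft <- ncol(bank$weights) * 2L - 2L
  P <- frame_power_spectrum(fm, n_fft)
  E <- P %*% t(bank$weights)
  logE <- log(pmax(E, cfg$log_floor))
  D <- dct_matrix(ncol(logE))
  rows <- if (cfg$include_c0) seq_len(cfg$n_coeffs) else seq_len(cfg$n_coeffs) + 1L
  C <- logE %*% t(D[rows, , drop = FALSE])
  colnames(C) <- as.character(if (cfg$include_c0) 0:(cfg$n_coeffs - 1L)
                              else seq_len(cfg$n_coeffs))
  C
}

#' Mel-frequency cepstral coefficients per frame
#'
#' Per frame: power spectrum of the windowed (zero-padded) frame, mel
#' filterbank energies, floored log, orthonormal DCT-II, first `n_coeffs`
#' coefficients.
#'
#' @param fm a `frame_matrix` (from [frame_signal]).
#' @param cfg a [cepstral_config].
#' @return `n_frames x n_coeffs` matrix.
#' @export
mfcc <- function(fm, cfg = cepstral_config()) {
  stopifnot(inherits(fm, "frame_matrix"))
  n_fft <- next_pow2(fm$frame_len)
  cepstra_from_bank(fm, build_mel_filterbank(cfg, n_fft, fm$rate), cfg)
}

#' Gammatone cepstral coefficients per frame
#'
#' Identical pipeline to [mfcc] with the gammatone filterbank substituted.
#'
#' @inheritParams mfcc
#' @return `n_frames x n_coeffs` matrix.
#' @export
gtcc <- function(fm, cfg = cepstral_config()) {
  stopifnot(inherits(fm, "frame_matrix"))
  n_fft <- next_pow2(fm$frame_len)
  cepstra_from_bank(fm, build_gammatone_filterbank(cfg, n_fft, fm$rate), cfg)
}

aggregate_frames <- function(C, how) {
  switch(how,
    mean    = colMeans(C),
    median  = apply(C, 2L, stats::median),
    mean_sd = c(colMeans(C), apply(C, 2L, stats::sd)))
}

#' Cepstral feature vector of one audio sample
#'
#' Pre-emphasis, framing, per-frame MFCC and GTCC, then per-coefficient
#' pooling across frames (mean by default): the 26-value descriptor one
#' classifier row is built from.
#'
#' @param sample a [waveform] (at least one frame long).
#' @param cfg a [cepstral_config].
#' @param label optional class label (`"HC"`/`"PD"`).
#' @return A named numeric vector (`mfcc_0..mfcc_12`, `gtcc_0..gtcc_12`
#'   under defaults) with attributes `label` and `source_id`.
#' @export
featurize_sample <- function(sample, cfg = cepstral_config(), label = NA_character_) {
  stopifnot(inherits(sample, "waveform"))
  emph <- pre_emphasis(sample, cfg$preemph_alpha)
  fm <- frame_signal(emph, cfg$frame_len_s, cfg$hop_s, cfg$window)
  m <- aggregate_frames(mfcc(fm, cfg), cfg$aggregate)
  g <- aggregate_frames(gtcc(fm, cfg), cfg$aggregate)
  idx <- if (cfg$include_c0) 0:(cfg$n_coeffs - 1L) else seq_len(cfg$n_coeffs)
  nm <- if (cfg$aggregate == "mean_sd") {
    c(paste0("mfcc_", idx), paste0("mfcc_sd_", idx),
      paste0("gtcc_", idx), paste0("gtcc_sd_", idx))
  } else c(paste0("mfcc_", idx), paste0("gtcc_", idx))
  out <- c(m, g)
  names(out) <- nm
  attr(out, "label") <- label
  attr(out, "source_id") <- sample$source_id
  out
}

#' Feature table for a cohort of labelled recordings
#'
#' Partitions each recording into non-overlapping fixed-length samples and
#' featurizes every sample.
#'
#' @param recordings list of `list(wave = waveform, label = "HC"|"PD")`.
#' @param cfg a [cepstral_config].
#' @param sample_len_s partition length in seconds (default 1.0).
#' @return A data.frame: feature columns, `label`, `source_id`,
#'   `chunk_index`.
#' @export
featurize_cohort <- function(recordings, cfg = cepstral_config(),
                             sample_len_s = 1.0) {
  rows <- lapply(recordings, function(rec) {
    chunks <- partition_samples(rec$wave, sample_len_s)
    if (length(chunks) == 0L) return(NULL)
    vecs <- lapply(chunks, featurize_sample, cfg = cfg, label = rec$label)
    df <- as.data.frame(do.call(rbind, vecs))
    df$label <- rec$label
    df$source_id <- rec$wave$source_id
    df$chunk_index <- seq_along(chunks)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the cepstral feature columns of a table
#'
#' @param df a feature data.frame.
#' @param set `"combined"` (default), `"mfcc"` or `"gtcc"`.
#' @return Character vector of column names.
#' @export
feature_columns <- function(df, set = c("combined", "mfcc", "gtcc")) {
  set <- match.arg(set)
  pat <- switch(set, combined = "^(mfcc|gtcc)_", mfcc = "^mfcc_", gtcc = "^gtcc_")
  grep(pat, names(df), value = TRUE)
}

#' z-score normalization
#'
#' `zscore_fit` computes per-column mean and sample standard deviation on a
#' fit (training) set; `zscore_apply` standardizes any table with those
#' statistics. Fitting on training rows only and applying to test rows is
#' the leak-free default used by the pipeline; passing the pooled table to
#' `zscore_fit` reproduces a "global" normalization.
#'
#' @param x numeric matrix or data.frame of feature columns (>= 2 rows).
#' @param stats a `norm_stats` object from `zscore_fit`.
#' @return `zscore_fit`: a `norm_stats` list with `mean` and `sd`;
#'   `zscore_apply`: `x` standardized, same shape and names.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 rows to fit z-score statistics")
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  bad <- which(sdev == 0)
  if (length(bad))
    stop("zero-variance column(s): ", paste(colnames(x)[bad], collapse = ", "))
  structure(list(mean = mu, sd = sdev), class = "norm_stats")
}

#' @rdname zscore_fit
#' @export
zscore_apply <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  m <- as.matrix(x)
  if (!is.null(colnames(m)) && !is.null(names(stats$mean)))
    stopifnot(identical(colnames(m), names(stats$mean)))
  out <- sweep(sweep(m, 2L, stats$mean, `-`), 2L, stats$sd, `/`)
  if (is.data.frame(x)) as.data.frame(out) else out
}

#' Read/write feature tables as CSV
#'
#' Plain CSV with a header row (feature columns, `label`, `source_id`,
#' `chunk_index`); the extraction configuration can be written alongside as
#' key/value lines via [write_config].
#'
#' @param df feature data.frame.
#' @param path file path.
#' @return `read_feature_table`: the data.frame; `write_feature_table`:
#'   `path` invisibly.
#' @export
write_feature_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a flat config object as key/value lines
#'
#' @param cfg a list-like configuration object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v)
    if (is.null(v)) "null" else paste(format(v, digits = 15), collapse = ","),
    character(1))
  writeLines(paste0(names(cfg), ": ", vals), path)
  invisible(path)
}
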