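# Independent oracles used across the suite. These deliberately avoid the
# package's fft/mvfft/DCT code paths: naive O(N^2) Fourier sums, explicit
# cosine sums, brute-force enumeration.

## naive DFT: one-sided power spectrum of a real vector, O(N^2)
naive_power_spectrum <- function(x, n_fft) {
  x <- c(x, numeric(n_fft - length(x)))
  n <- seq_along(x) - 1
  vapply(0:(n_fft %/% 2), function(k) {
    re <- sum(x * cos(-2 * pi * k * n / n_fft))
    im <- sum(x * sin(-2 * pi * k * n / n_fft))
    re^2 + im^2
  }, numeric(1))
}

## explicit orthonormal DCT-II by direct cosine sums
naive_dct <- function(v) {
  N <- length(v)
  vapply(0:(N - 1), function(k) {
    s <- sum(v * cos(pi * (2 * (0:(N - 1)) + 1) * k / (2 * N)))
    s * sqrt(2 / N) * if (k == 0) 1 / sqrt(2) else 1
  }, numeric(1))
}

## full cepstral pipeline on one windowed frame, from first principles,
## given a filterbank weight matrix
naive_cepstra <- function(frame, weights, n_coeffs, log_floor, include_c0 = TRUE) {
  n_fft <- (ncol(weights) - 1L) * 2L
  P <- naive_power_spectrum(frame, n_fft)
  E <- as.numeric(weights %*% P)
  logE <- log(pmax(E, log_floor))
  cc <- naive_dct(logE)
  if (include_c0) cc[seq_len(n_coeffs)] else cc[seq_len(n_coeffs) + 1L]
}

## brute-force frame count: place frames until one no longer fits
brute_force_frame_count <- function(N, frame_len, hop) {
  count <- 0L
  start <- 1L
  while (start + frame_len - 1L <= N) {
    count <- count + 1L
    start <- start + hop
  }
  count
}

## exact two-sided permutation p-value for the two-sample pooled-t statistic
perm_ttest_pvalue <- function(a, b) {
  pooled_t <- function(x, y) {
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  obs <- abs(pooled_t(a, b))
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  stats <- apply(idx, 2L, function(i) abs(pooled_t(pool[i], pool[-i])))
  mean(stats >= obs - 1e-12)
}

## two clearly distinct synthetic speakers plus an alternating-turn script
make_test_speakers <- function() {
  list(a = voice_spec(105, 5, 0.5, 2, 25, label = "HC"),
       b = voice_spec(210, 5, 0.5, 2, 25,
                      formants = cbind(c(600, 1800, 2900), c(80, 120, 160)),
                      label = "HC"))
}

make_test_conversation <- function(seed, n_turns = 6L, dur_range = c(3, 4)) {
  sp <- make_test_speakers()
  durs <- with_seed(seed, runif(n_turns, dur_range[1], dur_range[2]))
  scr <- conversation_script(rep_len(c(0L, 1L), n_turns), durs)
  synth_conversation(sp$a, sp$b, scr, seed = seed)
}

## two Gaussian classes in the 26-column cepstral dialect; `sep` is the
## centroid distance in units of the (unit) per-dimension sd
make_gauss_features <- function(n_per_class, sep = 6, seed = 1) {
  shift <- sep / sqrt(26)
  with_seed(seed, {
    mk <- function(n, mu, label) {
      df <- as.data.frame(matrix(rnorm(n * 26, mu), n, 26))
      names(df) <- c(paste0("mfcc_", 0:12), paste0("gtcc_", 0:12))
      df$label <- label
      df$source_id <- sprintf("%s%03d", label, seq_len(n))
      df$chunk_index <- 1L
      df
    }
    rbind(mk(n_per_class, 0, "HC"), mk(n_per_class, shift, "PD"))
  })
}
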