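test_that("mel and ERB scales are exact and invertible", {
  expect_identical(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(1000), 2595 * log10(1 + 1000 / 700))
  expect_lt(abs(hz_to_mel(1000) - 1000), 1)
  f <- with_seed(5, runif(100, 0, 22050))
  expect_equal(mel_to_hz(hz_to_mel(f)), f, tolerance = 1e-9)
  expect_equal(mel_to_hz(hz_to_mel(f, "slaney"), "slaney"), f, tolerance = 1e-9)
  expect_error(hz_to_mel(-1), ">= 0")

  expect_equal(erb_bandwidth(0), 24.7)
  expect_equal(erb_bandwidth(1000), 24.7 * (4.37 + 1))
  expect_equal(erb_rate_to_hz(hz_to_erb_rate(f)), f, tolerance = 1e-9)
  f2 <- with_seed(6, matrix(runif(200, 0, 8000), 100))
  expect_true(all(diff(erb_bandwidth(sort(f2[, 1]))) > 0))
})

test_that("DCT matrix is orthonormal at all used sizes", {
  for (n in c(13, 20, 40)) {
    D <- dct_matrix(n)
    expect_lt(max(abs(D %*% t(D) - diag(n))), 1e-10)
  }
})

test_that("mel filterbank peaks at its centers and tiles the band", {
  cfg <- cepstral_config(n_mel_filters = 30)
  bank <- build_mel_filterbank(cfg, 512, 16000)
  freqs <- (0:256) * 16000 / 512
  expect_equal(length(bank$center_freqs), 30)
  expect_true(all(diff(bank$center_freqs) > 0))
  bin_w <- 16000 / 512
  for (k in seq_len(30)) {
    peak_f <- freqs[which.max(bank$weights[k, ])]
    expect_lt(abs(peak_f - bank$center_freqs[k]), bin_w + 1e-9)
  }
  inside <- freqs > cfg$fmin + bin_w & freqs < 8000 - bin_w
  expect_true(all(colSums(bank$weights)[inside] > 0))
})

test_that("a pure tone at a filter's center maximizes that filter's output", {
  cfg <- cepstral_config(n_mel_filters = 24)
  bank <- build_mel_filterbank(cfg, 512, 16000)
  for (k in c(3, 12, 20)) {
    tone <- cos(2 * pi * bank$center_freqs[k] * (0:511) / 16000)
    P <- naive_power_spectrum(tone, 512)
    expect_equal(which.max(as.numeric(bank$weights %*% P)), k)
  }
})

test_that("gammatone filters sit on the ERB-rate grid with the 4th-order bandwidth", {
  cfg <- cepstral_config(n_gammatone_filters = 32)
  bank <- build_gammatone_filterbank(cfg, 4096, 16000)
  expect_equal(length(bank$center_freqs), 32)
  expect_true(all(diff(bank$center_freqs) > 0))
  freqs <- (0:2048) * 16000 / 4096
  for (k in seq_len(32)) {
    fc <- bank$center_freqs[k]
    expect_lt(abs(freqs[which.max(bank$weights[k, ])] - fc),
              erb_bandwidth(fc))
    ## 3 dB bandwidth via interpolated half-power crossings
    resp <- bank$weights[k, ]^2
    half <- max(resp) / 2
    above <- which(resp >= half)
    lo <- min(above); hi <- max(above)
    interp <- function(i1, i2) {
      if (i1 < 1 || i2 > length(resp)) return(freqs[max(1, min(i1, i2))])
      stats::approx(resp[c(i1, i2)], freqs[c(i1, i2)], xout = half)$y
    }
    bw <- interp(hi, hi + 1) - interp(lo, lo - 1)
    expect_lt(abs(bw - 0.887 * erb_bandwidth(fc)), 0.3 * 0.887 * erb_bandwidth(fc))
  }
})

test_that("zero frames give the constant-log cepstrum", {
  fm <- structure(list(frames = matrix(0, 2, 64), frame_len = 64L, hop = 32L,
                       window = "rectangular", rate = 8000),
                  class = "frame_matrix")
  cfg <- cepstral_config(n_mel_filters = 20, n_gammatone_filters = 20)
  m <- mfcc(fm, cfg)
  expect_equal(unname(m[1, 1]), sqrt(20) * log(1e-10))
  expect_equal(as.numeric(m[, 2:13]), numeric(24))
  g <- gtcc(fm, cfg)
  expect_equal(as.numeric(g[, 2:13]), numeric(24))
})

test_that("log-mel energies are recoverable through the full DCT", {
  cfg <- cepstral_config(n_mel_filters = 20, n_gammatone_filters = 20,
                         n_coeffs = 20)
  fm <- structure(list(frames = matrix(with_seed(7, rnorm(3 * 64)), 3, 64),
                       frame_len = 64L, hop = 32L, window = "rectangular",
                       rate = 8000),
                  class = "frame_matrix")
  C <- mfcc(fm, cfg)            # all 20 coefficients
  D <- dct_matrix(20)
  bank <- build_mel_filterbank(cfg, 64, 8000)
  for (i in 1:3) {
    P <- naive_power_spectrum(fm$frames[i, ], 64)
    logE <- log(pmax(as.numeric(bank$weights %*% P), cfg$log_floor))
    expect_equal(as.numeric(t(D) %*% C[i, ]), logE, tolerance = 1e-8)
  }
})

test_that("mfcc and gtcc match the naive-DFT matrix-product oracle", {
  cfg <- cepstral_config(n_mel_filters = 20, n_gammatone_filters = 20)
  mel_bank <- build_mel_filterbank(cfg, 64, 8000)
  gt_bank <- build_gammatone_filterbank(cfg, 64, 8000)
  frames <- matrix(with_seed(11, rnorm(10 * 64)), 10, 64)
  fm <- structure(list(frames = frames, frame_len = 64L, hop = 32L,
                       window = "rectangular", rate = 8000),
                  class = "frame_matrix")
  M <- mfcc(fm, cfg); G <- gtcc(fm, cfg)
  for (i in 1:10) {
    expect_equal(as.numeric(M[i, ]),
                 naive_cepstra(frames[i, ], mel_bank$weights, 13, cfg$log_floor),
                 tolerance = 1e-8)
    expect_equal(as.numeric(G[i, ]),
                 naive_cepstra(frames[i, ], gt_bank$weights, 13, cfg$log_floor),
                 tolerance = 1e-8)
  }
  ## the two banks are genuinely different front-ends
  expect_gt(max(abs(M[1, -1] - G[1, -1])), 1e-3)
})

test_that("a sample of identical frames featurizes to the single-frame cepstra", {
  ## 100 Hz sine at 16 kHz: period 160 = hop, frame 400; alpha 0 so every
  ## frame is the same slice
  x <- sin(2 * pi * 100 * (0:15999) / 16000) * 0.8
  w <- waveform(x, 16000, "per")
  cfg <- cepstral_config(preemph_alpha = 0)
  v <- featurize_sample(w, cfg)
  fm <- frame_signal(w, cfg$frame_len_s, cfg$hop_s, cfg$window)
  one <- mfcc(fm, cfg)[1, ]
  expect_equal(as.numeric(v[1:13]), as.numeric(one), tolerance = 1e-9)
  expect_identical(v, featurize_sample(w, cfg))
})

test_that("amplitude scaling moves only the 0th coefficient of each set", {
  sp <- voice_spec(120, 0, 0, 0, Inf, label = "HC")
  w <- synth_voice(sp, 1.0, 16000, seed = 9)
  half <- waveform(w$samples / 2, 16000, w$source_id)
  cfg <- cepstral_config(log_floor = 1e-300)
  v1 <- featurize_sample(w, cfg)
  v2 <- featurize_sample(half, cfg)
  d <- as.numeric(v1) - as.numeric(v2)
  expect_lt(max(abs(d[c(2:13, 15:26)])), 1e-6)
  expect_gt(abs(d[1]), 1)
  expect_gt(abs(d[14]), 1)
})

test_that("z-score fit/apply standardizes and is affine-consistent", {
  X <- matrix(with_seed(13, rnorm(200)), 50, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  st <- zscore_fit(X)
  Z <- zscore_apply(X, st)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_equal(apply(Z, 2, sd), setNames(rep(1, 4), colnames(X)),
               tolerance = 1e-9)

  one <- matrix(c(0, 0, 10), dimnames = list(NULL, "c"))
  z <- zscore_apply(one, zscore_fit(one))
  expect_equal(as.numeric(z), c(-0.57735027, -0.57735027, 1.15470054),
               tolerance = 1e-7)

  Y <- 3 * X + 5
  st2 <- zscore_fit(Y)
  expect_equal(zscore_apply(Y, st2), Z, tolerance = 1e-9)

  X0 <- X; X0[, 2] <- 7
  expect_error(zscore_fit(X0), "c2")
})
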