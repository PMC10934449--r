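test_that("segment_stream windows tile the stream at the hop", {
  w <- waveform(numeric(10 * 16000), 16000, "s")
  cfg <- diarization_config(window_s = 1, hop_s = 0.5)
  wins <- segment_stream(w, cfg)
  expect_length(wins, 19)                       # 1 + floor((10-1)/0.5)
  expect_equal(wins[[1]]$start, 0)
  expect_equal(wins[[19]]$end, 10)
  starts <- vapply(wins, `[[`, numeric(1), "start")
  expect_equal(diff(starts), rep(0.5, 18))

  cfg2 <- diarization_config(window_s = 1, hop_s = 1)
  wins2 <- segment_stream(w, cfg2)
  ends <- vapply(wins2, `[[`, numeric(1), "end")
  starts2 <- vapply(wins2, `[[`, numeric(1), "start")
  expect_equal(starts2[-1], ends[-length(ends)])  # disjoint when hop = window
  expect_error(segment_stream(waveform(numeric(100), 16000), cfg), "shorter")
})

test_that("embeddings are deterministic, 26-dim, and separate speakers", {
  sp <- make_test_speakers()
  cfg <- diarization_config()
  wa <- synth_voice(sp$a, 1.0, 16000, seed = 1)
  expect_identical(embed_window(wa, cfg), embed_window(wa, cfg))
  expect_length(embed_window(wa, cfg), 26)

  ea <- lapply(1:10, function(s) embed_window(synth_voice(sp$a, 1, 16000, s), cfg))
  eb <- lapply(1:10, function(s) embed_window(synth_voice(sp$b, 1, 16000, s), cfg))
  dist2 <- function(u, v) sqrt(sum((u - v)^2))
  within <- mean(c(vapply(2:10, function(i) dist2(ea[[1]], ea[[i]]), numeric(1)),
                   vapply(2:10, function(i) dist2(eb[[1]], eb[[i]]), numeric(1))))
  between <- mean(vapply(1:10, function(i) dist2(ea[[i]], eb[[i]]), numeric(1)))
  expect_gt(between, within)
})

test_that("silent windows embed without error", {
  cfg <- diarization_config()
  e <- embed_window(waveform(numeric(16000), 16000), cfg)
  expect_true(all(is.finite(e)))
})

test_that("k-means recovers well-separated clouds and matches stats::kmeans", {
  E <- with_seed(21, rbind(matrix(rnorm(60, 0), 30, 2),
                           matrix(rnorm(80, 10), 40, 2)))
  km <- cluster_speakers(E, 2, seed = 1)
  truth <- rep(1:2, c(30, 40))
  agree <- max(mean(km$cluster == truth), mean(km$cluster == 3 - truth))
  expect_equal(agree, 1)
  ref <- stats::kmeans(E, 2, nstart = 5)
  agree_ref <- max(mean(km$cluster == ref$cluster),
                   mean(km$cluster == 3 - ref$cluster))
  expect_equal(agree_ref, 1)

  km1 <- cluster_speakers(E, 1, seed = 1)
  expect_true(all(km1$cluster == 1))
  expect_equal(as.numeric(km1$centers[1, ]), colMeans(E))
  expect_error(cluster_speakers(E[1:2, ], 3, 1), "exceeds")
})

test_that("the clustering objective never increases and ends at a Lloyd fixed point", {
  E <- with_seed(33, matrix(rnorm(200 * 5), 200, 5))
  km <- cluster_speakers(E, 4, seed = 2)
  expect_true(all(diff(km$wss) <= 1e-9))
  D2 <- vapply(seq_len(4), function(j)
    rowSums(sweep(E, 2, km$centers[j, ])^2), numeric(nrow(E)))
  expect_true(all(km$cluster == max.col(-D2, ties.method = "first")))
})

test_that("label smoothing takes majorities, keeps edges, and is idempotent", {
  expect_equal(smooth_labels(c(0, 0, 1, 0, 0), 3), rep(0, 5))
  expect_equal(smooth_labels(rep(2, 7), 5), rep(2, 7))
  expect_equal(smooth_labels(c(1, 2, 1, 2, 1), 1), c(1, 2, 1, 2, 1))
  expect_error(smooth_labels(1:3, 2), "odd")

  with_seed(17, for (i in 1:20) {
    x <- sample(0:1, 30, replace = TRUE)
    once <- smooth_labels(x, 3)
    expect_equal(smooth_labels(once, 3), once)
  })
})

test_that("diarization is deterministic and a single speaker yields one segment", {
  sp <- make_test_speakers()
  w <- synth_voice(sp$a, 4, 16000, seed = 8)
  d1 <- diarize(w, diarization_config(n_speakers = 1, seed = 3))
  expect_equal(nrow(d1$segments), 1)
  expect_equal(d1$segments$start, 0)
  expect_equal(d1$segments$end, 4)

  conv <- make_test_conversation(5)
  da <- diarize(conv$wave, diarization_config(n_speakers = 2, seed = 5))
  db <- diarize(conv$wave, diarization_config(n_speakers = 2, seed = 5))
  expect_identical(da$segments, db$segments)
})

test_that("the accuracy scorer is invariant to cluster relabelling", {
  conv <- make_test_conversation(7)
  d <- diarize(conv$wave, diarization_config(n_speakers = 2, seed = 7))
  acc1 <- diarization_accuracy(d, conv$timeline)$accuracy
  d2 <- d
  d2$segments$cluster <- 3L - d2$segments$cluster
  expect_equal(diarization_accuracy(d2, conv$timeline)$accuracy, acc1)
})

test_that("speaker audio extraction copies samples verbatim", {
  w <- waveform(with_seed(9, runif(32000, -1, 1)), 16000, "x")
  d <- structure(list(segments = data.frame(start = c(0, 1.5),
                                            end = c(1.0, 2.0),
                                            cluster = c(1L, 1L)),
                      noise_cluster = NA_integer_, rate = 16000,
                      source_id = "x", k = 1L),
                 class = "diarization")
  out <- extract_speaker_audio(w, d, 1L)
  expect_identical(out$samples,
                   c(w$samples[1:16000], w$samples[24001:32000]))
  expect_equal(out$source_id, "x_spk1")
  whole <- structure(list(segments = data.frame(start = 0, end = 2, cluster = 1L),
                          noise_cluster = NA_integer_, rate = 16000,
                          source_id = "x", k = 1L),
                     class = "diarization")
  expect_identical(extract_speaker_audio(w, whole, 1L)$samples, w$samples)
  expect_error(extract_speaker_audio(w, d, 9L), "not present")
})

test_that("a noise cluster absorbs long silences when requested", {
  sp <- make_test_speakers()
  scr <- conversation_script(c(0L, 1L), c(3, 3), gap = 2)
  conv <- synth_conversation(sp$a, sp$b, scr, seed = 12)
  d <- diarize(conv$wave,
               diarization_config(n_speakers = 2, include_noise_cluster = TRUE,
                                  seed = 12))
  expect_equal(d$k, 3)
  expect_false(is.na(d$noise_cluster))
  ## the noise cluster should own the middle of the long gap
  gap_mid <- 3 + 1
  idx <- which(d$segments$start <= gap_mid & d$segments$end >= gap_mid)
  expect_equal(d$segments$cluster[idx], d$noise_cluster)
  expect_false(dominant_cluster(d) == d$noise_cluster)
})
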