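test_that("voice_spec enforces its invariants", {
  expect_error(voice_spec(0), "f0_mean")
  expect_error(voice_spec(100, jitter_pct = 60), "jitter")
  expect_error(voice_spec(100, shimmer_pct = 120), "shimmer")
  expect_error(voice_spec(100, formants = cbind(c(500, 400), c(80, 80))),
               "increasing")
  expect_error(voice_spec(100, formants = cbind(c(500, 1500), c(80, 0))),
               "bandwidth")
  expect_error(voice_spec(100, formants = cbind(500, 80)), "two")
})

test_that("an unperturbed voice is periodic at round(rate/f0) after settling", {
  sp <- voice_spec(100, 0, 0, 0, Inf, label = "HC")
  w <- synth_voice(sp, 1.0, 16000, seed = 7)
  expect_length(w$samples, 16000)
  x <- w$samples
  T <- 160                      # round(16000 / 100)
  ## resonator transients decay geometrically; compare late cycles
  expect_lt(max(abs(x[(10 * T + 1):(40 * T)] - x[(11 * T + 1):(41 * T)])), 1e-8)
})

test_that("synthesis is bit-deterministic given the seed", {
  sp <- voice_spec(140, 10, 1.5, 4, 18, label = "PD")
  w1 <- synth_voice(sp, 1.5, 16000, seed = 3)
  w2 <- synth_voice(sp, 1.5, 16000, seed = 3)
  expect_identical(w1$samples, w2$samples)
  w3 <- synth_voice(sp, 1.5, 16000, seed = 4)
  expect_false(identical(w1$samples, w3$samples))
  expect_error(synth_voice(sp, 0.001, 16000, 1), "period")
})

test_that("jitter and shimmer are recoverable from the pulse train", {
  sp <- voice_spec(120, 0, 2.0, 5, 20, label = "PD")
  est <- estimate_perturbations(glottal_pulse_train(sp, 3, seed = 3))
  expect_lt(abs(est$jitter_pct - 2.0), 0.5)

  for (seed in 1:20) {
    spj <- voice_spec(110, 5, 3.0, 6, 15, label = "PD")
    e <- estimate_perturbations(glottal_pulse_train(spj, 3, seed = seed))
    expect_lt(abs(e$jitter_pct - 3.0) / 3.0, 0.25)
    expect_lt(abs(e$shimmer_pct - 6.0) / 6.0, 0.25)
  }
})

test_that("synth_cohort produces the requested labelled recordings deterministically", {
  co <- synth_cohort(21, 16, duration = 0.5, seed = 2)
  expect_length(co, 37)
  expect_equal(sum(vapply(co, `[[`, character(1), "label") == "HC"), 21)
  expect_equal(sum(vapply(co, `[[`, character(1), "label") == "PD"), 16)
  expect_s3_class(co[[1]]$spec, "voice_spec")

  a <- synth_cohort(1, 1, duration = 0.5, seed = 9)
  b <- synth_cohort(1, 1, duration = 0.5, seed = 9)
  expect_identical(lapply(a, `[[`, "wave"), lapply(b, `[[`, "wave"))
  expect_error(synth_cohort(0, 1, seed = 1), "at least one")
})

test_that("cohort class means separate: PD jitter exceeds HC jitter", {
  co <- synth_cohort(50, 50, duration = 0.5, seed = 31)
  jit <- vapply(seq_along(co), function(i)
    estimate_perturbations(
      glottal_pulse_train(co[[i]]$spec, 2, seed = i))$jitter_pct,
    numeric(1))
  labs <- vapply(co, `[[`, character(1), "label")
  expect_lt(mean(jit[labs == "HC"]), mean(jit[labs == "PD"]))
})

test_that("conversations assemble the scripted timeline exactly", {
  sp <- make_test_speakers()
  scr <- conversation_script(c(0L, 1L), c(2, 2), gap = 0)
  conv <- synth_conversation(sp$a, sp$b, scr, seed = 1)
  expect_equal(conv$timeline,
               data.frame(start = c(0, 2), end = c(2, 4), speaker = 0:1))
  expect_equal(wave_duration(conv$wave), 4)

  scr2 <- conversation_script(c(0L, 1L, 0L), c(1.5, 2, 1), gap = 0.25)
  conv2 <- synth_conversation(sp$a, sp$b, scr2, seed = 1)
  expect_equal(wave_duration(conv2$wave), 1.5 + 2 + 1 + 0.25 * 2)
  ## timeline covers exactly the speech portion
  expect_equal(sum(conv2$timeline$end - conv2$timeline$start), 4.5)
  expect_true(all(diff(as.vector(rbind(conv2$timeline$start,
                                       conv2$timeline$end))) >= 0))

  expect_error(conversation_script(c(0L, 0L), c(1, 1)), "both")
  expect_error(conversation_script(c(0L, 1L), c(1, -1)), "> 0")
})

test_that("the lower voice has the lower spectral centroid on its segments", {
  sp <- make_test_speakers()        # f0 105 vs 210 Hz, distinct formants
  scr <- conversation_script(c(0L, 1L, 0L, 1L), rep(2, 4))
  conv <- synth_conversation(sp$a, sp$b, scr, seed = 6)
  centroid <- function(x, rate) {
    p <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) / length(x) * rate
    keep <- f <= rate / 2
    sum(f[keep] * p[keep]) / sum(p[keep])
  }
  cents <- vapply(seq_len(nrow(conv$timeline)), function(i) {
    a <- round(conv$timeline$start[i] * 16000) + 1
    b <- round(conv$timeline$end[i] * 16000)
    centroid(conv$wave$samples[a:b], 16000)
  }, numeric(1))
  expect_lt(mean(cents[conv$timeline$speaker == 0]),
            mean(cents[conv$timeline$speaker == 1]))
})

test_that("RTTM files round-trip diarization segments", {
  seg <- data.frame(start = c(0, 2.5), end = c(2.5, 4.75), speaker = c("0", "1"))
  path <- withr::local_tempfile(fileext = ".rttm")
  write_rttm(seg, path, file_id = "convA")
  back <- read_rttm(path)
  expect_equal(back$start, seg$start, tolerance = 1e-3)
  expect_equal(back$end, seg$end, tolerance = 1e-3)
  expect_equal(back$speaker, seg$speaker)
})
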