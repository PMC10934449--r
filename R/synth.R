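#' Generative specification of one synthetic voice
#'
#' Parameters of the source-filter synthesizer, expressed as the standard
#' acoustic-phonetic quantities elevated in hypokinetic dysarthria research:
#' utterance-level pitch variability (monopitch when low), cycle-to-cycle
#' frequency perturbation (jitter), cycle-to-cycle amplitude perturbation
#' (shimmer), and harmonics-to-noise ratio of the glottal source.
#'
#' @param f0_mean mean fundamental frequency, Hz (> 0).
#' @param f0_sd utterance-level pitch variability, Hz (f0 is redrawn per
#'   0.5 s utterance segment from Normal(f0_mean, f0_sd)).
#' @param jitter_pct cycle-to-cycle period perturbation, percent (0-50).
#' @param shimmer_pct cycle-to-cycle amplitude perturbation, percent (0-100).
#' @param hnr_db harmonics-to-noise ratio of the source in dB; `Inf`
#'   disables aspiration noise.
#' @param formants two-column matrix (or list of pairs) of vocal-tract
#'   resonances: center Hz (strictly increasing) and bandwidth Hz (> 0);
#'   at least two.
#' @param label class label, `"HC"` or `"PD"`.
#' @return An object of class `voice_spec`.
#' @export
voice_spec <- function(f0_mean, f0_sd = 0, jitter_pct = 0, shimmer_pct = 0,
                       hnr_db = Inf,
                       formants = cbind(c(500, 1500, 2500), c(80, 120, 160)),
                       label = c("HC", "PD")) {
  label <- match.arg(label)
  if (is.list(formants)) formants <- do.call(rbind, formants)
  formants <- as.matrix(formants)
  if (!(is.numeric(f0_mean) && f0_mean > 0)) stop("f0_mean must be > 0")
  if (f0_sd < 0) stop("f0_sd must be >= 0")
  if (jitter_pct < 0 || jitter_pct >= 50) stop("jitter_pct must lie in [0, 50)")
  if (shimmer_pct < 0 || shimmer_pct >= 100) stop("shimmer_pct must lie in [0, 100)")
  if (nrow(formants) < 2L || ncol(formants) != 2L)
    stop("need at least two (center, bandwidth) formants")
  if (any(diff(formants[, 1L]) <= 0)) stop("formant centers must be strictly increasing")
  if (any(formants[, 2L] <= 0)) stop("formant bandwidths must be > 0")
  structure(list(f0_mean = f0_mean, f0_sd = f0_sd, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, hnr_db = hnr_db,
                 formants = unname(formants), label = label),
            class = "voice_spec")
}

#' Glottal pulse train of a synthetic voice
#'
#' The excitation sequence underlying [synth_voice], exposed so jitter and
#' shimmer can be re-measured from the exact (unquantized) cycle times.
#' f0 is drawn once per `segment_s` utterance segment from
#' Normal(f0_mean, f0_sd); each cycle's period is then perturbed by
#' Normal(0, jitter_pct/100 * period) and its amplitude by
#' Normal(0, shimmer_pct/100).
#'
#' @param spec a [voice_spec].
#' @param duration seconds (> 0, at least one pitch period).
#' @param seed integer seed; the call is deterministic given it.
#' @param segment_s utterance-segment length for f0 redraws (default 0.5 s).
#' @return List with `times` (exact pulse onsets, s), `amps`, `segment`
#'   (segment index per pulse) and `f0_segments`.
#' @export
glottal_pulse_train <- function(spec, duration, seed, segment_s = 0.5) {
  stopifnot(inherits(spec, "voice_spec"))
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (duration < 1 / spec$f0_mean)
    stop("duration shorter than one pitch period")
  with_seed(seed, {
    n_seg <- ceiling(duration / segment_s)
    f0_seg <- pmax(20, rnorm(n_seg, spec$f0_mean, spec$f0_sd))
    times <- numeric(0); amps <- numeric(0); seg_of <- integer(0)
    t <- 0
    while (t < duration) {
      seg <- min(n_seg, 1L + floor(t / segment_s))
      period <- 1 / f0_seg[seg]
      period <- period + rnorm(1L, 0, spec$jitter_pct / 100 * period)
      period <- max(period, 0.2 / f0_seg[seg])
      amp <- max(0.05, 1 + rnorm(1L, 0, spec$shimmer_pct / 100))
      times <- c(times, t); amps <- c(amps, amp); seg_of <- c(seg_of, seg)
      t <- t + period
    }
    list(times = times, amps = amps, segment = seg_of, f0_segments = f0_seg)
  })
}

#' Re-estimate jitter and shimmer from a pulse train
#'
#' Jitter is the within-segment coefficient of variation of consecutive
#' periods (averaged over segments with at least three cycles); shimmer is
#' the coefficient of variation of pulse amplitudes. Both in percent.
#'
#' @param pulses output of [glottal_pulse_train].
#' @return Named list `jitter_pct`, `shimmer_pct`.
#' @export
estimate_perturbations <- function(pulses) {
  jit <- c()
  for (s in unique(pulses$segment)) {
    tt <- pulses$times[pulses$segment == s]
    if (length(tt) >= 4L) {
      periods <- diff(tt)
      jit <- c(jit, stats::sd(periods) / mean(periods) * 100)
    }
  }
  list(jitter_pct = mean(jit),
       shimmer_pct = stats::sd(pulses$amps) / mean(pulses$amps) * 100)
}

resonator_filter <- function(x, fc, bw, rate) {
  r <- exp(-pi * bw / rate)
  theta <- 2 * pi * fc / rate
  as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2), method = "recursive"))
}

#' Synthesize one voice recording
#'
#' Source-filter scheme: a glottal pulse train (impulse train with per-cycle
#' jitter and shimmer, low-pass shaped by a double real pole to mimic the
#' glottal-flow spectral roll-off), mixed with white aspiration noise at the
#' specified harmonics-to-noise ratio, then passed through cascaded
#' second-order resonators at the formants, a first-difference lip
#' radiation filter (+6 dB/oct), and peak-normalized to 0.9.
#' Deterministic given `seed`.
#'
#' @param spec a [voice_spec].
#' @param duration seconds.
#' @param rate sample rate in Hz (>= 8000).
#' @param seed integer seed.
#' @param source_id provenance tag for the returned waveform.
#' @return A [waveform].
#' @export
synth_voice <- function(spec, duration, rate = 16000, seed = 1L,
                        source_id = NULL) {
  stopifnot(inherits(spec, "voice_spec"))
  if (rate < 8000) stop("rate must be >= 8000 Hz")
  pulses <- glottal_pulse_train(spec, duration, seed = derive_seed(seed, 1L))
  n <- round(duration * rate)
  x <- numeric(n)
  idx <- pmin(n, round(pulses$times * rate) + 1L)
  for (i in seq_along(idx)) x[idx[i]] <- x[idx[i]] + pulses$amps[i]
  ## glottal-flow shaping: double real pole (~ -12 dB/oct above ~200 Hz)
  rg <- exp(-2 * pi * 200 / rate)
  h <- as.numeric(stats::filter(x, c(2 * rg, -rg^2), method = "recursive"))
  src <- h
  if (is.finite(spec$hnr_db)) {
    p_h <- mean(h^2)
    noise <- with_seed(derive_seed(seed, 2L), rnorm(n))
    noise <- noise * sqrt(p_h * 10^(-spec$hnr_db / 10) / mean(noise^2))
    src <- h + noise
  }
  y <- src
  for (k in seq_len(nrow(spec$formants)))
    y <- resonator_filter(y, spec$formants[k, 1L], spec$formants[k, 2L], rate)
  y <- c(y[1L], diff(y))          # lip radiation: +6 dB/oct
  y <- 0.9 * y / max(abs(y))
  if (is.null(source_id))
    source_id <- sprintf("synth_%s_f0%.0f_seed%d", spec$label, spec$f0_mean, seed)
  waveform(y, rate, source_id)
}

#' Class-level generative distributions
#'
#' Per-recording [voice_spec] parameters are drawn around these class means:
#' healthy controls with low jitter/shimmer, high HNR and normal pitch
#' variability; Parkinson's voices with elevated jitter/shimmer, reduced HNR
#' and monopitch (small f0_sd). The values are package constants taken from
#' typical dysarthria-literature ranges; they are configuration of the
#' synthetic cohort, not estimates of any real corpus.
#'
#' @return Named list of distribution parameters (mean and spread per knob).
#' @export
hc_class_defaults <- function() {
  list(f0_mean = c(130, 20), f0_sd = c(15, 3), jitter_pct = c(0.5, 0.15),
       shimmer_pct = c(3, 0.8), hnr_db = c(20, 2),
       formant_centers = c(500, 1500, 2500), formant_bw = c(80, 120, 160),
       formant_jitter = 0.05)
}

#' @rdname hc_class_defaults
#' @export
pd_class_defaults <- function() {
  list(f0_mean = c(125, 20), f0_sd = c(4, 1), jitter_pct = c(2, 0.5),
       shimmer_pct = c(8, 2), hnr_db = c(10, 2),
       formant_centers = c(500, 1500, 2500), formant_bw = c(80, 120, 160),
       formant_jitter = 0.05)
}

draw_spec <- function(defs, label) {
  dr <- function(p, lo) max(lo, rnorm(1L, p[1L], p[2L]))
  centers <- defs$formant_centers * exp(rnorm(length(defs$formant_centers),
                                              0, defs$formant_jitter))
  voice_spec(f0_mean = dr(defs$f0_mean, 60),
             f0_sd = dr(defs$f0_sd, 0.5),
             jitter_pct = min(45, dr(defs$jitter_pct, 0.05)),
             shimmer_pct = min(90, dr(defs$shimmer_pct, 0.2)),
             hnr_db = dr(defs$hnr_db, 2),
             formants = cbind(sort(centers), defs$formant_bw),
             label = label)
}

#' Synthesize a labelled two-class cohort
#'
#' Draws a per-recording [voice_spec] from the class distributions
#' ([hc_class_defaults], [pd_class_defaults]) and synthesizes each
#' recording; every item carries its spec for parameter-recovery checks.
#'
#' @param n_hc,n_pd recordings per class (>= 1).
#' @param duration seconds per recording (default 3).
#' @param rate sample rate in Hz.
#' @param seed integer seed; deterministic given it.
#' @return List of `list(wave, label, spec)`.
#' @export
synth_cohort <- function(n_hc, n_pd, duration = 3, rate = 16000, seed = 1L) {
  if (n_hc < 1L || n_pd < 1L) stop("need at least one recording per class")
  labels <- c(rep("HC", n_hc), rep("PD", n_pd))
  specs <- with_seed(derive_seed(seed, 3L), lapply(labels, function(lb)
    draw_spec(if (lb == "HC") hc_class_defaults() else pd_class_defaults(), lb)))
  lapply(seq_along(specs), function(i) {
    w <- synth_voice(specs[[i]], duration, rate, seed = derive_seed(seed, 100L + i),
                     source_id = sprintf("%s_%03d", labels[i], i))
    list(wave = w, label = labels[i], spec = specs[[i]])
  })
}

#' Two-speaker conversation script
#'
#' @param speakers integer vector of turn owners (0 or 1; both must appear).
#' @param durations turn durations in seconds (> 0), same length.
#' @param gap silence between consecutive turns in seconds (default 0.25).
#' @return An object of class `conversation_script`.
#' @export
conversation_script <- function(speakers, durations, gap = 0.25) {
  if (length(speakers) != length(durations) || length(speakers) == 0L)
    stop("speakers and durations must be non-empty and matched")
  if (!all(speakers %in% c(0L, 1L))) stop("speakers must be 0 or 1")
  if (length(unique(speakers)) < 2L) stop("both speakers need at least one turn")
  if (any(durations <= 0)) stop("turn durations must be > 0")
  if (gap < 0) stop("gap must be >= 0")
  structure(list(turns = data.frame(speaker = as.integer(speakers),
                                    duration = as.numeric(durations)),
                 gap = gap),
            class = "conversation_script")
}

#' Synthesize a two-speaker conversation with ground truth
#'
#' Turns are synthesized per speaker spec and concatenated in script order
#' with silent gaps; no additive background noise (emulating a call recorded
#' off-stream). The returned timeline covers exactly the speech portion.
#'
#' @param spec_a,spec_b [voice_spec] of speaker 0 and speaker 1.
#' @param script a [conversation_script].
#' @param rate sample rate, Hz.
#' @param seed integer seed.
#' @param equalize_rms scale every turn to the quietest turn's RMS level
#'   (default `TRUE`), emulating the automatic gain control of a telephone
#'   channel so neither party is systematically louder.
#' @return List with `wave` (a [waveform]) and `timeline` (data.frame
#'   `start`, `end`, `speaker`).
#' @export
synth_conversation <- function(spec_a, spec_b, script, rate = 16000, seed = 1L,
                               equalize_rms = TRUE) {
  stopifnot(inherits(script, "conversation_script"))
  n_turns <- nrow(script$turns)
  turns_audio <- lapply(seq_len(n_turns), function(i) {
    spec <- if (script$turns$speaker[i] == 0L) spec_a else spec_b
    synth_voice(spec, script$turns$duration[i], rate,
                seed = derive_seed(seed, 200L + i))$samples
  })
  if (equalize_rms) {
    rms <- vapply(turns_audio, function(s) sqrt(mean(s^2)), numeric(1))
    turns_audio <- lapply(seq_len(n_turns), function(i)
      turns_audio[[i]] * min(rms) / rms[i])
  }
  pieces <- vector("list", n_turns)
  starts <- ends <- numeric(n_turns)
  t <- 0
  for (i in seq_len(n_turns)) {
    pieces[[i]] <- turns_audio[[i]]
    starts[i] <- t; ends[i] <- t + length(pieces[[i]]) / rate
    t <- ends[i]
    if (i < n_turns) {
      pieces[[i]] <- c(pieces[[i]], numeric(round(script$gap * rate)))
      t <- t + round(script$gap * rate) / rate
    }
  }
  wave <- waveform(unlist(pieces), rate, sprintf("conv_seed%d", seed))
  list(wave = wave,
       timeline = data.frame(start = starts, end = ends,
                             speaker = script$turns$speaker))
}

#' Read/write diarization segments as RTTM
#'
#' One `SPEAKER` line per segment: `SPEAKER <file-id> 1 <onset> <duration>
#' <NA> <NA> <name> <NA> <NA>`.
#'
#' @param segments data.frame with `start`, `end` and a speaker/cluster
#'   column (third column used as the name).
#' @param path output path.
#' @param file_id recording identifier written in each line.
#' @return `write_rttm`: `path` invisibly; `read_rttm`: a data.frame
#'   `start`, `end`, `speaker`.
#' @export
write_rttm <- function(segments, path, file_id = "rec") {
  name <- segments[[3L]]
  lines <- sprintf("SPEAKER %s 1 %.3f %.3f <NA> <NA> %s <NA> <NA>",
                   file_id, segments$start, segments$end - segments$start, name)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rttm
#' @export
read_rttm <- function(path) {
  fields <- strsplit(readLines(path), " +")
  fields <- Filter(function(f) length(f) >= 8L && f[1L] == "SPEAKER", fields)
  start <- vapply(fields, function(f) as.numeric(f[4L]), numeric(1))
  dur <- vapply(fields, function(f) as.numeric(f[5L]), numeric(1))
  data.frame(start = start, end = start + dur,
             speaker = vapply(fields, `[`, character(1), 8L))
}
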