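#' Diarization configuration
#'
#' @param window_s embedding window length, seconds (default 1.0).
#' @param hop_s hop between window starts, seconds (default 0.25; the hop
#'   sets the time resolution of speaker-change boundaries, which snap to
#'   a hop-sized stride grid).
#' @param n_speakers expected number of speakers (>= 1).
#' @param include_noise_cluster add one extra cluster intended to absorb
#'   background noise (the clusters-equals-speakers-plus-one rule); the
#'   noise cluster is identified as the one with lowest mean window energy
#'   and excluded from speaker export. Default `FALSE` (clean calls).
#' @param smoothing_width odd number of windows for majority-vote label
#'   smoothing (default 5).
#' @param seed integer seed for the clustering initialization.
#' @param embedder `"cepstral-stats"` (default) or a function
#'   `(waveform, cfg) -> numeric` supplying an external embedding.
#' @param cepstral a [cepstral_config] used by the default embedder.
#' @return An object of class `diarization_config`.
#' @export
diarization_config <- function(window_s = 1.0, hop_s = 0.25, n_speakers = 2L,
                               include_noise_cluster = FALSE,
                               smoothing_width = 5L, seed = 1L,
                               embedder = "cepstral-stats",
                               cepstral = cepstral_config()) {
  if (n_speakers < 1L) stop("n_speakers must be >= 1")
  if (smoothing_width %% 2L != 1L) stop("smoothing_width must be odd")
  structure(list(window_s = window_s, hop_s = hop_s,
                 n_speakers = as.integer(n_speakers),
                 include_noise_cluster = isTRUE(include_noise_cluster),
                 smoothing_width = as.integer(smoothing_width),
                 seed = as.integer(seed), embedder = embedder,
                 cepstral = cepstral),
            class = "diarization_config")
}

#' Sliding windows over an audio stream
#'
#' @param w a [waveform] at least one window long.
#' @param cfg a [diarization_config].
#' @return List of `list(wave, start, end)`; the last partial window is
#'   dropped.
#' @export
segment_stream <- function(w, cfg) {
  stopifnot(inherits(w, "waveform"))
  win <- round(cfg$window_s * w$rate)
  hop <- round(cfg$hop_s * w$rate)
  n <- length(w$samples)
  if (n < win) stop("stream shorter than one window")
  n_win <- 1L + (n - win) %/% hop
  lapply(seq_len(n_win), function(i) {
    a <- (i - 1L) * hop
    piece <- w
    piece$samples <- w$samples[(a + 1L):(a + win)]
    piece$source_id <- sprintf("%s@%0.2fs", w$source_id, a / w$rate)
    list(wave = piece, start = a / w$rate, end = (a + win) / w$rate)
  })
}

#' Speaker embedding of one window
#'
#' Default "cepstral-stats" strategy: energy-weighted per-window mean and
#' standard deviation of the per-frame MFCCs (26 values under the default
#' 13-coefficient front-end) — a deterministic spectral-statistics
#' descriptor standing where a neural speaker embedding would plug in.
#' Frames are weighted by their linear energy, so near-silent frames (turn
#' gaps clipped by the window grid) contribute negligibly and a boundary
#' window is characterized by the speech it actually contains. A fully
#' silent window degenerates to the unweighted statistics of the
#' floor-energy cepstra rather than erroring.
#'
#' @param window a [waveform] (one analysis window).
#' @param cfg a [diarization_config].
#' @return Numeric embedding vector.
#' @export
embed_window <- function(window, cfg) {
  if (is.function(cfg$embedder)) return(cfg$embedder(window, cfg))
  ccfg <- cfg$cepstral
  emph <- pre_emphasis(window, ccfg$preemph_alpha)
  fm <- frame_signal(emph, ccfg$frame_len_s, ccfg$hop_s, ccfg$window)
  C <- mfcc(fm, ccfg)
  wt <- rowMeans(fm$frames^2)
  if (sum(wt) <= 0) wt <- rep(1, nrow(C))
  wt <- wt / sum(wt)
  mu <- colSums(C * wt)
  sds <- sqrt(colSums((C - rep(mu, each = nrow(C)))^2 * wt))
  c(mu, sds)
}

#' K-means clustering of embeddings (Lloyd iteration)
#'
#' Greedy farthest-point seeding from a seeded random first centre, then
#' standard Lloyd assignment/update until assignments are stable or 300
#' iterations. Deterministic given `seed`; assignment ties break toward the
#' lowest cluster index.
#'
#' @param embeddings numeric matrix, one row per window.
#' @param k number of clusters (<= rows).
#' @param seed integer seed.
#' @return List: `cluster` (integer labels 1..k), `centers`, `wss`
#'   (within-cluster sum of squares after each iteration), `iterations`.
#' @export
cluster_speakers <- function(embeddings, k, seed = 1L) {
  E <- as.matrix(embeddings)
  n <- nrow(E)
  if (k > n) stop("k exceeds number of embeddings")
  sq <- rowSums(E^2)
  d2_to <- function(center) pmax(0, sq - 2 * drop(E %*% center) + sum(center^2))
  centers <- matrix(0, k, ncol(E))
  first <- with_seed(seed, sample.int(n, 1L))
  centers[1L, ] <- E[first, ]
  if (k > 1L) {
    mind <- d2_to(centers[1L, ])
    for (j in 2:k) {
      centers[j, ] <- E[which.max(mind), ]
      mind <- pmin(mind, d2_to(centers[j, ]))
    }
  }
  lab <- integer(n)
  wss_trace <- numeric(0)
  for (it in seq_len(300L)) {
    D2 <- vapply(seq_len(k), function(j) d2_to(centers[j, ]), numeric(n))
    if (n == 1L) D2 <- matrix(D2, nrow = 1L)
    new_lab <- max.col(-D2, ties.method = "first")
    wss_trace <- c(wss_trace, sum(D2[cbind(seq_len(n), new_lab)]))
    for (j in seq_len(k)) {
      rows <- which(new_lab == j)
      if (length(rows)) {
        centers[j, ] <- colMeans(E[rows, , drop = FALSE])
      } else {
        ## empty cluster: re-seed at the point farthest from its centre
        far <- which.max(D2[cbind(seq_len(n), new_lab)])
        centers[j, ] <- E[far, ]
      }
    }
    if (it > 1L && all(new_lab == lab)) break
    lab <- new_lab
  }
  list(cluster = lab, centers = centers, wss = wss_trace, iterations = it)
}

#' Majority-vote label smoothing
#'
#' Recursive sliding-window majority over `width` labels (truncated at the
#' edges): positions before the current one contribute their
#' already-smoothed values, which makes a single pass reach a fixed point
#' of the filter. Ties break toward the preceding (already-smoothed)
#' label, favouring temporal continuity, and otherwise toward the smallest
#' label.
#'
#' @param labels integer (or character) label sequence.
#' @param width odd window width (>= 1); 1 is the identity.
#' @return Smoothed sequence of the same length.
#' @export
smooth_labels <- function(labels, width = 5L) {
  if (width %% 2L != 1L || width < 1L) stop("width must be odd and >= 1")
  n <- length(labels)
  if (width == 1L || n == 0L) return(labels)
  h <- (width - 1L) %/% 2L
  out <- labels
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    win <- c(if (lo < i) out[lo:(i - 1L)], labels[i:min(n, i + h)])
    cnt <- table(win)
    top <- names(cnt)[cnt == max(cnt)]
    prev <- as.character(if (i > 1L) out[i - 1L] else labels[i])
    pick <- if (prev %in% top) prev else sort(top)[1L]
    out[i] <- if (is.numeric(labels)) as.numeric(pick) else pick
  }
  out
}

#' Diarize a conversation recording
#'
#' Sliding windows, per-window embeddings, k-means with
#' `k = n_speakers + include_noise_cluster`, majority smoothing, then
#' merging: each hop-sized stride takes the label of the window centred
#' nearest to it, and consecutive same-label strides merge into segments.
#'
#' @param w a [waveform].
#' @param cfg a [diarization_config].
#' @return An object of class `diarization`: list with `segments`
#'   (data.frame `start`, `end`, `cluster`), `window_labels`,
#'   `window_spans`, `k`, `noise_cluster` (NA unless requested), `rate`,
#'   `source_id`.
#' @export
diarize <- function(w, cfg = diarization_config()) {
  windows <- segment_stream(w, cfg)
  E <- do.call(rbind, lapply(windows, function(win) embed_window(win$wave, cfg)))
  k <- cfg$n_speakers + as.integer(cfg$include_noise_cluster)
  km <- cluster_speakers(E, k, cfg$seed)
  lab <- smooth_labels(km$cluster, cfg$smoothing_width)
  centers_t <- vapply(windows, function(win) (win$start + win$end) / 2, numeric(1))
  last_end <- windows[[length(windows)]]$end
  stride_starts <- seq(0, last_end - cfg$hop_s + 1e-9, by = cfg$hop_s)
  stride_lab <- vapply(stride_starts, function(s0) {
    dd <- abs(centers_t - (s0 + cfg$hop_s / 2))
    ## equidistant windows: prefer the later one, so a speaker change seen
    ## by the fresher window takes effect at this stride
    lab[max(which(dd <= min(dd) + 1e-9))]
  }, numeric(1))
  runs <- rle(stride_lab)
  ends_i <- cumsum(runs$lengths)
  starts_i <- c(0L, head(ends_i, -1L))
  segments <- data.frame(start = stride_starts[starts_i + 1L],
                         end = c(stride_starts[ends_i] + cfg$hop_s),
                         cluster = as.integer(runs$values))
  ## the final partial window was dropped; let the last label run out to the
  ## end of the stream so the segments cover it entirely
  segments$end[nrow(segments)] <- wave_duration(w)
  noise <- NA_integer_
  if (cfg$include_noise_cluster) {
    energy <- vapply(windows, function(win) mean(win$wave$samples^2), numeric(1))
    mean_by <- tapply(energy, km$cluster, mean)
    noise <- as.integer(names(mean_by)[which.min(mean_by)])
  }
  structure(list(segments = segments, window_labels = lab,
                 window_spans = data.frame(
                   start = vapply(windows, `[[`, numeric(1), "start"),
                   end = vapply(windows, `[[`, numeric(1), "end")),
                 k = k, noise_cluster = noise, rate = w$rate,
                 source_id = w$source_id),
            class = "diarization")
}

#' @export
print.diarization <- function(x, ...) {
  cat(sprintf("<diarization> %s: %d segments, k = %d\n",
              x$source_id, nrow(x$segments), x$k))
  print(x$segments)
  invisible(x)
}

#' Concatenate one cluster's audio
#'
#' Copies the cluster's segments verbatim (no resampling, no gain) in
#' temporal order.
#'
#' @param w the diarized [waveform].
#' @param d a [diarize] result.
#' @param cluster_id cluster to extract.
#' @return A [waveform] tagged `<source_id>_spk<cluster>`.
#' @export
extract_speaker_audio <- function(w, d, cluster_id) {
  stopifnot(inherits(d, "diarization"))
  seg <- d$segments[d$segments$cluster == cluster_id, , drop = FALSE]
  if (nrow(seg) == 0L) stop("cluster ", cluster_id, " not present in diarization")
  pieces <- lapply(seq_len(nrow(seg)), function(i) {
    a <- round(seg$start[i] * w$rate) + 1L
    b <- min(length(w$samples), round(seg$end[i] * w$rate))
    w$samples[a:b]
  })
  waveform(unlist(pieces), w$rate,
           sprintf("%s_spk%d", w$source_id, as.integer(cluster_id)))
}

#' Cluster with the greatest total speaking time
#'
#' The default rule identifying the subject in a two-party call; the noise
#' cluster (when present) is excluded.
#'
#' @param d a [diarize] result.
#' @return Integer cluster id.
#' @export
dominant_cluster <- function(d) {
  seg <- d$segments
  if (!is.na(d$noise_cluster)) seg <- seg[seg$cluster != d$noise_cluster, ]
  tot <- tapply(seg$end - seg$start, seg$cluster, sum)
  as.integer(names(tot)[which.max(tot)])
}

segment_label_at <- function(segments, t) {
  idx <- findInterval(t, segments$start)
  lab <- rep(NA_integer_, length(t))
  ok <- idx >= 1L
  ok[ok] <- t[ok] <= segments$end[idx[ok]] + 1e-9
  lab[ok] <- segments$cluster[idx[ok]]
  lab
}

#' Time-weighted diarization accuracy against a ground-truth timeline
#'
#' Samples the ground-truth speech regions on a fine grid, maps each true
#' speaker to a distinct cluster by the best (maximum-agreement)
#' assignment, and returns the agreed fraction of speech time. Invariant
#' under any relabelling of the clusters.
#'
#' @param d a [diarize] result.
#' @param timeline data.frame `start`, `end`, `speaker` (ground truth).
#' @param grid_s evaluation grid step, seconds (default 0.01).
#' @return List: `accuracy` (fraction in \[0, 1\]), `mapping` (named
#'   integer: cluster per speaker).
#' @export
diarization_accuracy <- function(d, timeline, grid_s = 0.01) {
  pts <- do.call(rbind, lapply(seq_len(nrow(timeline)), function(i) {
    tt <- seq(timeline$start[i] + grid_s / 2, timeline$end[i], by = grid_s)
    data.frame(t = tt, speaker = timeline$speaker[i])
  }))
  pred <- segment_label_at(d$segments, pts$t)
  speakers <- sort(unique(pts$speaker))
  clusters <- sort(unique(d$segments$cluster))
  perms <- all_injections(length(speakers), clusters)
  best <- 0; best_map <- NULL
  for (p in perms) {
    map <- stats::setNames(p, speakers)
    hit <- !is.na(pred) & pred == map[as.character(pts$speaker)]
    acc <- mean(hit)
    if (acc >= best) { best <- acc; best_map <- map }
  }
  list(accuracy = best, mapping = best_map)
}

all_injections <- function(n_slots, values) {
  if (n_slots == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(values)) {
    rest <- all_injections(n_slots - 1L, values[-i])
    out <- c(out, lapply(rest, function(r) c(values[i], r)))
  }
  out
}

#' Purity of extracted speaker audio
#'
#' Fraction of the duration of one cluster's segments that overlaps the
#' ground-truth regions of a given speaker.
#'
#' @param d a [diarize] result.
#' @param cluster_id cluster whose audio was extracted.
#' @param timeline ground-truth data.frame `start`, `end`, `speaker`.
#' @param speaker true speaker index to score against.
#' @return Fraction in \[0, 1\].
#' @export
speaker_purity <- function(d, cluster_id, timeline, speaker) {
  seg <- d$segments[d$segments$cluster == cluster_id, , drop = FALSE]
  truth <- timeline[timeline$speaker == speaker, , drop = FALSE]
  total <- sum(seg$end - seg$start)
  if (total == 0) return(0)
  overlap <- 0
  for (i in seq_len(nrow(seg)))
    for (j in seq_len(nrow(truth)))
      overlap <- overlap + max(0, min(seg$end[i], truth$end[j]) -
                                  max(seg$start[i], truth$start[j]))
  overlap / total
}
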