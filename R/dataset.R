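#' Train/test split specification
#'
#' @param n_train,n_test total rows of the training and testing tables
#'   (even when `balanced`).
#' @param balanced equal per-class counts (default `TRUE`, the
#'   evenness rule the classification tables are built under).
#' @param subject_disjoint when `TRUE`, the draw is over recordings
#'   (source ids) first, so no subject contributes rows to both tables.
#'   Default `FALSE`, replicating a plain sample-level random draw; the
#'   audit always reports the resulting subject overlap.
#' @param seed integer seed (mandatory; no implicit randomness).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(n_train, n_test, balanced = TRUE,
                       subject_disjoint = FALSE, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (balanced && (n_train %% 2L != 0L || n_test %% 2L != 0L))
    stop("balanced tables need even n_train and n_test")
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 balanced = isTRUE(balanced),
                 subject_disjoint = isTRUE(subject_disjoint),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Build class-balanced training and testing tables
#'
#' Draws, per class, `n_train/2` then `n_test/2` feature rows without
#' replacement (so the tables are disjoint at row level); with
#' `subject_disjoint`, recordings are first split between the tables so no
#' source id spans both.
#'
#' @param features feature data.frame with `label`, `source_id`,
#'   `chunk_index` columns (e.g. from [featurize_cohort]).
#' @param spec a [split_spec].
#' @return List `train`, `test` (data.frames with a `role` attribute) and
#'   `spec`.
#' @export
build_tables <- function(features, spec) {
  stopifnot(inherits(spec, "split_spec"))
  classes <- sort(unique(features$label))
  if (length(classes) != 2L) stop("expected exactly two classes")
  per_tr <- if (spec$balanced) spec$n_train %/% 2L else NA_integer_
  per_te <- if (spec$balanced) spec$n_test %/% 2L else NA_integer_
  picks <- with_seed(spec$seed, lapply(classes, function(cl) {
    rows <- which(features$label == cl)
    need_tr <- per_tr; need_te <- per_te
    if (!spec$balanced) {
      need_tr <- round(spec$n_train * length(rows) / nrow(features))
      need_te <- round(spec$n_test * length(rows) / nrow(features))
    }
    if (length(rows) < need_tr + need_te)
      stop(sprintf("class %s: need %d rows, have %d (shortfall %d)",
                   cl, need_tr + need_te, length(rows),
                   need_tr + need_te - length(rows)))
    if (spec$subject_disjoint) {
      subj <- sample(unique(features$source_id[rows]))
      sizes <- vapply(subj, function(s)
        sum(features$source_id[rows] == s), integer(1))
      cut <- which(cumsum(sizes) >= need_tr)[1L]
      if (is.na(cut) || sum(sizes[-seq_len(cut)]) < need_te)
        stop(sprintf("class %s: cannot split subjects disjointly (%d train + %d test rows requested)",
                     cl, need_tr, need_te))
      tr_pool <- rows[features$source_id[rows] %in% subj[seq_len(cut)]]
      te_pool <- rows[features$source_id[rows] %in% subj[-seq_len(cut)]]
      list(train = sample(tr_pool, need_tr), test = sample(te_pool, need_te))
    } else {
      draw <- sample(rows, need_tr + need_te)
      list(train = draw[seq_len(need_tr)], test = draw[need_tr + seq_len(need_te)])
    }
  }))
  train <- features[sort(unlist(lapply(picks, `[[`, "train"))), , drop = FALSE]
  test <- features[sort(unlist(lapply(picks, `[[`, "test"))), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  attr(train, "role") <- "train"; attr(test, "role") <- "test"
  list(train = train, test = test, spec = spec)
}

#' Audit a feature table (and its companion)
#'
#' Reports class counts, subject counts, duplicated provenance keys, and —
#' when a second table is given — the subjects appearing in both. The
#' subject-overlap report is always produced because a sample-level draw
#' typically places samples of one speaker in both tables, an optimistic
#' bias worth surfacing.
#'
#' @param t feature data.frame.
#' @param other optional second table to check subject overlap against.
#' @return List `class_counts`, `n_subjects`, `duplicates` (data.frame of
#'   repeated `(source_id, chunk_index)` keys), `subject_overlap`
#'   (character vector, possibly empty).
#' @export
audit_table <- function(t, other = NULL) {
  key <- paste(t$source_id, t$chunk_index, sep = "::")
  dup <- t[duplicated(key), c("source_id", "chunk_index"), drop = FALSE]
  overlap <- character(0)
  if (!is.null(other))
    overlap <- intersect(unique(t$source_id), unique(other$source_id))
  list(class_counts = table(t$label),
       n_subjects = length(unique(t$source_id)),
       duplicates = dup,
       subject_overlap = overlap)
}
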