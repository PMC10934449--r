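#' Significance stars from a p-value
#'
#' Conventional thresholds: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return Character vector of star codes.
#' @export
stars_from_p <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Unpaired two-sample t-test
#'
#' Student (pooled variance, df = n_a + n_b - 2) or Welch
#' (Welch-Satterthwaite df) variant, two-sided. The degenerate case of two
#' zero-variance groups with identical means returns t = 0, p = 1 rather
#' than an error.
#'
#' @param a,b numeric vectors (>= 2 finite values each).
#' @param variant `"student"` (default) or `"welch"`.
#' @return An object of class `ttest_result`: `t_statistic`, `df`,
#'   `p_value`, `stars`, group means and sds.
#' @export
unpaired_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, parameter = length(a) + length(b) - 2L,
                  p.value = 1)
    } else {
      res <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                  parameter = length(a) + length(b) - 2L, p.value = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = (variant == "student"))
    res <- list(statistic = unname(tt$statistic),
                parameter = unname(tt$parameter), p.value = tt$p.value)
  }
  structure(list(t_statistic = res$statistic, df = res$parameter,
                 p_value = res$p.value, stars = stars_from_p(res$p.value),
                 variant = variant,
                 mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b)),
            class = "ttest_result")
}

#' Per-coefficient group comparison panel
#'
#' One unpaired t-test per cepstral coefficient column between the
#' healthy-control and disease tables, MFCC coefficients first then GTCC.
#' Stars come from the (optionally Holm-corrected) p-values; both raw and
#' corrected p are reported side by side.
#'
#' @param hc_table,pd_table feature data.frames sharing the cepstral
#'   column dialect.
#' @param variant `"student"` (default) or `"welch"`.
#' @param correction `"none"` (default) or `"holm"`.
#' @return A data.frame with one row per coefficient: `coefficient`,
#'   per-group n/mean/sd, `t`, `df`, `p`, `p_corrected`, `stars`.
#' @export
coefficient_panel <- function(hc_table, pd_table,
                              variant = c("student", "welch"),
                              correction = c("none", "holm")) {
  variant <- match.arg(variant)
  correction <- match.arg(correction)
  cols <- c(feature_columns(hc_table, "mfcc"), feature_columns(hc_table, "gtcc"))
  if (!all(cols %in% names(pd_table))) stop("tables do not share columns")
  rows <- lapply(cols, function(cl) {
    r <- unpaired_ttest(hc_table[[cl]], pd_table[[cl]], variant)
    data.frame(coefficient = cl, n_hc = r$n_a, n_pd = r$n_b,
               mean_hc = r$mean_a, sd_hc = r$sd_a,
               mean_pd = r$mean_b, sd_pd = r$sd_b,
               t = r$t_statistic, df = r$df, p = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- if (correction == "holm") stats::p.adjust(out$p, "holm") else out$p
  out$stars <- stars_from_p(out$p_corrected)
  out
}
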