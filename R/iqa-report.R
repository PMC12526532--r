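# Composite image-quality scoring: normalization of the seven metrics to
# [0, 1] (1 = best), the averaged composite score, blur-severity bands,
# and group statistics (95% confidence intervals, paired t-tests).

# distance metrics are mapped through 1 - clip(raw / cap, 0, 1); the caps
# are a reconstruction calibrated so that typical blurred-image scores
# span the published composite range, and are configuration-exposed
default_metric_caps <- function() {
  c(DISTS = 1.0, LPIPS = 1.0, GMSD = 0.35, NLPD = 1.0)
}

#' Normalize a raw metric value to \[0, 1\]
#'
#' Similarity metrics (VSI, FSIM, MS-SSIM) pass through clipped to
#' \[0, 1\]; distance metrics (DISTS, LPIPS, GMSD, NLPD) are mapped as
#' `1 - clip(raw / cap, 0, 1)` with per-metric caps.
#'
#' @param name metric name (see [iqa_metric_names()]).
#' @param raw finite raw value.
#' @param caps named cap vector for the distance metrics.
#' @return normalized score in \[0, 1\], 1 = best.
#' @export
normalize_metric <- function(name, raw, caps = default_metric_caps()) {
  name <- toupper(name)
  if (!is.finite(raw)) stop("raw metric value must be finite",
                            call. = FALSE)
  if (name %in% c("VSI", "FSIM", "MS-SSIM"))
    return(min(max(raw, 0), 1))
  if (name %in% names(caps))
    return(1 - min(max(raw / caps[[name]], 0), 1))
  stop(sprintf("unknown metric '%s'", name), call. = FALSE)
}

#' Composite image-quality score
#'
#' Arithmetic mean of the seven normalized metric scores.
#'
#' @param normalized numeric vector of exactly seven values in \[0, 1\].
#' @param digits rounding of the reported score (3 decimals by
#'   convention; `NULL` for exact).
#' @return composite score S in \[0, 1\].
#' @export
composite_score <- function(normalized, digits = 3L) {
  if (length(normalized) != 7L)
    stop("composite score requires exactly seven normalized values",
         call. = FALSE)
  if (any(!is.finite(normalized)) || any(normalized < 0 | normalized > 1))
    stop("normalized scores must lie in [0, 1]", call. = FALSE)
  s <- mean(normalized)
  if (is.null(digits)) s else round(s, digits)
}

#' Blur-severity band of a composite score
#'
#' Bands partition \[0, 1\]: scores below 0.6 indicate severe blur,
#' \[0.6, 0.7) moderate, \[0.7, 0.8) mild, and 0.8 or above sharp
#' (left-closed bands).
#'
#' @param score composite score in \[0, 1\].
#' @return one of `"severe"`, `"moderate"`, `"mild"`, `"sharp"`.
#' @export
severity_band <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || !is.finite(score) ||
      score < 0 || score > 1)
    stop("score must be a single value in [0, 1]", call. = FALSE)
  if (score < 0.6) "severe"
  else if (score < 0.7) "moderate"
  else if (score < 0.8) "mild"
  else "sharp"
}

#' Full image-quality report
#'
#' Computes the seven metrics, normalizes each, and returns the
#' composite score with its severity band. DISTS and LPIPS require
#' registered backends ([iqa_register_backend]); without them the report
#' fails explicitly unless those metrics are excluded via `metrics`
#' (in which case no composite is defined and an error is also raised --
#' the composite is only defined over the full seven-metric set).
#'
#' @param ref,test images in \[0, 1\], identical shape.
#' @param caps distance-metric caps, see [normalize_metric].
#' @return an `iqa_report`: list with `per_metric` (data.frame of name,
#'   raw, normalized), `composite` and `severity`.
#' @export
iqa_report <- function(ref, test, caps = default_metric_caps()) {
  names_ <- iqa_metric_names()
  raw <- vapply(names_, function(nm) compute_raw_metric(nm, ref, test),
                numeric(1))
  normalized <- vapply(names_, function(nm)
    normalize_metric(nm, raw[[nm]], caps), numeric(1))
  s <- composite_score(unname(normalized), digits = NULL)
  structure(list(per_metric = data.frame(name = names_, raw = unname(raw),
                                         normalized = unname(normalized)),
                 composite = s, severity = severity_band(s)),
            class = "iqa_report")
}

#' @export
print.iqa_report <- function(x, ...) {
  cat("Image-quality report\n")
  print(transform(x$per_metric, raw = round(raw, 4),
                  normalized = round(normalized, 4)), row.names = FALSE)
  cat(sprintf("composite S = %.3f (%s)\n", x$composite, x$severity))
  invisible(x)
}

#' Paired group comparison
#'
#' Per-group means with 95% t-distribution confidence half-widths and a
#' two-sided paired t-test on the differences. Zero-variance differences
#' are reported as degenerate rather than as `p = 0`.
#'
#' @param scores_a,scores_b equal-length numeric vectors (n >= 2).
#' @return a `group_comparison`: list with `mean_a`, `mean_b`, `ci95_a`,
#'   `ci95_b`, `t_stat`, `p_value`, `df`, `n`, `degenerate`.
#' @export
paired_comparison <- function(scores_a, scores_b) {
  n <- length(scores_a)
  if (length(scores_b) != n)
    stop("groups must have equal length", call. = FALSE)
  if (n < 2L) stop("need at least two paired observations", call. = FALSE)
  half <- function(v) stats::qt(0.975, n - 1L) * stats::sd(v) / sqrt(n)
  diffs <- scores_a - scores_b
  degenerate <- stats::sd(diffs) < .Machine$double.eps^0.5
  if (degenerate) {
    t_stat <- NA_real_
    p_value <- NA_real_
  } else {
    tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_value <- tt$p.value
  }
  structure(list(mean_a = mean(scores_a), mean_b = mean(scores_b),
                 ci95_a = half(scores_a), ci95_b = half(scores_b),
                 t_stat = t_stat, p_value = p_value, df = n - 1L, n = n,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' Score paired image sets and summarize
#'
#' Batch helper: computes composite scores of `tests` against `refs`
#' (elementwise) and returns per-image scores plus the group summary
#' against a comparison set when given.
#'
#' @param refs,tests equal-length lists of images.
#' @param caps distance-metric caps.
#' @return data.frame with per-image composite scores and severity bands.
#' @export
score_image_set <- function(refs, tests, caps = default_metric_caps()) {
  stopifnot(length(refs) == length(tests))
  rows <- lapply(seq_along(refs), function(j) {
    rep_ <- iqa_report(refs[[j]], tests[[j]], caps)
    data.frame(index = j, composite = rep_$composite,
               severity = rep_$severity)
  })
  do.call(rbind, rows)
}
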