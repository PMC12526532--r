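# Detection-metric reporting across image-quality conditions
# (sharp / blurred / restored): derived scores (F1, false negative rate)
# and relative-improvement percentages between conditions.

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR / (P + R)`.
#'
#' @param precision,recall values in \[0, 1\].
#' @param digits rounding applied to the returned value (3 decimals by
#'   reporting convention; use `NULL` for the exact value).
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(precision, recall, digits = 3L) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  f1 <- ifelse(precision + recall == 0, {
    warning("precision and recall are both zero; F1 defined as 0")
    0
  }, 2 * precision * recall / (precision + recall))
  if (is.null(digits)) f1 else round(f1, digits)
}

#' False negative rate
#'
#' @param recall value in \[0, 1\].
#' @return `1 - recall`.
#' @export
false_negative_rate <- function(recall) {
  stopifnot(all(recall >= 0 & recall <= 1))
  1 - recall
}

#' Relative change between two metric values
#'
#' @param before,after metric values; `before` must be non-zero.
#' @param digits rounding of the percentage (1 decimal by reporting
#'   convention; `NULL` for exact).
#' @return signed percent change `100 * (after - before) / before`.
#' @export
relative_change <- function(before, after, digits = 1L) {
  if (any(before == 0))
    stop("relative change is undefined for a zero baseline", call. = FALSE)
  pct <- 100 * (after - before) / before
  if (is.null(digits)) pct else round(pct, digits)
}

#' Read a detection-metrics table
#'
#' Expects columns `source` (sharp/blur/restore), `class_name`, `map50`,
#' `map5095`, `precision`, `recall`, `f1`, `fnr`, `mconf`. CSV and JSON
#' are supported.
#'
#' @param path file path; defaults to the packaged table of published
#'   orchard detection metrics.
#' @return data.frame of `detection_row`s.
#' @export
read_detection_table <- function(path = system.file(
  "extdata", "detection_metrics.csv", package = "aggdeblur")) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else
    utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("source", "class_name", "map50", "map5095", "precision",
                "recall", "f1", "fnr", "mconf")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("detection table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- setdiff(required, c("source", "class_name"))
  bad <- vapply(num, function(cn) any(tab[[cn]] < 0 | tab[[cn]] > 1),
                logical(1))
  if (any(bad))
    stop("metric values must lie in [0, 1]", call. = FALSE)
  tab
}

#' Improvement report across image-quality conditions
#'
#' For every class present in at least two conditions, computes the
#' blur-to-restore and blur-to-sharp relative changes of every metric,
#' and cross-checks the stored `f1` and `fnr` columns against
#' recomputation from precision and recall. Discrepancies beyond
#' `consistency_tol` are flagged in the `flags` element, never silently
#' corrected.
#'
#' @param rows a detection table as returned by [read_detection_table].
#' @param consistency_tol absolute tolerance for the stored-versus-
#'   recomputed F1/FNR check. The default 0.002 admits what rounding the
#'   stored three-decimal precision/recall values can explain; genuinely
#'   inconsistent published cells are therefore flagged.
#' @return an `improvement_report`: list with `changes` (data.frame of
#'   class, metric, comparison, percent change) and `flags` (data.frame
#'   of consistency findings).
#' @export
improvement_report <- function(rows, consistency_tol = 0.002) {
  conditions <- unique(rows$source)
  if (length(conditions) < 2L)
    stop("need rows for at least two conditions", call. = FALSE)
  metrics <- c("map50", "map5095", "precision", "recall", "f1", "fnr",
               "mconf")
  flags <- list()
  for (j in seq_len(nrow(rows))) {
    f1r <- f1_score(rows$precision[j], rows$recall[j], digits = NULL)
    if (abs(f1r - rows$f1[j]) > consistency_tol)
      flags[[length(flags) + 1L]] <- data.frame(
        source = rows$source[j], class_name = rows$class_name[j],
        field = "f1", stored = rows$f1[j], recomputed = round(f1r, 3L))
    fnrr <- false_negative_rate(rows$recall[j])
    if (abs(fnrr - rows$fnr[j]) > consistency_tol)
      flags[[length(flags) + 1L]] <- data.frame(
        source = rows$source[j], class_name = rows$class_name[j],
        field = "fnr", stored = rows$fnr[j], recomputed = round(fnrr, 3L))
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(source = character(), class_name = character(),
               field = character(), stored = numeric(),
               recomputed = numeric())
  changes <- list()
  comparisons <- list(c("blur", "restore"), c("blur", "sharp"))
  for (cl in unique(rows$class_name)) {
    for (cmp in comparisons) {
      a <- rows[rows$class_name == cl & rows$source == cmp[1L], ]
      b <- rows[rows$class_name == cl & rows$source == cmp[2L], ]
      if (nrow(a) != 1L || nrow(b) != 1L) {
        warning(sprintf("missing condition %s or %s for class %s; %s",
                        cmp[1L], cmp[2L], cl,
                        "report is partial"), call. = FALSE)
        next
      }
      for (m in metrics) {
        if (a[[m]] == 0) next
        changes[[length(changes) + 1L]] <- data.frame(
          class_name = cl, metric = m,
          comparison = paste(cmp, collapse = "_to_"),
          before = a[[m]], after = b[[m]],
          change_pct = relative_change(a[[m]], b[[m]]))
      }
    }
  }
  structure(list(changes = do.call(rbind, changes), flags = flags),
            class = "improvement_report")
}
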