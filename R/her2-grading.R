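# HER2 grading from per-nucleus signal counts.
#
# Grading consumes a signal-count table (one row per nucleus inside the
# detected ROIs, with HER2 and CEP17 signal counts) and reports the mean
# HER2 copy number per nucleus, the pooled HER2/CEP17 ratio, and a binary
# Pos/Neg status at the guideline ratio cut-off of 2.0. The pooled
# (sum/sum) ratio is the standard in situ hybridization convention and is
# robust to individual nuclei with zero CEP17 signals.

HER2_RATIO_CUTOFF <- 2.0

#' HER2 status from a score
#'
#' @param score HER2/CEP17 ratio(s), >= 0.
#' @return `"Pos"` if `score >= 2.0`, else `"Neg"` (vectorized).
#' @export
status_from_score <- function(score) {
  if (any(score < 0)) stop("score must be >= 0")
  ifelse(score >= HER2_RATIO_CUTOFF, "Pos", "Neg")
}

#' Grade one case from its signal-count table
#'
#' @param table data.frame with columns `her2_count` and `cep17_count`
#'   (non-negative integers), one row per nucleus.
#' @param case_id case identifier.
#' @return a `CaseScore` list: `case_id`, `her2_mean_per_nucleus`
#'   (`sum(her2) / n`), `her2_cep17_ratio` (`sum(her2) / sum(cep17)`), and
#'   `status`.
#' @export
grade_case <- function(table, case_id = "case") {
  if (NROW(table) == 0L) stop("empty table: at least one nucleus required")
  her2 <- table$her2_count
  cep17 <- table$cep17_count
  if (any(her2 < 0) || any(cep17 < 0)) stop("counts must be non-negative")
  if (any(her2 != trunc(her2)) || any(cep17 != trunc(cep17))) {
    stop("counts must be integers")
  }
  total_cep17 <- sum(cep17)
  if (total_cep17 == 0) stop("ratio undefined: total CEP17 count is zero")
  ratio <- sum(her2) / total_cep17
  structure(
    list(
      case_id = case_id,
      her2_mean_per_nucleus = sum(her2) / length(her2),
      her2_cep17_ratio = ratio,
      status = status_from_score(ratio)
    ),
    class = "CaseScore"
  )
}

#' @export
print.CaseScore <- function(x, ...) {
  cat(sprintf("Case %s: mean HER2/nucleus %.2f, HER2/CEP17 ratio %.2f -> %s\n",
              x$case_id, x$her2_mean_per_nucleus, x$her2_cep17_ratio,
              x$status))
  invisible(x)
}

#' Grade several cases and return a score table
#' @param tables named list of signal-count tables (one per case).
#' @return data.frame with `case_id`, `score`, `status`.
#' @export
grade_cases <- function(tables) {
  rows <- lapply(names(tables), function(id) {
    cs <- grade_case(tables[[id]], case_id = id)
    data.frame(case_id = id, score = cs$her2_cep17_ratio, status = cs$status)
  })
  do.call(rbind, rows)
}
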