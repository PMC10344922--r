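# Agreement statistics between paired case scores and statuses.
#
# Three statistics summarize observer or method agreement on HER2 grading:
# mean squared error between paired scores (1/n normalization), the
# Pearson correlation coefficient, and Cohen's kappa on the binary
# Pos/Neg statuses. Reference case tables (two independent users' automated
# scores; clinical vs method scores; test vs retest scores) ship as CSV
# fixtures, see [load_case_table()].

#' Mean squared error between paired scores
#' @param x,y numeric vectors of equal length.
#' @return `mean((x - y)^2)`.
#' @export
score_mse <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (!length(x)) stop("need at least one pair")
  mean((x - y)^2)
}

#' Pearson correlation between paired scores
#' @param x,y numeric vectors (length >= 2, both with nonzero variance).
#' @return sample Pearson correlation coefficient.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least two pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

#' Cohen's kappa between two raters' binary labels
#'
#' @param status_x,status_y character/factor vectors of equal length.
#' @return kappa = (p_o - p_e) / (1 - p_e), with expected agreement p_e
#'   from the raters' marginal label frequencies. When both raters are
#'   constant and identical (p_e = 1), kappa is defined as 1 by convention
#'   and a message is logged.
#' @export
cohens_kappa <- function(status_x, status_y) {
  if (length(status_x) != length(status_y)) stop("length mismatch")
  n <- length(status_x)
  if (!n) stop("need at least one pair")
  levels_all <- sort(unique(c(as.character(status_x), as.character(status_y))))
  fx <- factor(status_x, levels = levels_all)
  fy <- factor(status_y, levels = levels_all)
  tab <- table(fx, fy)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    message("both raters constant and equal; kappa defined as 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Bundle agreement statistics for paired case scores
#'
#' @param x,y paired numeric scores.
#' @param status_x,status_y optional paired statuses; when missing they
#'   are derived from the scores via [status_from_score()].
#' @return an `AgreementReport` list: `n`, `mse`, `pcc`, `kappa`, and the
#'   2x2 `contingency` table of statuses.
#' @export
agreement_report <- function(x, y, status_x = NULL, status_y = NULL) {
  status_x <- status_x %||% status_from_score(x)
  status_y <- status_y %||% status_from_score(y)
  fx <- factor(status_x, levels = c("Neg", "Pos"))
  fy <- factor(status_y, levels = c("Neg", "Pos"))
  structure(
    list(
      n = length(x),
      mse = score_mse(x, y),
      pcc = pearson_cc(x, y),
      kappa = cohens_kappa(status_x, status_y),
      contingency = table(fx, fy)
    ),
    class = "AgreementReport"
  )
}

#' @export
print.AgreementReport <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement over %d cases: MSE %.*f, PCC %.*f, kappa %.*f\n",
              x$n, digits, x$mse, digits, x$pcc, digits, x$kappa))
  print(x$contingency)
  invisible(x)
}

#' Load a bundled reference case table
#'
#' Three paired-score tables ship with the package, transcribed verbatim
#' from the reference study's printed case tables:
#' \describe{
#'   \item{`interobserver`}{two users' automated HER2 scores/statuses for
#'     12 cases (high inter-observer disagreement).}
#'   \item{`clinical`}{clinical scores vs the two users' scores and the
#'     automated-ROI method's scores for the same 12 cases.}
#'   \item{`test_retest`}{the automated method's test and retest scores.}
#' }
#'
#' @param name one of `"interobserver"`, `"clinical"`, `"test_retest"`.
#' @return data.frame.
#' @export
load_case_table <- function(name = c("interobserver", "clinical", "test_retest")) {
  name <- match.arg(name)
  file <- c(
    interobserver = "interobserver_scores.csv",
    clinical = "clinical_scores.csv",
    test_retest = "test_retest_scores.csv"
  )[[name]]
  path <- system.file("extdata", file, package = "slideroi")
  if (path == "") stop("bundled table not found: ", file)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
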