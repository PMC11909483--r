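#' Symptom scale scoring and category definitions
#'
#' The GAD-7 (7 items, 0-3 each, total 0-21) measures generalized anxiety;
#' the PHQ-9 (9 items, 0-3 each, total 0-27) measures depression. Their sum,
#' the PHQ-ADS (0-48), is a combined anxiety-depression severity scale.
#' These functions implement the scoring rules, the trial eligibility rule
#' (clinically significant anxiety or depression at baseline), joint
#' remission, and the severity/comorbidity category grids used in
#' descriptive tables.
#'
#' @name scales
NULL

GAD7_MAX <- 21L
PHQ9_MAX <- 27L
PHQ_ADS_MAX <- 48L

.check_score <- function(x, scale = c("GAD-7", "PHQ-9"), allow_na = FALSE) {
  scale <- match.arg(scale)
  max <- if (scale == "GAD-7") GAD7_MAX else PHQ9_MAX
  bad <- !is.na(x) & (x < 0 | x > max | x != round(x))
  if (any(bad)) {
    stop(sprintf("%s scores must be integers in [0, %d]; got %s",
                 scale, max, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop(sprintf("%s scores contain NA", scale), call. = FALSE)
  }
  invisible(x)
}

#' Combined anxiety-depression score (PHQ-ADS)
#'
#' @param gad7 integer vector of GAD-7 totals (0-21).
#' @param phq9 integer vector of PHQ-9 totals (0-27).
#' @return Integer vector of PHQ-ADS totals (0-48).
#' @examples
#' score_phq_ads(10, 13)  # 23
#' @export
score_phq_ads <- function(gad7, phq9) {
  .check_score(gad7, "GAD-7")
  .check_score(phq9, "PHQ-9")
  as.integer(gad7 + phq9)
}

#' Joint anxiety-depression remission
#'
#' Remission at a follow-up wave is defined as scoring 0-4 simultaneously on
#' the GAD-7 and the PHQ-9.
#'
#' @param gad7,phq9 follow-up scale totals.
#' @return Logical vector.
#' @export
is_joint_remission <- function(gad7, phq9) {
  if (anyNA(gad7) || anyNA(phq9)) {
    stop("remission is undefined for non-completed waves", call. = FALSE)
  }
  .check_score(gad7, "GAD-7")
  .check_score(phq9, "PHQ-9")
  gad7 <= 4 & phq9 <= 4
}

#' Baseline eligibility: clinically significant anxiety or depression
#'
#' @param gad7,phq9 baseline scale totals.
#' @return Logical vector: \code{gad7 >= 10 | phq9 >= 10}.
#' @export
is_eligible <- function(gad7, phq9) {
  .check_score(gad7, "GAD-7")
  .check_score(phq9, "PHQ-9")
  gad7 >= 10 | phq9 >= 10
}

#' Severity category of a scale score
#'
#' GAD-7: 0-9 mild/none, 10-14 moderate, >=15 severe. PHQ-9: 0-9 mild/none,
#' 10-14 moderate, 15-19 moderately severe, >=20 severe.
#'
#' @param scale "GAD-7" or "PHQ-9".
#' @param score integer vector of totals.
#' @return Ordered factor of severity levels.
#' @export
severity_category <- function(scale = c("GAD-7", "PHQ-9"), score) {
  scale <- match.arg(scale)
  .check_score(score, scale)
  if (scale == "GAD-7") {
    lv <- c("mild/none", "moderate", "severe")
    out <- lv[1L + (score >= 10) + (score >= 15)]
  } else {
    lv <- c("mild/none", "moderate", "moderately severe", "severe")
    out <- lv[1L + (score >= 10) + (score >= 15) + (score >= 20)]
  }
  factor(out, levels = lv, ordered = TRUE)
}

#' Anxiety-depression comorbidity category
#'
#' Five-level cross-classification of the two severity categories. On the
#' PHQ-9 side, "severe" pools the severe and moderately severe bands
#' (PHQ-9 >= 15); "moderate" is the 10-14 band of each scale.
#'
#' @param gad7,phq9 integer scale totals.
#' @return Factor with the five comorbidity levels.
#' @export
comorbidity_category <- function(gad7, phq9) {
  .check_score(gad7, "GAD-7")
  .check_score(phq9, "PHQ-9")
  g <- 1L + (gad7 >= 10) + (gad7 >= 15)             # 1 mild, 2 moderate, 3 severe
  p <- 1L + (phq9 >= 10) + (phq9 >= 15)             # PHQ-9 severe pools >=15
  p <- pmin(p, 3L)
  lv <- c("severe on both",
          "severe on one, moderate on the other",
          "severe on one, mild/none on the other",
          "moderate on both",
          "moderate on one, mild/none on the other",
          "mild/none on both")
  hi <- pmax(g, p)
  lo <- pmin(g, p)
  out <- ifelse(hi == 3 & lo == 3, lv[1],
         ifelse(hi == 3 & lo == 2, lv[2],
         ifelse(hi == 3 & lo == 1, lv[3],
         ifelse(hi == 2 & lo == 2, lv[4],
         ifelse(hi == 2 & lo == 1, lv[5], lv[6])))))
  factor(out, levels = lv)
}
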