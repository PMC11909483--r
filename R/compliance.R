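#' Usage-metadata compliance metrics
#'
#' Platform engagement is measured as minutes logged on per week over the
#' 52 weeks after randomization. The guidance phase covers weeks 1-12; the
#' post-guidance period weeks 13-52 defines the compliance construct used
#' by the prediction model.
#'
#' @name compliance
NULL

.usage_matrix <- function(usage) {
  wk <- paste0("week_", 1:52)
  missing_cols <- setdiff(wk, names(usage))
  if (length(missing_cols))
    stopf("usage table lacks columns: %s",
          paste(utils::head(missing_cols, 3), collapse = ", "))
  m <- as.matrix(usage[, wk])
  m[is.na(m)] <- 0
  if (any(m < 0)) stopf("usage minutes must be nonnegative")
  m
}

#' Per-period usage summary and between-arm comparison
#'
#' Mean and SD of minutes per participant-week within a period, per arm;
#' proportions of participant-weeks at or above the minute thresholds; and a
#' rank-based (Wilcoxon) 1-df chi-square comparing guided vs self-guided
#' participants' period mean minutes.
#'
#' @param usage usage table (\code{participant_id}, \code{week_1..week_52}).
#' @param arms arm assignment data.frame.
#' @param period \code{"1-12"} or \code{"13-52"}.
#' @param thresholds minutes-per-week thresholds.
#' @param mode \code{"participant_weeks"} computes threshold proportions over
#'   participant-weeks; \code{"participants_any_week"} over participants with
#'   any qualifying week.
#' @return A list of class \code{period_summary}: per-arm statistics and the
#'   guided-vs-self-guided test.
#' @export
summarize_usage <- function(usage, arms, period = c("1-12", "13-52"),
                            thresholds = c(5, 10, 30),
                            mode = c("participant_weeks",
                                     "participants_any_week")) {
  period <- match.arg(period)
  mode <- match.arg(mode)
  weeks <- if (period == "1-12") 1:12 else 13:52
  m <- .usage_matrix(usage)[, weeks, drop = FALSE]
  arm <- arms$arm[match(usage$participant_id, arms$participant_id)]
  stats_by_arm <- lapply(ARM_LEVELS, function(a) {
    rows <- which(arm == a)
    if (!length(rows)) stopf("no participants in arm '%s'", a)
    pw <- as.vector(m[rows, , drop = FALSE])
    props <- vapply(thresholds, function(thr) {
      if (mode == "participant_weeks") mean(pw >= thr)
      else mean(apply(m[rows, , drop = FALSE], 1, function(r) any(r >= thr)))
    }, 0)
    names(props) <- paste0("ge_", thresholds)
    list(arm = a, n = length(rows), mean = mean(pw), sd = stats::sd(pw),
         proportions = props)
  })
  names(stats_by_arm) <- ARM_LEVELS

  pm <- rowMeans(m)
  g <- pm[arm == "guided"]; s <- pm[arm == "self_guided"]
  wt <- suppressWarnings(stats::wilcox.test(g, s, exact = FALSE,
                                            correct = FALSE))
  z <- stats::qnorm(wt$p.value / 2)
  chi2 <- z^2
  structure(list(period = period, by_arm = stats_by_arm,
                 guided_vs_self = list(chi2 = chi2, df = 1L,
                                       p = wt$p.value),
                 thresholds = thresholds, mode = mode),
            class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("Usage summary, weeks %s (minutes per participant-week)\n",
              x$period))
  for (s in x$by_arm) {
    cat(sprintf("  %-12s n=%4d  mean %6.2f  sd %6.2f  %s\n", s$arm, s$n,
                s$mean, s$sd,
                paste(sprintf("P(>=%s)=%.3f",
                              sub("ge_", "", names(s$proportions)),
                              s$proportions), collapse = "  ")))
  }
  cat(sprintf("  guided vs self-guided: chi2(1)=%.1f, p=%.3g\n",
              x$guided_vs_self$chi2, x$guided_vs_self$p))
  invisible(x)
}

#' Scalar compliance target per participant
#'
#' Total minutes logged on over the post-guidance period (weeks 13-52 by
#' default), log1p-transformed. This is the quantity the compliance
#' prediction model is trained on in the self-guided arm.
#'
#' @param usage usage table.
#' @param weeks integer vector of weeks to total (default 13:52).
#' @param transform \code{"log1p"} (default), \code{"total"} (raw minutes)
#'   or \code{"mean"} (minutes per week).
#' @return Named numeric vector (participant ids).
#' @export
compliance_target <- function(usage, weeks = 13:52,
                              transform = c("log1p", "total", "mean")) {
  transform <- match.arg(transform)
  m <- .usage_matrix(usage)[, weeks, drop = FALSE]
  tot <- rowSums(m)
  out <- switch(transform,
                log1p = log1p(tot),
                total = tot,
                mean = tot / length(weeks))
  names(out) <- usage$participant_id
  out
}
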