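## Automatable cohort quality control.
##
## Exclusion criteria, applied in a fixed order with each subject
## attributed to the first criterion it fails:
##   1. age under 18 years
##   2. incomplete demographics (any of diagnosis, age, sex, education,
##      site, mean FD missing)
##   3. repetition time != 2 s (uniform temporal resolution for the
##      dynamic analysis)
##   4. poor image quality by manual checking -- NOT automatable from ROI
##      series; recorded as not applied
##   5. excessive head motion: mean framewise displacement > 0.2 mm
##   6. signal loss in a region, approximated by a zero-variance ROI
##      series

.qcCriteria <- c("age_lt_18", "incomplete_demographics", "tr_not_2s",
                 "fd_gt_0.2mm", "zero_variance_roi")

#' Quality-control filter for a cohort
#'
#' Applies the automatable exclusion criteria above and returns the
#' retained cohort together with a bookkeeping report. The manual
#' image-quality criterion has no computable definition and is logged as
#' not applied. The bookkeeping identity
#' `nRetained + sum(excluded) == nInput` always holds (each subject counts
#' once, under its first failing criterion).
#'
#' @param cohort a [DmnCohort-class].
#' @param trRequiredS required repetition time in seconds (default 2).
#' @param fdMaxMm maximum allowed mean framewise displacement (default 0.2).
#' @return A list with elements `cohort` (retained [DmnCohort-class]) and
#'   `report`: `nInput`, `nRetained`, `excludedByCriterion` (named counts),
#'   `reasons` (data.frame subject_id/reason), `manualQualityApplied = FALSE`.
#' @export
qcFilter <- function(cohort, trRequiredS = 2, fdMaxMm = 0.2) {
  stopifnot(is(cohort, "DmnCohort"))
  ph <- phenotypes(cohort)
  tsl <- timeSeriesList(cohort)
  n <- nrow(ph)
  reason <- rep(NA_character_, n)
  demo <- c("diagnosis", "age", "sex", "education", "site", "mean_fd")
  for (i in seq_len(n)) {
    ts <- if (length(tsl)) tsl[[ph$subject_id[i]]] else NULL
    tr <- if (!is.null(ts)) trSeconds(ts) else
      if ("tr_s" %in% names(ph)) ph$tr_s[i] else NA_real_
    if (!is.na(ph$age[i]) && ph$age[i] < 18) {
      reason[i] <- "age_lt_18"
    } else if (anyNA(ph[i, demo])) {
      reason[i] <- "incomplete_demographics"
    } else if (!is.na(tr) && tr != trRequiredS) {
      reason[i] <- "tr_not_2s"
    } else if (!is.na(ph$mean_fd[i]) && ph$mean_fd[i] > fdMaxMm) {
      reason[i] <- "fd_gt_0.2mm"
    } else if (!is.null(ts) && any(apply(tsMatrix(ts), 2L, sd) == 0)) {
      reason[i] <- "zero_variance_roi"
    }
  }
  keep <- is.na(reason)
  counts <- vapply(.qcCriteria, function(cr) sum(reason == cr, na.rm = TRUE),
                   integer(1))
  retained <- new("DmnCohort",
                  phenotypes = ph[keep, , drop = FALSE],
                  timeSeries = if (length(tsl)) tsl[ph$subject_id[keep]]
                               else list(),
                  roiSet = roiSet(cohort))
  report <- list(
    nInput = n,
    nRetained = sum(keep),
    excludedByCriterion = counts,
    reasons = data.frame(subject_id = ph$subject_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE),
    manualQualityApplied = FALSE)
  list(cohort = retained, report = report)
}
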