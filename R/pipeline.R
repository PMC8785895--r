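## Orchestration: per-subject metrics, the full analysis report, and the
## sliding-window validation grid.

#' Compute both connectivity outcomes for every subject
#'
#' Deterministic given its inputs. Per-subject failures (e.g. a window plan
#' that does not fit a short scan) are collected, reported via a message,
#' and the subject is dropped from the table; the failures are attached as
#' the `"errors"` attribute.
#'
#' @param cohort a QC-passed [DmnCohort-class] with time series.
#' @param widthS,stepS sliding-window parameters in seconds.
#' @param transform Fisher r-to-z variant?
#' @return A metrics data.frame: the phenotype columns joined with
#'   `fc_strength` and `dfc_variability`.
#' @export
computeAllMetrics <- function(cohort, widthS = 100, stepS = 6,
                              transform = FALSE) {
  stopifnot(is(cohort, "DmnCohort"))
  ph <- phenotypes(cohort)
  tsl <- timeSeriesList(cohort)
  if (!length(tsl)) stop("cohort has no time series")
  rows <- vector("list", nrow(ph))
  for (i in seq_len(nrow(ph))) {
    id <- ph$subject_id[i]
    rows[[i]] <- tryCatch(
      subjectMetrics(tsl[[id]], widthS = widthS, stepS = stepS,
                     transform = transform),
      error = function(e) e)
  }
  ok <- !vapply(rows, inherits, logical(1), what = "condition")
  errs <- vapply(rows[!ok], conditionMessage, character(1))
  names(errs) <- ph$subject_id[!ok]
  if (any(!ok)) {
    message(sum(!ok), " subject(s) dropped during metric computation: ",
            paste(names(errs), collapse = ", "))
  }
  met <- do.call(rbind, rows[ok])
  out <- merge(ph[ok, , drop = FALSE],
               met[, c("subject_id", "fc_strength", "dfc_variability")],
               by = "subject_id", sort = FALSE)
  out <- out[match(ph$subject_id[ok], out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window_width_s") <- widthS
  attr(out, "step_s") <- stepS
  attr(out, "errors") <- errs
  out
}

.groupStats <- function(metrics, outcome) {
  rM <- groupAgeCorrelation(metrics, outcome, "MDD")
  rH <- groupAgeCorrelation(metrics, outcome, "HC")
  nM <- sum(metrics$diagnosis == "MDD")
  nH <- sum(metrics$diagnosis == "HC")
  list(r_mdd = rM, n_mdd = nM, r_hc = rH, n_hc = nH,
       comparison = compareIndependentCorrelations(rM, nM, rH, nH))
}

.clinicalPartials <- function(metrics, outcome) {
  covCols <- c("age", "sex", "education", "site", "mean_fd")
  out <- list()
  for (clin in c("illness_duration", "hamd", "hama")) {
    if (!clin %in% names(metrics)) next
    sub <- metrics[metrics$diagnosis == "MDD" & !is.na(metrics[[clin]]), ,
                   drop = FALSE]
    sub <- sub[stats::complete.cases(sub[, c(outcome, covCols)]), ,
               drop = FALSE]
    if (!nrow(sub)) next
    cm <- data.frame(age = sub$age,
                     sex = as.numeric(sub$sex == "female"),
                     education = sub$education,
                     mean_fd = sub$mean_fd)
    for (s in sort(unique(sub$site))[-1L]) {
      cm[[paste0("site_", s)]] <- as.numeric(sub$site == s)
    }
    ## drop constant covariate columns (e.g. single-site subsets)
    cm <- cm[, vapply(cm, function(v) sd(v) > 0, logical(1)), drop = FALSE]
    if (nrow(sub) <= ncol(cm) + 3L) next
    out[[clin]] <- partialCorrelation(sub[[outcome]], sub[[clin]], cm)
  }
  out
}

.episodicityAncova <- function(metrics, outcome) {
  if (!"episodicity" %in% names(metrics)) return(NULL)
  sub <- metrics[metrics$diagnosis == "MDD" & !is.na(metrics$episodicity), ,
                 drop = FALSE]
  if (length(unique(sub$episodicity)) != 2L || nrow(sub) < 20L) return(NULL)
  ancovaBinary(sub, outcome, "episodicity",
               c("age", "sex", "education", "site", "mean_fd"))
}

#' Run the full analysis
#'
#' Executes the whole pipeline on a cohort: QC filtering, per-subject
#' metrics at the primary window parameters, the diagnosis-by-age
#' interaction regression for both outcomes, within-group age correlations
#' with Fisher r-to-z group comparison, clinical partial correlations and
#' the episodicity ANCOVA (patients only), heteroscedasticity diagnostics
#' with a natural-log refit when significant, and a validation grid of
#' dynamic-FC regressions over all width-by-step combinations. With
#' `outdir` set, all tables plus a plain-text run log are written
#' (deterministic content, byte-identical across reruns).
#'
#' @param cohort a [DmnCohort-class] with time series.
#' @param widthS,stepS primary sliding-window parameters (seconds).
#' @param fisherZ apply Fisher r-to-z inside all FC/dFC matrices
#'   (validation variant)?
#' @param gridWidthsS,gridStepsS window grids for the validation analysis.
#' @param hetAlpha significance level triggering the log refit.
#' @param outdir output directory or `NULL`.
#' @return A list of class `dmnAnalysisReport` with elements `qc`,
#'   `metrics`, `fits`, `ageCorrelations`, `clinical`, `episodicity`,
#'   `heteroscedasticity`, `logRefits`, `grid`, `params`.
#' @export
runAnalysis <- function(cohort, widthS = 100, stepS = 6, fisherZ = FALSE,
                        gridWidthsS = c(80, 100, 120),
                        gridStepsS = c(6, 8, 10),
                        hetAlpha = 0.05, outdir = NULL) {
  qc <- qcFilter(cohort)
  if (!nrow(phenotypes(qc$cohort))) {
    stop("qc stage: no subjects retained")
  }
  metrics <- tryCatch(
    computeAllMetrics(qc$cohort, widthS, stepS, transform = fisherZ),
    error = function(e) stop("metrics stage: ", conditionMessage(e)))

  outcomes <- c("fc_strength", "dfc_variability")
  fits <- lapply(outcomes, function(oc) {
    tryCatch(fitInteractionModel(metrics, oc),
             error = function(e) stop("regression stage (", oc, "): ",
                                      conditionMessage(e)))
  })
  names(fits) <- outcomes

  ageCor <- lapply(outcomes, function(oc) .groupStats(metrics, oc))
  names(ageCor) <- outcomes

  clinical <- lapply(outcomes, function(oc) .clinicalPartials(metrics, oc))
  names(clinical) <- outcomes
  episodicity <- lapply(outcomes, function(oc) .episodicityAncova(metrics, oc))
  names(episodicity) <- outcomes

  het <- lapply(fits, heteroscedasticityCheck)
  logRefits <- list()
  for (oc in outcomes) {
    if (het[[oc]]$p < hetAlpha && all(metrics[[oc]] > 0)) {
      logRefits[[oc]] <- logTransformRefit(metrics, oc)
    }
  }

  grid <- list()
  for (w in gridWidthsS) {
    for (s in gridStepsS) {
      key <- sprintf("w%g_s%g", w, s)
      gm <- tryCatch(
        computeAllMetrics(qc$cohort, w, s, transform = fisherZ),
        error = function(e) stop("validation grid stage (", key, "): ",
                                 conditionMessage(e)))
      grid[[key]] <- fitInteractionModel(gm, "dfc_variability")
    }
  }

  report <- structure(
    list(qc = qc$report, metrics = metrics, fits = fits,
         ageCorrelations = ageCor, clinical = clinical,
         episodicity = episodicity, heteroscedasticity = het,
         logRefits = logRefits, grid = grid,
         params = list(widthS = widthS, stepS = stepS, fisherZ = fisherZ,
                       gridWidthsS = gridWidthsS, gridStepsS = gridStepsS,
                       hetAlpha = hetAlpha)),
    class = "dmnAnalysisReport")
  if (!is.null(outdir)) .writeReport(report, outdir)
  report
}

## Serialize a report to TSV tables plus a deterministic run log.
.writeReport <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeMetrics(report$metrics, file.path(outdir, "metrics.tsv"))
  for (oc in names(report$fits)) {
    writeMetrics(coefTable(report$fits[[oc]]),
                 file.path(outdir, paste0("regression_", oc, ".tsv")))
  }
  cmp <- do.call(rbind, lapply(names(report$ageCorrelations), function(oc) {
    gs <- report$ageCorrelations[[oc]]
    data.frame(outcome = oc, r_mdd = gs$r_mdd, n_mdd = gs$n_mdd,
               r_hc = gs$r_hc, n_hc = gs$n_hc,
               z = gs$comparison$z, p = gs$comparison$p)
  }))
  writeMetrics(cmp, file.path(outdir, "age_correlations.tsv"))
  gridTab <- do.call(rbind, lapply(names(report$grid), function(key) {
    cf <- coefTable(report$grid[[key]])
    cbind(cell = key, cf[cf$term %in%
                           c("diagnosis", "age", "diagnosis_x_age"), ])
  }))
  writeMetrics(gridTab, file.path(outdir, "validation_grid.tsv"))
  qcTab <- data.frame(criterion = names(report$qc$excludedByCriterion),
                      excluded = as.integer(report$qc$excludedByCriterion))
  writeMetrics(qcTab, file.path(outdir, "qc_report.tsv"))
  log <- c("dmnAging run log",
           paste0("package version: ", as.character(packageVersion("dmnAging"))),
           paste0("n input subjects: ", report$qc$nInput),
           paste0("n retained: ", report$qc$nRetained),
           "manual image-quality criterion: not applied (not automatable)",
           paste0("window width (s): ", report$params$widthS),
           paste0("step (s): ", report$params$stepS),
           paste0("fisher r-to-z matrices: ", report$params$fisherZ),
           paste0("grid widths (s): ",
                  paste(report$params$gridWidthsS, collapse = ",")),
           paste0("grid steps (s): ",
                  paste(report$params$gridStepsS, collapse = ",")),
           paste0("log-refit outcomes: ",
                  paste(names(report$logRefits), collapse = ",")))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.dmnAnalysisReport <- function(x, ...) {
  cat("DMN connectivity analysis report\n")
  cat(sprintf("  subjects: %d retained of %d (QC)\n",
              x$qc$nRetained, x$qc$nInput))
  for (oc in names(x$fits)) {
    cf <- coefTable(x$fits[[oc]])
    ia <- cf[cf$term == "diagnosis_x_age", ]
    ag <- cf[cf$term == "age", ]
    cat(sprintf("  %s: age beta = %.3f (t = %.2f, p = %.3g); ",
                oc, ag$beta_std, ag$t, ag$p))
    cat(sprintf("diagnosis x age beta = %.3f (t = %.2f, p = %.3g)\n",
                ia$beta_std, ia$t, ia$p))
  }
  cat(sprintf("  validation grid: %d cells\n", length(x$grid)))
  invisible(x)
}
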