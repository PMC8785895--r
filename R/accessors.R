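## Accessor and show methods.

#' @describeIn RoiSet-class number of regions
#' @param x object
#' @export
setMethod("nRois", "RoiSet", function(x) length(x@labels))

#' @describeIn RoiSet-class region labels
#' @export
setMethod("roiLabels", "RoiSet", function(x) x@labels)

#' @describeIn RoiSet-class MNI coordinate matrix (mm)
#' @export
setMethod("roiCoords", "RoiSet", function(x) x@coords)

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet with", nRois(object), "regions\n")
  cat("  labels:", paste(head(object@labels, 4L), collapse = ", "),
      if (nRois(object) > 4L) "..." else "", "\n")
})

#' @describeIn TimeSeriesMatrix-class subject identifier
#' @param x object
#' @export
setMethod("subjectId", "TimeSeriesMatrix", function(x) x@subjectId)

#' @describeIn TimeSeriesMatrix-class repetition time (s)
#' @export
setMethod("trSeconds", "TimeSeriesMatrix", function(x) x@trS)

#' @describeIn TimeSeriesMatrix-class number of volumes (rows)
#' @export
setMethod("nVolumes", "TimeSeriesMatrix", function(x) nrow(x@data))

#' @describeIn TimeSeriesMatrix-class number of ROIs (columns)
#' @export
setMethod("nRois", "TimeSeriesMatrix", function(x) ncol(x@data))

#' @describeIn TimeSeriesMatrix-class the volumes x ROIs matrix
#' @export
setMethod("tsMatrix", "TimeSeriesMatrix", function(x) x@data)

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat("TimeSeriesMatrix", object@subjectId, ":",
      nVolumes(object), "volumes x", nRois(object), "ROIs, TR =",
      object@trS, "s\n")
})

#' @describeIn FcMatrix-class the correlation matrix
#' @param x object
#' @export
setMethod("fcValues", "FcMatrix", function(x) x@values)

#' @describeIn FcMatrix-class was Fisher r-to-z applied?
#' @export
setMethod("isTransformed", "FcMatrix", function(x) x@transformed)

#' @describeIn FcMatrix-class matrix dimension
#' @export
setMethod("nRois", "FcMatrix", function(x) nrow(x@values))

setMethod("show", "FcMatrix", function(object) {
  cat("FcMatrix", nRois(object), "x", nRois(object),
      if (object@transformed) "(Fisher z)" else "(raw r)", "\n")
})

#' @describeIn WindowSpec-class number of windows T
#' @param x object
#' @export
setMethod("windowCount", "WindowSpec", function(x) length(x@starts))

#' @describeIn WindowSpec-class 0-based window start volumes
#' @export
setMethod("windowStarts", "WindowSpec", function(x) x@starts)

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec: width %gs (%d vol), step %gs (%d vol), T = %d\n",
              object@widthS, object@widthVol, object@stepS, object@stepVol,
              windowCount(object)))
})

#' @describeIn DfcStack-class number of windows
#' @param x object
#' @export
setMethod("windowCount", "DfcStack", function(x) dim(x@values)[3])

#' @describeIn DfcStack-class matrix dimension
#' @export
setMethod("nRois", "DfcStack", function(x) dim(x@values)[1])

#' @describeIn DfcStack-class i-th windowed FC matrix
#' @param i window index (1-based)
#' @export
setMethod("dfcMatrix", "DfcStack", function(x, i) x@values[, , i])

#' @describeIn DfcStack-class was Fisher r-to-z applied?
#' @export
setMethod("isTransformed", "DfcStack", function(x) x@transformed)

setMethod("show", "DfcStack", function(object) {
  cat("DfcStack", object@subjectId, ":", windowCount(object),
      "windows of", nRois(object), "x", nRois(object), "matrices\n")
})

#' @describeIn DmnCohort-class phenotype table
#' @param x object
#' @export
setMethod("phenotypes", "DmnCohort", function(x) x@phenotypes)

#' @describeIn DmnCohort-class named list of per-subject time series
#' @export
setMethod("timeSeriesList", "DmnCohort", function(x) x@timeSeries)

#' @describeIn DmnCohort-class the ROI definition in use
#' @export
setMethod("roiSet", "DmnCohort", function(x) x@roiSet)

setMethod("show", "DmnCohort", function(object) {
  ph <- object@phenotypes
  cat("DmnCohort:", nrow(ph), "subjects")
  if (nrow(ph) && "diagnosis" %in% names(ph)) {
    tb <- table(ph$diagnosis)
    cat(" (", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat(",", length(object@timeSeries), "time series,",
      nRois(object@roiSet), "ROIs\n")
})

#' @describeIn RegressionResult-class coefficient table
#'   (`term`, `b`, `beta_std`, `t`, `p`)
#' @param x object
#' @export
setMethod("coefTable", "RegressionResult", function(x) x@coefficients)

#' @describeIn RegressionResult-class model residuals
#' @param object object
#' @export
setMethod("residuals", "RegressionResult", function(object) object@residuals)

setMethod("show", "RegressionResult", function(object) {
  cat("RegressionResult for", object@outcomeName,
      if (object@logTransformed) "(ln-transformed)" else "",
      "- n =", object@n, "\n")
  cf <- object@coefficients
  main <- cf[cf$term %in% c("diagnosis", "age", "diagnosis_x_age", "sex"), ]
  print(format(main, digits = 4), row.names = FALSE)
})
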