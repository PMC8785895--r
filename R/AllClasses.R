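## S4 classes for the DMN connectivity pipeline.

#' RoiSet: a network region definition
#'
#' Holds the labels and MNI coordinates (mm) of the regions whose pairwise
#' connectivity is analysed. The packaged default has 58 regions, the size of
#' the default-mode-network set used throughout; its coordinates are a
#' synthetic stand-in (see [readRoiSet()]).
#'
#' @slot labels character vector of unique region identifiers.
#' @slot coords numeric matrix with columns `x`, `y`, `z` (MNI mm), one row
#'   per region.
#' @exportClass RoiSet
setClass("RoiSet",
  slots = c(labels = "character", coords = "matrix"))

setValidity("RoiSet", function(object) {
  msg <- character()
  if (length(object@labels) < 2L) {
    msg <- c(msg, "a RoiSet needs at least 2 regions")
  }
  if (anyDuplicated(object@labels)) {
    msg <- c(msg, "region labels must be unique")
  }
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L) {
    msg <- c(msg, "coords must be a numeric matrix with 3 columns (x, y, z)")
  } else {
    if (nrow(object@coords) != length(object@labels)) {
      msg <- c(msg, "coords must have one row per label")
    }
    if (anyNA(object@coords)) msg <- c(msg, "coords must not contain NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RoiSet
#'
#' @param labels character vector of unique region identifiers.
#' @param coords numeric matrix (regions x 3) of MNI coordinates in mm.
#' @return A [RoiSet-class] object.
#' @export
RoiSet <- function(labels, coords) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y", "z")
  new("RoiSet", labels = as.character(labels), coords = coords)
}

#' TimeSeriesMatrix: one subject's ROI signal array
#'
#' A volumes-by-regions real matrix of preprocessed BOLD time courses with
#' its repetition time. Column names carry the ROI labels and are matched to
#' a [RoiSet-class] on read.
#'
#' @slot subjectId character scalar.
#' @slot trS repetition time in seconds (> 0).
#' @slot data numeric matrix, volumes x ROIs, no missing values.
#' @exportClass TimeSeriesMatrix
setClass("TimeSeriesMatrix",
  slots = c(subjectId = "character", trS = "numeric", data = "matrix"))

setValidity("TimeSeriesMatrix", function(object) {
  msg <- character()
  if (length(object@trS) != 1L || !is.finite(object@trS) || object@trS <= 0) {
    msg <- c(msg, "trS must be a single positive number (seconds)")
  }
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (anyNA(object@data)) msg <- c(msg, "data must not contain missing values")
  if (nrow(object@data) < 2L) msg <- c(msg, "need at least 2 volumes")
  if (ncol(object@data) < 2L) msg <- c(msg, "need at least 2 ROIs")
  if (is.null(colnames(object@data))) {
    msg <- c(msg, "data must carry ROI labels as column names")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TimeSeriesMatrix
#'
#' @param subjectId subject identifier.
#' @param data numeric matrix, volumes x ROIs, column names = ROI labels.
#' @param trS repetition time in seconds.
#' @return A [TimeSeriesMatrix-class] object.
#' @export
TimeSeriesMatrix <- function(subjectId, data, trS) {
  new("TimeSeriesMatrix", subjectId = as.character(subjectId),
      trS = as.numeric(trS), data = as.matrix(data))
}

#' FcMatrix: a weighted functional-connectivity adjacency matrix
#'
#' Symmetric matrix of pairwise Pearson correlations between ROI time
#' courses (optionally Fisher r-to-z transformed off the diagonal). The
#' diagonal is excluded from all downstream averages.
#'
#' @slot values numeric n x n matrix.
#' @slot transformed logical; `TRUE` if atanh was applied to off-diagonals.
#' @exportClass FcMatrix
setClass("FcMatrix",
  slots = c(values = "matrix", transformed = "logical"))

setValidity("FcMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (nrow(v) >= 2L && !isTRUE(all.equal(v, t(v), tolerance = 1e-10))) {
    msg <- c(msg, "values must be symmetric")
  }
  off <- v[upper.tri(v)]
  if (!object@transformed && any(is.finite(off) & abs(off) > 1 + 1e-12)) {
    msg <- c(msg, "raw correlations must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' WindowSpec: a sliding-window segmentation plan
#'
#' Converts window width and step from seconds to volumes for a given
#' repetition time and series length. Windows are full (no partial tail
#' window), contiguous in steps of `stepVol`, and use 0-based half-open
#' volume index ranges `[start, start + widthVol)` internally.
#'
#' @slot widthS,stepS,trS window width, step and repetition time in seconds.
#' @slot widthVol,stepVol the same in volumes (exact integers).
#' @slot starts integer vector of 0-based window start volumes.
#' @exportClass WindowSpec
setClass("WindowSpec",
  slots = c(widthS = "numeric", stepS = "numeric", trS = "numeric",
            widthVol = "integer", stepVol = "integer", starts = "integer"))

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (object@widthVol < 2L) msg <- c(msg, "window width must span >= 2 volumes")
  if (object@stepVol < 1L) msg <- c(msg, "step must span >= 1 volume")
  if (length(object@starts) < 2L) {
    msg <- c(msg, "need at least 2 windows for a variability estimate")
  }
  if (is.unsorted(object@starts, strictly = TRUE)) {
    msg <- c(msg, "window starts must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' DfcStack: the ordered windowed-connectivity stack of one subject
#'
#' The sequence of windowed FC matrices produced by [dfcStack()], stored as
#' an `nRois x nRois x T` array in window order.
#'
#' @slot subjectId character scalar.
#' @slot spec the [WindowSpec-class] used.
#' @slot values numeric array, `nRois x nRois x T`.
#' @slot transformed logical; Fisher r-to-z applied to every matrix.
#' @exportClass DfcStack
setClass("DfcStack",
  slots = c(subjectId = "character", spec = "WindowSpec",
            values = "array", transformed = "logical"))

setValidity("DfcStack", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3L || d[1] != d[2]) {
    msg <- c(msg, "values must be an nRois x nRois x T array")
  }
  if (length(d) == 3L && d[3] < 2L) msg <- c(msg, "need T >= 2 windows")
  if (length(d) == 3L && d[3] != length(object@spec@starts)) {
    msg <- c(msg, "window count must match the WindowSpec")
  }
  if (length(msg)) msg else TRUE
})

#' DmnCohort: phenotypes plus time series for a set of subjects
#'
#' @slot phenotypes data.frame with one row per subject (columns
#'   `subject_id`, `diagnosis`, `age`, `sex`, `education`, `site`,
#'   `mean_fd`, optional clinical columns).
#' @slot timeSeries named list of [TimeSeriesMatrix-class], one per subject.
#' @slot roiSet the [RoiSet-class] defining matrix dimensions.
#' @exportClass DmnCohort
setClass("DmnCohort",
  slots = c(phenotypes = "data.frame", timeSeries = "list", roiSet = "RoiSet"))

setValidity("DmnCohort", function(object) {
  msg <- character()
  ids <- object@phenotypes$subject_id
  if (is.null(ids)) {
    msg <- c(msg, "phenotypes must have a subject_id column")
  } else {
    if (anyDuplicated(ids)) msg <- c(msg, "subject_id must be unique")
    if (length(object@timeSeries) &&
        !setequal(names(object@timeSeries), ids)) {
      msg <- c(msg, "timeSeries names must match phenotype subject_id values")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DmnCohort
#'
#' @param phenotypes data.frame of subject records.
#' @param timeSeries named list of [TimeSeriesMatrix-class] objects keyed by
#'   subject id (may be empty for phenotype-only work).
#' @param roiSet a [RoiSet-class]; defaults to the packaged 58-region set.
#' @return A [DmnCohort-class].
#' @export
DmnCohort <- function(phenotypes, timeSeries = list(), roiSet = readRoiSet()) {
  new("DmnCohort", phenotypes = as.data.frame(phenotypes),
      timeSeries = timeSeries, roiSet = roiSet)
}

#' RegressionResult: a fitted diagnosis-by-age interaction model
#'
#' Output of [fitInteractionModel()]: ordinary-least-squares coefficients
#' with standardized betas (b * SD(x) / SD(y)), t statistics, two-tailed
#' p-values, and the residual vector needed for heteroscedasticity checks.
#'
#' @slot coefficients data.frame with columns `term`, `b`, `beta_std`, `t`, `p`.
#' @slot residuals numeric, one per subject (model order).
#' @slot n number of subjects used.
#' @slot outcomeName name of the modelled outcome column.
#' @slot logTransformed `TRUE` when the outcome was natural-log transformed.
#' @slot moderators data.frame of model-frame covariates kept for diagnostics.
#' @exportClass RegressionResult
setClass("RegressionResult",
  slots = c(coefficients = "data.frame", residuals = "numeric", n = "integer",
            outcomeName = "character", logTransformed = "logical",
            moderators = "data.frame"))

setValidity("RegressionResult", function(object) {
  cf <- object@coefficients
  msg <- character()
  need <- c("term", "b", "beta_std", "t", "p")
  if (!all(need %in% names(cf))) {
    msg <- c(msg, "coefficients must have columns term, b, beta_std, t, p")
  } else if (any(cf$p < 0 | cf$p > 1, na.rm = TRUE)) {
    msg <- c(msg, "p-values must lie in [0, 1]")
  }
  if (length(object@residuals) != object@n) {
    msg <- c(msg, "one residual per subject required")
  }
  if (length(msg)) msg else TRUE
})
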