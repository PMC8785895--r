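## Generics for accessors shared across classes.

#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @export
setGeneric("roiCoords", function(x) standardGeneric("roiCoords"))

#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))

#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))

#' @export
setGeneric("isTransformed", function(x) standardGeneric("isTransformed"))

#' @export
setGeneric("windowCount", function(x) standardGeneric("windowCount"))

#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))

#' @export
setGeneric("dfcMatrix", function(x, i) standardGeneric("dfcMatrix"))

#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @export
setGeneric("timeSeriesList", function(x) standardGeneric("timeSeriesList"))

#' @export
setGeneric("roiSet", function(x) standardGeneric("roiSet"))

#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))
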