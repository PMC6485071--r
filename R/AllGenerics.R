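#' @include AllClasses.R
NULL

#' @export
setGeneric("dosage", function(x, ...) standardGeneric("dosage"))

#' @export
setGeneric("sampleGroups", function(x, ...) standardGeneric("sampleGroups"))

#' @export
setGeneric("fstValues", function(x, ...) standardGeneric("fstValues"))

#' @export
setGeneric("pairSummaries", function(x, ...) standardGeneric("pairSummaries"))

#' @export
setGeneric("dValues", function(x, ...) standardGeneric("dValues"))

#' @export
setGeneric("percentiles", function(x, ...) standardGeneric("percentiles"))

#' @export
setGeneric("outlierCalls", function(x, ...) standardGeneric("outlierCalls"))

#' @export
setGeneric("tags", function(x, ...) standardGeneric("tags"))

## `members` reuses the IRanges generic so the accessor dispatches
## correctly when both namespaces are attached
#' @importFrom IRanges members
#' @export members
NULL

#' @export
setGeneric("spans", function(x, ...) standardGeneric("spans"))

#' @export
setGeneric("rates", function(x, ...) standardGeneric("rates"))

#' @export
setGeneric("computeRccr", function(x, ...) standardGeneric("computeRccr"))

#' @export
setGeneric("rccrValues", function(x, ...) standardGeneric("rccrValues"))

#' @export
setGeneric("crossingTimes", function(x, ...) standardGeneric("crossingTimes"))

#' @export
setGeneric("permScores", function(x, ...) standardGeneric("permScores"))

#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))
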