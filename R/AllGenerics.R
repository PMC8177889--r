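#' @export
setGeneric("entryIds", function(x) standardGeneric("entryIds"))

#' @export
setGeneric("activeIds", function(x) standardGeneric("activeIds"))

#' @export
setGeneric("excludedIds", function(x) standardGeneric("excludedIds"))

#' @export
setGeneric("dbMeta", function(x) standardGeneric("dbMeta"))

#' @export
setGeneric("dbProteins", function(x, active = TRUE) standardGeneric("dbProteins"))

#' @export
setGeneric("activityCategories", function(x, active = TRUE)
  standardGeneric("activityCategories"))

#' @export
setGeneric("applyExclusions", function(x, ids) standardGeneric("applyExclusions"))

#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))

#' @export
setGeneric("isKnockout", function(x) standardGeneric("isKnockout"))

#' @export
setGeneric("mate1", function(x) standardGeneric("mate1"))

#' @export
setGeneric("mate2", function(x) standardGeneric("mate2"))

#' @export
setGeneric("qualities1", function(x) standardGeneric("qualities1"))

#' @export
setGeneric("qualities2", function(x) standardGeneric("qualities2"))

#' @export
setGeneric("readTruth", function(x) standardGeneric("readTruth"))
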