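#' @rdname CohortTable-class
#' @param object,x a \linkS4class{CohortTable} (or other object as documented).
#' @export
setGeneric("lx", function(object) standardGeneric("lx"))

#' @rdname CohortTable-class
#' @export
setGeneric("mx", function(object) standardGeneric("mx"))

#' @rdname CohortTable-class
#' @export
setGeneric("ages", function(object) standardGeneric("ages"))

#' @rdname CohortTable-class
#' @export
setGeneric("cohortSize", function(object) standardGeneric("cohortSize"))

#' @rdname DemographyResult-class
#' @param object a \linkS4class{DemographyResult}.
#' @export
setGeneric("intrinsicRate", function(object) standardGeneric("intrinsicRate"))

#' @rdname DemographyResult-class
#' @export
setGeneric("bootstrapReplicates",
           function(object) standardGeneric("bootstrapReplicates"))
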