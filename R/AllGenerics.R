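#' @rdname Cohort-accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname Cohort-accessors
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname Cohort-accessors
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))

#' @rdname Cohort-accessors
#' @export
setGeneric("diagnoses", function(x) standardGeneric("diagnoses"))

#' @rdname Cohort-accessors
#' @export
setGeneric("indexCodes", function(x) standardGeneric("indexCodes"))

#' @rdname ComorbidityNetwork-accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname ComorbidityNetwork-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname ComorbidityNetwork-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname ComorbidityNetwork-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname ComorbidityNetwork-accessors
#' @export
setGeneric("totalEdgeWeight", function(x) standardGeneric("totalEdgeWeight"))

#' @rdname ComorbidityNetwork-accessors
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @rdname CommunityPartition-accessors
#' @export
setGeneric("membershipVector", function(x) standardGeneric("membershipVector"))

#' @rdname CommunityPartition-accessors
#' @export
setGeneric("modularityValue", function(x) standardGeneric("modularityValue"))

#' @rdname CommunityPartition-accessors
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))
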