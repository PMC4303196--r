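#' @name regact-generics
#' @title Accessor generics for regact containers
#' @description Small accessor generics shared by the regact S4 classes:
#'   gene/sample identifiers, channel mode, raw values and result tables.
#'   Concrete methods are documented with their classes.
#' @param x a regact object
#' @keywords internal
NULL

#' @rdname regact-generics
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname regact-generics
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname regact-generics
#' @export
setGeneric("channelMode", function(x) standardGeneric("channelMode"))

#' @rdname regact-generics
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname regact-generics
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname regact-generics
#' @export
setGeneric("signatureSources", function(x) standardGeneric("signatureSources"))

#' @rdname regact-generics
#' @export
setGeneric("iras", function(x) standardGeneric("iras"))

#' @rdname regact-generics
#' @export
setGeneric("activityGroups", function(x) standardGeneric("activityGroups"))

#' @rdname regact-generics
#' @export
setGeneric("activityTable", function(x) standardGeneric("activityTable"))

#' @rdname regact-generics
#' @export
setGeneric("subtypeNames", function(x) standardGeneric("subtypeNames"))

#' @rdname regact-generics
#' @export
setGeneric("centroidValues", function(x) standardGeneric("centroidValues"))

#' @rdname regact-generics
#' @export
setGeneric("coxTable", function(x) standardGeneric("coxTable"))
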