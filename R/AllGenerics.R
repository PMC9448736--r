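#' @title Generics for the cki data model
#' @name cki-generics
#' @description Accessor generics shared by the cki S4 classes.
#' @keywords internal
NULL

#' @rdname cki-generics
#' @param x an object
#' @export
setGeneric("kinases", function(x) standardGeneric("kinases"))

#' @rdname cki-generics
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname cki-generics
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' @rdname cki-generics
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname cki-generics
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname cki-generics
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @rdname cki-generics
#' @export
setGeneric("lpClass", function(x) standardGeneric("lpClass"))

#' @rdname cki-generics
#' @export
setGeneric("designUnits", function(x) standardGeneric("designUnits"))

#' @rdname cki-generics
#' @export
setGeneric("minHits", function(x) standardGeneric("minHits"))

#' @rdname cki-generics
#' @export
setGeneric("channelThresholds", function(x) standardGeneric("channelThresholds"))

#' @rdname cki-generics
#' @export
setGeneric("ckiTable", function(x) standardGeneric("ckiTable"))

#' @rdname cki-generics
#' @export
setGeneric("tsiMatrix", function(x) standardGeneric("tsiMatrix"))

#' @rdname cki-generics
#' @export
setGeneric("tsiTotals", function(x) standardGeneric("tsiTotals"))

#' @rdname cki-generics
#' @export
setGeneric("kniRecords", function(x) standardGeneric("kniRecords"))

#' @rdname cki-generics
#' @export
setGeneric("kniTotals", function(x) standardGeneric("kniTotals"))

#' @rdname cki-generics
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname cki-generics
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
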