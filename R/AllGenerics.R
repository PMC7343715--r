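# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname accessors
#' @export
setGeneric("traitUnit", function(x) standardGeneric("traitUnit"))

#' @rdname accessors
#' @export
setGeneric("variantData", function(x) standardGeneric("variantData"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))

#' @rdname accessors
#' @export
setGeneric("harmonizedData", function(x, retained = TRUE)
  standardGeneric("harmonizedData"))

#' @rdname accessors
#' @export
setGeneric("actionCounts", function(x) standardGeneric("actionCounts"))

#' @rdname accessors
#' @export
setGeneric("instrumentIds", function(x) standardGeneric("instrumentIds"))

#' @rdname accessors
#' @export
setGeneric("fStatistics", function(x) standardGeneric("fStatistics"))

#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname accessors
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' @rdname accessors
#' @export
setGeneric("mrCI", function(x) standardGeneric("mrCI"))

#' @rdname accessors
#' @export
setGeneric("mrPvalue", function(x) standardGeneric("mrPvalue"))

#' @rdname accessors
#' @export
setGeneric("mrNsnp", function(x) standardGeneric("mrNsnp"))

#' @rdname accessors
#' @export
setGeneric("mrOR", function(x) standardGeneric("mrOR"))

#' @rdname accessors
#' @export
setGeneric("mrIntercept", function(x) standardGeneric("mrIntercept"))
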