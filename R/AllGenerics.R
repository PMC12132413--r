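#' @rdname PromoterRegion-class
#' @param object,x an object.
#' @export
setGeneric("promoterId", function(x) standardGeneric("promoterId"))

#' @rdname PromoterRegion-class
#' @export
setGeneric("windowSequence", function(x) standardGeneric("windowSequence"))

#' @rdname VariantLibrary-class
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname VariantLibrary-class
#' @export
setGeneric("variantSequences", function(x) standardGeneric("variantSequences"))

#' @rdname VariantLibrary-class
#' @export
setGeneric("mutationMask", function(x) standardGeneric("mutationMask"))

#' @rdname VariantLibrary-class
#' @export
setGeneric("wildtypeId", function(x) standardGeneric("wildtypeId"))

#' @rdname Footprint-class
#' @export
setGeneric("footprintMi", function(x) standardGeneric("footprintMi"))

#' @rdname Footprint-class
#' @export
setGeneric("footprintCoverage", function(x) standardGeneric("footprintCoverage"))

#' @rdname RegArchitecture-class
#' @export
setGeneric("regSites", function(x) standardGeneric("regSites"))

#' @rdname RegArchitecture-class
#' @export
setGeneric("conditionActivity", function(x) standardGeneric("conditionActivity"))
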