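#' @rdname PromoterRegion-class
#' @export
setMethod("promoterId", "PromoterRegion", function(x) x@promoterId)

#' @rdname VariantLibrary-class
#' @export
setMethod("promoterId", "VariantLibrary", function(x) x@promoterId)

#' @rdname RegArchitecture-class
#' @export
setMethod("promoterId", "RegArchitecture", function(x) x@promoterId)

#' @rdname Footprint-class
#' @export
setMethod("promoterId", "Footprint", function(x) x@promoterId)

#' @rdname PromoterRegion-class
#' @export
setMethod("windowSequence", "PromoterRegion", function(x) x@sequence)

#' @rdname VariantLibrary-class
#' @export
setMethod("variantIds", "VariantLibrary", function(x) x@variantId)

#' @rdname VariantLibrary-class
#' @export
setMethod("variantSequences", "VariantLibrary", function(x)
  setNames(x@sequences, x@variantId))

#' @rdname VariantLibrary-class
#' @export
setMethod("mutationMask", "VariantLibrary", function(x) {
  m <- x@mask
  rownames(m) <- x@variantId
  m
})

#' @rdname VariantLibrary-class
#' @export
setMethod("wildtypeId", "VariantLibrary", function(x) x@wildtypeId)

#' @rdname Footprint-class
#' @export
setMethod("footprintMi", "Footprint", function(x) x@mi)

#' @rdname Footprint-class
#' @export
setMethod("footprintCoverage", "Footprint", function(x) x@coverage)

#' @rdname RegArchitecture-class
#' @export
setMethod("regSites", "RegArchitecture", function(x)
  setNames(x@sites, vapply(x@sites, function(s) s@siteId, character(1))))

#' @rdname RegArchitecture-class
#' @export
setMethod("conditionActivity", "RegArchitecture", function(x)
  x@conditionActivity)

setMethod("length", "VariantLibrary", function(x) length(x@variantId))

setMethod("show", "PromoterRegion", function(object) {
  cat("PromoterRegion", object@promoterId,
      sprintf("(gene %s)", object@gene), "\n")
  cat("  TSS:", object@tss, "strand:", object@strand, "\n")
  cat("  window: -115..+45 (", windowLength(), "bp )\n")
  cat("  sequence:", substr(object@sequence, 1, 24), "...\n")
})

setMethod("show", "VariantLibrary", function(object) {
  cat("VariantLibrary for promoter", object@promoterId, "\n")
  cat(" ", length(object@variantId), "variants of length",
      ncol(object@mask), "bp;", "wild type:", object@wildtypeId, "\n")
  cat("  mean mutated fraction:",
      signif(mean(object@mask), 4), "\n")
})

setMethod("show", "RegSite", function(object) {
  cat(sprintf("RegSite %s [%s] window %d..%d (offsets %+d..%+d), weight %.3g, omega %.3g\n",
              object@siteId, object@kind, object@start, object@end,
              indexToOffset(object@start), indexToOffset(object@end),
              object@weight, object@omega))
})

setMethod("show", "RegArchitecture", function(object) {
  cat("RegArchitecture for promoter", object@promoterId, "\n")
  for (s in object@sites) show(s)
  cat("  conditions:", paste(rownames(object@conditionActivity), collapse = ", "), "\n")
})

setMethod("show", "Footprint", function(object) {
  cat(sprintf("Footprint %s | %s | rep %s: %d positions, peak %.4f bits, mean %.5f bits\n",
              object@promoterId, object@condition, object@replicate,
              length(object@mi), max(object@mi), mean(object@mi)))
})
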