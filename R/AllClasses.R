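#' @import methods
#' @importFrom stats sd cor median quantile dnorm rmultinom rpois rlnorm
#'   rnorm runif rgamma hclust cutree as.dist cophenetic setNames aggregate
#' @importFrom utils adist head
NULL

## ---------------------------------------------------------------------------
## PromoterRegion: a 160-bp TSS-anchored promoter window
## ---------------------------------------------------------------------------

#' PromoterRegion: a TSS-anchored promoter window
#'
#' Holds the 160-base promoter window from 115 bp upstream of the
#' transcription start site to 45 bp downstream, together with the genomic
#' anchor used to extract it. Window positions are labelled
#' \code{-115..-1, +1..+45} (no 0; +1 is the TSS base); minus-strand windows
#' are stored reverse-complemented so the stored sequence always reads in
#' promoter orientation.
#'
#' @slot promoterId single promoter identifier.
#' @slot gene gene name (annotation only).
#' @slot tss 0-based genomic coordinate of the +1 base on the reference.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot sequence 160-character DNA string in promoter orientation.
#'
#' @seealso [extractWindow()], [promoterOffsets()]
#' @export
setClass("PromoterRegion",
  representation(
    promoterId = "character",
    gene = "character",
    tss = "integer",
    strand = "character",
    sequence = "character"
  )
)

setValidity("PromoterRegion", function(object) {
  msg <- character()
  if (length(object@promoterId) != 1L) msg <- c(msg, "promoterId must be length 1")
  if (length(object@sequence) != 1L || nchar(object@sequence) != windowLength())
    msg <- c(msg, sprintf("sequence must be a single %d-base string", windowLength()))
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  if (grepl("[^ACGT]", object@sequence))
    msg <- c(msg, "sequence alphabet must be {A,C,G,T}")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## VariantLibrary: mutagenized variants of one promoter window
## ---------------------------------------------------------------------------

#' VariantLibrary: mutant pool for one promoter
#'
#' The designed variant pool of a single promoter: the wild-type window plus
#' \code{n} random mutants, each with a per-position mutation mask. Exactly
#' one entry (the wild type) has an all-\code{FALSE} mask, and every
#' \code{TRUE} mask cell corresponds to a base differing from wild type.
#'
#' @slot promoterId promoter the library belongs to.
#' @slot variantId character vector of variant identifiers.
#' @slot sequences character vector of variant sequences (same length as the
#'   window).
#' @slot mask logical matrix, variants x positions; \code{TRUE} where mutated.
#' @slot wildtypeId identifier of the wild-type entry.
#'
#' @seealso [mutateVariants()], [assignBarcodes()]
#' @export
setClass("VariantLibrary",
  representation(
    promoterId = "character",
    variantId = "character",
    sequences = "character",
    mask = "matrix",
    wildtypeId = "character"
  )
)

setValidity("VariantLibrary", function(object) {
  msg <- character()
  n <- length(object@variantId)
  if (length(object@sequences) != n) msg <- c(msg, "sequences/variantId length mismatch")
  if (!is.logical(object@mask) || nrow(object@mask) != n)
    msg <- c(msg, "mask must be a logical matrix with one row per variant")
  if (anyDuplicated(object@variantId)) msg <- c(msg, "variant ids must be unique")
  if (!object@wildtypeId %in% object@variantId)
    msg <- c(msg, "wildtypeId must be one of variantId")
  L <- unique(nchar(object@sequences))
  if (length(L) > 1L) msg <- c(msg, "all sequences must share one length")
  if (length(L) == 1L && ncol(object@mask) != L)
    msg <- c(msg, "mask must have one column per position")
  wt <- which(rowSums(object@mask) == 0L)
  if (length(wt) >= 1L) {
    wt_id <- object@variantId[wt]
    if (!object@wildtypeId %in% wt_id)
      msg <- c(msg, "the wild-type entry must have an all-FALSE mask")
  } else {
    msg <- c(msg, "exactly one entry must have an all-FALSE mask")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Thermodynamic model classes
## ---------------------------------------------------------------------------

#' EnergyMatrix: additive nucleotide binding-energy model
#'
#' A 4 x L matrix of per-position binding-energy contributions in units of
#' kT (beta = 1), rows named A, C, G, T, plus a reference-energy offset.
#' Binding energy of a site sequence is the reference energy plus the sum of
#' the matrix entries selected by the sequence (purely additive; no
#' epistasis).
#'
#' @slot epsilon numeric 4 x L matrix, rownames A,C,G,T, entries in kT.
#' @slot referenceEnergy numeric offset in kT.
#'
#' @seealso [energyMatrix()], [siteEnergy()]
#' @export
setClass("EnergyMatrix",
  representation(epsilon = "matrix", referenceEnergy = "numeric")
)

setValidity("EnergyMatrix", function(object) {
  msg <- character()
  if (!is.numeric(object@epsilon) || nrow(object@epsilon) != 4L)
    msg <- c(msg, "epsilon must be a numeric 4 x L matrix")
  if (!identical(rownames(object@epsilon), DNA_BASES))
    msg <- c(msg, "epsilon rownames must be A, C, G, T")
  if (length(object@referenceEnergy) != 1L || !is.finite(object@referenceEnergy))
    msg <- c(msg, "referenceEnergy must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' RegSite: a regulatory binding site in a thermodynamic architecture
#'
#' One binding site (RNA polymerase, activator or repressor) on the promoter
#' window, with its energy matrix, a dimensionless Boltzmann weight (the
#' copy-number factor, absorbing TF concentration over non-specific
#' background), and a cooperativity factor \code{omega} describing
#' stabilization of RNA polymerase by an activator (\code{omega > 1});
#' repressors act by competitive exclusion and have \code{omega == 1}.
#'
#' @slot siteId site identifier.
#' @slot kind \code{"rnap"}, \code{"activator"} or \code{"repressor"}.
#' @slot start,end inclusive window indices (1..160) of the site span.
#' @slot matrix an [EnergyMatrix-class] with one column per site position.
#' @slot weight dimensionless copy-number factor, \eqn{\ge 0}.
#' @slot omega cooperativity with RNA polymerase (> 0; 1 for repressors).
#'
#' @seealso [regSite()], [expressionRate()]
#' @export
setClass("RegSite",
  representation(
    siteId = "character",
    kind = "character",
    start = "integer",
    end = "integer",
    matrix = "EnergyMatrix",
    weight = "numeric",
    omega = "numeric"
  )
)

setValidity("RegSite", function(object) {
  msg <- character()
  if (!object@kind %in% c("rnap", "activator", "repressor"))
    msg <- c(msg, "kind must be rnap, activator or repressor")
  len <- object@end - object@start + 1L
  if (len < 1L) msg <- c(msg, "end must be >= start")
  if (ncol(object@matrix@epsilon) != len)
    msg <- c(msg, "energy matrix width must equal the site length")
  if (object@weight < 0) msg <- c(msg, "weight must be >= 0")
  if (object@omega <= 0) msg <- c(msg, "omega must be > 0")
  if (object@kind == "repressor" && object@omega != 1)
    msg <- c(msg, "repressors must have omega == 1 (competitive exclusion)")
  if (length(msg)) msg else TRUE
})

#' RegArchitecture: planted regulatory architecture of one promoter
#'
#' The simulation ground truth for one promoter: exactly one RNA-polymerase
#' site plus any number of transcription-factor sites, and a per-condition
#' activity map giving the active fraction (allosteric state, in [0,1]) of
#' each site in each growth condition.
#'
#' @slot promoterId promoter identifier.
#' @slot sites list of [RegSite-class] objects.
#' @slot conditionActivity numeric matrix, conditions x sites, entries in
#'   [0,1]; rownames are condition names, colnames are site ids.
#'
#' @seealso [regArchitecture()], [expressionRate()], [simulateCounts()]
#' @export
setClass("RegArchitecture",
  representation(
    promoterId = "character",
    sites = "list",
    conditionActivity = "matrix"
  )
)

setValidity("RegArchitecture", function(object) {
  msg <- character()
  kinds <- vapply(object@sites, function(s) s@kind, character(1))
  if (sum(kinds == "rnap") != 1L)
    msg <- c(msg, "architecture must contain exactly one rnap site")
  ids <- vapply(object@sites, function(s) s@siteId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "site ids must be unique")
  act <- object@conditionActivity
  if (!is.numeric(act)) msg <- c(msg, "conditionActivity must be numeric")
  if (!identical(colnames(act), ids))
    msg <- c(msg, "conditionActivity columns must match site ids (in order)")
  if (is.numeric(act) && length(act) &&
      (min(act) < 0 || max(act) > 1))
    msg <- c(msg, "activities must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Footprint: per-position mutual information
## ---------------------------------------------------------------------------

#' Footprint: per-position mutual-information footprint
#'
#' The information footprint of one promoter in one condition/replicate: at
#' each window position, the mutual information (bits) between the mutation
#' status of the base (wild-type vs mutated) and the expression class of a
#' read (DNA vs RNA), plus the mutant read mass covering the position.
#' For this binary-by-binary channel the mutual information is bounded by
#' 1 bit.
#'
#' @slot promoterId promoter identifier.
#' @slot condition growth-condition label.
#' @slot replicate replicate label.
#' @slot mi numeric vector of mutual information in bits, one per position.
#' @slot coverage numeric vector of mutant read mass per position.
#'
#' @seealso [informationFootprint()], [smoothFootprint()],
#'   [classifyFootprint()]
#' @export
setClass("Footprint",
  representation(
    promoterId = "character",
    condition = "character",
    replicate = "character",
    mi = "numeric",
    coverage = "numeric"
  )
)

setValidity("Footprint", function(object) {
  msg <- character()
  if (length(object@mi) != length(object@coverage))
    msg <- c(msg, "mi and coverage must have equal length")
  if (any(object@mi < -1e-12)) msg <- c(msg, "mutual information must be >= 0")
  if (any(object@mi > 1 + 1e-9))
    msg <- c(msg, "mutual information of a 2x2 channel cannot exceed 1 bit")
  if (length(msg)) msg else TRUE
})
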