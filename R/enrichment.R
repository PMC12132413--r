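## Transcription-factor enrichment from DNA-pulldown mass spectrometry.
##
## Protein abundances from a pulldown with the candidate binding-site bait
## are compared against a control bait carrying no specific site; enrichment
## is the pseudocounted log2 target/control ratio, and candidate binders must
## additionally be abundant (percentile of target abundance), since weakly
## detected proteins give unreliable ratios.

#' Score protein enrichment against the control bait
#'
#' Computes \code{log2((target + psi) / (control + psi))} per protein, plus
#' the percentile rank of each protein's target abundance among all proteins.
#' The default pseudocount is half the smallest nonzero abundance in the
#' table. Proteins missing in one column are treated as 0 and flagged.
#'
#' @param abundance data.frame with columns \code{protein_id}, \code{target},
#'   \code{control}; \code{NA} abundances are treated as 0 and flagged.
#' @param pseudocount ratio-stabilizing pseudocount (default: smallest
#'   nonzero abundance / 2).
#' @return data.frame sorted by descending \code{log2_ratio} with columns
#'   \code{protein_id}, \code{target}, \code{control}, \code{log2_ratio},
#'   \code{abundance_percentile}, \code{flagged_missing}.
#' @examples
#' tab <- data.frame(protein_id = c("a", "b"), target = c(8, 1),
#'                   control = c(1, 1))
#' enrichmentScores(tab, pseudocount = 0)
#' @export
enrichmentScores <- function(abundance, pseudocount = NULL) {
  stopifnot(all(c("protein_id", "target", "control") %in% names(abundance)))
  tgt <- abundance$target; ctl <- abundance$control
  flagged <- is.na(tgt) | is.na(ctl)
  tgt[is.na(tgt)] <- 0; ctl[is.na(ctl)] <- 0
  if (any(tgt < 0) || any(ctl < 0)) stop("abundances must be nonnegative")
  if (is.null(pseudocount)) {
    nz <- c(tgt[tgt > 0], ctl[ctl > 0])
    if (!length(nz)) stop("all abundances are zero")
    pseudocount <- min(nz) / 2
  }
  ratio <- log2((tgt + pseudocount) / (ctl + pseudocount))
  if (any(!is.finite(ratio)))
    stop("non-finite ratio; use a positive pseudocount")
  pct <- 100 * (rank(tgt, ties.method = "average") - 0.5) / length(tgt)
  out <- data.frame(protein_id = abundance$protein_id,
                    target = tgt, control = ctl,
                    log2_ratio = ratio, abundance_percentile = pct,
                    flagged_missing = flagged, stringsAsFactors = FALSE)
  out <- out[order(-out$log2_ratio), ]
  rownames(out) <- NULL
  out
}

#' Call enriched proteins
#'
#' Keeps records with \code{log2_ratio >= ratioFloor} and target-abundance
#' percentile \code{>= percentileFloor}. Proteins passing the ratio floor but
#' failing the abundance criterion (enriched but weakly detected) are
#' reported separately in the \code{below_abundance} attribute.
#'
#' @param records data.frame from [enrichmentScores()].
#' @param ratioFloor minimum log2 enrichment (default 2, i.e. 4-fold).
#' @param percentileFloor minimum target-abundance percentile (default 50,
#'   i.e. above the median of all protein abundances).
#' @return the called subset (ranked), with attribute \code{below_abundance}.
#' @export
callEnriched <- function(records, ratioFloor = 2, percentileFloor = 50) {
  hi_ratio <- records$log2_ratio >= ratioFloor
  abundant <- records$abundance_percentile >= percentileFloor
  out <- records[hi_ratio & abundant, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "below_abundance") <- records[hi_ratio & !abundant, , drop = FALSE]
  out
}

#' Read / write enrichment tables
#'
#' @param path TSV path with columns protein_id, target, control (extra
#'   annotation columns preserved).
#' @return data.frame.
#' @export
readAbundanceTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readAbundanceTable
#' @param records ranked enrichment table.
#' @export
writeEnrichmentTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
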