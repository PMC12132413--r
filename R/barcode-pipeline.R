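## Barcode/variant reconstruction from paired mapping reads.
##
## Reads are grouped by the barcode-side read; pairs (barcode, promoter
## window) seen fewer than minSupport times in total are discarded. The
## retained consensus window is matched to the nearest designed variant.
## Designed variants and reads share one fixed length with substitution-only
## errors, so Hamming distance equals edit distance; utils::adist is the
## fallback when lengths differ.

.charMatrix <- function(seqs) do.call(rbind, strsplit(seqs, "", fixed = TRUE))

## majority base per position over reads supporting one barcode
.consensusSeq <- function(reads) {
  if (length(reads) == 1L) return(reads)
  lens <- nchar(reads)
  if (length(unique(lens)) > 1L) {
    ## keep the modal length only
    keep <- lens == as.integer(names(which.max(table(lens))))
    reads <- reads[keep]
    if (length(reads) == 1L) return(reads)
  }
  m <- .charMatrix(reads)
  cons <- apply(m, 2L, function(col) names(which.max(table(col))))
  paste(cons, collapse = "")
}

.hammingToAll <- function(query, refMat) {
  q <- .seqToChars(query)
  colSums(t(refMat) != q)
}

#' Map barcodes to designed promoter variants
#'
#' Reconstructs the barcode-to-variant map from paired mapping reads. Reads
#' are tallied per barcode; barcodes with read support below
#' \code{minSupport} are discarded. The per-position majority consensus of
#' each retained barcode's variant-side reads is assigned to the nearest
#' designed variant (exact match first, then minimum edit distance). When the
#' pool spans several promoters, the promoter is resolved first by best
#' wild-type match. Consensus sequences farther than \code{maxEditDistance}
#' from every design are retained as novel variants (synthesis errors) when
#' their support reaches \code{novelMinSupport}, and dropped otherwise.
#'
#' @param reads list with \code{variant_read} and \code{barcode_read}
#'   (parallel character vectors), as from [simulateReads()] or
#'   [readReadsFastq()].
#' @param libraries a [VariantLibrary-class] or list of them (one per
#'   promoter).
#' @param minSupport minimum total reads per barcode (default 3).
#' @param maxEditDistance maximum distance to a designed variant.
#' @param novelMinSupport support needed to keep an unmatched consensus as a
#'   novel variant.
#' @return data.frame with columns \code{barcode}, \code{variant_id},
#'   \code{promoter_id}, \code{read_support}, \code{edit_distance},
#'   \code{novel}. Novel variants get ids \code{novel_<k>} and their
#'   consensus sequence in a \code{sequence} attribute column.
#' @export
mapBarcodes <- function(reads, libraries, minSupport = 3L,
                        maxEditDistance = 20L, novelMinSupport = 10L) {
  if (is(libraries, "VariantLibrary")) libraries <- list(libraries)
  stopifnot(all(vapply(libraries, is, logical(1), "VariantLibrary")))
  vr <- reads$variant_read; br <- reads$barcode_read
  stopifnot(length(vr) == length(br))
  ok <- !is.na(vr) & !is.na(br) & nzchar(vr) & nzchar(br) &
    !grepl("[^ACGT]", vr) & !grepl("[^ACGT]", br)
  n_skipped <- sum(!ok)
  vr <- vr[ok]; br <- br[ok]
  empty <- data.frame(barcode = character(), variant_id = character(),
                      promoter_id = character(), read_support = integer(),
                      edit_distance = integer(), novel = logical(),
                      sequence = character(), stringsAsFactors = FALSE)
  attr(empty, "skipped_reads") <- n_skipped
  if (!length(vr)) return(empty)

  support <- table(br)
  keep_bc <- names(support)[support >= minSupport]
  if (!length(keep_bc)) return(empty)

  ## per-library lookup structures
  wt_seqs <- vapply(libraries, function(l)
    variantSequences(l)[[wildtypeId(l)]], character(1))
  lib_ids <- vapply(libraries, promoterId, character(1))
  refMats <- lapply(libraries, function(l) .charMatrix(l@sequences))

  rows <- vector("list", length(keep_bc))
  novel_k <- 0L
  for (i in seq_along(keep_bc)) {
    bc <- keep_bc[i]
    rds <- vr[br == bc]
    cons <- .consensusSeq(rds)
    ## resolve promoter by best wild-type match
    lib_j <- if (length(libraries) == 1L) 1L else {
      d_wt <- vapply(wt_seqs, function(w)
        if (nchar(w) == nchar(cons))
          sum(.seqToChars(w) != .seqToChars(cons))
        else adist(w, cons)[1, 1], numeric(1))
      which.min(d_wt)
    }
    lib <- libraries[[lib_j]]
    hit <- match(cons, lib@sequences)
    if (!is.na(hit)) {
      dist <- 0L; v_idx <- hit
    } else if (nchar(cons) == ncol(refMats[[lib_j]])) {
      d <- .hammingToAll(cons, refMats[[lib_j]])
      v_idx <- which.min(d); dist <- as.integer(d[v_idx])
    } else {
      d <- drop(adist(cons, lib@sequences))
      v_idx <- which.min(d); dist <- as.integer(d[v_idx])
    }
    sup <- as.integer(support[[bc]])
    if (dist <= maxEditDistance) {
      rows[[i]] <- data.frame(
        barcode = bc, variant_id = lib@variantId[v_idx],
        promoter_id = lib_ids[lib_j], read_support = sup,
        edit_distance = dist, novel = FALSE, sequence = cons,
        stringsAsFactors = FALSE)
    } else if (sup >= novelMinSupport) {
      novel_k <- novel_k + 1L
      rows[[i]] <- data.frame(
        barcode = bc, variant_id = sprintf("novel_%03d", novel_k),
        promoter_id = lib_ids[lib_j], read_support = sup,
        edit_distance = dist, novel = TRUE, sequence = cons,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  attr(out, "skipped_reads") <- n_skipped
  out
}

#' Count barcodes in expression sequencing reads
#'
#' Exact-match tally of barcode-side reads per sample against a barcode map;
#' barcodes absent from the map are tallied separately as unmapped.
#'
#' @param samples named list: for each sample, a list with elements
#'   \code{condition}, \code{replicate}, \code{dna} (character vector of
#'   DNA-library barcode reads) and \code{rna} (RNA-library barcode reads).
#' @param mapping barcode map (data.frame with a \code{barcode} column), as
#'   from [mapBarcodes()] or [assignBarcodes()].
#' @return a count-table \code{data.frame} (\code{barcode}, \code{condition},
#'   \code{replicate}, \code{dna_count}, \code{rna_count}) with an
#'   \code{unmapped} attribute (data.frame of unmapped tallies per sample).
#' @export
countBarcodes <- function(samples, mapping) {
  stopifnot(is.list(samples), "barcode" %in% names(mapping))
  known <- unique(mapping$barcode)
  out <- vector("list", length(samples))
  unm <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (is.null(s$condition) || is.null(s$replicate))
      stop("sample sheet mismatch: every sample needs condition and replicate")
    tal <- function(x) table(factor(x[x %in% known], levels = known))
    dna <- tal(s$dna); rna <- tal(s$rna)
    out[[i]] <- data.frame(
      barcode = known, condition = s$condition,
      replicate = as.character(s$replicate),
      dna_count = as.integer(dna), rna_count = as.integer(rna),
      stringsAsFactors = FALSE)
    unm[[i]] <- data.frame(
      condition = s$condition, replicate = as.character(s$replicate),
      unmapped_dna = sum(!s$dna %in% known),
      unmapped_rna = sum(!s$rna %in% known),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "unmapped") <- do.call(rbind, unm)
  res
}

#' Aggregate barcode counts to variant counts
#'
#' Sums DNA and RNA counts over each variant's retained barcodes per
#' condition and replicate, and records the number of contributing barcodes.
#' Variants whose barcodes were all filtered appear with zero counts and
#' \code{n_barcodes = 0}.
#'
#' @param countTable count table (\code{barcode}, \code{condition},
#'   \code{replicate}, \code{dna_count}, \code{rna_count}).
#' @param mapping barcode map with \code{barcode}, \code{variant_id},
#'   \code{promoter_id}.
#' @param allVariants optional character vector of variant ids that must
#'   appear in the output even with no retained barcode.
#' @return data.frame with columns \code{promoter_id}, \code{variant_id},
#'   \code{condition}, \code{replicate}, \code{dna_count}, \code{rna_count},
#'   \code{n_barcodes}, plus attribute \code{median_barcodes_per_variant}.
#' @export
aggregateVariantCounts <- function(countTable, mapping, allVariants = NULL) {
  m <- merge(countTable, mapping[, c("barcode", "variant_id", "promoter_id")],
             by = "barcode")
  agg <- aggregate(cbind(dna_count, rna_count) ~
                     promoter_id + variant_id + condition + replicate,
                   data = m, FUN = sum)
  nb <- aggregate(barcode ~ promoter_id + variant_id + condition + replicate,
                  data = m, FUN = function(x) length(unique(x)))
  names(nb)[names(nb) == "barcode"] <- "n_barcodes"
  out <- merge(agg, nb,
               by = c("promoter_id", "variant_id", "condition", "replicate"))
  if (!is.null(allVariants)) {
    combos <- unique(countTable[, c("condition", "replicate")])
    missing <- setdiff(allVariants, unique(out$variant_id))
    if (length(missing) && nrow(combos)) {
      pad <- merge(
        data.frame(variant_id = missing, stringsAsFactors = FALSE), combos)
      pad$promoter_id <- if (nrow(out)) out$promoter_id[1L] else NA_character_
      pad$dna_count <- 0L; pad$rna_count <- 0L; pad$n_barcodes <- 0L
      out <- rbind(out, pad[, names(out)])
    }
  }
  out <- out[order(out$condition, out$replicate, out$variant_id), ]
  rownames(out) <- NULL
  per_var <- unique(out[, c("variant_id", "condition", "replicate", "n_barcodes")])
  attr(out, "median_barcodes_per_variant") <-
    median(per_var$n_barcodes[per_var$n_barcodes > 0])
  out
}
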