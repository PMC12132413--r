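#' Design configuration for a mutant promoter pool
#'
#' Parameters of the mutagenesis design: every position of the 160-bp window
#' is mutated independently with probability \code{mutationRate} (substituting
#' one of the three alternative bases uniformly), \code{nVariants} mutants are
#' synthesized per promoter, and each variant receives randomized barcodes of
#' \code{barcodeLength} bases.
#'
#' @param mutationRate per-position substitution probability (default 0.1).
#' @param nVariants number of mutants per promoter (default 1500; the wild
#'   type is added on top of these).
#' @param barcodeLength barcode length in bases (default 20).
#' @param minBarcodesPerVariant minimum barcodes a variant must receive.
#' @return a list of class \code{"DesignConfig"}.
#' @examples
#' designConfig()
#' @export
designConfig <- function(mutationRate = 0.1, nVariants = 1500L,
                         barcodeLength = 20L, minBarcodesPerVariant = 1L) {
  stopifnot(mutationRate >= 0, mutationRate <= 1,
            nVariants >= 1, barcodeLength >= 1, minBarcodesPerVariant >= 1)
  structure(
    list(mutationRate = mutationRate,
         nVariants = as.integer(nVariants),
         barcodeLength = as.integer(barcodeLength),
         minBarcodesPerVariant = as.integer(minBarcodesPerVariant)),
    class = "DesignConfig")
}

#' Extract a TSS-anchored promoter window from a reference sequence
#'
#' Takes the 160-bp region from 115 bp upstream of the transcription start
#' site to 45 bp downstream of it. For minus-strand promoters, upstream lies
#' on the higher-coordinate side of the reference, so the genomic span
#' \code{[tss - 45, tss + 115]} is taken and reverse-complemented; the stored
#' sequence always reads in promoter orientation with position +1 at the TSS
#' base.
#'
#' @param reference reference DNA as a single character string or a
#'   \linkS4class{DNAString}.
#' @param tss 0-based coordinate of the TSS (+1) base on the reference.
#' @param strand \code{"+"} or \code{"-"}.
#' @param promoterId,gene identifiers carried into the result.
#' @return a [PromoterRegion-class].
#' @examples
#' ref <- paste(sample(c("A","C","G","T"), 1000, replace = TRUE), collapse = "")
#' extractWindow(ref, tss = 500L, strand = "+", promoterId = "p1", gene = "g1")
#' @export
extractWindow <- function(reference, tss, strand = "+",
                          promoterId = "promoter", gene = NA_character_) {
  reference <- as.character(reference)
  .checkDna(reference, "reference")
  tss <- as.integer(tss)
  stopifnot(strand %in% c("+", "-"))
  n <- nchar(reference)
  up <- windowUpstream(); down <- windowDownstream()
  if (strand == "+") {
    start0 <- tss - up          # 0-based inclusive
    end0 <- tss + down          # 0-based exclusive
  } else {
    start0 <- tss - down + 1L
    end0 <- tss + up + 1L
  }
  if (start0 < 0L || end0 > n)
    stop(sprintf(
      "window [%d, %d) for tss=%d (%s) exceeds reference bounds [0, %d)",
      start0, end0, tss, strand, n))
  seq <- substr(reference, start0 + 1L, end0)
  if (strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  new("PromoterRegion", promoterId = promoterId, gene = gene,
      tss = tss, strand = strand, sequence = seq)
}

.seqToChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Mutagenize a promoter window into a variant library
#'
#' Generates \code{nVariants} random mutants of the window: every position is
#' mutated independently with probability \code{mutationRate}, and a mutated
#' position receives one of the three non-wild-type bases uniformly at
#' random. The wild-type sequence is included once as an additional entry, so
#' the library holds \code{nVariants + 1} sequences. Insertions and deletions
#' are never generated.
#'
#' @param region a [PromoterRegion-class].
#' @param config a [designConfig()] list.
#' @param seed integer seed making the library reproducible.
#' @return a [VariantLibrary-class].
#' @examples
#' ref <- paste(rep("ACGT", 250), collapse = "")
#' reg <- extractWindow(ref, 500L, "+", "p1")
#' lib <- mutateVariants(reg, designConfig(nVariants = 10), seed = 1)
#' mean(mutationMask(lib))
#' @export
mutateVariants <- function(region, config = designConfig(), seed = 1L) {
  stopifnot(is(region, "PromoterRegion"))
  wt <- .seqToChars(region@sequence)
  L <- length(wt)
  if (L == 0L) stop("empty promoter region")
  n <- config$nVariants
  set.seed(as.integer(seed))
  mask <- matrix(runif(n * L) < config$mutationRate, nrow = n, ncol = L)
  seqs <- matrix(rep(wt, each = n), nrow = n, ncol = L)
  idx <- which(mask)
  if (length(idx)) {
    ## uniform draw over the 3 alternatives to the wild-type base
    seqs[idx] <- .ALT_BASES[cbind(match(seqs[idx], DNA_BASES),
                                  sample.int(3L, length(idx), replace = TRUE))]
  }
  sequences <- c(region@sequence, apply(seqs, 1L, paste, collapse = ""))
  ids <- c(paste0(region@promoterId, "_wt"),
           sprintf("%s_v%04d", region@promoterId, seq_len(n)))
  full_mask <- rbind(rep(FALSE, L), mask)
  new("VariantLibrary", promoterId = region@promoterId,
      variantId = ids, sequences = sequences, mask = full_mask,
      wildtypeId = ids[1L])
}

.randomBarcodes <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Assign randomized barcodes to library variants
#'
#' Draws random DNA barcodes of \code{config$barcodeLength} bases, unique
#' across the pool (collisions are resolved by redrawing), and assigns
#' \code{perVariant[i]} of them to variant \code{i}.
#'
#' @param library a [VariantLibrary-class].
#' @param perVariant integer: barcodes per variant, either a single count or
#'   one count per variant (each \eqn{\ge 1}).
#' @param config a [designConfig()] list (supplies the barcode length).
#' @param seed integer seed.
#' @param existing optional character vector of barcodes already in use
#'   elsewhere in the pool, kept disjoint from the new draws.
#' @return a \code{data.frame} with columns \code{barcode}, \code{variant_id},
#'   \code{promoter_id}.
#' @export
assignBarcodes <- function(library, perVariant = 3L, config = designConfig(),
                           seed = 1L, existing = character()) {
  stopifnot(is(library, "VariantLibrary"))
  n <- length(library)
  if (length(perVariant) == 1L) perVariant <- rep(as.integer(perVariant), n)
  stopifnot(length(perVariant) == n, all(perVariant >= 1L))
  total <- sum(perVariant)
  len <- config$barcodeLength
  capacity <- 4^len
  if (total + length(existing) > capacity)
    stop(sprintf("cannot draw %d unique barcodes of length %d (capacity %.0f)",
                 total + length(existing), len, capacity))
  set.seed(as.integer(seed))
  bc <- character(0)
  need <- total
  while (need > 0L) {
    draw <- .randomBarcodes(need, len)
    bc <- unique(c(bc, setdiff(draw, existing)))
    need <- total - length(bc)
  }
  data.frame(
    barcode = bc,
    variant_id = rep(library@variantId, times = perVariant),
    promoter_id = library@promoterId,
    stringsAsFactors = FALSE)
}

#' Design the full mutagenized promoter pool
#'
#' Builds a variant library for every promoter and assembles the pool
#' manifest. The pool holds exactly \code{n_promoters * (nVariants + 1)}
#' entries (each promoter contributes its wild type plus \code{nVariants}
#' mutants).
#'
#' @param promoters list of [PromoterRegion-class] objects with unique ids.
#' @param config a [designConfig()] list.
#' @param seed integer seed; each promoter library is derived from it
#'   deterministically.
#' @param flank5,flank3 optional constant flanks (cloning sites and primer
#'   pads) prepended/appended in the manifest \code{oligo} column; they carry
#'   no analytic role.
#' @return a list with elements \code{manifest} (data.frame: promoter_id,
#'   variant_id, sequence, and oligo when flanks are given) and
#'   \code{libraries} (named list of [VariantLibrary-class]).
#' @examples
#' ref <- paste(rep("ACGT", 250), collapse = "")
#' regs <- list(extractWindow(ref, 400L, "+", "pA"),
#'              extractWindow(ref, 700L, "+", "pB"))
#' pool <- designPool(regs, designConfig(nVariants = 5), seed = 1)
#' nrow(pool$manifest)  # 2 * (5 + 1)
#' @export
designPool <- function(promoters, config = designConfig(), seed = 1L,
                       flank5 = NULL, flank3 = NULL) {
  ids <- vapply(promoters, promoterId, character(1))
  if (anyDuplicated(ids)) stop("duplicate promoter ids in the pool design")
  libs <- vector("list", length(promoters))
  names(libs) <- ids
  rows <- vector("list", length(promoters))
  for (i in seq_along(promoters)) {
    libs[[i]] <- mutateVariants(promoters[[i]], config,
                                seed = as.integer(seed) + i - 1L)
    rows[[i]] <- data.frame(
      promoter_id = ids[i],
      variant_id = libs[[i]]@variantId,
      sequence = libs[[i]]@sequences,
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(promoter_id = character(), variant_id = character(),
               sequence = character(), stringsAsFactors = FALSE)
  if (!is.null(flank5) || !is.null(flank3))
    manifest$oligo <- paste0(if (is.null(flank5)) "" else flank5,
                             manifest$sequence,
                             if (is.null(flank3)) "" else flank3)
  rownames(manifest) <- NULL
  list(manifest = manifest, libraries = libs)
}

#' Read a promoter table and extract all windows
#'
#' @param promoterFile TSV with columns promoter_id, gene, tss, strand.
#' @param referenceFile FASTA with the reference sequence (first record used
#'   unless the table has a \code{seqname} column naming records).
#' @return list of [PromoterRegion-class].
#' @export
readPromoters <- function(promoterFile, referenceFile) {
  tab <- utils::read.delim(promoterFile, stringsAsFactors = FALSE)
  stopifnot(all(c("promoter_id", "tss", "strand") %in% names(tab)))
  refs <- Biostrings::readDNAStringSet(referenceFile)
  lapply(seq_len(nrow(tab)), function(i) {
    ref <- if ("seqname" %in% names(tab))
      refs[[tab$seqname[i]]] else refs[[1L]]
    extractWindow(as.character(ref), tab$tss[i], tab$strand[i],
                  promoterId = tab$promoter_id[i],
                  gene = if ("gene" %in% names(tab)) tab$gene[i] else NA_character_)
  })
}

#' Write pool design artifacts
#'
#' Writes the pool FASTA (one record per variant), the barcode map TSV and
#' the manifest TSV.
#'
#' @param pool result of [designPool()].
#' @param barcodeMap data.frame from [assignBarcodes()] (rows for all
#'   promoters combined).
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writePoolFiles <- function(pool, barcodeMap, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "pool.fasta")
  seqs <- Biostrings::DNAStringSet(pool$manifest$sequence)
  names(seqs) <- pool$manifest$variant_id
  Biostrings::writeXStringSet(seqs, fa)
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(pool$manifest, man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bm <- file.path(dir, "barcode_map.tsv")
  utils::write.table(barcodeMap, bm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, manifest = man, barcode_map = bm))
}
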