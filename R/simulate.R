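#' Default planted regulatory architecture
#'
#' A ground-truth architecture for simulations, mirroring a classic
#' inducible promoter: an RNA-polymerase site spanning -40..-1, an activator
#' at -75..-55 that is active only in the conditions named in
#' \code{activeIn}, and optionally a repressor at +1..+15 active everywhere.
#' Energy matrices are gauged so the wild-type sequence is the consensus
#' (mismatches cost \code{mismatchPenalty} kT), so mutations in a site window
#' weaken binding.
#'
#' @param region a [PromoterRegion-class]; site consensus sequences are taken
#'   from its wild-type window.
#' @param conditions character vector of condition names.
#' @param activeIn conditions in which the activator is active (subset of
#'   \code{conditions}).
#' @param withRepressor include the +1..+15 repressor site.
#' @param rnapWeight,activatorWeight,repressorWeight copy-number factors.
#' @param activatorOmega cooperativity of the activator with RNAP.
#' @param mismatchPenalty kT per mismatched base in each site.
#' @return a [RegArchitecture-class].
#' @examples
#' ref <- paste(rep("ACGT", 250), collapse = "")
#' reg <- extractWindow(ref, 500L, "+", "p1")
#' exampleArchitecture(reg, conditions = c("glucose", "arabinose"),
#'                     activeIn = "arabinose")
#' @export
exampleArchitecture <- function(region,
                                conditions = c("condA", "condB"),
                                activeIn = conditions[1L],
                                withRepressor = TRUE,
                                rnapWeight = 0.5,
                                activatorWeight = 2,
                                repressorWeight = 10,
                                activatorOmega = 15,
                                mismatchPenalty = 2) {
  stopifnot(is(region, "PromoterRegion"), all(activeIn %in% conditions))
  wt <- windowSequence(region)
  span <- function(from, to) substr(wt, offsetToIndex(from), offsetToIndex(to))
  sites <- list(
    regSite("rnap", "rnap", -40L, -1L,
            consensusEnergyMatrix(span(-40L, -1L), mismatchPenalty / 4),
            weight = rnapWeight),
    regSite("activator", "activator", -75L, -55L,
            consensusEnergyMatrix(span(-75L, -55L), mismatchPenalty),
            weight = activatorWeight, omega = activatorOmega))
  if (withRepressor)
    sites <- c(sites, list(
      regSite("repressor", "repressor", 1L, 15L,
              consensusEnergyMatrix(span(1L, 15L), mismatchPenalty),
              weight = repressorWeight)))
  act <- matrix(1, nrow = length(conditions), ncol = length(sites),
                dimnames = list(conditions,
                                vapply(sites, function(s) s@siteId, character(1))))
  act[, "activator"] <- as.numeric(conditions %in% activeIn)
  regArchitecture(promoterId(region), sites, act)
}

#' Null architecture (RNAP only)
#'
#' An architecture with a single constitutive RNA-polymerase site carrying a
#' flat (all-zero) energy matrix, so every variant expresses identically;
#' used to calibrate the footprint classifier and measure false-positive site
#' calls.
#'
#' @inheritParams exampleArchitecture
#' @param rnapWeight RNAP copy-number factor.
#' @return a [RegArchitecture-class].
#' @export
nullArchitecture <- function(region, conditions = "condA", rnapWeight = 0.5) {
  L <- offsetToIndex(-1L) - offsetToIndex(-40L) + 1L
  sites <- list(regSite("rnap", "rnap", -40L, -1L,
                        energyMatrix(matrix(0, 4L, L)), weight = rnapWeight))
  act <- matrix(1, length(conditions), 1L,
                dimnames = list(conditions, "rnap"))
  regArchitecture(promoterId(region), sites, act)
}

#' Draw per-variant barcode multiplicities
#'
#' Poisson draws shifted so the realized median equals
#' \code{medianBarcodes} (matching the reported barcode multiplicities of
#' genome-integrated libraries), then floored at \code{minimum}.
#'
#' @param n number of variants.
#' @param medianBarcodes target median multiplicity (default 13).
#' @param minimum floor per variant.
#' @param seed integer seed.
#' @return integer vector of length \code{n}.
#' @export
drawBarcodeMultiplicity <- function(n, medianBarcodes = 13, minimum = 1L,
                                    seed = 1L) {
  set.seed(as.integer(seed))
  draws <- rpois(n, medianBarcodes)
  draws <- draws + as.integer(round(medianBarcodes - median(draws)))
  pmax(as.integer(minimum), draws)
}

#' Simulate DNA/RNA barcode count tables
#'
#' Generates sequencing counts for every barcode in every condition and
#' replicate. Barcode abundances in the cell pool are the designed uniform
#' abundances perturbed by mild lognormal jitter (one draw per barcode; the
#' pool is a single physical library shared by all samples). DNA counts are
#' multinomial over barcodes with probabilities proportional to abundance;
#' RNA counts are multinomial with probabilities proportional to abundance
#' times the variant's thermodynamic expression rate in that condition.
#' Optional Dirichlet overdispersion multiplies each sample's probabilities
#' by Gamma noise with concentration \code{overdispersion} (smaller = noisier;
#' \code{Inf} disables it, the default).
#'
#' @param library a [VariantLibrary-class].
#' @param barcodeMap data.frame from [assignBarcodes()].
#' @param arch a [RegArchitecture-class] for the same promoter.
#' @param conditions conditions to simulate (default: all rows of the
#'   activity map).
#' @param depthDna,depthRna total reads per sample.
#' @param replicates replicates per condition.
#' @param seed integer seed (all draws flow from one stream, so equal seeds
#'   give identical tables).
#' @param abundanceSdlog sdlog of the lognormal abundance jitter.
#' @param overdispersion Dirichlet concentration (default \code{Inf}: pure
#'   multinomial).
#' @return a \code{data.frame} count table with columns \code{barcode},
#'   \code{condition}, \code{replicate}, \code{dna_count}, \code{rna_count}.
#' @export
simulateCounts <- function(library, barcodeMap, arch,
                           conditions = rownames(conditionActivity(arch)),
                           depthDna = 1e6, depthRna = 1e6,
                           replicates = 2L, seed = 1L,
                           abundanceSdlog = 0.25,
                           overdispersion = Inf) {
  stopifnot(is(library, "VariantLibrary"), is(arch, "RegArchitecture"),
            depthDna > 0, depthRna > 0)
  if (!all(variantIds(library) %in% barcodeMap$variant_id))
    stop("every variant must carry at least one barcode")
  set.seed(as.integer(seed))
  nb <- nrow(barcodeMap)
  abundance <- rlnorm(nb, 0, abundanceSdlog)
  seqs <- variantSequences(library)[barcodeMap$variant_id]
  out <- vector("list", length(conditions) * replicates)
  k <- 0L
  for (cond in conditions) {
    rate <- expressionRate(unname(seqs), arch, cond)
    p_dna <- abundance / sum(abundance)
    w_rna <- abundance * rate
    if (sum(w_rna) <= 0) stop("zero total RNA probability")
    p_rna <- w_rna / sum(w_rna)
    for (rep_i in seq_len(replicates)) {
      pd <- p_dna; pr <- p_rna
      if (is.finite(overdispersion)) {
        pd <- pd * rgamma(nb, shape = overdispersion, rate = overdispersion)
        pr <- pr * rgamma(nb, shape = overdispersion, rate = overdispersion)
        pd <- pd / sum(pd); pr <- pr / sum(pr)
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        barcode = barcodeMap$barcode,
        condition = cond,
        replicate = as.character(rep_i),
        dna_count = as.integer(rmultinom(1L, as.integer(depthDna), pd)),
        rna_count = as.integer(rmultinom(1L, as.integer(depthRna), pr)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.mutateReads <- function(seqs, errorRate) {
  if (errorRate <= 0) return(seqs)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  hit <- which(matrix(runif(length(mat)) < errorRate, nrow(mat)))
  if (length(hit)) {
    mat[hit] <- .ALT_BASES[cbind(match(mat[hit], DNA_BASES),
                                 sample.int(3L, length(hit), replace = TRUE))]
  }
  apply(mat, 1L, paste, collapse = "")
}

#' Simulate paired mapping reads
#'
#' Emits paired read records for barcode-to-variant mapping: read 1 covers
#' the variant window, read 2 the barcode, each with independent per-base
#' substitution errors at \code{errorRate}. Reads are drawn uniformly over
#' barcodes, \code{nReads} pairs in total.
#'
#' @param library a [VariantLibrary-class].
#' @param barcodeMap data.frame from [assignBarcodes()].
#' @param nReads number of read pairs.
#' @param errorRate per-base substitution probability in [0, 1).
#' @param seed integer seed.
#' @return list with character vectors \code{variant_read} and
#'   \code{barcode_read} (parallel, length \code{nReads}).
#' @export
simulateReads <- function(library, barcodeMap, nReads, errorRate = 0.005,
                          seed = 1L) {
  stopifnot(errorRate >= 0, errorRate < 1)
  set.seed(as.integer(seed))
  nReads <- as.integer(nReads)
  if (nReads == 0L)
    return(list(variant_read = character(), barcode_read = character()))
  idx <- sample.int(nrow(barcodeMap), nReads, replace = TRUE)
  seqs <- variantSequences(library)[barcodeMap$variant_id[idx]]
  list(variant_read = .mutateReads(unname(seqs), errorRate),
       barcode_read = .mutateReads(barcodeMap$barcode[idx], errorRate))
}

#' Write paired reads as FASTQ files
#'
#' @param reads list from [simulateReads()].
#' @param prefix output path prefix; writes \code{<prefix>_R1.fastq} (variant
#'   side) and \code{<prefix>_R2.fastq} (barcode side).
#' @return invisibly, the two paths.
#' @export
writeReadsFastq <- function(reads, prefix) {
  write_one <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- sprintf("read%06d", seq_along(seqs))
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  }
  p1 <- paste0(prefix, "_R1.fastq"); p2 <- paste0(prefix, "_R2.fastq")
  if (length(reads$variant_read)) {
    write_one(reads$variant_read, p1)
    write_one(reads$barcode_read, p2)
  } else {
    file.create(p1, p2)
  }
  invisible(c(R1 = p1, R2 = p2))
}

#' Read paired FASTQ mapping reads
#'
#' @param r1,r2 FASTQ paths (variant side, barcode side).
#' @return list with \code{variant_read} and \code{barcode_read}.
#' @export
readReadsFastq <- function(r1, r2) {
  rd <- function(p) {
    if (file.size(p) == 0) return(character())
    as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
  }
  list(variant_read = unname(rd(r1)), barcode_read = unname(rd(r2)))
}

#' Simulate a DNA-pulldown protein abundance table
#'
#' Null proteins have lognormal abundances identical in target and control
#' pulldowns up to lognormal measurement noise; each planted binder's target
#' abundance is multiplied by \code{plantedFold}. Planted binders are drawn
#' from the upper half of the abundance distribution unless
#' \code{plantedAbundanceQuantile} says otherwise.
#'
#' @param nProteins number of proteins.
#' @param plantedBinders number of true binders.
#' @param plantedFold fold enrichment of binders in the target pulldown.
#' @param noiseSdlog sdlog of the per-column measurement noise.
#' @param plantedAbundanceQuantile lower quantile bound for binder abundance.
#' @param seed integer seed.
#' @return data.frame with columns \code{protein_id}, \code{target},
#'   \code{control}, \code{is_planted}.
#' @export
simulatePulldown <- function(nProteins = 2000L, plantedBinders = 1L,
                             plantedFold = 16, noiseSdlog = 0.3,
                             plantedAbundanceQuantile = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  base <- rlnorm(nProteins, meanlog = 4, sdlog = 1)
  planted <- rep(FALSE, nProteins)
  if (plantedBinders > 0L) {
    eligible <- which(base >= quantile(base, plantedAbundanceQuantile))
    planted[sample(eligible, plantedBinders)] <- TRUE
  }
  target <- base * rlnorm(nProteins, 0, noiseSdlog)
  target[planted] <- target[planted] * plantedFold
  control <- base * rlnorm(nProteins, 0, noiseSdlog)
  data.frame(protein_id = sprintf("prot%04d", seq_len(nProteins)),
             target = target, control = control, is_planted = planted,
             stringsAsFactors = FALSE)
}

#' Ground-truth site table of an architecture
#'
#' BED-like table of planted sites in promoter-relative coordinates, for
#' scoring site calls against simulation truth.
#'
#' @param arch a [RegArchitecture-class].
#' @return data.frame with columns \code{site_id}, \code{kind},
#'   \code{start}, \code{end} (1-based window indices, inclusive),
#'   \code{offset_start}, \code{offset_end}.
#' @export
groundTruthSites <- function(arch) {
  sites <- regSites(arch)
  data.frame(
    site_id = names(sites),
    kind = vapply(sites, function(s) s@kind, character(1)),
    start = vapply(sites, function(s) s@start, integer(1)),
    end = vapply(sites, function(s) s@end, integer(1)),
    offset_start = vapply(sites, function(s) indexToOffset(s@start), integer(1)),
    offset_end = vapply(sites, function(s) indexToOffset(s@end), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
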