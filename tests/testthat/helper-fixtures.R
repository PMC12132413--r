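# Shared fixtures, built in code.

randomReference <- function(n = 2000L, seed = 99L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

testRegion <- function(seed = 99L, id = "pTest", strand = "+") {
  extractWindow(randomReference(seed = seed), tss = 500L, strand = strand,
                promoterId = id, gene = "geneTest")
}

## a small library + barcode map for pipeline-level tests
smallLibrary <- function(nVariants = 30L, perVariant = 3L, seed = 5L,
                         region = testRegion()) {
  cfg <- designConfig(nVariants = nVariants)
  lib <- mutateVariants(region, cfg, seed = seed)
  bm <- assignBarcodes(lib, perVariant, cfg, seed = seed + 1L)
  list(region = region, config = cfg, lib = lib, bm = bm)
}

## hand-built two-variant library: wild type plus one variant mutated at
## chosen positions; lets tests pin exact 2x2 tables per position
twoVariantLibrary <- function(mutatedAt, L = windowLength(), region = testRegion()) {
  wt <- windowSequence(region)
  chars <- strsplit(wt, "")[[1]]
  mut <- chars
  for (p in mutatedAt) mut[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  mask <- rbind(rep(FALSE, L), seq_len(L) %in% mutatedAt)
  new("VariantLibrary", promoterId = "pTest",
      variantId = c("wt", "mut"),
      sequences = c(wt, paste(mut, collapse = "")),
      mask = mask, wildtypeId = "wt")
}

variantCountRows <- function(ids, dna, rna, condition = "c1", replicate = "1") {
  data.frame(promoter_id = "pTest", variant_id = ids,
             condition = condition, replicate = replicate,
             dna_count = dna, rna_count = rna,
             n_barcodes = 1L, stringsAsFactors = FALSE)
}

## interval Jaccard between calls and planted truth over the window
intervalJaccard <- function(calls, truth, L = windowLength()) {
  called <- rep(FALSE, L); planted <- rep(FALSE, L)
  for (i in seq_len(nrow(calls))) called[calls$start[i]:calls$end[i]] <- TRUE
  for (i in seq_len(nrow(truth))) planted[truth$start[i]:truth$end[i]] <- TRUE
  if (!any(called | planted)) return(NA_real_)
  sum(called & planted) / sum(called | planted)
}

## plug-in 2x2 mutual information, written independently of the package path
miOracle <- function(n) {
  N <- sum(n); p <- n / N
  rs <- rowSums(p); cs <- colSums(p)
  tot <- 0
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0) tot <- tot + p[i, j] * log2(p[i, j] / (rs[i] * cs[j]))
  }
  tot
}

adjustedRandIndex <- function(a, b) mclust::adjustedRandIndex(a, b)
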