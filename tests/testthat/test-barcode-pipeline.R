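test_that("barcodes below the read-support threshold are discarded", {
  fx <- smallLibrary(nVariants = 5L)
  bm <- fx$bm
  # graded support: barcode i seen i times
  n_bc <- 6L
  reps <- seq_len(n_bc)
  vr <- rep(unname(variantSequences(fx$lib)[bm$variant_id[1:n_bc]]), reps)
  br <- rep(bm$barcode[1:n_bc], reps)
  mp <- mapBarcodes(list(variant_read = vr, barcode_read = br), fx$lib)
  expect_setequal(mp$barcode, bm$barcode[3:n_bc])
  expect_equal(min(mp$read_support), 3L)
  expect_identical(mp$variant_id[match(bm$barcode[3:n_bc], mp$barcode)],
                   bm$variant_id[3:n_bc])
})

test_that("noiseless reads recover the designed map exactly", {
  fx <- smallLibrary(nVariants = 25L)
  rd <- simulateReads(fx$lib, fx$bm, nReads = 3000L, errorRate = 0, seed = 7)
  mp <- mapBarcodes(rd, fx$lib)
  truth <- setNames(fx$bm$variant_id, fx$bm$barcode)
  expect_true(all(mp$variant_id == truth[mp$barcode]))
  expect_true(all(mp$edit_distance == 0L))
  expect_true(all(mp$read_support >= 3L))
})

test_that("majority consensus overrides a single read error", {
  fx <- smallLibrary(nVariants = 5L)
  bc <- fx$bm$barcode[1]
  true_seq <- unname(variantSequences(fx$lib)[fx$bm$variant_id[1]])
  bad <- true_seq
  substr(bad, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(true_seq, 10, 10))[1]
  rd <- list(variant_read = c(rep(true_seq, 4L), bad),
             barcode_read = rep(bc, 5L))
  mp <- mapBarcodes(rd, fx$lib)
  expect_equal(nrow(mp), 1L)
  expect_identical(mp$variant_id, fx$bm$variant_id[1])
  expect_equal(mp$edit_distance, 0L)
  expect_equal(mp$read_support, 5L)
})

test_that("high-support consensus beyond the distance cap becomes a novel variant", {
  fx <- smallLibrary(nVariants = 5L)
  set.seed(1)
  alien <- paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE),
                 collapse = "")
  bc_new <- strrep("A", 20)
  rd <- list(variant_read = rep(alien, 12L),
             barcode_read = rep(bc_new, 12L))
  mp <- mapBarcodes(rd, fx$lib, maxEditDistance = 20L, novelMinSupport = 10L)
  expect_equal(nrow(mp), 1L)
  expect_true(mp$novel)
  expect_match(mp$variant_id, "^novel_")
  expect_identical(mp$sequence, alien)
  # same consensus at low support is dropped instead
  rd5 <- list(variant_read = rep(alien, 5L), barcode_read = rep(bc_new, 5L))
  expect_equal(nrow(mapBarcodes(rd5, fx$lib, novelMinSupport = 10L)), 0L)
})

test_that("multi-promoter pools resolve the promoter before the variant", {
  ref <- randomReference(4000)
  regA <- extractWindow(ref, 500L, "+", "pA")
  regB <- extractWindow(ref, 2500L, "+", "pB")
  cfg <- designConfig(nVariants = 10L)
  libA <- mutateVariants(regA, cfg, seed = 1)
  libB <- mutateVariants(regB, cfg, seed = 2)
  bmA <- assignBarcodes(libA, 2L, cfg, seed = 3)
  bmB <- assignBarcodes(libB, 2L, cfg, seed = 4, existing = bmA$barcode)
  rdA <- simulateReads(libA, bmA, 400L, errorRate = 0.005, seed = 5)
  rdB <- simulateReads(libB, bmB, 400L, errorRate = 0.005, seed = 6)
  rd <- list(variant_read = c(rdA$variant_read, rdB$variant_read),
             barcode_read = c(rdA$barcode_read, rdB$barcode_read))
  mp <- mapBarcodes(rd, list(libA, libB))
  truth <- setNames(c(bmA$promoter_id, bmB$promoter_id),
                    c(bmA$barcode, bmB$barcode))
  expect_true(all(mp$promoter_id == truth[mp$barcode]))
})

test_that("assignment accuracy stays high at realistic error rates", {
  fx <- smallLibrary(nVariants = 40L, perVariant = 2L)
  rd <- simulateReads(fx$lib, fx$bm, nReads = 1600L, errorRate = 0.01,
                      seed = 17)
  mp <- mapBarcodes(rd, fx$lib, minSupport = 5L)
  expect_gt(nrow(mp), 30L)
  truth <- setNames(fx$bm$variant_id, fx$bm$barcode)
  acc <- mean(mp$variant_id == truth[mp$barcode])
  expect_gte(acc, 0.99)
})

test_that("malformed reads are skipped with a logged count", {
  fx <- smallLibrary(nVariants = 5L)
  good <- simulateReads(fx$lib, fx$bm, 30L, errorRate = 0, seed = 2)
  rd <- list(variant_read = c(good$variant_read, "NNNN", ""),
             barcode_read = c(good$barcode_read, fx$bm$barcode[1], fx$bm$barcode[2]))
  mp <- mapBarcodes(rd, fx$lib)
  expect_equal(attr(mp, "skipped_reads"), 2L)
  empty <- mapBarcodes(list(variant_read = character(),
                            barcode_read = character()), fx$lib)
  expect_equal(nrow(empty), 0L)
})

test_that("barcode counting tallies exact matches and routes unmapped reads", {
  fx <- smallLibrary(nVariants = 4L)
  bm <- fx$bm
  samples <- list(
    s1 = list(condition = "c1", replicate = 1,
              dna = c(rep(bm$barcode[1], 5L), rep(bm$barcode[2], 2L),
                      strrep("T", 20)),
              rna = c(rep(bm$barcode[1], 3L), rep("GATTACAGATTACAGATTAC", 2L))))
  ct <- countBarcodes(samples, bm)
  expect_equal(ct$dna_count[ct$barcode == bm$barcode[1]], 5L)
  expect_equal(ct$dna_count[ct$barcode == bm$barcode[2]], 2L)
  expect_equal(ct$rna_count[ct$barcode == bm$barcode[1]], 3L)
  unm <- attr(ct, "unmapped")
  expect_equal(unm$unmapped_dna, 1L)
  expect_equal(unm$unmapped_rna, 2L)
  expect_error(countBarcodes(list(list(dna = "A", rna = "C")), bm),
               "sample sheet")
})

test_that("counts round-trip through read expansion when error-free", {
  fx <- smallLibrary(nVariants = 8L)
  arch <- nullArchitecture(fx$region)
  ct <- simulateCounts(fx$lib, fx$bm, arch, depthDna = 2000, depthRna = 2000,
                       replicates = 1L, seed = 9)
  samples <- list(list(condition = "condA", replicate = "1",
                       dna = rep(ct$barcode, ct$dna_count),
                       rna = rep(ct$barcode, ct$rna_count)))
  back <- countBarcodes(samples, fx$bm)
  back <- back[match(ct$barcode, back$barcode), ]
  expect_equal(back$dna_count, ct$dna_count)
  expect_equal(back$rna_count, ct$rna_count)
})

test_that("variant aggregation sums barcodes and conserves totals", {
  bm <- data.frame(barcode = c("AAAA", "CCCC", "GGGG"),
                   variant_id = c("v1", "v1", "v2"),
                   promoter_id = "pTest", stringsAsFactors = FALSE)
  ct <- data.frame(barcode = c("AAAA", "CCCC", "GGGG"),
                   condition = "c1", replicate = "1",
                   dna_count = c(3L, 5L, 7L), rna_count = c(1L, 2L, 3L),
                   stringsAsFactors = FALSE)
  vc <- aggregateVariantCounts(ct, bm, allVariants = c("v1", "v2", "v3"))
  expect_equal(vc$dna_count[vc$variant_id == "v1"], 8L)
  expect_equal(vc$n_barcodes[vc$variant_id == "v1"], 2L)
  expect_equal(vc$dna_count[vc$variant_id == "v3"], 0L)
  expect_equal(vc$n_barcodes[vc$variant_id == "v3"], 0L)
  # conservation: aggregated totals equal retained count-table totals
  expect_equal(sum(vc$dna_count), sum(ct$dna_count))
  expect_equal(sum(vc$rna_count), sum(ct$rna_count))
})

test_that("median barcodes per variant is recomputed from the table", {
  fx <- smallLibrary(nVariants = 150L)
  per <- drawBarcodeMultiplicity(length(fx$lib), medianBarcodes = 13, seed = 3)
  bm <- assignBarcodes(fx$lib, per, fx$config, seed = 4)
  arch <- nullArchitecture(fx$region)
  ct <- simulateCounts(fx$lib, bm, arch, depthDna = 1e4, depthRna = 1e4,
                       replicates = 1L, seed = 5)
  vc <- aggregateVariantCounts(ct, bm, allVariants = variantIds(fx$lib))
  expect_equal(unname(attr(vc, "median_barcodes_per_variant")), 13)
})
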