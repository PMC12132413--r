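test_that("footprint reproduces hand-computed 2x2 mutual information", {
  lib <- twoVariantLibrary(mutatedAt = 1L)
  # wt: DNA 400, RNA 450; mut: DNA 100, RNA 50 -> 0.014377 bits
  vc <- variantCountRows(c("wt", "mut"), dna = c(400L, 100L),
                         rna = c(450L, 50L))
  fp <- informationFootprint(vc, lib, pseudocount = 0)
  expect_equal(footprintMi(fp)[1], 0.01437846, tolerance = 1e-6)
  # wt: DNA 500, RNA 1000; mut: DNA 500, RNA 0 -> 0.311278 bits
  vc2 <- variantCountRows(c("wt", "mut"), dna = c(500L, 500L),
                          rna = c(1000L, 0L))
  fp2 <- informationFootprint(vc2, lib, pseudocount = 0)
  expect_equal(footprintMi(fp2)[1], 0.3112781, tolerance = 1e-6)
  # independence: identical RNA/DNA proportions give zero information
  vc3 <- variantCountRows(c("wt", "mut"), dna = c(400L, 100L),
                          rna = c(800L, 200L))
  fp3 <- informationFootprint(vc3, lib, pseudocount = 0)
  expect_equal(footprintMi(fp3)[1], 0, tolerance = 1e-12)
})

test_that("positions with zero mutant mass get mi 0 and zero coverage", {
  lib <- twoVariantLibrary(mutatedAt = 5L)
  vc <- variantCountRows(c("wt", "mut"), dna = c(100L, 100L),
                         rna = c(200L, 10L))
  fp <- informationFootprint(vc, lib)
  expect_gt(footprintMi(fp)[5], 0)
  expect_equal(footprintMi(fp)[10], 0)
  expect_equal(footprintCoverage(fp)[10], 0)
  expect_gt(footprintCoverage(fp)[5], 0)
  expect_error(informationFootprint(
    variantCountRows(c("wt", "mut"), c(0L, 0L), c(0L, 0L)), lib),
    "zero")
})

test_that("vectorized footprint equals the brute-force plug-in estimator", {
  # 100 random count tables over a library with random masks
  set.seed(1234)
  fx <- smallLibrary(nVariants = 40L)
  lib <- fx$lib
  mask <- mutationMask(lib)
  n <- length(lib)
  for (k in 1:100) {
    dna <- rpois(n, 50)
    rna <- rpois(n, 50)
    vc <- variantCountRows(variantIds(lib), dna, rna)
    fp <- informationFootprint(vc, lib, pseudocount = 0.5)
    # independent oracle: explicit per-position 2x2 tables
    oracle <- vapply(seq_len(ncol(mask)), function(i) {
      mut <- mask[, i]
      if (!any(dna[mut] + rna[mut] > 0)) return(0)
      tab <- matrix(c(sum(dna[!mut]), sum(rna[!mut]),
                      sum(dna[mut]), sum(rna[mut])),
                    2L, byrow = TRUE) + 0.5
      max(0, miOracle(tab))
    }, numeric(1))
    expect_equal(footprintMi(fp), oracle, tolerance = 1e-12)
  }
})

test_that("null footprints stay below the plug-in bias bound", {
  fx <- smallLibrary(nVariants = 200L, perVariant = 2L)
  arch <- nullArchitecture(fx$region)
  ct <- simulateCounts(fx$lib, fx$bm, arch, depthDna = 1e5, depthRna = 1e5,
                       replicates = 1L, seed = 77)
  vc <- aggregateVariantCounts(ct, fx$bm, allVariants = variantIds(fx$lib))
  fp <- informationFootprint(vc, fx$lib, condition = "condA", replicate = 1)
  expect_lt(mean(footprintMi(fp)), 0.005)
})

test_that("expression shifts recover hand-computed averages", {
  # three variants: wt (rho 1), two mutants at position 1 with rho 2 and 4
  reg <- testRegion()
  wt <- windowSequence(reg)
  chars <- strsplit(wt, "")[[1]]
  alt <- setdiff(c("A", "C", "G", "T"), chars[1])[1]
  m1 <- chars; m1[1] <- alt
  m2 <- chars; m2[1] <- alt
  m2[80] <- setdiff(c("A", "C", "G", "T"), chars[80])[1]  # differentiates ids
  mask <- rbind(FALSE, seq_len(160) == 1,
                seq_len(160) %in% c(1L, 80L))
  lib <- new("VariantLibrary", promoterId = "pTest",
             variantId = c("wt", "m1", "m2"),
             sequences = c(wt, paste(m1, collapse = ""),
                           paste(m2, collapse = "")),
             mask = mask, wildtypeId = "wt")
  vc <- variantCountRows(c("wt", "m1", "m2"), dna = c(100L, 100L, 100L),
                         rna = c(100L, 200L, 400L))
  sh <- expressionShiftMatrix(vc, lib, pseudocount = 0)
  expect_equal(sh[alt, 1], 1.5, tolerance = 1e-12)
  expect_equal(sh[chars[1], 1], 0)
  # cells no variant carries are missing
  other <- setdiff(c("A", "C", "G", "T"), c(chars[1], alt))
  expect_true(all(is.na(sh[other, 1])))
  # all-equal expression gives all-zero shifts where defined
  vc0 <- variantCountRows(c("wt", "m1", "m2"), dna = c(100L, 100L, 100L),
                          rna = c(100L, 100L, 100L))
  sh0 <- expressionShiftMatrix(vc0, lib, pseudocount = 0)
  expect_true(all(abs(sh0[is.finite(sh0)]) < 1e-12))
})

test_that("planted repressor sites show positive shifts, RNAP negative", {
  reg <- testRegion()
  cfg <- designConfig(nVariants = 800L)
  lib <- mutateVariants(reg, cfg, seed = 23)
  bm <- assignBarcodes(lib, 3L, cfg, seed = 24)
  arch <- exampleArchitecture(reg, conditions = "on", activeIn = "on")
  ct <- simulateCounts(lib, bm, arch, depthDna = 1e6, depthRna = 1e6,
                       replicates = 1L, seed = 25)
  vc <- aggregateVariantCounts(ct, bm, allVariants = variantIds(lib))
  sh <- expressionShiftMatrix(vc, lib, condition = "on", replicate = 1)
  pos_mean <- function(cols) {
    vals <- sh[, cols, drop = FALSE]
    vapply(seq_along(cols), function(j) {
      v <- vals[, j]; mean(v[is.finite(v) & v != 0])
    }, numeric(1))
  }
  rep_cols <- offsetToIndex(1L):offsetToIndex(15L)
  rnap_cols <- offsetToIndex(-40L):offsetToIndex(-1L)
  act_cols <- offsetToIndex(-75L):offsetToIndex(-55L)
  # sign agreement on >= 90% of covered site positions
  expect_gte(mean(pos_mean(rep_cols) > 0), 0.9)
  expect_gte(mean(pos_mean(rnap_cols) < 0), 0.9)
  expect_gte(mean(pos_mean(act_cols) < 0), 0.9)
})

test_that("Gaussian smoothing conserves structure", {
  expect_equal(smoothFootprint(rep(2, 50), sigma = 3), rep(2, 50),
               tolerance = 1e-12)
  spike <- c(rep(0, 20), 1, rep(0, 20))
  sm <- smoothFootprint(spike, sigma = 2)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  r <- 8L  # kernel radius at sigma = 2
  k <- dnorm(seq(-r, r), sd = 2); k <- k / sum(k)
  expect_equal(sm[(21 - r):(21 + r)], k, tolerance = 1e-12)
  # small sigma approaches the identity
  near <- smoothFootprint(spike, sigma = 0.05)
  expect_equal(near, spike, tolerance = 1e-6)
})

test_that("footprints serialize to TSV and JSON", {
  lib <- twoVariantLibrary(mutatedAt = 3L)
  vc <- variantCountRows(c("wt", "mut"), c(50L, 50L), c(80L, 20L))
  fp <- informationFootprint(vc, lib)
  sh <- expressionShiftMatrix(vc, lib)
  dir <- withr::local_tempdir()
  paths <- writeFootprint(fp, sh, file.path(dir, "t"))
  tab <- read.delim(paths[1])
  expect_equal(nrow(tab), 160L)
  expect_equal(tab$mi_bits, footprintMi(fp), tolerance = 1e-6)
  js <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(js$mi_bits, footprintMi(fp), tolerance = 1e-9)
})
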