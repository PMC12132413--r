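test_that("classifier separates noise, blocks and spikes", {
  set.seed(5)
  noise <- exp(rnorm(160, -9, 1))      # positionally uncorrelated noise
  expect_identical(classifyFootprint(noise)$class, "inactive")

  block <- rep(0.0003, 160)            # 12-bp block of high information
  block[70:81] <- 0.01
  expect_identical(classifyFootprint(block)$class, "active_with_sites")

  spike <- rep(0.0003, 160)            # isolated single-position spike
  spike[90] <- 0.02
  expect_identical(classifyFootprint(spike)$class, "emergent_tss_candidate")

  expect_identical(classifyFootprint(rep(0, 160))$class, "inactive")
})

test_that("classification is invariant to uniform scaling", {
  set.seed(6)
  for (x in list(exp(rnorm(160, -9, 1)),
                 {b <- rep(3e-4, 160); b[50:65] <- 0.01; b},
                 {s <- rep(3e-4, 160); s[120] <- 0.03; s})) {
    c1 <- classifyFootprint(x)
    c2 <- classifyFootprint(x * 1000)
    c3 <- classifyFootprint(x / 57)
    expect_identical(c1$class, c2$class)
    expect_identical(c1$class, c3$class)
    expect_equal(c1$cv_raw, c2$cv_raw, tolerance = 1e-12)
  }
})

test_that("call merging and minimum-length rules apply", {
  post <- rep(0, 160)
  post[c(30:40, 43:50)] <- 0.9   # gap of 2 -> merged
  post[100:102] <- 0.9           # 3 bp -> dropped
  hmm <- list(posterior = post)
  fp <- new("Footprint", promoterId = "p", condition = "c", replicate = "1",
            mi = rep(0.001, 160), coverage = rep(1, 160))
  calls <- callSites(fp, hmm)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 30L)
  expect_equal(calls$end, 50L)
  # empty posterior gives empty calls
  expect_equal(nrow(callSites(fp, list(posterior = rep(0, 160)))), 0L)
})

test_that("call signs follow the expression-shift convention", {
  post <- rep(0, 160); post[20:30] <- 1
  mi <- rep(0.001, 160)
  fp <- new("Footprint", promoterId = "p", condition = "c", replicate = "1",
            mi = mi, coverage = rep(1, 160))
  mk_shifts <- function(v) {
    m <- matrix(NA_real_, 4, 160, dimnames = list(c("A", "C", "G", "T"), NULL))
    m["A", ] <- 0          # pretend wild type is A everywhere
    m["C", ] <- v; m["G", ] <- v; m["T", ] <- v
    attr(m, "wildtype") <- rep("A", 160)
    m
  }
  up <- callSites(fp, list(posterior = post), mk_shifts(1.2))
  expect_identical(up$sign, "repressor-like")
  dn <- callSites(fp, list(posterior = post), mk_shifts(-0.8))
  expect_identical(dn$sign, "activator-like")
  mx <- callSites(fp, list(posterior = post), mk_shifts(0.01))
  expect_identical(mx$sign, "mixed")
})

test_that("emergent -10 rule follows the important-triple logic", {
  # CATAAT -> TATAAT via C->T at hexamer position 1
  seqs <- paste0(strrep("G", 20), "CATAAT", strrep("G", 20))
  ev <- detectEmergentTss(seqs, position = 21L)
  expect_true(any(ev$creating_base == "T" & ev$frame_start == 21L))
  hit <- ev[ev$frame_start == 21L & ev$creating_base == "T", ]
  expect_identical(hit$hexamer_before, "CATAAT")
  expect_identical(hit$hexamer_after, "TATAAT")

  # an existing TATAAT produces no event at its own positions
  tat <- paste0(strrep("G", 20), "TATAAT", strrep("G", 20))
  for (p in 21:26) {
    ev2 <- detectEmergentTss(tat, position = p)
    if (nrow(ev2))
      expect_false(any(ev2$frame_start == 21L))
  }
})

test_that("emergent rule equals brute-force enumeration over a full window", {
  wt <- windowSequence(testRegion(seed = 123L))
  got <- scanTssCreation(wt)
  # independent oracle: mutate the full sequence, then scan important
  # positions of every frame covering the mutation via substring comparison
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(wt, "")[[1]]
  L <- length(chars)
  matches_triple <- function(s, fs)
    substr(s, fs, fs) == "T" && substr(s, fs + 1, fs + 1) == "A" &&
      substr(s, fs + 5, fs + 5) == "T"
  expected <- list()
  for (p in seq_len(L)) for (b in setdiff(bases, chars[p])) {
    mut <- chars; mut[p] <- b
    mut_s <- paste(mut, collapse = "")
    for (fs in max(1L, p - 5L):min(p, L - 5L)) {
      if (matches_triple(mut_s, fs) && !matches_triple(wt, fs)) {
        expected[[length(expected) + 1L]] <-
          data.frame(position = p, creating_base = b, frame_start = fs,
                     stringsAsFactors = FALSE)
      }
    }
  }
  expected <- do.call(rbind, expected)
  key <- function(d) sort(paste(d$position, d$creating_base, d$frame_start))
  expect_identical(key(got), key(expected))
})

test_that("shift filtering keeps only strongly up substitutions", {
  seqs <- paste0(strrep("G", 20), "CATAAT", strrep("G", 20))
  m <- matrix(0, 4, nchar(seqs), dimnames = list(c("A", "C", "G", "T"), NULL))
  m["T", 21] <- 2.0   # only T at the spike is strongly positive
  m["A", 21] <- 0.1
  ev <- detectEmergentTss(seqs, position = 21L, shifts = m, shiftFloor = 0.5)
  expect_true(all(ev$creating_base == "T"))
  ev_none <- detectEmergentTss(seqs, position = 21L,
                               shifts = matrix(0, 4, nchar(seqs),
                                               dimnames = list(c("A","C","G","T"), NULL)),
                               shiftFloor = 0.5)
  expect_equal(nrow(ev_none), 0L)
})

test_that("frames truncated at the window edge are skipped", {
  seqs <- paste0("CATAAT", strrep("G", 30))
  ev <- detectEmergentTss(seqs, position = 1L)
  expect_true(all(ev$frame_start >= 1L))
  ev_edge <- detectEmergentTss(seqs, position = 36L)
  expect_true(all(ev_edge$frame_start + 5L <= 36L))
})

test_that("an emergent TSS planted in simulation is recovered end to end", {
  # promoter with no active TSS but a CATAAT one mutation away from TATAAT:
  # variants carrying that C->T mutation express; all others are silent
  set.seed(31)
  chars <- sample(c("A", "C", "G"), 160, replace = TRUE)  # avoid chance TATAAT
  pos <- 40L
  chars[pos:(pos + 5L)] <- c("C", "A", "T", "A", "A", "T")
  wt <- paste(chars, collapse = "")
  reg <- new("PromoterRegion", promoterId = "pEmerge", gene = "g",
             tss = 500L, strand = "+", sequence = wt)
  cfg <- designConfig(nVariants = 1500L)
  lib <- mutateVariants(reg, cfg, seed = 32)
  bm <- assignBarcodes(lib, 3L, cfg, seed = 33)
  # expression: on only when position 40 is T (new -10 created)
  seqs <- unname(variantSequences(lib))
  eps <- matrix(8, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  eps["T", 1] <- 0
  sites <- list(regSite("rnap", "rnap", pos, pos, energyMatrix(eps),
                        weight = 1, coords = "index"))
  arch <- regArchitecture("pEmerge", sites,
                          matrix(1, 1, 1, dimnames = list("c1", "rnap")))
  ct <- simulateCounts(lib, bm, arch, depthDna = 1e6, depthRna = 1e6,
                       replicates = 1L, seed = 34)
  vc <- aggregateVariantCounts(ct, bm, allVariants = variantIds(lib))
  fp <- informationFootprint(vc, lib, condition = "c1", replicate = 1)
  cls <- classifyFootprint(fp)
  expect_identical(cls$class, "emergent_tss_candidate")
  spike <- which.max(footprintMi(fp))
  expect_equal(spike, pos)
  sh <- expressionShiftMatrix(vc, lib, condition = "c1", replicate = 1)
  ev <- detectEmergentTss(wt, spike, sh, shiftFloor = 0.5)
  expect_true(any(ev$creating_base == "T" & ev$frame_start == pos))
})
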