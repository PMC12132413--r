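#!/usr/bin/env Rscript

# Calibrates the footprint classifier's activity threshold on null
# simulations at matched sequencing depth. The activity statistic is the
# smoothed-footprint coefficient of variation (scale-free); the threshold is
# placed at the 99.9th percentile of its null distribution, rounded up, so a
# promoter with no active TSS is called inactive. Run from the repository
# root:
#   Rscript scripts/calibrate_thresholds.R [--seeds N] [--depth D]

suppressPackageStartupMessages(library(regseqtools))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i)) as.numeric(args[i + 1L]) else default
}
n_seeds <- getArg("--seeds", 40)
depth <- getArg("--depth", 1e6)

ref <- paste(rep(c("A", "C", "G", "T"), length.out = 1000), collapse = "")
set.seed(424242)
ref <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
reg <- extractWindow(ref, 500L, "+", "null_promoter")
cfgd <- designConfig()
lib <- mutateVariants(reg, cfgd, seed = 424242)
bm <- assignBarcodes(lib, drawBarcodeMultiplicity(length(lib), seed = 1),
                     cfgd, seed = 2)
narch <- nullArchitecture(reg)

stats <- t(vapply(seq_len(n_seeds), function(s) {
  ct <- simulateCounts(lib, bm, narch, depthDna = depth, depthRna = depth,
                       replicates = 1L, seed = 1000L + s)
  vc <- aggregateVariantCounts(ct, bm, allVariants = variantIds(lib))
  fp <- informationFootprint(vc, lib, condition = "condA", replicate = 1)
  cl <- classifyFootprint(fp, classifierConfig(activityThreshold = Inf))
  c(cv_raw = cl$cv_raw, cv_smooth = cl$cv_smooth, cv_ratio = cl$cv_ratio)
}, numeric(3)))

cat(sprintf("null CV_smooth over %d seeds at depth %g:\n", n_seeds, depth))
print(round(quantile(stats[, "cv_smooth"], c(0.5, 0.9, 0.99, 0.999)), 3))
cat(sprintf("null CV_raw median %.3f, cv_ratio median %.3f\n",
            median(stats[, "cv_raw"]), median(stats[, "cv_ratio"])))
thr <- ceiling(quantile(stats[, "cv_smooth"], 0.999) * 10) / 10
cat(sprintf("suggested activityThreshold (ceil of 99.9th pct to 0.1): %.1f\n", thr))
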