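# regseqtools

Massively parallel reporter assays (MPRA / Reg-Seq) dissect bacterial gene
regulation base by base: a promoter window is randomly mutagenized, thousands
of barcode-tagged variants are grown across environmental conditions, and
expression of every variant is read out by sequencing DNA and RNA barcode
counts. `regseqtools` is for researchers running or modelling such
experiments in *E. coli*-like systems. It implements:

* **library design** — TSS-anchored 160-bp windows (−115..+45), 10%-per-base
  mutagenesis, 1500 variants per promoter, unique 20-bp barcodes
  (`extractWindow()`, `mutateVariants()`, `assignBarcodes()`, `designPool()`);
* **ground-truth simulation** from thermodynamic occupancy models — for each
  site *j* with additive energy matrix ε_j and weight *w_j*, the Boltzmann
  weight is W_j(s) = w_j·exp(−E_j(s)), and expression is the polymerase
  occupancy
  p_bound = p·ω_eff / (1 + p·ω_eff + r), with r the summed weights of active
  repressors (competitive exclusion) and ω_eff the activator stabilization
  factor; condition dependence enters through per-condition site activities
  a_j ∈ [0,1] (`expressionRate()`, `simulateCounts()`, `simulateReads()`);
* **barcode pipeline** — barcode↔variant map reconstruction from paired
  reads with a 3-read support filter and nearest-design alignment, exact
  barcode counting, per-variant aggregation (`mapBarcodes()`,
  `countBarcodes()`, `aggregateVariantCounts()`);
* **information footprints** — per position *i*, the mutual information
  I_i = Σ p(m,μ) log2[ p(m,μ) / (p(m)p(μ)) ] between mutation status
  m ∈ {wt, mut} and read class μ ∈ {DNA, RNA}, in bits, plus signed
  expression-shift matrices Δ(i,b) (`informationFootprint()`,
  `expressionShiftMatrix()`);
* **site discovery** — CV-under-smoothing classification into
  active / emergent-TSS / inactive, two-state Gaussian HMM segmentation
  (Baum–Welch, written here and tested against exhaustive path enumeration),
  signed binding-site calls, and the σ70 −10 rule (a single substitution
  completing the important T-A-..-T triple of TATAAT) for emergent
  transcription start sites (`classifyFootprint()`, `fitTwoStateHMM()`,
  `callSites()`, `detectEmergentTss()`);
* **condition clustering** — replicate QC by Pearson correlation,
  per-promoter and global hierarchical clustering with correlation distance
  and average linkage (`replicateCorrelation()`, `clusterPromoterConditions()`,
  `clusterGlobal()`);
* **pulldown enrichment** — log2 target/control ratios with an
  abundance-percentile criterion for DNA-chromatography mass spectrometry
  (`enrichmentScores()`, `callEnriched()`).

`runPipeline()` chains design → simulate → aggregate → footprint → discover
→ cluster under one seeded YAML/JSON config;
`inst/scripts/regseq-pipeline.R` exposes `design`, `map`, `enrich` and
`run-all` as shell subcommands.

## Worked example

Design a library for one promoter, simulate an arabinose-inducible
architecture (RNAP at −40..−1, activator at −75..−55 active only with
arabinose, repressor at +1..+15), and call sites in both conditions:

```r
library(regseqtools)

set.seed(99)
ref <- paste(sample(c("A","C","G","T"), 2000, replace = TRUE), collapse = "")
region <- extractWindow(ref, tss = 500L, strand = "+",
                        promoterId = "araB_like", gene = "araB")
cfg <- designConfig()           # 10% per base, 1500 variants, 20-bp barcodes
lib <- mutateVariants(region, cfg, seed = 1)
lib
#> VariantLibrary for promoter araB_like
#>   1501 variants of length 160 bp; wild type: araB_like_wt
#>   mean mutated fraction: 0.1

bm   <- assignBarcodes(lib, drawBarcodeMultiplicity(length(lib), seed = 1),
                       cfg, seed = 2)
arch <- exampleArchitecture(region, conditions = c("arabinose", "glucose"),
                            activeIn = "arabinose")
ct <- simulateCounts(lib, bm, arch, depthDna = 1e6, depthRna = 1e6,
                     replicates = 1, seed = 3)
vc <- aggregateVariantCounts(ct, bm, allVariants = variantIds(lib))

fp <- informationFootprint(vc, lib, condition = "arabinose", replicate = 1)
fp
#> Footprint araB_like | arabinose | rep 1: 160 positions, peak 0.0067 bits, mean 0.00126 bits
sh <- expressionShiftMatrix(vc, lib, condition = "arabinose", replicate = 1)

discoverSites(fp, sh)$calls[, c("offset_start","offset_end","mean_mi","sign")]
#>   offset_start offset_end     mean_mi           sign
#> 1          -75        -55 0.003365701 activator-like
#> 2          -40         15 0.002103895 activator-like
```

The first call recovers the planted activator exactly (−75..−55); the second
merges the adjacent RNAP element and downstream repressor (−40..+15). Mean
MI is the average footprint height inside the call (bits); the sign comes
from expression shifts (mutations lowering expression ⇒ activator-like).
In glucose the activator site vanishes — only the constitutive block
remains, whose mixed sign reflects the opposing RNAP (down) and repressor
(up) mutations it spans:

```r
fp2 <- informationFootprint(vc, lib, condition = "glucose", replicate = 1)
sh2 <- expressionShiftMatrix(vc, lib, condition = "glucose", replicate = 1)
discoverSites(fp2, sh2)$calls[, c("offset_start","offset_end","mean_mi","sign")]
#>   offset_start offset_end     mean_mi  sign
#> 1          -40         15 0.002702092 mixed
```

`plotFootprint(fp, discoverSites(fp, sh)$calls)` draws the footprint with
called intervals shaded.

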