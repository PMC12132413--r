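---
title: "Methods: from mutant promoter libraries to regulatory architectures"
author: "regseqtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from mutant promoter libraries to regulatory architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regseqtools)
```

## The measurement this package models

Massively parallel reporter assays read out bacterial gene regulation at
base-pair resolution: a promoter window is randomly mutagenized, thousands of
variants are tagged with DNA barcodes and integrated into the genome, and the
culture is sequenced twice — once from DNA (how many cells carry each
variant) and once from mRNA (how strongly each variant expresses). Repeating
the measurement across growth conditions reveals which bases matter for
expression *in which environment*, and therefore where condition-dependent
transcription-factor binding sites sit.

`regseqtools` implements the full computational arc: library design,
ground-truth simulation from thermodynamic models, barcode-map
reconstruction, per-base information footprints and expression shifts,
binding-site segmentation, emergent-promoter detection, cross-condition
clustering, and enrichment scoring for DNA-pulldown mass spectrometry.

## Library design

The designed window spans 115 bp upstream to 45 bp downstream of the
transcription start site (160 bp; positions are labelled −115..−1, +1..+45
with no 0, since most cis-regulation falls in this range). Every position is
mutated independently at rate 0.1, substituting one of the three alternative
bases uniformly; 1500 mutants plus the wild type are kept per promoter, and
each variant receives randomized 20-bp barcodes. These defaults reproduce the
published design arithmetic (119 promoters × 1501 entries = 178,619) and give
each position ~150 mutant variants — enough mutational coverage for
per-position statistics. Insertions and deletions are never generated, and
each promoter's wild type is included exactly once; duplicate TSSs are
treated as independent promoters.

On a minus-strand promoter "upstream" is the higher-coordinate side of the
reference, so the extracted genomic span is `[tss − 45, tss + 115]` and the
window is reverse-complemented; the stored sequence always reads in promoter
orientation with +1 at the TSS base.

## The thermodynamic simulator

Simulated ground truth drives every downstream test. Expression of a variant
sequence $s$ is the equilibrium occupancy of RNA polymerase. Each site $j$
carries an additive energy matrix $\varepsilon_j(b, i)$ (units of $k_BT$,
$\beta \equiv 1$) and a dimensionless weight $w_j$ that absorbs copy number
and non-specific background; its Boltzmann weight on $s$ is
$W_j(s) = w_j e^{-E_j(s)}$ with $E_j(s) = E_{j,\mathrm{ref}} + \sum_i
\varepsilon_j(s_i, i)$. With $p = W_{\mathrm{RNAP}}(s)$, repressors acting by
competitive exclusion ($r = \sum_j a_j W_j$), and activators stabilizing
polymerase with cooperativity $\omega_k$ in the simple-activation limit,

$$
p_{\mathrm{bound}} =
\frac{p\,\omega_{\mathrm{eff}}}{1 + p\,\omega_{\mathrm{eff}} + r},
\qquad
\omega_{\mathrm{eff}} = 1 + \sum_k a_k
\frac{W_k(s)\,(\omega_k - 1)}{1 + W_k(s)} .
$$

Condition dependence enters through activities $a_j \in [0,1]$ (the
allosteric state of each factor in each growth condition). The default
planted architecture mirrors a classic inducible promoter: RNAP at −40..−1,
an activator at −75..−55 active only in chosen conditions, and a repressor
at +1..+15. Energy matrices are gauged so the wild type is consensus, with
2 $k_BT$ per mismatch for transcription factors and 0.5 $k_BT$ per mismatch
for the 40-bp RNAP element.

Counts are multinomial: DNA reads proportional to barcode abundance (uniform
design × lognormal jitter, sdlog 0.25, drawn once per library since the pool
is one physical object), RNA reads proportional to abundance ×
$p_{\mathrm{bound}}$. An optional Dirichlet concentration parameter adds the
overdispersion real libraries show; it is off by default so that count noise
is exactly understood in tests. What the simulator deliberately omits:
epistasis between positions, DNA looping, growth-rate coupling between
expression and abundance, and PCR jackpotting — so passing tests demonstrate
correctness of the estimators under the stated model, not robustness to
every artifact of real libraries.

## Barcode mapping

Paired mapping reads (variant window, barcode) are grouped by barcode;
barcodes with fewer than 3 total reads are discarded (the support threshold
is applied to raw pair counts, before consensus). The per-position majority
consensus of each retained barcode's reads is matched to the nearest
designed variant — exact match first, otherwise minimum distance. Since
designs and reads share one length and errors are substitutions, Hamming
distance equals edit distance; `utils::adist` covers length mismatches. The
distance cap defaults to 20 (≈ expected mutations plus sequencing errors);
high-support consensus sequences beyond the cap are retained as novel
variants, because synthesis errors genuinely add pool members. Barcode
matching at the counting stage is exact: 20-mers at realistic depths
essentially never collide, and no error-correction rule is part of the
design.

## Information footprints and expression shifts

Expression is discretized as the two sequencing classes of a read: DNA or
RNA. At each window position $i$, reads are cross-tabulated by the mutation
status $m \in \{\text{wt}, \text{mut}\}$ of their variant at $i$ and the
class $\mu \in \{\text{DNA}, \text{RNA}\}$, each variant contributing its
counts as weights. The footprint is the plug-in mutual information

$$
I_i = \sum_{m,\mu} p(m, \mu) \log_2 \frac{p(m,\mu)}{p(m)\,p(\mu)} ,
$$

bounded by 1 bit for this 2×2 channel. A pseudocount of $\psi = 0.5$ per
cell bounds the estimator at low coverage without influencing depths
$\ge 10^4$; the plug-in bias ($\approx 1/(2N\ln 2)$ per table) is negligible
at the simulated depths, which the null-simulation test verifies directly.
Positions never covered by a mutant get $I_i = 0$ and zero coverage.
Replicates are footprinted separately; when a combined view is needed, the
counts are summed first — mutual information is not averaged.

The expression-shift matrix asks *which way* a substitution moves
expression: $\Delta(i, b)$ is the mean $\log_2$ RNA/DNA ratio (pseudocounted
and normalized by library totals) over variants carrying base $b$ at $i$,
minus the mean over variants carrying the wild-type base. Mutations that
relieve repression shift positive; mutations that weaken polymerase or
activator binding shift negative. This sign convention propagates into site
calls.

## Classifying footprints and calling sites

Footprints fall into three classes: an active promoter with binding sites,
an otherwise inactive window where a single mutation creates a new
transcription start site (an isolated high-MI spike), and an inactive
window. The classifier compares the coefficient of variation (CV = sd/mean)
of the footprint before and after Gaussian smoothing (σ = 3 bp):
positionally uncorrelated noise is destroyed by smoothing, extended site
structure survives it, and a single spike loses most of its CV. Activity is
therefore gated on the smoothed CV, and the spike-vs-sites decision on the
ratio CV$_{\text{smooth}}$/CV$_{\text{raw}}$ (default boundary 0.5). During
development we found the raw CV cannot gate activity: under the null it is
*higher* (≈1.3–1.5, near-exponential noise) than for genuinely active
footprints (≈1.1–1.4), whereas the smoothed CV separates the two cleanly.
The activity threshold (0.6) is the 99.9th percentile of the null smoothed
CV at matched depth, rounded up, as computed by
`scripts/calibrate_thresholds.R`; both statistics are scale-free, so
classification is invariant to uniform rescaling of the footprint.

Active footprints are segmented by a two-state hidden Markov model with
Gaussian emissions on log MI — "site" and "background" states. Fitting is
Baum–Welch EM with scaled forward–backward recursions: emission means
initialized at the 25th/90th percentiles of the observations, convergence
when the log-likelihood gain drops below 1e−6 (cap 500 iterations), states
relabelled so the site state has the larger mean. Collapsed fits (merged
means or an empty state) fall back to thresholding at the 90th percentile,
flagged `degenerate`. Sites are the posterior-decoded segments with
P(site) > 0.5; gaps ≤ 2 bp are bridged, segments < 4 bp dropped — values
chosen for stability at the simulated depths and exposed in the config. Each
call is signed by the coverage-weighted mean expression shift inside the
interval (repressor-like / activator-like / mixed below a 0.15 log2 floor).

Emergent-TSS candidates use the σ70 −10 element rule: consensus TATAAT,
with positions 1, 2 and 6 dominating binding. A substitution is reported
when, in at least one of the six hexamer frames covering it, the three
important positions all match T, A, T after the mutation but not before.
Frames truncated at the window edge are skipped; the −35 element and spacer
are not modelled. A brute-force oracle over all 3L single mutants × frames
verifies exact equivalence in the tests.

## Clustering conditions

Footprints are compared with Pearson correlation; distance 1 − r with
average linkage (the standard pairing for correlation distances; the data do
not dictate a linkage). Per promoter, only conditions classified
active-with-sites enter. Globally, rows are condition × replicate vectors of
concatenated footprints over all promoters; promoters silent in a condition
are zero-filled rather than dropped, preserving the "silent here" signal
(a masking mode exists). Rows are kept at replicate level because replicate
pairing itself is informative — each row's nearest neighbour should be its
replicate. Replicate QC computes within-condition Pearson r and flags pairs
below 0.3 (configurable; the choice of floor is the package's, not derived
from data), suggesting exclusion of the replicate that correlates worse with
the remaining experiments. Ties in clustering are broken by row order, so
results are deterministic given the matrix.

## Pulldown enrichment

DNA-chromatography/mass-spec abundance tables are scored as
$\log_2((\text{target} + \psi)/(\text{control} + \psi))$ per protein, with
$\psi$ = half the smallest nonzero abundance. Candidate binders must pass
both the ratio floor (default 2, i.e. 4-fold) and an abundance floor — the
percentile of target abundance, default 50 — since ratios of weakly detected
proteins are unstable; proteins enriched but below the abundance floor are
reported separately. Enrichment is operationalized as this ratio + percentile
pair; no replicate-variance model is fitted, matching the qualitative way
such pulldowns are read.

## Problem sizes and numerical choices

The test suite simulates at the designed library scale (1500 variants,
median 13 barcodes per variant) and sequencing depth $10^6$ per sample for
site-recovery checks (50 seeded replicates; median interval Jaccard against
planted truth ≥ 0.6 observed ≈ 0.95), depth $10^5$ for clustering checks,
and three promoters × four conditions for the end-to-end pipeline test.
These sizes are the package's choices for demonstrating the statistical
properties at desk scale. Other numerical details: substitution draws are
uniform over the three alternatives; all random stages take explicit integer
seeds and two runs with equal seeds are byte-identical; energies are
validated finite before exponentiation; MI values are clipped at 0 against
floating-point undershoot.

## Known limitations

* The MI estimator is the 2×2 plug-in with pseudocount; no bias-corrected or
  multi-bin estimator is provided (the binning of expression into DNA/RNA
  read classes is itself the estimator definition here).
* The emergence rule scores only the −10 important triple; candidate
  strength (spacer, −35, discriminator) is out of scope.
* Energy-matrix inference from data is out of scope — the package consumes
  known matrices for simulation and produces footprints, not models.
* Real-data idiosyncrasies (overdispersion beyond the Dirichlet option, PCR
  artifacts, mapping chimeras) are not emulated, so simulation-based
  guarantees transfer to real libraries only qualitatively.
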