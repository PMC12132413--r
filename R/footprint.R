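## Information footprints and expression-shift matrices.
##
## Expression is discretized as the two sequencing classes of a read (DNA vs
## RNA); at each window position the mutation status of a variant's base
## (wild-type vs mutated) defines the second binary variable. The footprint
## is the per-position plug-in mutual information of that 2x2 channel, with a
## pseudocount per cell to stabilize low-coverage positions.

.mi2x2 <- function(n) {
  ## n: 2x2 counts [m, mu]; plug-in MI in bits
  N <- sum(n)
  if (N <= 0) stop("all-zero contingency table")
  p <- n / N
  pm <- rowSums(p); pmu <- colSums(p)
  e <- outer(pm, pmu)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

.alignCounts <- function(counts, library, condition = NULL, replicate = NULL) {
  if (!is.null(condition)) counts <- counts[counts$condition == condition, ]
  if (!is.null(replicate))
    counts <- counts[counts$replicate == as.character(replicate), ]
  if (!nrow(counts)) stop("no count rows after filtering")
  if (length(unique(counts$variant_id)) != nrow(counts))
    stop("counts must hold one row per variant; filter condition/replicate")
  idx <- match(counts$variant_id, variantIds(library))
  if (anyNA(idx))
    counts <- counts[!is.na(idx), , drop = FALSE]
  idx <- match(counts$variant_id, variantIds(library))
  if (!nrow(counts)) stop("counts and library share no variant ids")
  list(counts = counts, idx = idx)
}

#' Per-base information footprint
#'
#' For every window position, reads are cross-tabulated by the mutation
#' status of that position in their variant of origin (wild-type base vs
#' mutated) and by their sequencing class (DNA vs RNA), each variant
#' contributing its DNA and RNA counts as weights. The footprint value is the
#' plug-in mutual information of that 2x2 table in bits, after adding
#' \code{pseudocount} to every cell. Positions with zero mutant read mass get
#' \code{mi = 0} and are flagged by \code{coverage = 0}.
#'
#' @param counts per-variant counts for one promoter (columns
#'   \code{variant_id}, \code{dna_count}, \code{rna_count}; rows for one
#'   condition and replicate, or use \code{condition}/\code{replicate} to
#'   filter).
#' @param library the matching [VariantLibrary-class].
#' @param condition,replicate optional filters applied to \code{counts};
#'   also stored as labels on the result.
#' @param pseudocount added to each cell of every 2x2 table (default 0.5).
#' @return a [Footprint-class].
#' @export
informationFootprint <- function(counts, library, condition = NULL,
                                 replicate = NULL, pseudocount = 0.5) {
  al <- .alignCounts(counts, library, condition, replicate)
  counts <- al$counts
  M <- library@mask[al$idx, , drop = FALSE]  # variants x positions
  dna <- as.numeric(counts$dna_count)
  rna <- as.numeric(counts$rna_count)
  if (sum(dna) + sum(rna) <= 0) stop("all counts are zero")
  ## per position: mutant-class masses by read class
  mut_dna <- drop(crossprod(M, dna))
  mut_rna <- drop(crossprod(M, rna))
  wt_dna <- sum(dna) - mut_dna
  wt_rna <- sum(rna) - mut_rna
  L <- ncol(M)
  mi <- numeric(L)
  covered <- (mut_dna + mut_rna) > 0
  for (i in which(covered)) {
    n <- matrix(c(wt_dna[i], wt_rna[i], mut_dna[i], mut_rna[i]),
                nrow = 2L, byrow = TRUE) + pseudocount
    mi[i] <- max(0, .mi2x2(n))
  }
  new("Footprint",
      promoterId = promoterId(library),
      condition = if (is.null(condition)) unique(counts$condition)[1] else condition,
      replicate = if (is.null(replicate)) as.character(unique(counts$replicate)[1])
                  else as.character(replicate),
      mi = mi, coverage = mut_dna + mut_rna)
}

#' Expression-shift matrix
#'
#' For every position \code{i} and base \code{b} differing from wild type,
#' the shift is the mean log2 expression ratio of variants carrying \code{b}
#' at \code{i} minus the mean over variants carrying the wild-type base
#' there. A variant's expression ratio is \code{(rna + psi) / (dna + psi)}
#' normalized by the library-wide RNA/DNA totals, so a mutation that relieves
#' repression yields positive shifts and one that weakens polymerase or
#' activator binding yields negative shifts. Wild-type cells are 0; cells no
#' variant covers are \code{NA}.
#'
#' @inheritParams informationFootprint
#' @return a 4 x L numeric matrix (rows A, C, G, T) with attributes
#'   \code{wildtype} (the wild-type base per position) and \code{offsets}.
#' @export
expressionShiftMatrix <- function(counts, library, condition = NULL,
                                  replicate = NULL, pseudocount = 0.5) {
  al <- .alignCounts(counts, library, condition, replicate)
  counts <- al$counts
  seqmat <- .charMatrix(library@sequences[al$idx])
  dna <- as.numeric(counts$dna_count)
  rna <- as.numeric(counts$rna_count)
  D <- sum(dna); R <- sum(rna)
  logrho <- log2(((rna + pseudocount) / R) / ((dna + pseudocount) / D))
  wt <- .seqToChars(library@sequences[match(wildtypeId(library),
                                            variantIds(library))])
  L <- length(wt)
  out <- matrix(NA_real_, 4L, L, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(L)) {
    base_i <- seqmat[, i]
    is_wt <- base_i == wt[i]
    if (!any(is_wt)) next
    mu_wt <- mean(logrho[is_wt])
    for (b in DNA_BASES) {
      if (b == wt[i]) { out[b, i] <- 0; next }
      sel <- base_i == b
      if (any(sel)) out[b, i] <- mean(logrho[sel]) - mu_wt
    }
  }
  if (L == windowLength()) colnames(out) <- promoterOffsets()
  attr(out, "wildtype") <- wt
  attr(out, "offsets") <- if (L == windowLength()) promoterOffsets() else seq_len(L)
  out
}

#' Smooth a footprint with a Gaussian kernel
#'
#' Discrete Gaussian convolution with reflective boundaries; total mutual
#' information mass is conserved up to boundary effects, and a constant
#' footprint is unchanged.
#'
#' @param fp a [Footprint-class] or numeric vector.
#' @param sigma kernel standard deviation in bases (> 0).
#' @return same type as \code{fp}, smoothed.
#' @export
smoothFootprint <- function(fp, sigma = 3) {
  stopifnot(sigma > 0)
  x <- if (is(fp, "Footprint")) footprintMi(fp) else fp
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  L <- length(x)
  if (r >= L) stop("kernel radius exceeds footprint length")
  pad <- c(x[r:1], x, x[L:(L - r + 1L)])  # reflect
  sm <- vapply(seq_len(L), function(i) sum(pad[i:(i + 2L * r)] * k), numeric(1))
  sm <- pmax(sm, 0)
  if (is(fp, "Footprint")) {
    out <- fp
    out@mi <- sm
    out
  } else sm
}

#' Write footprint and shift matrix to TSV / JSON
#'
#' @param fp a [Footprint-class].
#' @param shifts optional matrix from [expressionShiftMatrix()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeFootprint <- function(fp, shifts = NULL, prefix) {
  L <- length(footprintMi(fp))
  offs <- if (L == windowLength()) promoterOffsets() else seq_len(L)
  tab <- data.frame(position = offs, mi_bits = footprintMi(fp),
                    mutant_coverage = footprintCoverage(fp))
  tsv <- paste0(prefix, "_footprint.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- tsv
  if (!is.null(shifts)) {
    stsv <- paste0(prefix, "_shifts.tsv")
    utils::write.table(
      data.frame(position = offs, wildtype = attr(shifts, "wildtype"),
                 t(unclass(shifts))),
      stsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, stsv)
  }
  js <- paste0(prefix, "_footprint.json")
  jsonlite::write_json(
    list(promoter_id = fp@promoterId, condition = fp@condition,
         replicate = fp@replicate, position = offs,
         mi_bits = footprintMi(fp)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, js))
}

#' Plot an information footprint
#'
#' Bar panel of mutual information per window position, with optional site
#' calls shaded.
#'
#' @param fp a [Footprint-class].
#' @param calls optional data.frame of site calls (columns \code{start},
#'   \code{end} in window indices).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, \code{NULL}.
#' @export
plotFootprint <- function(fp, calls = NULL, ...) {
  mi <- footprintMi(fp)
  offs <- if (length(mi) == windowLength()) promoterOffsets() else seq_along(mi)
  graphics::plot(offs, mi, type = "h", xlab = "position relative to TSS",
                 ylab = "mutual information (bits)",
                 main = sprintf("%s | %s", fp@promoterId, fp@condition), ...)
  if (!is.null(calls) && nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      graphics::rect(indexToOffset(calls$start[i]), 0,
                     indexToOffset(calls$end[i]), max(mi),
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  invisible(NULL)
}
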