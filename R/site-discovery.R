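## From footprints to binding-site calls and emergent-TSS hypotheses.

#' Footprint classifier configuration
#'
#' The classifier computes the coefficient of variation (CV = sd/mean) of the
#' raw footprint, smooths the footprint with a Gaussian kernel and computes
#' the CV again. How the CV changes under smoothing separates the three
#' outcome classes: positionally uncorrelated noise (no active TSS) is
#' destroyed by smoothing, so footprints whose smoothed CV falls below
#' \code{activityThreshold} are inactive; among active footprints, a CV ratio
#' \code{CV_smooth / CV_raw >= cvRatioThreshold} indicates extended
#' binding-site structure that survives smoothing, while a strongly reduced
#' CV indicates an isolated single-position spike, the signature of an
#' emergent transcription start site. Both statistics are scale-free, so
#' classification is invariant to uniform rescaling of the footprint.
#'
#' @param kernelSigma Gaussian smoothing sd in bases.
#' @param cvRatioThreshold boundary on \code{CV_smooth / CV_raw}.
#' @param activityThreshold minimum smoothed CV for an active footprint
#'   (calibrated on null simulations at matched depth; see
#'   \code{scripts/calibrate_thresholds.R} in the source repository).
#' @return a list of class \code{"ClassifierConfig"}.
#' @export
classifierConfig <- function(kernelSigma = 3, cvRatioThreshold = 0.5,
                             activityThreshold = 0.6) {
  stopifnot(kernelSigma > 0, cvRatioThreshold > 0, activityThreshold > 0)
  structure(list(kernelSigma = kernelSigma,
                 cvRatioThreshold = cvRatioThreshold,
                 activityThreshold = activityThreshold),
            class = "ClassifierConfig")
}

#' Classify a footprint into the three outcome classes
#'
#' @param fp a [Footprint-class] or numeric MI vector.
#' @param cfg a [classifierConfig()].
#' @return a list with \code{class} (one of \code{"active_with_sites"},
#'   \code{"emergent_tss_candidate"}, \code{"inactive"}), \code{cv_raw},
#'   \code{cv_smooth}, \code{cv_ratio}.
#' @export
classifyFootprint <- function(fp, cfg = classifierConfig()) {
  x <- if (is(fp, "Footprint")) footprintMi(fp) else fp
  mu <- mean(x)
  if (mu <= 0)
    return(list(class = "inactive", cv_raw = NA_real_,
                cv_smooth = NA_real_, cv_ratio = NA_real_))
  cv_raw <- sd(x) / mu
  sm <- smoothFootprint(x, cfg$kernelSigma)
  cv_smooth <- sd(sm) / mean(sm)
  ratio <- cv_smooth / cv_raw
  cls <- if (cv_smooth < cfg$activityThreshold) "inactive"
         else if (ratio < cfg$cvRatioThreshold) "emergent_tss_candidate"
         else "active_with_sites"
  list(class = cls, cv_raw = cv_raw, cv_smooth = cv_smooth, cv_ratio = ratio)
}

.runsFromLogical <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Call binding sites from a fitted HMM
#'
#' Posterior decoding: positions with site-state probability above
#' \code{posteriorCut} form candidate segments; gaps up to \code{mergeGap}
#' positions are bridged, segments shorter than \code{minLength} are dropped.
#' Each call's regulatory sign comes from the coverage-weighted mean
#' expression shift of mutations inside the interval: positive means
#' repressor-like (mutations relieve repression), negative activator-like,
#' and a magnitude below \code{noiseFloor} is reported as mixed.
#'
#' @param fp a [Footprint-class].
#' @param hmm result of [fitTwoStateHMM()].
#' @param shifts matrix from [expressionShiftMatrix()] (optional; without it
#'   the sign is \code{NA}).
#' @param posteriorCut site-state probability threshold.
#' @param mergeGap bridge gaps up to this many positions.
#' @param minLength drop calls shorter than this.
#' @param noiseFloor |mean shift| below which the sign is "mixed".
#' @return data.frame of site calls: \code{promoter_id}, \code{condition},
#'   \code{start}, \code{end} (window indices), \code{offset_start},
#'   \code{offset_end}, \code{mean_mi}, \code{posterior}, \code{sign}.
#' @export
callSites <- function(fp, hmm, shifts = NULL, posteriorCut = 0.5,
                      mergeGap = 2L, minLength = 4L, noiseFloor = 0.15) {
  stopifnot(is(fp, "Footprint"))
  post <- hmm$posterior
  mi <- footprintMi(fp)
  stopifnot(length(post) == length(mi))
  empty <- data.frame(promoter_id = character(), condition = character(),
                      start = integer(), end = integer(),
                      offset_start = integer(), offset_end = integer(),
                      mean_mi = numeric(), posterior = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  flag <- post > posteriorCut
  if (!any(flag)) return(empty)
  segs <- .runsFromLogical(flag)
  ## merge segments separated by <= mergeGap
  if (nrow(segs) > 1L) {
    keep <- list(segs[1L, ])
    for (i in 2L:nrow(segs)) {
      last <- keep[[length(keep)]]
      if (segs$start[i] - last$end - 1L <= mergeGap) {
        keep[[length(keep)]]$end <- segs$end[i]
      } else keep[[length(keep) + 1L]] <- segs[i, ]
    }
    segs <- do.call(rbind, keep)
  }
  segs <- segs[segs$end - segs$start + 1L >= minLength, , drop = FALSE]
  if (!nrow(segs)) return(empty)
  cov <- footprintCoverage(fp)
  L <- length(mi)
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    sel <- segs$start[i]:segs$end[i]
    sgn <- NA_character_
    if (!is.null(shifts)) {
      sh <- shifts[, sel, drop = FALSE]
      ## mean over mutant cells, weighted by positional mutant coverage
      pos_mean <- apply(sh, 2L, function(col) {
        v <- col[is.finite(col) & col != 0]
        if (length(v)) mean(v) else NA_real_
      })
      w <- cov[sel]
      okp <- is.finite(pos_mean) & w > 0
      m <- if (any(okp)) sum(pos_mean[okp] * w[okp]) / sum(w[okp]) else NA_real_
      sgn <- if (!is.finite(m)) NA_character_
             else if (abs(m) < noiseFloor) "mixed"
             else if (m > 0) "repressor-like" else "activator-like"
    }
    data.frame(promoter_id = fp@promoterId, condition = fp@condition,
               start = segs$start[i], end = segs$end[i],
               offset_start = if (L == windowLength())
                 indexToOffset(segs$start[i]) else segs$start[i],
               offset_end = if (L == windowLength())
                 indexToOffset(segs$end[i]) else segs$end[i],
               mean_mi = mean(mi[sel]), posterior = mean(post[sel]),
               sign = sgn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discover and call sites for one footprint
#'
#' Convenience wrapper: classify, and when the footprint is active with
#' sites, fit the HMM and call sites.
#'
#' @inheritParams callSites
#' @param cfg a [classifierConfig()].
#' @param ... passed to [callSites()].
#' @return list with \code{classification} and \code{calls} (empty for
#'   non-active classes).
#' @export
discoverSites <- function(fp, shifts = NULL, cfg = classifierConfig(), ...) {
  cls <- classifyFootprint(fp, cfg)
  calls <- data.frame(promoter_id = character(), condition = character(),
                      start = integer(), end = integer(),
                      offset_start = integer(), offset_end = integer(),
                      mean_mi = numeric(), posterior = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  if (cls$class == "active_with_sites") {
    hmm <- fitTwoStateHMM(fp)
    calls <- callSites(fp, hmm, shifts, ...)
  }
  list(classification = cls, calls = calls)
}

## --------------------------------------------------------------------------
## Emergent -10 element (TATAAT) rule
## --------------------------------------------------------------------------

.TATAAT_IMPORTANT <- c(1L, 2L, 6L)
.TATAAT_CONS <- c("T", "A", "T")

.matchesImportant <- function(hexamer) {
  all(hexamer[.TATAAT_IMPORTANT] == .TATAAT_CONS)
}

#' Single-mutation emergent -10 elements
#'
#' The sigma70 -10 element has consensus TATAAT, with positions 1, 2 and 6
#' dominating binding. A single substitution is reported as creating a
#' candidate -10 element when, in at least one of the six hexamer frames
#' covering the mutated base, all three important positions match the
#' consensus after the substitution but not before.
#'
#' \code{scanTssCreation()} enumerates the rule over every possible single
#' substitution of a sequence; \code{detectEmergentTss()} restricts it to a
#' classified spike position and to substitutions with strongly positive
#' expression shift.
#'
#' @param sequence wild-type window sequence (character).
#' @param position 1-based position of the classified MI spike.
#' @param shifts matrix from [expressionShiftMatrix()]; substitutions with
#'   shift \code{>= shiftFloor} are candidates (use \code{shifts = NULL} to
#'   test all three substitutions).
#' @param shiftFloor minimum log2 shift for a substitution to count.
#' @return data.frame with one row per (substitution, frame) event:
#'   \code{position}, \code{wildtype_base}, \code{creating_base},
#'   \code{frame_start}, \code{hexamer_before}, \code{hexamer_after}.
#' @export
detectEmergentTss <- function(sequence, position, shifts = NULL,
                              shiftFloor = 0.5) {
  sequence <- as.character(sequence)
  .checkDna(sequence)
  chars <- .seqToChars(sequence)
  L <- length(chars)
  stopifnot(position >= 1L, position <= L)
  wt_b <- chars[position]
  cand <- setdiff(DNA_BASES, wt_b)
  if (!is.null(shifts)) {
    sh <- shifts[cand, position]
    cand <- cand[is.finite(sh) & sh >= shiftFloor]
  }
  rows <- list()
  for (b in cand) {
    for (j in 1L:6L) {          # j = position of the mutation inside the hexamer
      fs <- position - j + 1L
      if (fs < 1L || fs + 5L > L) next   # truncated frame at the window edge
      hex_before <- chars[fs:(fs + 5L)]
      hex_after <- hex_before
      hex_after[j] <- b
      if (.matchesImportant(hex_after) && !.matchesImportant(hex_before)) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = position, wildtype_base = wt_b, creating_base = b,
          frame_start = fs,
          hexamer_before = paste(hex_before, collapse = ""),
          hexamer_after = paste(hex_after, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(position = integer(), wildtype_base = character(),
                      creating_base = character(), frame_start = integer(),
                      hexamer_before = character(), hexamer_after = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @rdname detectEmergentTss
#' @export
scanTssCreation <- function(sequence) {
  sequence <- as.character(sequence)
  L <- nchar(sequence)
  out <- lapply(seq_len(L), function(p)
    detectEmergentTss(sequence, p, shifts = NULL))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write site calls as a BED-like table
#'
#' Promoter-relative intervals; when the promoter's genomic anchor is given,
#' genome-projected coordinates are added.
#'
#' @param calls data.frame from [callSites()].
#' @param path output TSV path.
#' @param region optional [PromoterRegion-class] supplying the genomic anchor.
#' @return invisibly, the path.
#' @export
writeSiteCalls <- function(calls, path, region = NULL) {
  out <- calls
  if (!is.null(region) && nrow(calls)) {
    tss <- region@tss
    if (region@strand == "+") {
      out$genome_start <- tss - windowUpstream() + calls$start - 1L
      out$genome_end <- tss - windowUpstream() + calls$end - 1L
    } else {
      out$genome_start <- tss + windowUpstream() - (calls$end - 1L)
      out$genome_end <- tss + windowUpstream() - (calls$start - 1L)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
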