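## Promoter window geometry. Windows span 115 bases upstream of the
## transcription start site (TSS) and 45 bases downstream; positions are
## labelled -115..-1, +1..+45 with no position 0 and +1 at the TSS base.

#' @rdname promoterOffsets
#' @export
windowUpstream <- function() 115L

#' @rdname promoterOffsets
#' @export
windowDownstream <- function() 45L

#' @rdname promoterOffsets
#' @export
windowLength <- function() windowUpstream() + windowDownstream()

#' Promoter window coordinate labels
#'
#' The per-base labels of a TSS-anchored promoter window: \code{-115..-1}
#' upstream, \code{+1..+45} downstream, no position 0, \code{+1} at the TSS
#' base. \code{offsetToIndex()} and \code{indexToOffset()} convert between
#' these labels and 1-based indices into the 160-base window.
#'
#' @param offset integer vector of window labels (no zeros).
#' @param index integer vector of 1-based window indices.
#' @return \code{promoterOffsets()}: integer vector of length 160.
#' @examples
#' offsetToIndex(c(-115L, -1L, 1L, 45L))
#' indexToOffset(c(1L, 115L, 116L, 160L))
#' @export
promoterOffsets <- function() {
  c(seq.int(-windowUpstream(), -1L), seq.int(1L, windowDownstream()))
}

#' @rdname promoterOffsets
#' @export
offsetToIndex <- function(offset) {
  offset <- as.integer(offset)
  if (any(offset == 0L)) stop("promoter offsets have no position 0")
  if (any(offset < -windowUpstream() | offset > windowDownstream()))
    stop("offset outside the -115..+45 window")
  ifelse(offset < 0L, offset + windowUpstream() + 1L, offset + windowUpstream())
}

#' @rdname promoterOffsets
#' @export
indexToOffset <- function(index) {
  index <- as.integer(index)
  if (any(index < 1L | index > windowLength()))
    stop("index outside 1..160")
  ifelse(index <= windowUpstream(), index - windowUpstream() - 1L,
         index - windowUpstream())
}

DNA_BASES <- c("A", "C", "G", "T")

## row b: the three substitution alternatives to base b
.ALT_BASES <- t(vapply(DNA_BASES,
                       function(b) setdiff(DNA_BASES, b), character(3)))

.checkDna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(what, " contains characters outside {A,C,G,T}")
  invisible(x)
}
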