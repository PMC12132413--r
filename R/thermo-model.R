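#' Construct an energy matrix
#'
#' @param epsilon numeric 4 x L matrix of binding-energy contributions in kT;
#'   rows are taken in order A, C, G, T (rownames are set if absent).
#' @param referenceEnergy scalar offset in kT (default 0).
#' @return an [EnergyMatrix-class].
#' @examples
#' em <- energyMatrix(matrix(0, 4, 6))
#' @export
energyMatrix <- function(epsilon, referenceEnergy = 0) {
  epsilon <- as.matrix(epsilon)
  if (is.null(rownames(epsilon))) rownames(epsilon) <- DNA_BASES
  new("EnergyMatrix", epsilon = epsilon, referenceEnergy = referenceEnergy)
}

#' Energy matrix with a given consensus sequence
#'
#' Gauged so the consensus base contributes 0 kT at every position and each
#' mismatch adds \code{mismatchPenalty} kT (scalar or per-position vector).
#'
#' @param consensus DNA string defining the zero-energy sequence.
#' @param mismatchPenalty kT penalty per mismatched base.
#' @param referenceEnergy scalar offset in kT.
#' @return an [EnergyMatrix-class].
#' @export
consensusEnergyMatrix <- function(consensus, mismatchPenalty = 2,
                                  referenceEnergy = 0) {
  .checkDna(consensus, "consensus")
  b <- .seqToChars(consensus)
  L <- length(b)
  pen <- rep_len(mismatchPenalty, L)
  eps <- matrix(rep(pen, each = 4L), nrow = 4L,
                dimnames = list(DNA_BASES, NULL))
  eps[cbind(match(b, DNA_BASES), seq_len(L))] <- 0
  energyMatrix(eps, referenceEnergy)
}

#' Construct a regulatory site
#'
#' @param siteId identifier.
#' @param kind \code{"rnap"}, \code{"activator"} or \code{"repressor"}.
#' @param start,end inclusive site span, given as window offsets on the
#'   -115..+45 axis (no 0) by default, or as 1-based window indices when
#'   \code{coords = "index"}.
#' @param matrix an [EnergyMatrix-class] of width \code{end - start + 1}
#'   (offsets spanning 0 are collapsed accordingly).
#' @param weight dimensionless copy-number factor.
#' @param omega RNAP-cooperativity factor (activators > 1; repressors must be
#'   1).
#' @param coords \code{"offset"} (default) or \code{"index"}.
#' @return a [RegSite-class].
#' @examples
#' em <- consensusEnergyMatrix(strrep("A", 15))
#' regSite("rep1", "repressor", -60, -46, em, weight = 10)
#' @export
regSite <- function(siteId, kind, start, end, matrix, weight = 1,
                    omega = if (kind == "activator") 5 else 1,
                    coords = c("offset", "index")) {
  coords <- match.arg(coords)
  if (coords == "offset") {
    start <- offsetToIndex(start)
    end <- offsetToIndex(end)
  }
  new("RegSite", siteId = siteId, kind = kind,
      start = as.integer(start), end = as.integer(end),
      matrix = matrix, weight = weight, omega = omega)
}

#' Construct a regulatory architecture
#'
#' @param promoterId promoter identifier.
#' @param sites list of [regSite()] objects (exactly one of kind
#'   \code{"rnap"}).
#' @param conditionActivity numeric matrix (conditions x sites, values in
#'   [0,1]) with rownames naming conditions; columns may be named by site id
#'   or are taken in site order. The RNAP column is conventionally 1.
#' @return a [RegArchitecture-class].
#' @export
regArchitecture <- function(promoterId, sites, conditionActivity) {
  ids <- vapply(sites, function(s) s@siteId, character(1))
  conditionActivity <- as.matrix(conditionActivity)
  if (is.null(colnames(conditionActivity))) {
    colnames(conditionActivity) <- ids
  } else {
    conditionActivity <- conditionActivity[, ids, drop = FALSE]
  }
  new("RegArchitecture", promoterId = promoterId, sites = sites,
      conditionActivity = conditionActivity)
}

#' Binding energy of a site on a sequence
#'
#' Additive model: the site's reference energy plus the sum over site
#' positions of the energy-matrix entry selected by the sequence base. A
#' single substitution therefore changes the energy by exactly
#' \code{eps[new, i] - eps[old, i]}.
#'
#' @param sequence variant sequence (character) covering the site span.
#' @param site a [RegSite-class].
#' @return binding energy in kT.
#' @examples
#' em <- consensusEnergyMatrix("AAAA", mismatchPenalty = 1)
#' s <- regSite("s", "repressor", 1, 4, em, coords = "index")
#' siteEnergy("AATA", s)  # one mismatch -> 1 kT
#' @export
siteEnergy <- function(sequence, site) {
  stopifnot(is(site, "RegSite"))
  sequence <- as.character(sequence)
  if (nchar(sequence) < site@end)
    stop("sequence window is shorter than the site span")
  b <- .seqToChars(substr(sequence, site@start, site@end))
  eps <- site@matrix@epsilon
  e <- site@matrix@referenceEnergy +
    sum(eps[cbind(match(b, DNA_BASES), seq_along(b))])
  if (!is.finite(e)) stop("non-finite site energy")
  e
}

## Boltzmann weights of every site for a batch of sequences.
## Returns a matrix variants x sites of w * exp(-E).
.siteBoltzmann <- function(sequences, sites) {
  n <- length(sequences)
  out <- matrix(NA_real_, n, length(sites))
  seqmat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  for (j in seq_along(sites)) {
    s <- sites[[j]]
    eps <- s@matrix@epsilon
    cols <- s@start:s@end
    E <- rep(s@matrix@referenceEnergy, n)
    for (k in seq_along(cols)) {
      E <- E + eps[cbind(match(seqmat[, cols[k]], DNA_BASES), k)]
    }
    if (any(!is.finite(E))) stop("non-finite site energy")
    out[, j] <- s@weight * exp(-E)
  }
  colnames(out) <- vapply(sites, function(s) s@siteId, character(1))
  out
}

#' Expression rate of a promoter variant under a thermodynamic model
#'
#' Occupancy of RNA polymerase at the promoter in the canonical
#' thermodynamic model. With \eqn{p = w_P e^{-E_P(s)}} the polymerase
#' Boltzmann weight, repressors excluding polymerase competitively,
#' \eqn{r = \sum_j a_j w_j e^{-E_j(s)}}, and activators stabilizing
#' polymerase through a cooperativity factor \eqn{\omega_k} in the
#' simple-activation limit,
#' \deqn{\omega_{eff} = 1 + \sum_k a_k \frac{w_k e^{-E_k(s)}
#'   (\omega_k - 1)}{1 + w_k e^{-E_k(s)}},}
#' the bound probability is
#' \deqn{p_{bound} = \frac{p\,\omega_{eff}}{1 + p\,\omega_{eff} + r}.}
#' Condition-dependent allostery enters through the activities
#' \eqn{a_j \in [0,1]} given by the architecture's activity map.
#'
#' @param sequence one variant sequence, or a character vector of sequences.
#' @param arch a [RegArchitecture-class].
#' @param condition condition name (a row of the activity map).
#' @return numeric vector of \eqn{p_{bound}} values in (0, 1].
#' @examples
#' em0 <- energyMatrix(matrix(0, 4, 4))
#' rnap <- regSite("rnap", "rnap", 1, 4, em0, weight = 0.1, coords = "index")
#' arch <- regArchitecture("p", list(rnap),
#'   matrix(1, 1, 1, dimnames = list("c1", "rnap")))
#' expressionRate(strrep("A", 4), arch, "c1")  # 0.1 / 1.1
#' @export
expressionRate <- function(sequence, arch, condition) {
  stopifnot(is(arch, "RegArchitecture"))
  act <- arch@conditionActivity
  if (!condition %in% rownames(act))
    stop("unknown condition: ", condition)
  a <- act[condition, ]
  sites <- arch@sites
  kinds <- vapply(sites, function(s) s@kind, character(1))
  W <- .siteBoltzmann(as.character(sequence), sites)
  p <- W[, which(kinds == "rnap"), drop = TRUE]
  r <- 0
  for (j in which(kinds == "repressor")) r <- r + a[j] * W[, j]
  omega_eff <- 1
  for (j in which(kinds == "activator")) {
    wj <- W[, j]
    omega_eff <- omega_eff + a[j] * wj * (sites[[j]]@omega - 1) / (1 + wj)
  }
  unname(p * omega_eff / (1 + p * omega_eff + r))
}
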