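## Two-state Gaussian hidden Markov model for footprint segmentation.
##
## Observations are log-transformed mutual information values; state 0 is
## background (low MI), state 1 is a binding site (high MI). Fitting is
## Baum-Welch EM with scaled forward-backward recursions.

.hmmEmissions <- function(y, means, sds) {
  cbind(dnorm(y, means[1], sds[1]), dnorm(y, means[2], sds[2]))
}

#' Forward-backward posterior of a two-state Gaussian HMM
#'
#' Scaled forward-backward recursions returning per-position posterior state
#' probabilities and the observation log-likelihood.
#'
#' @param y numeric observation vector.
#' @param initial length-2 initial state distribution.
#' @param transition 2x2 row-stochastic transition matrix.
#' @param means,sds length-2 Gaussian emission parameters.
#' @return list with \code{posterior} (length(y) x 2 matrix),
#'   \code{logLik}, and \code{xi} (summed pairwise transition posteriors,
#'   2x2, for EM).
#' @export
hmmForwardBackward <- function(y, initial, transition, means, sds) {
  Tn <- length(y)
  B <- .hmmEmissions(y, means, sds)
  B <- pmax(B, .Machine$double.xmin)
  alpha <- matrix(0, Tn, 2L); beta <- matrix(0, Tn, 2L)
  scale <- numeric(Tn)
  a <- initial * B[1L, ]
  scale[1L] <- sum(a)
  alpha[1L, ] <- a / scale[1L]
  for (t in 2L:Tn) {
    a <- (alpha[t - 1L, ] %*% transition) * B[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta[Tn, ] <- 1
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    b <- transition %*% (B[t + 1L, ] * beta[t + 1L, ])
    beta[t, ] <- b / scale[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, 2L, 2L)
  if (Tn > 1L) for (t in 1L:(Tn - 1L)) {
    m <- outer(alpha[t, ], B[t + 1L, ] * beta[t + 1L, ]) * transition /
      scale[t + 1L]
    xi <- xi + m
  }
  list(posterior = gamma, logLik = sum(log(scale)), xi = xi)
}

#' Fit a two-state HMM to a footprint
#'
#' Baum-Welch EM with Gaussian emissions on \code{log(mi + floor)}.
#' Initialization splits the observations at their 25th/90th percentiles
#' (background/site emission means); EM stops when the log-likelihood gain
#' drops below \code{tol} or after \code{maxIter} iterations. States are
#' labelled so that state 2 ("site") has the larger emission mean. When the
#' fit degenerates (emission means collapse or a state receives no mass), a
#' fallback segmentation thresholds the footprint at its 90th percentile and
#' the result is flagged \code{degenerate = TRUE}.
#'
#' @param fp a [Footprint-class] or numeric MI vector.
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @param logFloor added to MI before the log transform.
#' @return list of class \code{"TwoStateHMM"} with elements \code{initial},
#'   \code{transition}, \code{means}, \code{sds} (emission parameters on the
#'   log scale), \code{posterior} (site-state probability per position),
#'   \code{logLik} (trace over iterations), \code{degenerate}.
#' @export
fitTwoStateHMM <- function(fp, tol = 1e-6, maxIter = 500L, logFloor = 1e-8) {
  x <- if (is(fp, "Footprint")) footprintMi(fp) else fp
  y <- log(x + logFloor)
  Tn <- length(y)
  q <- quantile(y, c(0.25, 0.9), names = FALSE)
  means <- c(q[1], q[2])
  s0 <- sd(y)
  fallback <- function() {
    thr <- quantile(x, 0.9, names = FALSE)
    post <- as.numeric(x > thr)
    structure(list(initial = c(1, 0), transition = diag(2),
                   means = means, sds = c(s0, s0),
                   posterior = post, logLik = NA_real_,
                   degenerate = TRUE),
              class = "TwoStateHMM")
  }
  if (!is.finite(s0) || s0 < 1e-12 || means[2] - means[1] < 1e-9)
    return(fallback())
  sds <- c(s0, s0)
  initial <- c(0.9, 0.1)
  transition <- matrix(c(0.95, 0.05, 0.10, 0.90), 2L, byrow = TRUE)
  ll_trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    fb <- hmmForwardBackward(y, initial, transition, means, sds)
    ll_trace <- c(ll_trace, fb$logLik)
    g <- fb$posterior
    w <- colSums(g)
    if (any(w < 1e-8)) return(fallback())
    new_means <- colSums(g * y) / w
    new_sds <- sqrt(pmax(colSums(g * (outer(y, new_means, "-"))^2) / w, 1e-6))
    new_trans <- fb$xi / rowSums(fb$xi)
    new_init <- g[1L, ]
    means <- new_means; sds <- new_sds
    transition <- new_trans; initial <- new_init
    if (abs(means[2] - means[1]) < 1e-9) return(fallback())
    if (it > 1L && ll_trace[it] - ll_trace[it - 1L] < tol) break
  }
  ## label states so "site" (index 2) has the larger emission mean
  if (means[1] > means[2]) {
    means <- rev(means); sds <- rev(sds); initial <- rev(initial)
    transition <- transition[2:1, 2:1]
  }
  fb <- hmmForwardBackward(y, initial, transition, means, sds)
  structure(list(initial = initial, transition = transition,
                 means = means, sds = sds,
                 posterior = fb$posterior[, 2L],
                 logLik = ll_trace, degenerate = FALSE),
            class = "TwoStateHMM")
}

#' @export
print.TwoStateHMM <- function(x, ...) {
  cat("Two-state Gaussian HMM",
      if (x$degenerate) "(degenerate fit; threshold fallback)" else "", "\n")
  cat(sprintf("  emission means (log MI): background %.3f, site %.3f\n",
              x$means[1], x$means[2]))
  cat(sprintf("  self-transition: background %.3f, site %.3f\n",
              x$transition[1, 1], x$transition[2, 2]))
  invisible(x)
}
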