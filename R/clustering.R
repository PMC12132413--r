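## Clustering of regulatory responses across growth conditions.
##
## Rows are condition x replicate footprints; distance is 1 - Pearson
## correlation, linkage is average (UPGMA). Both are scale-free in the MI
## values, so clustering is invariant to per-row affine rescaling.

#' Replicate correlation QC
#'
#' Pearson correlation between replicate footprints of each condition,
#' mirroring the replicate QC of multi-condition reporter experiments: a
#' replicate pair correlating below \code{floor} flags the condition for an
#' additional replicate, and a replicate whose within-condition correlation
#' is poor while its partner correlates better with the remaining experiments
#' is flagged for exclusion.
#'
#' @param footprints named list of numeric MI vectors (or
#'   [Footprint-class] objects); names like \code{"condition.replicate"}, or
#'   supply \code{conditions} explicitly.
#' @param conditions character vector assigning each footprint to a
#'   condition; defaults to the part of each name before the last ".".
#' @param floor correlation floor below which a pair is flagged (default
#'   0.3).
#' @return list with \code{correlation} (full Pearson matrix across all
#'   footprints), \code{pairs} (data.frame: condition, r, flagged) and
#'   \code{exclude} (names of replicates suggested for exclusion).
#' @export
replicateCorrelation <- function(footprints, conditions = NULL, floor = 0.3) {
  vecs <- lapply(footprints, function(f)
    if (is(f, "Footprint")) footprintMi(f) else f)
  nm <- names(vecs)
  if (is.null(nm)) stop("footprints must be named")
  if (is.null(conditions)) conditions <- sub("\\.[^.]*$", "", nm)
  X <- do.call(cbind, vecs)
  degenerate <- apply(X, 2L, sd) < 1e-12
  R <- suppressWarnings(cor(X))
  rows <- list(); exclude <- character()
  for (cond in unique(conditions)) {
    idx <- which(conditions == cond)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      i <- idx[a]; j <- idx[b]
      r <- R[i, j]
      flagged <- !is.finite(r) || r < floor
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, rep_a = nm[i], rep_b = nm[j],
        r = r, flagged = flagged, stringsAsFactors = FALSE)
      if (flagged) {
        others <- setdiff(seq_len(ncol(X)), idx)
        if (length(others)) {
          ens_i <- mean(R[i, others], na.rm = TRUE)
          ens_j <- mean(R[j, others], na.rm = TRUE)
          worse <- if (!is.finite(ens_i)) nm[i]
                   else if (!is.finite(ens_j)) nm[j]
                   else if (ens_i < ens_j) nm[i] else nm[j]
          exclude <- union(exclude, worse)
        }
      }
    }
  }
  exclude <- union(exclude, nm[degenerate])
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), rep_a = character(),
               rep_b = character(), r = numeric(), flagged = logical(),
               stringsAsFactors = FALSE)
  list(correlation = R, pairs = pairs, exclude = exclude)
}

.clusterRows <- function(X, k = NULL, h = NULL) {
  if (nrow(X) < 2L) stop("need at least two rows to cluster")
  keep <- apply(X, 1L, sd) >= 1e-12
  if (!all(keep))
    warning(sum(!keep), " constant rows dropped before clustering")
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2L) stop("fewer than two non-degenerate rows")
  d <- as.dist(1 - cor(t(X)))
  hc <- hclust(d, method = "average")
  labels <- if (!is.null(k)) cutree(hc, k = k)
            else if (!is.null(h)) cutree(hc, h = h)
            else cutree(hc, h = 0.5)
  list(tree = hc, labels = labels, cophenetic = cophenetic(hc),
       distance = d)
}

#' Cluster one promoter's footprints across conditions
#'
#' Hierarchical clustering (correlation distance, average linkage) of the
#' promoter's footprints over the conditions in which binding sites were
#' found. Conditions not classified \code{active_with_sites} are excluded
#' before clustering.
#'
#' @param footprints named list of footprints (numeric vectors or
#'   [Footprint-class]) across conditions for one promoter.
#' @param classes optional character vector of footprint classes parallel to
#'   \code{footprints}; only \code{"active_with_sites"} rows enter. Default:
#'   classify with [classifyFootprint()].
#' @param cfg [classifierConfig()] used when \code{classes} is missing.
#' @param k,h flat-cut parameters passed to [stats::cutree()] (count or
#'   height; default height 0.5).
#' @return a \code{ClusterResult} list (\code{tree}, \code{labels},
#'   \code{cophenetic}, \code{distance}), or a list with \code{reason} when
#'   fewer than two conditions are eligible.
#' @export
clusterPromoterConditions <- function(footprints, classes = NULL,
                                      cfg = classifierConfig(),
                                      k = NULL, h = NULL) {
  vecs <- lapply(footprints, function(f)
    if (is(f, "Footprint")) footprintMi(f) else f)
  if (is.null(classes))
    classes <- vapply(vecs, function(v) classifyFootprint(v, cfg)$class,
                      character(1))
  eligible <- classes == "active_with_sites"
  if (sum(eligible) < 2L)
    return(list(tree = NULL, labels = NULL, cophenetic = NULL,
                reason = sprintf("only %d conditions with binding sites",
                                 sum(eligible))))
  X <- do.call(rbind, vecs[eligible])
  rownames(X) <- names(vecs)[eligible]
  .clusterRows(X, k = k, h = h)
}

#' Assemble the global condition-by-position footprint matrix
#'
#' One row per condition x replicate, columns the concatenated window
#' positions of all promoters. Missing promoter x condition footprints
#' (promoters silent in a condition) are filled with zeros by default,
#' preserving the "silent here" signal; \code{fill = NA} masks them instead.
#'
#' @param footprints list of [Footprint-class] objects (any promoters,
#'   conditions, replicates).
#' @param fill value for missing promoter x condition blocks (0 or NA).
#' @return numeric matrix with dimnames; rows \code{condition.replicate},
#'   column blocks of width 160 per promoter.
#' @export
conditionMatrix <- function(footprints, fill = 0) {
  proms <- unique(vapply(footprints, function(f) f@promoterId, character(1)))
  rows <- unique(vapply(footprints, function(f)
    paste(f@condition, f@replicate, sep = "."), character(1)))
  L <- windowLength()
  X <- matrix(fill, nrow = length(rows), ncol = length(proms) * L,
              dimnames = list(rows, paste(rep(proms, each = L),
                                          rep(promoterOffsets(), length(proms)),
                                          sep = ":")))
  for (f in footprints) {
    r <- paste(f@condition, f@replicate, sep = ".")
    j0 <- (match(f@promoterId, proms) - 1L) * L
    X[r, (j0 + 1L):(j0 + L)] <- footprintMi(f)
  }
  X
}

#' Cluster all conditions globally
#'
#' Row clustering of the global footprint matrix (correlation distance,
#' average linkage), plus the nearest-neighbour structure used to check that
#' replicate rows pair together.
#'
#' @param X matrix from [conditionMatrix()].
#' @param k,h flat-cut parameters (see [clusterPromoterConditions()]).
#' @return a \code{ClusterResult} list with the extra element
#'   \code{nearest_neighbor}: named character vector giving each row's
#'   nearest row by correlation distance.
#' @export
clusterGlobal <- function(X, k = NULL, h = NULL) {
  if (!nrow(X)) stop("empty condition matrix")
  res <- .clusterRows(X, k = k, h = h)
  D <- as.matrix(res$distance)
  diag(D) <- Inf
  res$nearest_neighbor <- setNames(colnames(D)[apply(D, 1L, which.min)],
                                   rownames(D))
  res
}

#' Export a clustering result
#'
#' Writes the linkage tree as Newick text and the flat labels as TSV.
#'
#' @param result a \code{ClusterResult} from [clusterGlobal()] or
#'   [clusterPromoterConditions()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeClusterResult <- function(result, prefix) {
  stopifnot(!is.null(result$tree))
  nwk <- paste0(prefix, "_tree.nwk")
  ape::write.tree(ape::as.phylo(result$tree), file = nwk)
  lab <- paste0(prefix, "_clusters.tsv")
  utils::write.table(
    data.frame(row = names(result$labels), cluster = result$labels),
    lab, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(newick = nwk, labels = lab))
}

#' Heatmap of the global condition matrix
#'
#' @param X matrix from [conditionMatrix()].
#' @param ... passed to [stats::heatmap()].
#' @return invisibly, \code{NULL}.
#' @export
plotConditionHeatmap <- function(X, ...) {
  stats::heatmap(X, Rowv = NULL, Colv = NA, scale = "none",
                 distfun = function(m) as.dist(1 - cor(t(m))),
                 hclustfun = function(d) hclust(d, method = "average"),
                 labCol = NA, ...)
  invisible(NULL)
}
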