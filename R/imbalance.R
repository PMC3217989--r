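## Two-stage representative negative-sample selection.
##
## Stage 1 condenses each hairpin's negatives by k-NN density: the
## densest sample is kept and everything inside its k-NN radius deleted,
## until the group is exhausted. Stage 2 iteratively adds, per hairpin,
## the negative that most misleads the current model (highest prediction
## deviation), retraining once per sweep, until every hairpin is
## predicted correctly or exhausted.

#' Euclidean distance between two encoded samples
#'
#' @param vx,vi numeric vectors of equal dimension.
#' @return Nonnegative distance; zero iff the vectors are equal.
#' @export
sampleDistance <- function(vx, vi) {
  if (length(vx) != length(vi)) stop("dimension mismatch")
  sqrt(sum((vx - vi)^2))
}

#' k-NN radius of a sample within its group
#'
#' @param x numeric matrix, one row per negative sample of the group.
#' @param i row index of the query sample.
#' @param k neighbour count; must be smaller than the group size.
#' @return Distance from row i to its k-th nearest other row.
#' @export
knnRadius <- function(x, i, k) {
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the group size")
  d <- sqrt(rowSums((x[-i, , drop = FALSE] -
                     matrix(x[i, ], n - 1L, ncol(x), byrow = TRUE))^2))
  sort(d, method = "radix")[k]
}

logHypersphereVolume <- function(m, r) {
  if (r <= 0) return(-Inf)
  (m / 2) * log(pi) - lgamma(m / 2 + 1) + m * log(r)
}

#' k-NN density estimate of a sample
#'
#' The local density is the number of group members inside the
#' hypersphere reaching the k-th neighbour, divided by the total negative
#' count L and the hypersphere volume. The volume is evaluated in log
#' space so the estimate survives the ~700-dimensional encoded space;
#' within a group (fixed k, L, m) ordering by the density equals ordering
#' by descending neighbour count then ascending radius.
#'
#' @inheritParams knnRadius
#' @param L total number of negative samples in the whole negative space.
#' @param log return the log density.
#' @return Density (or log density). A zero radius (duplicated points)
#'   yields +Inf.
#' @export
knnDensity <- function(x, i, k, L = nrow(x), log = FALSE) {
  r <- knnRadius(x, i, k)
  d <- sqrt(rowSums((x - matrix(x[i, ], nrow(x), ncol(x), byrow = TRUE))^2))
  g <- sum(d[-i] <= r)
  logf <- base::log(g) - base::log(L) - logHypersphereVolume(ncol(x), r)
  if (log) logf else exp(logf)
}

#' Stage-1 negative selection by k-NN density condensation
#'
#' Processes each hairpin's negatives independently: repeatedly select
#' the sample with maximal density, then delete every sample within its
#' k-NN radius, recomputing on the shrunken group, until the group is
#' empty. Groups of at most k samples are kept whole (the radius is
#' undefined there). Density ties (zero radius among duplicates) are
#' broken by the larger neighbour count, then the smaller candidate
#' start.
#'
#' @param x numeric matrix of encoded negative samples (all groups).
#' @param groups group id (pre-miRNA id) per row.
#' @param k neighbour count; the published default is 11.
#' @param starts optional candidate start per row, used for tie-breaking
#'   (defaults to the row order).
#' @return Logical vector over rows: TRUE for selected samples. The
#'   \code{"degenerate_groups"} attribute counts groups kept whole.
#' @export
stage1Select <- function(x, groups, k = 11L, starts = seq_len(nrow(x))) {
  stopifnot(nrow(x) == length(groups), nrow(x) == length(starts))
  selected <- logical(nrow(x))
  degenerate <- 0L
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) <= k) {
      selected[idx] <- TRUE
      degenerate <- degenerate + 1L
      next
    }
    D <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
    remain <- seq_along(idx)
    while (length(remain) > 0L) {
      if (length(remain) <= k) {
        selected[idx[remain]] <- TRUE
        break
      }
      sub <- D[remain, remain, drop = FALSE]
      rk <- vapply(seq_along(remain), function(a)
        sort(sub[a, -a], method = "radix")[k], numeric(1L))
      gcount <- vapply(seq_along(remain), function(a)
        sum(sub[a, -a] <= rk[a]), numeric(1L))
      m <- ncol(x)
      logf <- log(gcount) -
        ((m / 2) * log(pi) - lgamma(m / 2 + 1) + m * log(rk))
      logf[rk == 0] <- Inf
      ord <- order(-logf, -gcount, starts[idx[remain]])
      pick <- ord[1L]
      selected[idx[remain[pick]]] <- TRUE
      drop <- sub[pick, ] <= rk[pick]
      drop[pick] <- TRUE
      remain <- remain[!drop]
    }
  }
  attr(selected, "degenerate_groups") <- degenerate
  selected
}

#' Prediction deviation of a negative sample
#'
#' The score of the negative minus the best positive score of its
#' hairpin; positive values mean the negative outranks every real duplex.
#'
#' @param scoreNeg score of the negative candidate.
#' @param positiveScores scores of the hairpin's real duplex(es).
#' @return The deviation sigma.
#' @export
predictionDeviation <- function(scoreNeg, positiveScores) {
  if (length(positiveScores) == 0L) stop("at least one positive score required")
  scoreNeg - max(positiveScores)
}

#' Stage-2 iterative selection of misleading negatives
#'
#' Starting from all positives plus the stage-1 negatives, repeatedly:
#' train a model on the current training set, score every candidate, and
#' for each hairpin not yet terminated add the unselected negative with
#' the highest positive prediction deviation. A hairpin terminates when
#' its top-scored candidate is a real duplex (or none of its remaining
#' negatives outranks the positives), or when all its negatives have been
#' selected. The model is retrained once per sweep.
#'
#' @param x encoded matrix of all candidates (the validation set V).
#' @param labels "real"/"pseudo" per row.
#' @param groups hairpin id per row.
#' @param stage1Idx row indices of the stage-1 selected negatives.
#' @param trainer function(x, labels) returning an object scorable with
#'   [decisionValues()] (e.g. a wrapper around [svmTrain()]).
#' @param maxIter sweep cap (the exhaustion bound can be large).
#' @return list with \code{trainIdx} (row indices of the final training
#'   set U), \code{iterations}, \code{terminated} (named logical per
#'   group) and \code{audit} (data.frame of iteration, group, row, sigma).
#' @export
stage2Select <- function(x, labels, groups, stage1Idx, trainer,
                         maxIter = 50L) {
  pos <- which(labels == "real")
  if (!length(pos)) stop("no positive samples")
  U <- sort(unique(c(pos, stage1Idx)))
  gids <- unique(groups)
  terminated <- stats::setNames(rep(FALSE, length(gids)), gids)
  audit <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    model <- trainer(x[U, , drop = FALSE], labels[U])
    scores <- decisionValues(model, x)
    added <- integer(0L)
    for (g in gids[!terminated]) {
      idx <- which(groups == g)
      topRow <- idx[which.max(scores[idx])]
      if (labels[topRow] == "real") { terminated[g] <- TRUE; next }
      gpos <- idx[labels[idx] == "real"]
      if (!length(gpos)) { terminated[g] <- TRUE; next }
      negOut <- setdiff(idx[labels[idx] == "pseudo"], U)
      if (!length(negOut)) { terminated[g] <- TRUE; next }
      sigma <- scores[negOut] - max(scores[gpos])
      best <- which.max(sigma)
      if (sigma[best] > 0) {
        added <- c(added, negOut[best])
        audit[[length(audit) + 1L]] <-
          data.frame(iteration = iter, group = g, row = negOut[best],
                     sigma = sigma[best])
      } else {
        terminated[g] <- TRUE
      }
    }
    U <- sort(unique(c(U, added)))
    if (all(terminated) || length(added) == 0L || iter >= maxIter) break
  }
  list(trainIdx = U, iterations = iter, terminated = terminated,
       audit = if (length(audit)) do.call(rbind, audit)
               else data.frame(iteration = integer(), group = character(),
                               row = integer(), sigma = numeric()))
}
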