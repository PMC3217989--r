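## Position-deviation evaluation: E(x), P(y), distance distributions,
## grouped cross-validation and the top-k comparison protocol.

#' Signed position deviation
#'
#' @param predicted predicted mature start(s).
#' @param actual actual mature start(s) (recycled).
#' @return predicted - actual: negative when the prediction lies
#'   upstream (in front) of the actual miRNA.
#' @export
positionDeviation <- function(predicted, actual) {
  predicted - actual
}

#' Mean absolute position deviation E
#'
#' @param deviations signed deviations, one per evaluated pre-miRNA.
#' @return Mean of |x_i| in nt; smaller is more accurate.
#' @export
averageDeviation <- function(deviations) {
  if (length(deviations) == 0L) stop("empty deviation vector")
  mean(abs(deviations))
}

#' Functional-strand prediction accuracy P
#'
#' @param flags 0/1 (or logical) per pre-miRNA: 1 when the predicted
#'   miRNA lies on the functional strand.
#' @return Percentage in [0, 100].
#' @export
strandAccuracy <- function(flags) {
  if (length(flags) == 0L) stop("empty flag vector")
  flags <- as.numeric(flags)
  if (!all(flags %in% c(0, 1))) stop("flags must be 0/1")
  100 * sum(flags) / length(flags)
}

#' Cumulative distance distribution
#'
#' @param deviations signed deviations.
#' @param bins distance cut-offs in nt.
#' @return Named numeric vector: percentage of pre-miRNAs with
#'   |deviation| <= d for each bin d (weakly increasing).
#' @export
distanceDistribution <- function(deviations, bins = c(0L, 1L, 2L, 4L, 6L, 8L)) {
  if (length(deviations) == 0L) stop("empty deviation vector")
  out <- vapply(bins, function(d) 100 * mean(abs(deviations) <= d),
                numeric(1L))
  names(out) <- paste0("±", bins, " nt")
  names(out)[bins == 0L] <- "0 nt"
  out
}

#' Minimum deviation among the top-k candidates
#'
#' The comparison protocol against genome-scale predictors reports, per
#' hairpin, the smallest distance between any of the k best-scored
#' candidates and any actual mature start.
#'
#' @param result a \code{predictionResult} from [predictHairpin()].
#' @param actualStarts annotated mature start(s) of the hairpin.
#' @param k how many top candidates to consider.
#' @return Minimum |predicted - actual| in nt (non-increasing in k).
#' @export
topkMinDeviation <- function(result, actualStarts, k = 10L) {
  if (is.null(result$ranked) || nrow(result$ranked) == 0L)
    stop("result has no candidates")
  top <- result$ranked$mirna_start[seq_len(min(k, nrow(result$ranked)))]
  min(abs(outer(top, actualStarts, "-")))
}

#' Build an evaluation report from per-hairpin predictions
#'
#' For hairpins with several mature miRNAs the deviation is computed
#' against the nearest true start on the predicted arm (falling back to
#' the nearest true start overall when no annotation shares the arm);
#' the strand flag compares the top-1 arm with the arm of the nearest
#' true miRNA.
#'
#' @param predictions list of \code{predictionResult}s.
#' @param annotations data.frame (premirna_id, mirna_start) of true
#'   starts; arms are taken from the matching enumerated candidates when
#'   available.
#' @param trueArms optional data.frame (premirna_id, mirna_start, arm)
#'   giving the arm of each annotated miRNA.
#' @return list of class \code{evalReport}: N, E, P, bins, deviations.
#' @export
evalReport <- function(predictions, annotations, trueArms = NULL) {
  devs <- numeric(0L)
  flags <- numeric(0L)
  for (res in predictions) {
    if (!is.null(res$reason)) next
    id <- res$top1$premirna_id
    truth <- annotations[annotations$premirna_id == id, , drop = FALSE]
    if (nrow(truth) == 0L) next
    starts <- truth$mirna_start
    arms <- if (!is.null(trueArms)) {
      ta <- trueArms[trueArms$premirna_id == id, , drop = FALSE]
      ta$arm[match(starts, ta$mirna_start)]
    } else rep(NA_character_, length(starts))
    p <- res$top1$mirna_start
    sameArm <- which(arms == res$top1$arm)
    cand <- if (length(sameArm)) starts[sameArm] else starts
    a <- cand[which.min(abs(p - cand))]
    devs <- c(devs, positionDeviation(p, a))
    nearest <- which.min(abs(p - starts))
    flags <- c(flags, as.numeric(is.na(arms[nearest]) ||
                                 arms[nearest] == res$top1$arm))
  }
  structure(list(N = length(devs),
                 E = averageDeviation(devs),
                 P = strandAccuracy(flags),
                 bins = distanceDistribution(devs),
                 deviations = devs),
            class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat("evalReport over ", x$N, " pre-miRNAs\n", sep = "")
  cat("  E = ", format(x$E, digits = 4), " nt,  P = ",
      format(x$P, digits = 4), "%\n", sep = "")
  cat("  |deviation| <= d: ",
      paste(names(x$bins), format(x$bins, digits = 3), sep = ": ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Grouped 10-fold cross-validation of the full pipeline
#'
#' Partitions hairpins (not candidates) into folds; for each fold the
#' training pipeline of [runTrain()] is executed on the remaining
#' hairpins and the held-out hairpins are predicted and scored.
#'
#' @param hairpins list of [PremiRNA-class] objects.
#' @param annotations annotation data.frame (premirna_id, mirna_start).
#' @param config a [runConfig()].
#' @param backend folding backend.
#' @param folds number of folds (default 10).
#' @param seed RNG seed controlling the fold assignment.
#' @return An \code{evalReport} aggregated over all folds.
#' @export
tenFoldCV <- function(hairpins, annotations, config = runConfig(),
                      backend = NULL, folds = 10L, seed = 1L) {
  ids <- vapply(hairpins, premirnaId, character(1L))
  if (length(ids) < folds) stop("need at least as many hairpins as folds")
  foldId <- groupFolds(ids, folds, seed)[as.character(ids)]
  preds <- list()
  for (f in seq_len(folds)) {
    trainSet <- hairpins[foldId != f]
    testSet <- hairpins[foldId == f]
    fit <- runTrain(trainSet,
                    annotations[annotations$premirna_id %in% ids[foldId != f], ],
                    config, backend)
    for (p in testSet)
      preds[[premirnaId(p)]] <- predictHairpin(p, fit$model, backend,
                                               config$thresholds)
  }
  evalReport(preds, annotations)
}
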