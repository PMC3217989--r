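## End-to-end pipeline: configuration, training, prediction.

#' Pipeline configuration
#'
#' Bundles every parameter of the training/prediction pipeline. The
#' plant profile uses 21-nt windows; the animal profile 22-nt windows.
#'
#' @param species "plant" or "animal"; sets the window length.
#' @param flank_len flanking region length for positional features.
#' @param use_mfe include the three duplex-energy features (the default,
#'   completing the published feature set); requires a folding backend
#'   (RNAfold) at train and predict time. Set FALSE for a folder-free
#'   pipeline on constructed structures.
#' @param thresholds candidate [filterThresholds()].
#' @param n_triplet triplet survivors for [composeSubset()] (default 14,
#'   the 86-feature plant subset at a 6-nt flank).
#' @param lambda5,lambda3 optional per-arm information-gain thresholds;
#'   supplying both switches the subset to threshold selection.
#' @param bins quantile bins for information gain.
#' @param k stage-1 neighbour count.
#' @param maxIter stage-2 sweep cap.
#' @param tune run [gridSearch()] for (C, gamma) on the selected
#'   training set (the default, as in the published pipeline); when
#'   FALSE, \code{cost}/\code{gamma} are used directly.
#' @param cost,gamma provisional SVM parameters, used by the stage-2
#'   trainer and as the final parameters when \code{tune = FALSE};
#'   \code{gamma = NULL} means 1/dimension.
#' @param costGrid,gammaGrid,tuneFolds grid-search controls.
#' @param seed RNG seed for fold assignments.
#' @return A list of class \code{runConfig}; element \code{feature} holds
#'   the derived [featureConfig()].
#' @export
runConfig <- function(species = c("plant", "animal"), flank_len = 6L,
                      use_mfe = TRUE, thresholds = filterThresholds(),
                      n_triplet = 14L, lambda5 = NULL, lambda3 = NULL,
                      bins = 10L, k = 11L, maxIter = 50L,
                      tune = TRUE, cost = 1, gamma = NULL,
                      costGrid = 2^seq(-5, 15, by = 4),
                      gammaGrid = 2^seq(-15, 3, by = 4),
                      tuneFolds = 3L, seed = 1L) {
  species <- match.arg(species)
  window_len <- if (species == "plant") 21L else 22L
  feature <- featureConfig(window_len, flank_len,
                           mfe_flanks = if (use_mfe) c(0L, 3L, 6L)
                                        else integer(0L))
  structure(c(as.list(environment())), class = "runConfig")
}

#' @export
print.runConfig <- function(x, ...) {
  cat("runConfig: ", x$species, " (window ", x$window_len, " nt, flank ",
      x$flank_len, " nt, MFE ", if (x$use_mfe) "on" else "off", ")\n",
      "  subset: ", if (!is.null(x$lambda5)) "lambda thresholds"
                    else paste0("top-", x$n_triplet, " triplets"),
      ";  stage-1 k = ", x$k, ";  SVM ",
      if (x$tune) "grid-tuned" else sprintf("C = %g", x$cost), "\n",
      sep = "")
  invisible(x)
}

## Enumerate, filter and label the candidates of a hairpin list.
collectCandidates <- function(hairpins, annotations, config) {
  out <- vector("list", length(hairpins))
  for (i in seq_along(hairpins)) {
    pre <- hairpins[[i]]
    anatomy <- annotateAnatomy(pre)
    cc <- enumerateCandidates(pre, config$window_len, anatomy)
    cc <- filterCandidates(cc, anatomy, config$thresholds)
    starts <- annotations$mirna_start[
      annotations$premirna_id == premirnaId(pre)]
    out[[i]] <- list(cands = labelCandidates(cc, as.integer(starts),
                                             length(pre)),
                     anatomy = anatomy)
  }
  out
}

#' Train the full pipeline on annotated hairpins
#'
#' Enumerates and filters duplex candidates, labels them against the
#' annotations, extracts all features, composes the feature subset by
#' information gain, condenses the negatives in two stages and fits the
#' final RBF-SVM.
#'
#' @param hairpins list of [PremiRNA-class] objects.
#' @param annotations data.frame (premirna_id, mirna_start) of true
#'   mature starts.
#' @param config a [runConfig()].
#' @param backend folding backend; required when \code{config$use_mfe}.
#' @return list with \code{model} ([TrainedModel-class]), \code{subset},
#'   \code{table} (the labelled feature table), \code{stage1Idx},
#'   \code{stage2} (audit from [stage2Select()]), \code{cost},
#'   \code{gamma} and \code{tuning} (grid, when tuned).
#' @export
runTrain <- function(hairpins, annotations, config = runConfig(),
                     backend = NULL) {
  if (config$use_mfe && is.null(backend)) backend <- viennaBackend()
  cfg <- config$feature
  parts <- collectCandidates(hairpins, annotations, config)
  tabs <- lapply(seq_along(hairpins), function(i)
    extractFeatureTable(parts[[i]]$cands, hairpins[[i]], cfg, backend,
                        parts[[i]]$anatomy, mfe = config$use_mfe))
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  if (!any(table$label == "real"))
    stop("no annotated real duplex survives candidate filtering")

  subset <- composeSubset(table, cfg, n_triplet = config$n_triplet,
                          lambda5 = config$lambda5,
                          lambda3 = config$lambda3, bins = config$bins)
  enc <- encodeNumeric(table, subset)
  labels <- table$label
  groups <- table$premirna_id

  negIdx <- which(labels == "pseudo")
  sel <- stage1Select(enc[negIdx, , drop = FALSE], groups[negIdx],
                      k = config$k, starts = table$mirna_start[negIdx])
  stage1Idx <- negIdx[sel]

  ## Stage 2 runs with the provisional parameters; the grid search then
  ## selects (C, gamma) on the final training set, scoring held-out
  ## hairpins over all their candidates (the actual prediction task).
  cost <- config$cost
  gamma <- if (is.null(config$gamma)) 1 / ncol(enc) else config$gamma
  trainer <- function(xx, ll) svmTrain(xx, ll, cost = cost, gamma = gamma)
  s2 <- stage2Select(enc, labels, groups, stage1Idx, trainer,
                     maxIter = config$maxIter)
  U <- s2$trainIdx
  tuning <- NULL
  if (config$tune) {
    tuning <- gridSearch(enc[U, , drop = FALSE], labels[U], groups[U],
                         costGrid = config$costGrid,
                         gammaGrid = config$gammaGrid,
                         folds = config$tuneFolds, seed = config$seed,
                         evalX = enc, evalLabels = labels,
                         evalGroups = groups,
                         evalStarts = table$mirna_start)
    cost <- tuning$cost
    gamma <- tuning$gamma
  }
  model <- svmTrain(enc[U, , drop = FALSE], labels[U],
                    cost = cost, gamma = gamma, subset = subset,
                    config = cfg)
  list(model = model, subset = subset, table = table,
       stage1Idx = stage1Idx, stage2 = s2, cost = cost, gamma = gamma,
       tuning = tuning)
}

#' Predict mature start positions for a set of hairpins
#'
#' @param hairpins list of (or a single) [PremiRNA-class] object(s).
#' @param model a [TrainedModel-class] from [runTrain()] / [loadModel()].
#' @param backend folding backend when the model uses energy features.
#' @param thresholds candidate [filterThresholds()].
#' @param topk top candidates to report per hairpin.
#' @return Named list of \code{predictionResult}s (see
#'   [predictHairpin()]).
#' @export
runPredict <- function(hairpins, model, backend = NULL,
                       thresholds = filterThresholds(), topk = 10L) {
  if (methods::is(hairpins, "PremiRNA")) hairpins <- list(hairpins)
  out <- lapply(hairpins, predictHairpin, model = model, backend = backend,
                thresholds = thresholds, topk = topk)
  names(out) <- vapply(hairpins, premirnaId, character(1L))
  out
}

#' Summarise predictions as a table
#'
#' @param predictions list of \code{predictionResult}s.
#' @return data.frame with one row per hairpin: id, predicted start, arm,
#'   score (NA rows for hairpins without surviving candidates).
#' @export
predictionTable <- function(predictions) {
  rows <- lapply(names(predictions), function(id) {
    p <- predictions[[id]]
    if (!is.null(p$reason))
      data.frame(premirna_id = id, mirna_start = NA_integer_,
                 arm = NA_character_, score = NA_real_)
    else
      data.frame(premirna_id = id, mirna_start = p$top1$mirna_start,
                 arm = p$top1$arm, score = p$top1$score)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
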