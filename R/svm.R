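## RBF-SVM training, decision-value scoring and candidate ranking.
##
## Training solves the soft-margin dual through libSVM (e1071); scoring
## is done by the package itself as the plain kernel expansion
## f(x) = sum_i alpha_i z_i K(x_i, x) + b, so that a model serialized to
## JSON and reloaded reproduces scores bit for bit.

#' RBF kernel
#'
#' K(u, v) = exp(-gamma * ||u - v||^2).
#'
#' @param u,v numeric vectors of equal dimension.
#' @param gamma positive kernel width.
#' @return Kernel value in (0, 1].
#' @export
rbfKernel <- function(u, v, gamma) {
  if (gamma <= 0) stop("gamma must be positive")
  if (length(u) != length(v)) stop("dimension mismatch")
  exp(-gamma * sum((u - v)^2))
}

## cross kernel matrix K[i, j] = K(x[i, ], y[j, ])
rbfKernelMatrix <- function(x, y, gamma) {
  sq <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  sq[sq < 0] <- 0
  exp(-gamma * sq)
}

normalizeLabels <- function(labels) {
  z <- as.character(labels)
  z[z %in% c("1", "+1", "real", "TRUE")] <- "real"
  z[z %in% c("-1", "pseudo", "FALSE")] <- "pseudo"
  if (!all(z %in% c("real", "pseudo")))
    stop("labels must be real/pseudo (or +1/-1)")
  factor(z, levels = c("real", "pseudo"))
}

#' Train an RBF-SVM duplex classifier
#'
#' Fits the soft-margin dual (tolerance 1e-3) on encoded samples; real
#' duplexes are the positive class, so positive decision values rank a
#' candidate as more miRNA-like.
#'
#' @param x numeric sample matrix (rows = encoded candidates).
#' @param labels "real"/"pseudo" (or +1/-1) per row; both classes must be
#'   present.
#' @param cost soft-margin penalty C.
#' @param gamma RBF kernel width; default 1/ncol(x).
#' @param subset optional \code{featureSubset} recorded in the model.
#' @param config optional [featureConfig()] recorded in the model.
#' @return A [TrainedModel-class].
#' @export
svmTrain <- function(x, labels, cost = 1, gamma = 1 / ncol(x),
                     subset = list(), config = list()) {
  z <- normalizeLabels(labels)
  if (nlevels(droplevels(z)) < 2L)
    stop("both classes required for training")
  fit <- e1071::svm(x, z, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE,
                    tolerance = 1e-3)
  coefs <- as.numeric(fit$coefs)
  b <- -fit$rho
  ## libSVM's decision value is positive for the first internal label;
  ## flip so that positive always means "real"
  if (fit$levels[fit$labels[1L]] != "real") {
    coefs <- -coefs
    b <- -b
  }
  new("TrainedModel", sv = unname(as.matrix(fit$SV)), coefs = coefs,
      b = b, gamma = gamma, cost = cost,
      subset = unclass(subset), config = unclass(config))
}

#' Decision values of a trained model
#'
#' @param model a [TrainedModel-class].
#' @param x numeric matrix (or single vector) of encoded candidates.
#' @return Numeric vector of decision values; positive favours "real".
#' @export
decisionValues <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  K <- rbfKernelMatrix(x, model@sv, model@gamma)
  as.vector(K %*% model@coefs + model@b)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Assign whole groups to cv folds, balancing fold sizes.
groupFolds <- function(groups, folds, seed) {
  gids <- unique(groups)
  if (folds > length(gids)) stop("fold count exceeds group count")
  perm <- withSeed(seed, sample(gids))
  fold <- rep(seq_len(folds), length.out = length(perm))
  stats::setNames(fold, perm)[as.character(groups)]
}

## Per-group top-1 accuracy and, when candidate start positions are
## supplied, the mean absolute deviation of the top-scored candidate's
## start from the (nearest) real candidate's start.
top1Stats <- function(scores, labels, groups, starts = NULL) {
  gids <- unique(groups)
  hit <- logical(length(gids))
  dev <- rep(NA_real_, length(gids))
  for (i in seq_along(gids)) {
    idx <- which(groups == gids[i])
    topIdx <- idx[which.max(scores[idx])]
    hit[i] <- labels[topIdx] == "real"
    if (!is.null(starts)) {
      trueStarts <- starts[idx[labels[idx] == "real"]]
      if (length(trueStarts))
        dev[i] <- min(abs(starts[topIdx] - trueStarts))
    }
  }
  c(accuracy = mean(hit),
    deviation = if (all(is.na(dev))) NA_real_ else mean(dev, na.rm = TRUE))
}

#' Grid search for the SVM parameters (C, gamma)
#'
#' Exhaustively evaluates the parameter grid by group-aware
#' cross-validation: all candidates of a pre-miRNA stay in one fold, and
#' the model selection metric is the top-1 position accuracy (the
#' fraction of held-out hairpins whose highest-scored candidate is the
#' real duplex) -- under the ~1:89 class imbalance, sample-level accuracy
#' would be a meaningless surrogate. Because top-1 accuracy over a few
#' dozen held-out hairpins is coarse (many grid points tie exactly),
#' accuracy ties are broken by the mean absolute deviation of the
#' top-scored candidate's start from the real start (a finer-grained
#' reading of the same ranking task, available when \code{evalStarts} is
#' supplied), then by the smaller C, then the smaller gamma.
#'
#' @param x encoded training sample matrix (e.g. the selected training
#'   set after stage-2).
#' @param labels "real"/"pseudo" per row.
#' @param groups hairpin id per row.
#' @param costGrid,gammaGrid parameter grids (duplicates are ignored).
#' @param folds number of cross-validation folds.
#' @param seed RNG seed for the fold assignment.
#' @param evalX,evalLabels,evalGroups optional evaluation pool: when
#'   given, the held-out fold is scored on these rows (all candidates of
#'   the held-out hairpins, not only the selected ones), matching the
#'   prediction task. Defaults to the training rows.
#' @param evalStarts optional candidate start position per evaluation
#'   row; enables the mean-deviation tie-break.
#' @param refine after the coarse pass, re-search a finer grid (factor
#'   2 steps) around the best point, as in the usual coarse-then-fine
#'   grid search procedure.
#' @return list(cost, gamma, accuracy, deviation, grid) where \code{grid}
#'   tabulates the cross-validated accuracy and mean deviation of every
#'   evaluated combination.
#' @export
gridSearch <- function(x, labels, groups,
                       costGrid = 2^seq(-5, 15, by = 4),
                       gammaGrid = 2^seq(-15, 3, by = 4),
                       folds = 5L, seed = 1L,
                       evalX = x, evalLabels = labels,
                       evalGroups = groups, evalStarts = NULL,
                       refine = TRUE) {
  if (!length(costGrid) || !length(gammaGrid)) stop("empty parameter grid")
  z <- normalizeLabels(labels)
  ez <- normalizeLabels(evalLabels)
  gids <- unique(groups)
  if (folds > length(gids)) stop("fold count exceeds group count")
  foldOf <- stats::setNames(rep(seq_len(folds),
                                length.out = length(gids)),
                            withSeed(seed, sample(gids)))
  foldId <- foldOf[as.character(groups)]
  evalFold <- foldOf[as.character(evalGroups)]   # NA: group never trained on
  cvScore <- function(cost, gamma) {
    accs <- numeric(folds)
    devs <- rep(NA_real_, folds)
    for (f in seq_len(folds)) {
      tr <- foldId != f
      if (length(unique(z[tr])) < 2L)
        return(c(accuracy = NA_real_, deviation = NA_real_))
      model <- svmTrain(x[tr, , drop = FALSE], z[tr],
                        cost = cost, gamma = gamma)
      te <- which(!is.na(evalFold) & evalFold == f)
      st <- top1Stats(decisionValues(model, evalX[te, , drop = FALSE]),
                      as.character(ez[te]), evalGroups[te],
                      evalStarts[te])
      accs[f] <- st[["accuracy"]]
      devs[f] <- st[["deviation"]]
    }
    c(accuracy = mean(accs),
      deviation = if (all(is.na(devs))) NA_real_ else mean(devs, na.rm = TRUE))
  }
  better <- function(acc, dev, best) {
    if (is.na(acc)) return(FALSE)
    if (acc > best$accuracy + 1e-12) return(TRUE)
    if (acc < best$accuracy - 1e-12) return(FALSE)
    ## exact accuracy tie: prefer the smaller mean deviation
    !is.na(dev) && !is.na(best$deviation) && dev < best$deviation - 1e-12
  }
  evalCombos <- function(combos, grid, best) {
    for (r in seq_len(nrow(combos))) {
      done <- any(abs(log2(grid$cost) - log2(combos$cost[r])) < 1e-9 &
                  abs(log2(grid$gamma) - log2(combos$gamma[r])) < 1e-9)
      if (done) next
      sc <- cvScore(combos$cost[r], combos$gamma[r])
      grid <- rbind(grid, data.frame(cost = combos$cost[r],
                                     gamma = combos$gamma[r],
                                     accuracy = sc[["accuracy"]],
                                     deviation = sc[["deviation"]]))
      if (better(sc[["accuracy"]], sc[["deviation"]], best))
        best <- list(cost = combos$cost[r], gamma = combos$gamma[r],
                     accuracy = sc[["accuracy"]],
                     deviation = sc[["deviation"]])
    }
    list(grid = grid, best = best)
  }
  ## gamma varies fastest, cost slowest: with strict-improvement updates
  ## this realizes the tie-break "smaller C, then smaller gamma"
  coarse <- expand.grid(gamma = sort(unique(gammaGrid)),
                        cost = sort(unique(costGrid)),
                        KEEP.OUT.ATTRS = FALSE)[, c("cost", "gamma")]
  state <- evalCombos(coarse,
                      data.frame(cost = numeric(), gamma = numeric(),
                                 accuracy = numeric(), deviation = numeric()),
                      list(cost = coarse$cost[1L], gamma = coarse$gamma[1L],
                           accuracy = -Inf, deviation = Inf))
  if (refine) {
    fine <- expand.grid(gamma = state$best$gamma * 2^(-2:2),
                        cost = state$best$cost * 2^(-2:2),
                        KEEP.OUT.ATTRS = FALSE)[, c("cost", "gamma")]
    state <- evalCombos(fine, state$grid, state$best)
  }
  c(state$best, list(grid = state$grid))
}

#' Score and rank the duplex candidates of one pre-miRNA
#'
#' Runs the full prediction chain on a hairpin: enumerate candidates,
#' filter by anatomy, extract features with the model's configuration,
#' encode with the model's subset and rank by decision value (ties broken
#' by the smaller start).
#'
#' @param pre a [PremiRNA-class] object.
#' @param model a [TrainedModel-class] carrying subset + config.
#' @param backend folding backend for the energy features.
#' @param thresholds candidate [filterThresholds()].
#' @param topk how many top candidates to report (default 10, the
#'   protocol used for tool comparisons).
#' @return list of class \code{predictionResult}: \code{ranked} (ordered
#'   candidate data.frame with scores), \code{top1}, \code{perArm} (best
#'   candidate of each arm) and \code{topk}; or an empty result with a
#'   \code{reason} when no candidate survives.
#' @export
predictHairpin <- function(pre, model, backend = NULL,
                           thresholds = filterThresholds(), topk = 10L) {
  cfgArgs <- model@config[c("window_len", "flank_len", "mfe_flanks",
                            "linker_len")]
  cfg <- do.call(featureConfig, cfgArgs[!vapply(cfgArgs, is.null, logical(1L))])
  if (is.null(backend) && length(cfg$mfe_flanks)) backend <- viennaBackend()
  anatomy <- annotateAnatomy(pre)
  cands <- enumerateCandidates(pre, cfg$window_len, anatomy)
  cands <- filterCandidates(cands, anatomy, thresholds)
  if (nrow(cands) == 0L) {
    return(structure(list(ranked = cands, top1 = NULL, perArm = NULL,
                          topk = cands, reason = "no surviving candidate"),
                     class = "predictionResult"))
  }
  feat <- extractFeatureTable(cands, pre, cfg, backend, anatomy)
  enc <- encodeNumeric(feat, model@subset)
  scores <- decisionValues(model, enc)
  ord <- order(-scores, cands$mirna_start)
  ranked <- cands[ord, , drop = FALSE]
  ranked$score <- scores[ord]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  perArm <- do.call(rbind, lapply(split(ranked, ranked$arm),
                                  function(d) d[1L, , drop = FALSE]))
  structure(list(ranked = ranked, top1 = ranked[1L, , drop = FALSE],
                 perArm = perArm,
                 topk = ranked[seq_len(min(topk, nrow(ranked))), , drop = FALSE],
                 reason = NULL),
            class = "predictionResult")
}

#' @export
print.predictionResult <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("predictionResult: ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  cat("predictionResult for '", x$top1$premirna_id, "': ",
      nrow(x$ranked), " candidates\n", sep = "")
  cat("  top-1 start: ", x$top1$mirna_start, " (", x$top1$arm,
      " arm, score ", format(x$top1$score, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Save / load a trained model as JSON
#'
#' The model file stores the support vectors, coefficients, kernel
#' parameters and the feature subset + encoding at full floating-point
#' precision, so scoring after a reload is exactly reproducible.
#'
#' @param model a [TrainedModel-class].
#' @param path output path.
#' @export
saveModel <- function(model, path) {
  ## doubles are written as "%.17g" strings: JSON numeric output keeps
  ## only 15 significant digits, which breaks bit-identical reloads
  num <- function(x) { s <- sprintf("%.17g", x); dim(s) <- dim(x); s }
  subset <- model@subset
  if (!is.null(subset$scaling))
    subset$scaling <- lapply(subset$scaling, num)
  payload <- list(
    format = "mirpos-model-1",
    cost = num(model@cost), gamma = num(model@gamma), b = num(model@b),
    coefs = num(model@coefs), sv = num(model@sv),
    subset = subset, config = model@config
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname saveModel
#' @return \code{loadModel} returns the [TrainedModel-class].
#' @export
loadModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "mirpos-model-1"))
    stop("not a recognised model file")
  subset <- p$subset
  if (!is.null(subset$scaling))
    subset$scaling <- lapply(subset$scaling, function(s)
      stats::setNames(as.numeric(s), c("min", "max")))
  sv <- as.matrix(p$sv)
  sv <- matrix(as.numeric(sv), nrow = nrow(sv))
  new("TrainedModel", sv = sv, coefs = as.numeric(p$coefs),
      b = as.numeric(p$b), gamma = as.numeric(p$gamma),
      cost = as.numeric(p$cost), subset = subset, config = p$config)
}
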