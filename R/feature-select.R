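## Information-gain feature ranking, subset composition, numeric encoding.

#' Shannon entropy of a discrete column
#'
#' @param values vector of discrete values (factors, strings, integers).
#' @return Entropy in bits; 0 for a constant column.
#' @examples
#' shannonEntropy(c(1, 1, -1, -1))  # 1 bit
#' @export
shannonEntropy <- function(values) {
  if (length(values) == 0L) stop("empty column")
  p <- table(values) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

discretizeColumn <- function(x, bins = 10L) {
  if (!is.numeric(x)) return(as.character(x))
  ux <- unique(x)
  if (length(ux) <= bins) return(as.character(x))
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                                   names = FALSE, type = 7))
  as.character(cut(x, breaks = breaks, include.lowest = TRUE))
}

#' Information gain of a feature with respect to the class
#'
#' IG(c, x) = H(c) - H(c | x), the reduction in class entropy achieved by
#' knowing the feature. Continuous features are discretized by
#' equal-frequency binning (default 10 bins) before the conditional
#' entropy is computed.
#'
#' @param featureCol feature values (categorical or numeric).
#' @param classCol class labels, same length (e.g. "real"/"pseudo").
#' @param bins number of quantile bins for continuous features.
#' @return Information gain in bits (>= 0 up to floating point).
#' @export
informationGain <- function(featureCol, classCol, bins = 10L) {
  if (length(featureCol) != length(classCol))
    stop("feature and class columns must have equal length")
  x <- discretizeColumn(featureCol, bins)
  hc <- shannonEntropy(classCol)
  cond <- 0
  for (v in unique(x)) {
    idx <- x == v
    cond <- cond + mean(idx) * shannonEntropy(classCol[idx])
  }
  max(0, hc - cond)
}

tripletFeatureNames <- function() {
  c(paste0("miRNA_", tripletPatterns()),
    paste0("miRNAstar_", tripletPatterns()))
}

numericBlockNames <- function(cfg = featureConfig()) {
  c("dis", "miRNA_5end", "miRNAstar_5end", mfeNames(cfg))
}

positionalFeatureNames <- function(cfg = featureConfig()) {
  setdiff(featureNames(cfg), c(tripletFeatureNames(), numericBlockNames(cfg)))
}

igOnPartition <- function(table, feats, bins) {
  if (nrow(table) == 0L)
    return(stats::setNames(rep(0, length(feats)), feats))
  vapply(feats, function(f) informationGain(table[[f]], table$label, bins),
         numeric(1L))
}

## Hairpins are partitioned by the arm carrying their real miRNA(s);
## hairpins with miRNAs on both arms contribute to both partitions.
armPartitionIds <- function(table) {
  real <- table[table$label == "real", c("premirna_id", "arm")]
  list(`5p` = unique(real$premirna_id[real$arm == "5p"]),
       `3p` = unique(real$premirna_id[real$arm == "3p"]))
}

#' Compose a feature subset
#'
#' Mirrors the published selection policy: keep every position-specific
#' feature at the configured flank length (66 at 6 nt) and all six
#' numeric features (dis, the two 5'-end codes, MFE_1..3); from the 64
#' triplet structure features keep only the informative ones. Triplet
#' survivors are chosen either as the \code{n_triplet} top-ranked by
#' information gain (the shipped plant policy keeps 14, giving the
#' 86-feature plant subset), or by information-gain thresholds applied
#' per arm partition (a feature survives when its IG on the 5'-arm
#' hairpins exceeds \code{lambda5} or its IG on the 3'-arm hairpins
#' exceeds \code{lambda3}).
#'
#' The returned subset also stores the numeric encoding specification:
#' categorical position symbols are one-hot encoded over the 10-symbol
#' alphabet and numeric features are linearly scaled to [-1, 1] using the
#' min/max of the supplied (training) table.
#'
#' @param table feature table from [extractFeatureTable()] with labels.
#' @param cfg the [featureConfig()] the table was extracted with.
#' @param n_triplet number of triplet features to keep (default 14).
#' @param lambda5,lambda3 per-arm information-gain thresholds; supplying
#'   them switches to threshold selection (use \code{-Inf} to keep all 64
#'   and \code{Inf} to keep none).
#' @param bins quantile bins for IG of continuous features.
#' @return A list of class \code{featureSubset} with elements
#'   \code{features}, \code{ig}, \code{categorical}, \code{numeric},
#'   \code{alphabet}, \code{scaling} and \code{provenance}.
#' @export
composeSubset <- function(table, cfg = featureConfig(), n_triplet = 14L,
                          lambda5 = NULL, lambda3 = NULL, bins = 10L) {
  posNames <- positionalFeatureNames(cfg)
  tripNames <- tripletFeatureNames()
  numNames <- numericBlockNames(cfg)
  missing <- setdiff(c(posNames, tripNames, numNames), names(table))
  if (length(missing))
    stop("table does not cover the feature inventory; missing e.g. ",
         missing[1L])

  igAll <- igOnPartition(table, c(posNames, tripNames, numNames), bins)

  if (!is.null(lambda5) || !is.null(lambda3)) {
    if (is.null(lambda5) || is.null(lambda3))
      stop("both lambda5 and lambda3 must be set for arm-split selection")
    arms <- armPartitionIds(table)
    ig5 <- igOnPartition(table[table$premirna_id %in% arms$`5p`, , drop = FALSE],
                         tripNames, bins)
    ig3 <- igOnPartition(table[table$premirna_id %in% arms$`3p`, , drop = FALSE],
                         tripNames, bins)
    keepTrip <- tripNames[ig5 > lambda5 | ig3 > lambda3]
    prov <- sprintf("lambda(%.4g, %.4g)", lambda5, lambda3)
  } else {
    ord <- order(-igAll[tripNames], tripNames)
    keepTrip <- tripNames[ord][seq_len(min(n_triplet, length(tripNames)))]
    keepTrip <- keepTrip[order(match(keepTrip, tripNames))]
    prov <- if (cfg$window_len == 21L && cfg$flank_len == 6L &&
                n_triplet == 14L) "default-plant-86"
            else sprintf("top-%d-triplet", n_triplet)
  }

  features <- c(posNames, keepTrip, numNames)
  numericFeats <- c(keepTrip, numNames)
  scaling <- lapply(numericFeats, function(f) {
    x <- table[[f]]
    c(min = min(x), max = max(x))
  })
  names(scaling) <- numericFeats

  structure(list(
    features = features,
    ig = igAll,
    categorical = posNames,
    numeric = numericFeats,
    alphabet = positionAlphabet(gap = TRUE),
    scaling = scaling,
    provenance = prov,
    window_len = cfg$window_len,
    flank_len = cfg$flank_len
  ), class = "featureSubset")
}

#' @export
print.featureSubset <- function(x, ...) {
  nTrip <- sum(x$features %in% tripletFeatureNames())
  cat("featureSubset (", x$provenance, "): ", length(x$features),
      " features (", length(x$categorical), " positional, ", nTrip,
      " triplet, ", length(x$numeric) - nTrip, " numeric)\n", sep = "")
  invisible(x)
}

#' Numeric encoding dimension of a subset
#'
#' @param subset a \code{featureSubset}.
#' @return Integer dimension of encoded vectors (one-hot categorical
#'   slots plus scaled numeric features).
#' @export
encodedDimension <- function(subset) {
  length(subset$categorical) * length(subset$alphabet) +
    length(subset$numeric)
}

#' Encode a feature table numerically for the SVM
#'
#' Categorical position symbols become one-hot vectors over the
#' 10-symbol alphabet; numeric features are linearly mapped to [-1, 1]
#' using the training min/max stored in the subset (constant training
#' columns map to 0). Encoding is deterministic and the dimension is
#' fixed by the subset.
#'
#' @param table feature table (rows to encode).
#' @param subset a \code{featureSubset} from [composeSubset()].
#' @return Numeric matrix, one row per input row.
#' @export
encodeNumeric <- function(table, subset) {
  miss <- setdiff(subset$features, names(table))
  if (length(miss))
    stop("missing feature column(s): ", paste(utils::head(miss, 3L),
                                              collapse = ", "))
  n <- nrow(table)
  alpha <- subset$alphabet
  nCat <- length(subset$categorical)
  catIdx <- matrix(0L, n, nCat)
  for (j in seq_len(nCat)) {
    v <- match(table[[subset$categorical[j]]], alpha)
    if (anyNA(v))
      stop("unseen position symbol in feature '", subset$categorical[j], "'")
    catIdx[, j] <- v
  }
  catMat <- matrix(0, n, nCat * length(alpha))
  for (j in seq_len(nCat)) {
    off <- (j - 1L) * length(alpha)
    catMat[cbind(seq_len(n), off + catIdx[, j])] <- 1
  }
  numMat <- matrix(0, n, length(subset$numeric))
  for (j in seq_along(subset$numeric)) {
    f <- subset$numeric[j]
    sc <- subset$scaling[[f]]
    x <- as.numeric(table[[f]])
    if (sc["max"] > sc["min"])
      numMat[, j] <- 2 * (x - sc["min"]) / (sc["max"] - sc["min"]) - 1
  }
  out <- cbind(catMat, numMat)
  colnames(out) <- c(as.vector(t(outer(subset$categorical, alpha, paste,
                                       sep = "="))),
                     subset$numeric)
  out
}

#' Information-gain report for a feature table
#'
#' @param table labelled feature table.
#' @param cfg the [featureConfig()] used for extraction.
#' @param bins quantile bins for continuous features.
#' @return data.frame with per-feature IG on the 5'-arm hairpins, the
#'   3'-arm hairpins and the full table.
#' @export
informationGainReport <- function(table, cfg = featureConfig(), bins = 10L) {
  feats <- featureNames(cfg)
  arms <- armPartitionIds(table)
  data.frame(
    feature = feats,
    IG_5parm = igOnPartition(table[table$premirna_id %in% arms$`5p`, ,
                                   drop = FALSE], feats, bins),
    IG_3parm = igOnPartition(table[table$premirna_id %in% arms$`3p`, ,
                                   drop = FALSE], feats, bins),
    IG_all = igOnPartition(table, feats, bins),
    row.names = NULL, check.names = FALSE
  )
}
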