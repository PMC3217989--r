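## Synthetic pre-miRNA hairpins with a planted miRNA:miRNA* duplex.
##
## A hairpin is assembled from S stem elements (paired or mismatched,
## with occasional 1-3 nt bulges outside the planted duplex) around a
## short terminal loop. The planted duplex occupies L + 2 consecutive
## stem elements whose pairing probability is q_in; the rest of the stem
## pairs with probability q_out. The mature miRNA window and its star
## follow the 2-nt 3' overhang geometry exactly, so the planted start is
## always recovered by locateStar(). Structures are constructed directly
## from the generative process (no folding backend needed); an optional
## backend refolds the sequence instead.

#' Parameters of the synthetic hairpin generator
#'
#' Defaults emulate plant-like pre-miRNAs: stems of 45-70 nt give
#' roughly 60-120 pseudo candidates per real duplex, matching the
#' extreme class imbalance of real training data (~1:89 on average).
#'
#' @param n_hairpins number of hairpins in a dataset.
#' @param stem_len range of stem element counts.
#' @param loop_len range of terminal loop lengths (nt).
#' @param q_in pairing probability inside the planted duplex.
#' @param q_out pairing probability elsewhere in the stem.
#' @param bulge_rate per-element probability of a 1-3 nt bulge outside
#'   the duplex.
#' @param bias probability of applying the 5'-end stability bias (A-U
#'   pair at the mature 5' end, G-C at the star 5' end).
#' @param second_mature_rate probability that the star strand is also
#'   annotated as a mature miRNA.
#' @param window_len mature window length (nt).
#' @param test_fraction fraction of hairpins held out by
#'   [sampleDataset()].
#' @param seed RNG seed used by [sampleDataset()].
#' @return A list of class \code{synthParams}.
#' @export
synthParams <- function(n_hairpins = 100L, stem_len = c(45L, 70L),
                        loop_len = c(4L, 10L), q_in = 0.95, q_out = 0.6,
                        bulge_rate = 0.05, bias = 0.9,
                        second_mature_rate = 0.1, window_len = 21L,
                        test_fraction = 0.3, seed = 1L) {
  if (q_in < q_out)
    warning("q_in < q_out: the planted duplex carries no pairing signal")
  structure(as.list(environment()), class = "synthParams")
}

RNA_BASES <- c("A", "C", "G", "U")
RNA_COMP <- c(A = "U", U = "A", G = "C", C = "G")

#' Sample one synthetic hairpin
#'
#' Uses the current RNG state; wrap in \code{set.seed()} or
#' [withSeed-like] helpers for reproducibility.
#'
#' @param params a [synthParams()] list.
#' @param id identifier for the hairpin.
#' @param backend optional folding backend; when supplied the constructed
#'   sequence is refolded and the thermodynamic structure replaces the
#'   constructed one.
#' @return list with elements \code{pre} ([PremiRNA-class]),
#'   \code{starts} (planted mature start(s), 1-based) and \code{arm} of
#'   the primary mature miRNA.
#' @export
sampleHairpin <- function(params = synthParams(), id = "synth",
                          backend = NULL) {
  L <- params$window_len
  S <- sample(params$stem_len[1L]:params$stem_len[2L], 1L)
  if (S < L + 7L) stop("infeasible parameters: stem shorter than window + margins")
  loopLen <- sample(params$loop_len[1L]:params$loop_len[2L], 1L)
  d <- sample(3L:(S - L - 3L), 1L)          # duplex footprint: elements d..d+L+1
  mature3p <- stats::runif(1L) < 0.5

  topC <- character(0L); topS <- character(0L); topE <- integer(0L)
  botC <- vector("list", S); botS <- vector("list", S); botE <- vector("list", S)
  for (i in seq_len(S)) {
    bc <- character(0L); bs <- character(0L); be <- integer(0L)
    inDup <- i >= d && i <= d + L + 1L
    if (!inDup && stats::runif(1L) < params$bulge_rate) {
      blen <- sample(1:3, 1L)
      if (stats::runif(1L) < 0.5) {
        topC <- c(topC, sample(RNA_BASES, blen, replace = TRUE))
        topS <- c(topS, rep(".", blen)); topE <- c(topE, rep(NA_integer_, blen))
      } else {
        bc <- sample(RNA_BASES, blen, replace = TRUE)
        bs <- rep(".", blen); be <- rep(NA_integer_, blen)
      }
    }
    biased <- stats::runif(1L) < params$bias
    if (i == d && biased) {
      tb <- if (mature3p) "G" else "U"     # star 5' G-C / mature 5' U-A
      paired <- TRUE
    } else if (i == d + L + 1L && biased) {
      tb <- if (mature3p) "A" else "C"     # mature 5' U-A / star 5' G-C
      paired <- TRUE
    } else {
      tb <- sample(RNA_BASES, 1L)
      paired <- stats::runif(1L) < (if (inDup) params$q_in else params$q_out)
    }
    if (paired) {
      topC <- c(topC, tb); topS <- c(topS, "("); topE <- c(topE, i)
      bc <- c(RNA_COMP[[tb]], bc); bs <- c(")", bs); be <- c(i, be)
    } else {
      topC <- c(topC, tb); topS <- c(topS, "."); topE <- c(topE, i)
      mb <- sample(setdiff(RNA_BASES, RNA_COMP[[tb]]), 1L)
      bc <- c(mb, bc); bs <- c(".", bs); be <- c(i, be)
    }
    botC[[i]] <- bc; botS[[i]] <- bs; botE[[i]] <- be
  }
  loopSeq <- sample(RNA_BASES, loopLen, replace = TRUE)
  seqChars <- c(topC, loopSeq, unlist(rev(botC)))
  strChars <- c(topS, rep(".", loopLen), unlist(rev(botS)))
  eIds <- c(topE, rep(NA_integer_, loopLen), unlist(rev(botE)))
  topLen <- length(topC)

  tPos <- function(e) which(eIds == e & seq_along(eIds) <= topLen)
  bPos <- function(e) which(eIds == e & seq_along(eIds) > topLen)
  m <- if (mature3p) bPos(d + L + 1L) else tPos(d)
  starStart <- if (mature3p) tPos(d) else bPos(d + L + 1L)
  starts <- m
  if (stats::runif(1L) < params$second_mature_rate)
    starts <- c(starts, starStart)

  sequence <- paste(seqChars, collapse = "")
  structure <- paste(strChars, collapse = "")
  pre <- if (is.null(backend)) {
    PremiRNA(id, sequence, structure)
  } else {
    PremiRNA(id, sequence, backend = backend)
  }
  list(pre = pre, starts = as.integer(starts),
       arm = if (mature3p) "3p" else "5p")
}

#' Sample a labelled synthetic dataset
#'
#' Generates hairpins, enumerates/filters/labels their candidates and
#' splits hairpins (never candidates) into training and test sets.
#'
#' @param params a [synthParams()] list; \code{params$seed} controls the
#'   whole generation.
#' @param thresholds candidate [filterThresholds()].
#' @param backend optional folding backend (see [sampleHairpin()]).
#' @return list with \code{hairpins} (named list of [PremiRNA-class]),
#'   \code{annotations} (premirna_id, mirna_start, arm), \code{candidates}
#'   (labelled candidate data.frame over all hairpins) and \code{split}
#'   (named "train"/"test" per hairpin id).
#' @export
sampleDataset <- function(params = synthParams(),
                          thresholds = filterThresholds(),
                          backend = NULL) {
  n <- params$n_hairpins
  out <- list(hairpins = list(),
              annotations = data.frame(premirna_id = character(),
                                       mirna_start = integer(),
                                       arm = character()),
              candidates = NULL,
              split = character(0L))
  if (n == 0L) {
    out$candidates <- labelCandidates(
      enumerateCandidates(PremiRNA("empty0", strrep("G", 12L),
                                   "((((....))))"), 4L)[0L, ], integer(0L))
    return(out)
  }
  withSeed(params$seed, {
    cands <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("synth%04d", i)
      h <- sampleHairpin(params, id, backend)
      out$hairpins[[id]] <- h$pre
      out$annotations <- rbind(out$annotations,
        data.frame(premirna_id = id, mirna_start = h$starts,
                   arm = h$arm))
      anatomy <- annotateAnatomy(h$pre)
      cc <- enumerateCandidates(h$pre, params$window_len, anatomy)
      cc <- filterCandidates(cc, anatomy, thresholds)
      cands[[i]] <- labelCandidates(cc, h$starts, length(h$pre))
    }
    out$candidates <- do.call(rbind, cands)
    rownames(out$candidates) <- NULL
    ids <- names(out$hairpins)
    nTest <- round(params$test_fraction * n)
    testIds <- sample(ids, nTest)
    out$split <- stats::setNames(ifelse(ids %in% testIds, "test", "train"), ids)
  })
  out
}
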