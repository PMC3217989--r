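## miRNA:miRNA* duplex candidate enumeration, filtering and labelling.
##
## A candidate set is a data.frame with one row per candidate and columns
##   premirna_id, mirna_start, window_len, star_start, star_end, arm, label
## (all coordinates 1-based inclusive). The miRNA window is
## [mirna_start, mirna_start + window_len - 1].

#' Locate the miRNA* window for a miRNA candidate
#'
#' The star has the same length as the miRNA window, lies on the opposite
#' strand of the duplex and its 3' end sits 2 nt before the pairing
#' partner of the miRNA 5' end (the 2-nt 3' overhang left by Dicer/DCL1
#' processing). When the 5'-terminal nucleotide of the window is unpaired
#' the anchor slides 3'-wards to the first paired position within the
#' window and the offset is corrected by the slide distance.
#'
#' @param pre a [PremiRNA-class] object.
#' @param mirnaStart 1-based start of the miRNA window.
#' @param L window length in nt.
#' @return Integer vector \code{c(star_start, star_end)} (1-based,
#'   inclusive), or NULL when the star is undefined (no paired anchor in
#'   the window, or the star would fall outside the sequence).
#' @export
locateStar <- function(pre, mirnaStart, L = 21L) {
  pt <- pairTable(pre)
  n <- length(pt)
  if (mirnaStart < 1L || mirnaStart + L - 1L > n)
    stop("miRNA window must lie inside the sequence")
  win <- mirnaStart:(mirnaStart + L - 1L)
  anchor <- win[which(!is.na(pt[win]))[1L]]
  if (is.na(anchor)) return(NULL)
  starEnd <- pt[anchor] - 2L + (anchor - mirnaStart)
  starStart <- starEnd - L + 1L
  if (starStart < 1L || starEnd > n) return(NULL)
  c(star_start = starStart, star_end = starEnd)
}

#' Enumerate miRNA:miRNA* duplex candidates
#'
#' Slides an L-nt window with step 1 over the whole hairpin; each
#' admissible start together with its star window (see [locateStar()]) is
#' one candidate. Starts whose star is undefined are dropped (the count
#' is recorded in the \code{"dropped"} attribute).
#'
#' @param pre a [PremiRNA-class] object.
#' @param L window length in nt (21 for plant, 22 for animal models).
#' @param anatomy optional precomputed [HairpinAnatomy-class]; used to
#'   assign each candidate to the 5p or 3p arm.
#' @return Candidate data.frame (possibly 0 rows).
#' @export
enumerateCandidates <- function(pre, L = 21L, anatomy = NULL) {
  n <- length(pre)
  empty <- data.frame(premirna_id = character(), mirna_start = integer(),
                      window_len = integer(), star_start = integer(),
                      star_end = integer(), arm = character(),
                      label = character(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  if (is.null(anatomy)) anatomy <- annotateAnatomy(pre)
  loopStart <- terminalLoop(anatomy)[1L]
  starts <- 1L:(n - L + 1L)
  stars <- lapply(starts, function(s) locateStar(pre, s, L))
  keep <- !vapply(stars, is.null, logical(1L))
  out <- data.frame(
    premirna_id = premirnaId(pre),
    mirna_start = starts[keep],
    window_len = L,
    star_start = vapply(stars[keep], `[[`, integer(1L), 1L),
    star_end = vapply(stars[keep], `[[`, integer(1L), 2L),
    arm = ifelse(starts[keep] < loopStart, "5p", "3p"),
    label = "unknown",
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Candidate filter thresholds
#'
#' Candidates overlapping large single-stranded regions are filtered out
#' before scoring: mature miRNAs rarely span the terminal loop, big
#' bulges or long unmatched stem ends. The thresholds are in nt.
#'
#' @param loop_overlap_max maximum tolerated overlap of a window with the
#'   terminal loop.
#' @param big_bulge_min minimum size of a bulge/internal loop that
#'   disqualifies overlapping candidates.
#' @param big_unmatched_min minimum size of a terminal unmatched region
#'   that disqualifies overlapping candidates.
#' @return A named list of thresholds.
#' @export
filterThresholds <- function(loop_overlap_max = 6L, big_bulge_min = 8L,
                             big_unmatched_min = 8L) {
  list(loop_overlap_max = loop_overlap_max,
       big_bulge_min = big_bulge_min,
       big_unmatched_min = big_unmatched_min)
}

spanOverlap <- function(a1, a2, b1, b2) {
  max(0L, min(a2, b2) - max(a1, b1) + 1L)
}

#' Filter miRNA:miRNA* candidates by hairpin anatomy
#'
#' Removes candidates whose miRNA or star window (i) overlaps the
#' terminal loop by more than \code{loop_overlap_max} nt, (ii) touches a
#' bulge or internal loop of at least \code{big_bulge_min} nt, or (iii)
#' touches a terminal unmatched region of at least
#' \code{big_unmatched_min} nt. Input order is preserved; per-rule
#' removal counts are stored in the \code{"removed"} attribute.
#'
#' @param cands candidate data.frame from [enumerateCandidates()].
#' @param anatomy [HairpinAnatomy-class] of the same hairpin.
#' @param thresholds see [filterThresholds()].
#' @return Filtered candidate data.frame.
#' @export
filterCandidates <- function(cands, anatomy, thresholds = filterThresholds()) {
  if (nrow(cands) == 0L) return(cands)
  loop <- terminalLoop(anatomy)
  bigSpans <- function(spans, minSize) {
    if (nrow(spans) == 0L) return(spans)
    spans[spans[, 2L] - spans[, 1L] + 1L >= minSize, , drop = FALSE]
  }
  bulgy <- bigSpans(rbind(anatomy@bulges, anatomy@internalLoops),
                    thresholds$big_bulge_min)
  ends <- bigSpans(anatomy@unmatchedEnds, thresholds$big_unmatched_min)

  windowHit <- function(w1, w2) {
    loopOv <- spanOverlap(w1, w2, loop[1L], loop[2L])
    if (loopOv > thresholds$loop_overlap_max) return("loop")
    for (k in seq_len(nrow(bulgy)))
      if (spanOverlap(w1, w2, bulgy[k, 1L], bulgy[k, 2L]) > 0L)
        return("bulge")
    for (k in seq_len(nrow(ends)))
      if (spanOverlap(w1, w2, ends[k, 1L], ends[k, 2L]) > 0L)
        return("unmatched")
    NA_character_
  }
  reason <- character(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    r <- windowHit(cands$mirna_start[i],
                   cands$mirna_start[i] + cands$window_len[i] - 1L)
    if (is.na(r))
      r <- windowHit(cands$star_start[i], cands$star_end[i])
    reason[i] <- r
  }
  keep <- is.na(reason)
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(loop = sum(reason == "loop", na.rm = TRUE),
                            bulge = sum(reason == "bulge", na.rm = TRUE),
                            unmatched = sum(reason == "unmatched", na.rm = TRUE))
  out
}

#' Label candidates as real or pseudo duplexes
#'
#' A candidate is a real miRNA:miRNA* duplex when its start coincides
#' with an annotated mature miRNA start of the same hairpin; all other
#' candidates are pseudo duplexes (negatives).
#'
#' @param cands candidate data.frame.
#' @param trueStarts integer vector of annotated mature starts (1-based);
#'   pre-miRNAs carry 1-4 mature miRNAs.
#' @param seqLength hairpin length, used to validate the annotation.
#' @return The candidate data.frame with the \code{label} column set to
#'   "real" or "pseudo".
#' @export
labelCandidates <- function(cands, trueStarts, seqLength = NULL) {
  trueStarts <- as.integer(trueStarts)
  if (!is.null(seqLength) && length(trueStarts) &&
      any(trueStarts < 1L | trueStarts > seqLength))
    stop("annotation error: true start outside the sequence")
  cands$label <- ifelse(cands$mirna_start %in% trueStarts, "real", "pseudo")
  cands
}
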