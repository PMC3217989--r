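## Feature extraction for miRNA:miRNA* duplex candidates.
##
## The full plant feature set at a 12-nt flank has 160 features:
##   90 position-specific symbols (21 miRNA + 21 miRNA* + 4 x 12 flanks),
##   64 local triplet structure frequencies (32 per strand),
##    6 numeric features: dis, the two 5'-end stability codes, MFE_1..3.

#' Feature extraction configuration
#'
#' @param window_len miRNA window length in nt (21 plant, 22 animal).
#' @param flank_len flanking region length in nt; one of 0, 2, 3, 6, 9,
#'   12. The default 6 nt maximises prediction performance.
#' @param mfe_flanks flank lengths for the three duplex energies
#'   MFE_1..3.
#' @param linker_len length of the non-pairing spacer joining the miRNA
#'   and star sequences in the energy calculation.
#' @return A list of class \code{featureConfig}.
#' @export
featureConfig <- function(window_len = 21L, flank_len = 6L,
                          mfe_flanks = c(0L, 3L, 6L), linker_len = 6L) {
  if (!flank_len %in% c(0L, 2L, 3L, 6L, 9L, 12L))
    stop("flank_len must be one of 0, 2, 3, 6, 9, 12")
  structure(list(window_len = as.integer(window_len),
                 flank_len = as.integer(flank_len),
                 mfe_flanks = as.integer(mfe_flanks),
                 linker_len = as.integer(linker_len)),
            class = "featureConfig")
}

mfeNames <- function(cfg) {
  if (length(cfg$mfe_flanks) == 0L) return(character(0L))
  paste0("MFE_", seq_along(cfg$mfe_flanks))
}

#' Position symbol alphabets
#'
#' Each position of a duplex candidate is encoded as one of 9 pairs: the
#' 8 base/pairing-state combinations (base in A, C, U, G; M = matched,
#' L = mismatched) plus "noValue" for slots outside the pre-miRNA. A 10th
#' symbol, the gap "-:L", marks alignment slots opposite a bulge where no
#' nucleotide exists.
#'
#' @param gap include the gap symbol.
#' @return Character vector of symbols.
#' @export
positionAlphabet <- function(gap = FALSE) {
  base <- c("A:M", "A:L", "C:M", "C:L", "U:M", "U:L", "G:M", "G:L",
            "noValue")
  if (gap) c(base, "-:L") else base
}

#' Encode one sequence position as a (base, pairing) symbol
#'
#' @param pre a [PremiRNA-class] object.
#' @param pos 1-based position; positions outside the sequence yield
#'   "noValue".
#' @return A single symbol string, e.g. "A:M" or "G:L".
#' @export
encodePosition <- function(pre, pos) {
  n <- length(pre)
  if (is.na(pos) || pos < 1L || pos > n) return("noValue")
  base <- substr(hairpinSequence(pre), pos, pos)
  state <- if (is.na(pairTable(pre)[pos])) "L" else "M"
  paste0(base, ":", state)
}

## Align the star strand against the miRNA window through the pair table.
## top: increasing positions (miRNA 5'->3'); bottom: positions of the star
## window, walked 3'->5' (antiparallel layout). Returns a 2-column matrix
## (top, bottom) of positions; NA marks an alignment gap.
alignDuplex <- function(pt, top, bottom) {
  bot <- rev(bottom)
  nT <- length(top); nB <- length(bot)
  i <- 1L; j <- 1L
  Ti <- integer(0L); Bi <- integer(0L)
  put <- function(t, b) { Ti[length(Ti) + 1L] <<- t; Bi[length(Bi) + 1L] <<- b }
  while (i <= nT || j <= nB) {
    if (i > nT) { put(NA_integer_, bot[j]); j <- j + 1L; next }
    if (j > nB) { put(top[i], NA_integer_); i <- i + 1L; next }
    t <- top[i]; b <- bot[j]
    lpT <- if (!is.na(pt[t]) && pt[t] <= b && pt[t] >= bot[nB]) pt[t] else NA_integer_
    lpB <- if (!is.na(pt[b]) && pt[b] >= t && pt[b] <= top[nT]) pt[b] else NA_integer_
    if (!is.na(lpT) && lpT == b) {            # duplex pair
      put(t, b); i <- i + 1L; j <- j + 1L
    } else if (is.na(lpT) && is.na(lpB)) {    # mismatch, both unpaired locally
      put(t, b); i <- i + 1L; j <- j + 1L
    } else if (is.na(lpT)) {                  # top nt bulged out
      put(t, NA_integer_); i <- i + 1L
    } else if (is.na(lpB)) {                  # bottom nt bulged out
      put(NA_integer_, b); j <- j + 1L
    } else {                                  # crossing partners; skip bottom
      put(NA_integer_, b); j <- j + 1L
    }
  }
  cbind(top = Ti, bottom = Bi)
}

#' Position-specific features of a duplex candidate
#'
#' Encodes the miRNA window, the star window and the four flanking
#' regions as position symbols. The miRNA side is read directly off the
#' sequence; the star window is laid against the miRNA window through the
#' pair table, so a miRNA nucleotide facing a bulge (no star nucleotide
#' opposite) produces the gap symbol "-:L" in the star row. Flank slots
#' beyond the sequence ends yield "noValue".
#'
#' @param cand one candidate (single row of a candidate data.frame, or a
#'   list with mirna_start, window_len, star_start, star_end).
#' @param pre the [PremiRNA-class] the candidate belongs to.
#' @param cfg a [featureConfig()].
#' @return Named character vector of 2L + 4s symbols (90 at s = 12, 66 at
#'   s = 6, 42 at s = 0).
#' @export
positionalFeatures <- function(cand, pre, cfg = featureConfig()) {
  L <- cfg$window_len; s <- cfg$flank_len
  m <- cand$mirna_start; ss <- cand$star_start; se <- cand$star_end
  pt <- pairTable(pre)

  sym <- function(pos) vapply(pos, function(p) encodePosition(pre, p),
                              character(1L))
  out <- character(0L)

  out[paste0("miRNA_", seq_len(L))] <- sym(m:(m + L - 1L))

  aln <- alignDuplex(pt, m:(m + L - 1L), ss:se)
  nc <- nrow(aln)
  starSym <- character(L)
  for (k in seq_len(L)) {
    b <- aln[nc - k + 1L, "bottom"]
    starSym[k] <- if (is.na(b)) "-:L" else encodePosition(pre, b)
  }
  out[paste0("miRNAstar_", seq_len(L))] <- starSym

  if (s > 0L) {
    ks <- seq_len(s)
    out[paste0("bef_miRNA_", ks)] <- sym(m - ks)
    out[paste0("aft_miRNA_", ks)] <- sym(m + L - 1L + ks)
    out[paste0("bef_miRNAstar_", ks)] <- sym(ss - ks)
    out[paste0("aft_miRNAstar_", ks)] <- sym(se + ks)
  }
  out
}

#' Distance from a candidate start to the terminal loop
#'
#' Unsigned distance in nt between the miRNA start and the nearest
#' boundary of the terminal loop; 0 when the start lies inside the loop.
#'
#' @param mirnaStart 1-based miRNA start.
#' @param anatomy a [HairpinAnatomy-class].
#' @return Nonnegative integer distance.
#' @export
disFeature <- function(mirnaStart, anatomy) {
  loop <- terminalLoop(anatomy)
  if (mirnaStart >= loop[1L] && mirnaStart <= loop[2L]) return(0L)
  if (mirnaStart < loop[1L]) loop[1L] - mirnaStart else mirnaStart - loop[2L]
}

#' 5'-end stability codes of the miRNA and star
#'
#' The thermodynamic stability of the duplex ends guides strand selection:
#' the mature miRNA usually has the less stable 5' end. The code of a
#' 5'-terminal nucleotide is 0 when it is unpaired, 1 for a G-U/U-G
#' wobble, 2 for A-U/U-A and 3 for G-C/C-G (non-canonical pairs, which
#' only arise in constructed structures, code as 0).
#'
#' @param cand candidate row (needs mirna_start and star_start).
#' @param pre the [PremiRNA-class] the candidate belongs to.
#' @return Integer vector c(miRNA_5end, miRNAstar_5end), each in 0..3.
#' @export
stability5prime <- function(cand, pre) {
  pt <- pairTable(pre)
  seq <- hairpinSequence(pre)
  code <- function(pos) {
    if (is.na(pt[pos])) return(0L)
    pairSet <- paste(sort(c(substr(seq, pos, pos),
                            substr(seq, pt[pos], pt[pos]))), collapse = "")
    switch(pairSet, "GU" = 1L, "AU" = 2L, "CG" = 3L, 0L)
  }
  c(miRNA_5end = code(cand$mirna_start), miRNAstar_5end = code(cand$star_start))
}

tripletPatterns <- function() {
  pats <- apply(expand.grid(c("(", "."), c("(", "."), c("(", "."))[, 3:1],
                1L, paste, collapse = "")
  as.vector(vapply(c("A", "C", "G", "U"),
                   function(b) paste0(b, pats), character(8L)))
}

#' Local contiguous triplet structure frequencies
#'
#' For every 3 adjacent nucleotides of a window, the paired/unpaired
#' pattern (brackets of both orientations collapsed to "(") combined with
#' the middle base gives one of 32 categories; the feature is the
#' category frequency over the L - 2 triplets of the window.
#'
#' @param seqWindow sequence of the window (length >= 3).
#' @param structWindow dot-bracket substructure of the window, taken from
#'   the full-hairpin fold.
#' @param prefix name prefix, e.g. "miRNA" or "miRNAstar".
#' @return Named numeric vector of 32 frequencies summing to 1.
#' @export
tripletFeatures <- function(seqWindow, structWindow, prefix = "miRNA") {
  n <- nchar(seqWindow)
  if (n < 3L) stop("window must have length >= 3")
  if (nchar(structWindow) != n)
    stop("sequence and structure windows must have equal length")
  collapsed <- gsub(")", "(", structWindow, fixed = TRUE)
  keys <- paste0(substring(seqWindow, 2:(n - 1L), 2:(n - 1L)),
                 substring(collapsed, 1:(n - 2L), 3:n))
  counts <- table(factor(keys, levels = tripletPatterns()))
  out <- as.numeric(counts) / (n - 2L)
  names(out) <- paste0(prefix, "_", tripletPatterns())
  out
}

#' Duplex minimum free energies with a non-pairing linker
#'
#' The miRNA and star sequences (with 0, 3 and 6 nt flanks for MFE_1,
#' MFE_2 and MFE_3; flanks are truncated at the sequence ends) are joined
#' by a spacer that is forced to remain unpaired, and the construct is
#' folded. More stable (more negative) duplexes indicate real
#' miRNA:miRNA* pairs.
#'
#' @param cands candidate data.frame (one or more rows).
#' @param pre the [PremiRNA-class] the candidates belong to.
#' @param cfg a [featureConfig()].
#' @param backend folding backend supporting constrained folds.
#' @return Numeric matrix with one row per candidate and columns
#'   MFE_1, MFE_2, MFE_3 (kcal/mol).
#' @export
mfeFeatures <- function(cands, pre, cfg = featureConfig(),
                        backend = viennaBackend()) {
  n <- length(pre)
  seq <- hairpinSequence(pre)
  linker <- strrep("N", cfg$linker_len)
  xs <- strrep("x", cfg$linker_len)
  seqs <- character(0L); cons <- character(0L)
  for (i in seq_len(nrow(cands))) {
    for (f in cfg$mfe_flanks) {
      a1 <- max(1L, cands$mirna_start[i] - f)
      a2 <- min(n, cands$mirna_start[i] + cands$window_len[i] - 1L + f)
      b1 <- max(1L, cands$star_start[i] - f)
      b2 <- min(n, cands$star_end[i] + f)
      s1 <- substr(seq, a1, a2); s2 <- substr(seq, b1, b2)
      seqs <- c(seqs, paste0(s1, linker, s2))
      cons <- c(cons, paste0(strrep(".", nchar(s1)), xs,
                             strrep(".", nchar(s2))))
    }
  }
  res <- backend$foldConstrained(seqs, cons)
  out <- matrix(res$mfe, ncol = length(cfg$mfe_flanks), byrow = TRUE)
  colnames(out) <- mfeNames(cfg)
  out
}

#' Full feature name inventory
#'
#' @param cfg a [featureConfig()].
#' @return Character vector of all feature names for this configuration,
#'   positional then triplet then the 6 numeric features (160 names at a
#'   12-nt flank, 136 at 6 nt).
#' @export
featureNames <- function(cfg = featureConfig()) {
  L <- cfg$window_len; s <- cfg$flank_len
  pos <- c(paste0("miRNA_", seq_len(L)), paste0("miRNAstar_", seq_len(L)))
  if (s > 0L)
    pos <- c(pos,
             paste0("bef_miRNA_", seq_len(s)), paste0("aft_miRNA_", seq_len(s)),
             paste0("bef_miRNAstar_", seq_len(s)), paste0("aft_miRNAstar_", seq_len(s)))
  trip <- c(paste0("miRNA_", tripletPatterns()),
            paste0("miRNAstar_", tripletPatterns()))
  c(pos, trip, "dis", "miRNA_5end", "miRNAstar_5end", mfeNames(cfg))
}

#' Extract the feature table for a set of candidates
#'
#' Computes every feature (position symbols, triplet frequencies, dis,
#' 5'-end codes and, unless \code{mfe = FALSE}, the three duplex
#' energies) for all candidates of one hairpin. Energies are folded in
#' one batch per hairpin.
#'
#' @param cands candidate data.frame for one hairpin.
#' @param pre the corresponding [PremiRNA-class].
#' @param cfg a [featureConfig()].
#' @param backend folding backend for the energy features.
#' @param anatomy optional precomputed anatomy.
#' @param mfe set FALSE to skip the energy features (they are then NA).
#' @return data.frame: columns premirna_id, mirna_start, arm, label, then
#'   one column per feature name (character for position symbols, numeric
#'   otherwise).
#' @export
extractFeatureTable <- function(cands, pre, cfg = featureConfig(),
                                backend = NULL, anatomy = NULL,
                                mfe = TRUE) {
  if (is.null(anatomy)) anatomy <- annotateAnatomy(pre)
  if (length(cfg$mfe_flanks) == 0L) mfe <- FALSE
  nms <- featureNames(cfg)
  meta <- cands[c("premirna_id", "mirna_start", "arm", "label")]
  if (nrow(cands) == 0L) {
    empty <- as.data.frame(matrix(nrow = 0L, ncol = length(nms)))
    names(empty) <- nms
    return(cbind(meta, empty))
  }
  seq <- hairpinSequence(pre)
  str <- hairpinStructure(pre)
  nr <- nrow(cands)
  nPos <- 2L * cfg$window_len + 4L * cfg$flank_len
  posMat <- matrix(NA_character_, nr, nPos)
  numMat <- matrix(NA_real_, nr, 64L + 3L)
  for (i in seq_len(nr)) {
    cand <- cands[i, ]
    posf <- positionalFeatures(cand, pre, cfg)
    if (i == 1L) colnames(posMat) <- names(posf)
    posMat[i, ] <- posf
    m <- cand$mirna_start; L <- cand$window_len
    tripM <- tripletFeatures(substr(seq, m, m + L - 1L),
                             substr(str, m, m + L - 1L), "miRNA")
    tripS <- tripletFeatures(substr(seq, cand$star_start, cand$star_end),
                             substr(str, cand$star_start, cand$star_end),
                             "miRNAstar")
    stab <- stability5prime(cand, pre)
    numMat[i, ] <- c(tripM, tripS, disFeature(m, anatomy), stab)
    if (i == 1L) colnames(numMat) <- c(names(tripM), names(tripS), "dis",
                                       names(stab))
  }
  feat <- cbind(as.data.frame(posMat, optional = TRUE),
                as.data.frame(numMat, optional = TRUE))
  if (mfe) {
    if (is.null(backend)) backend <- viennaBackend()
    mfeMat <- mfeFeatures(cands, pre, cfg, backend)
  } else {
    mfeMat <- matrix(NA_real_, nrow(cands), length(cfg$mfe_flanks),
                     dimnames = list(NULL, mfeNames(cfg)))
  }
  out <- cbind(meta, feat, as.data.frame(mfeMat))
  rownames(out) <- NULL
  stopifnot(identical(setdiff(names(out), names(meta)), nms))
  out
}

#' Extract features for a single candidate
#'
#' @inheritParams extractFeatureTable
#' @param cand one candidate row.
#' @return One-row feature data.frame (see [extractFeatureTable()]).
#' @export
extractFeatures <- function(cand, pre, cfg = featureConfig(),
                            backend = NULL, anatomy = NULL, mfe = TRUE) {
  extractFeatureTable(cand, pre, cfg, backend, anatomy, mfe)
}
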