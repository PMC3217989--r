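test_that("feature name inventory reproduces the published counts", {
  cfg12 <- featureConfig(flank_len = 12L)
  nms <- featureNames(cfg12)
  expect_length(nms, 160L)
  cfg6 <- featureConfig()
  expect_length(featureNames(cfg6), 136L)
  cfg0 <- featureConfig(flank_len = 0L)
  expect_length(featureNames(cfg0), 42L + 64L + 6L)
  expect_error(featureConfig(flank_len = 5L), "flank_len")
})

test_that("position symbols cover the 9-pair alphabet plus gap", {
  expect_length(positionAlphabet(), 9L)
  expect_length(positionAlphabet(gap = TRUE), 10L)
  p <- perfectHairpin()
  expect_identical(encodePosition(p, 1L), "G:M")         # paired G
  loopPos <- terminalLoop(annotateAnatomy(p))[1L]
  expect_identical(encodePosition(p, loopPos), "A:L")    # loop A unpaired
  expect_identical(encodePosition(p, 0L), "noValue")
  expect_identical(encodePosition(p, length(p) + 1L), "noValue")
})

test_that("positional features lay the star against the miRNA window", {
  p <- perfectHairpin(stem = 40L, loop = 6L)
  cc <- enumerateCandidates(p, 21L)
  cand <- cc[cc$mirna_start == 5L, ]
  pf <- positionalFeatures(cand, p, featureConfig())
  expect_length(pf, 66L)
  ## on a perfect stem every miRNA/star slot is matched
  expect_true(all(grepl(":M$", pf[paste0("miRNA_", 1:21)])))
  expect_true(all(grepl(":M$", pf[paste0("miRNAstar_", 1:21)])))
  ## star slots run 5'->3' along the star window (rightmost alignment
  ## column first)
  seqc <- strsplit(hairpinSequence(p), "")[[1L]]
  for (k in c(1L, 10L, 21L))
    expect_identical(pf[[paste0("miRNAstar_", k)]],
                     paste0(seqc[cand$star_start + k - 1L], ":M"))
  ## windows at the sequence edge produce noValue flanks
  edge <- cc[cc$mirna_start == 1L, ]
  pfe <- positionalFeatures(edge, p, featureConfig())
  expect_true(all(pfe[paste0("bef_miRNA_", 1:6)] == "noValue"))
})

test_that("a miRNA nucleotide facing a bulge yields the gap symbol", {
  ## one bulged nucleotide on the 5' arm inside the miRNA window: the
  ## miRNA nt at position 11 has no star nt opposite
  str <- paste0(strrep("(", 10L), ".", strrep("(", 15L), "....",
                strrep(")", 25L))
  seq <- paste0(strrep("G", 10L), "A", strrep("G", 15L), "AAAA",
                strrep("C", 25L))
  p <- PremiRNA("bulge", seq, str)
  cc <- enumerateCandidates(p, 21L)
  cand <- cc[cc$mirna_start == 1L, ]
  pf <- positionalFeatures(cand, p, featureConfig())
  star <- unlist(pf[paste0("miRNAstar_", 1:21)])
  expect_identical(sum(star == "-:L"), 1L)
})

test_that("triplet features count middle-base x pattern categories", {
  ## oracle: direct counting on a small window
  seqW <- "GACUGAC"
  strW <- "(((..))"
  tf <- tripletFeatures(seqW, strW, "miRNA")
  expect_length(tf, 32L)
  expect_equal(sum(tf), 1)
  ## collapsed structure "(((..((" -> windows (((, ((., (.., ..(, .((
  expect_equal(unname(tf[["miRNA_A((("]]), 1 / 5)
  expect_equal(unname(tf[["miRNA_C((."]]), 1 / 5)
  expect_equal(unname(tf[["miRNA_U(.."]]), 1 / 5)
  expect_equal(unname(tf[["miRNA_U((("]]), 0)
  expect_error(tripletFeatures("AC", "((", "x"), "length >= 3")
  expect_error(tripletFeatures("ACG", "((", "x"), "equal length")
})

test_that("bracket orientation is collapsed in triplet patterns", {
  a <- tripletFeatures("ACGUA", "((..)", "m")
  b <- tripletFeatures("ACGUA", ")(..(", "m")
  expect_identical(a, b)
})

test_that("5'-end stability codes follow pair identity", {
  ## G-C pair at miRNA 5' end -> 3; A-U -> 2; G-U wobble -> 1; unpaired -> 0
  p <- PremiRNA("s", "GAGUAAAAACUC", "((((....))))")
  ## pairs: 1G-12C, 2A-11U, 3G-10C? sequence: G A G U A A A A A C U C
  ## pt: 1-12 (G,C)=3; 2-11 (A,U)=2; 4-9 (U,A)=2; 3-10 (G,C)=3
  expect_identical(
    unname(stability5prime(list(mirna_start = 1L, star_start = 2L), p)),
    c(3L, 2L))
  q <- PremiRNA("w", "GAGUAAAAACUU", "((((....))))")  # 1G-12U wobble
  expect_identical(
    unname(stability5prime(list(mirna_start = 1L, star_start = 5L), q)),
    c(1L, 0L))
})

test_that("dis measures distance to the terminal loop", {
  p <- perfectHairpin(stem = 30L, loop = 4L)   # loop [31, 34]
  an <- annotateAnatomy(p)
  expect_identical(disFeature(1L, an), 30L)
  expect_identical(disFeature(31L, an), 0L)
  expect_identical(disFeature(33L, an), 0L)
  expect_identical(disFeature(40L, an), 6L)
})

test_that("duplex energies are folded with a forced-unpaired linker", {
  p <- perfectHairpin(stem = 40L, loop = 6L)
  cc <- enumerateCandidates(p, 21L)
  ## interior candidates: flank extensions are not clamped by the ends
  cc <- cc[cc$mirna_start %in% c(10L, 11L), ]
  seen <- new.env()
  bk <- makeFoldBackend(fold = function(s) stop("unused"),
    foldConstrained = function(seqs, cons) {
      seen$seqs <- seqs; seen$cons <- cons
      data.frame(structure = strrep(".", nchar(seqs)),
                 mfe = -as.numeric(seq_along(seqs)))
    })
  m <- mfeFeatures(cc, p, featureConfig(), bk)
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(colnames(m), c("MFE_1", "MFE_2", "MFE_3"))
  ## 2 candidates x 3 flank settings, batched in one call
  expect_length(seen$seqs, 6L)
  ## linker present and constrained unpaired
  expect_true(all(grepl("NNNNNN", seen$seqs)))
  expect_true(all(grepl("xxxxxx", seen$cons)))
  expect_identical(nchar(seen$seqs), nchar(seen$cons))
  ## MFE_2/MFE_3 constructs extend by the flank on both windows
  expect_identical(nchar(seen$seqs[2L]) - nchar(seen$seqs[1L]), 12L)
  ## row-major fill: candidate 1 energies are -1, -2, -3
  expect_identical(unname(m[1L, ]), c(-1, -2, -3))
})

test_that("extractFeatureTable covers the inventory and labels rows", {
  h <- withr::with_seed(21L, sampleHairpin(synthParams(), "ft"))
  an <- annotateAnatomy(h$pre)
  cc <- labelCandidates(
    filterCandidates(enumerateCandidates(h$pre, 21L, an), an), h$starts)
  tab <- extractFeatureTable(cc, h$pre, featureConfig(), flatBackend(), an)
  expect_identical(nrow(tab), nrow(cc))
  expect_true(all(featureNames(featureConfig()) %in% names(tab)))
  expect_identical(tab$label, cc$label)
  ## energy features populated by the stub
  expect_true(all(is.finite(tab$MFE_1)))
  ## without energies the MFE columns are absent from the inventory
  cfg0 <- featureConfig(mfe_flanks = integer(0))
  tab0 <- extractFeatureTable(cc, h$pre, cfg0, NULL, an, mfe = FALSE)
  expect_false(any(grepl("^MFE_", names(tab0))))
})

test_that("RNAfold backend folds a perfect stem to its hairpin", {
  ## integration with the system RNAfold
  fold <- foldSequence(paste0(strrep("G", 12L), "AAAA", strrep("C", 12L)))
  expect_lt(fold$mfe, 0)
  expect_identical(nchar(fold$structure), 28L)
  expect_gt(sum(strsplit(fold$structure, "")[[1L]] == "("), 8L)
})
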