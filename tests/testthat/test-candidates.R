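test_that("locateStar reproduces the 2-nt 3' overhang on a perfect stem", {
  p <- perfectHairpin(stem = 30L, loop = 4L)   # n = 64
  n <- length(p)
  L <- 21L
  for (m in c(1L, 3L, 7L)) {
    st <- locateStar(p, m, L)
    ## partner of the 5' anchor is n - m + 1; star 3' end 2 nt before it
    expect_identical(unname(st["star_end"]), n - m - 1L)
    expect_identical(unname(st["star_start"]), n - m - L)
  }
  ## 3' arm candidate: anchor pairs back to the 5' arm
  m3 <- 40L
  st3 <- locateStar(p, m3, L)
  expect_identical(unname(st3["star_end"]), length(p) - m3 + 1L - 2L)
})

test_that("locateStar slides the anchor over unpaired 5' ends", {
  ## first two window positions unpaired: anchor slides 2 nt, and the
  ## slide is compensated so the star end is unchanged relative to the
  ## window start
  str <- paste0(strrep("(", 10L), "..", strrep("(", 18L), "....",
                strrep(")", 28L), "..")
  seq <- strrep("G", 10L + 2L + 18L)
  seq <- paste0(seq, "AAAA", strrep("C", 28L), "AA")
  p <- PremiRNA("slide", seq, str)
  pt <- pairTable(p)
  m <- 11L                       # window starts on the unpaired gap
  st <- locateStar(p, m, 21L)
  anchor <- 13L                  # first paired position in the window
  expect_identical(unname(st["star_end"]),
                   pt[anchor] - 2L + (anchor - m))
})

test_that("locateStar returns NULL when the star is undefined", {
  p <- perfectHairpin(stem = 30L, loop = 4L)
  ## windows near the 3' end would need a star beyond the sequence end
  expect_null(locateStar(p, length(p) - 21L + 1L, 21L))
  expect_error(locateStar(p, 0L, 21L), "inside the sequence")
  expect_error(locateStar(p, length(p), 21L), "inside the sequence")
  ## fully unpaired window has no anchor
  q <- PremiRNA("x", strrep("A", 60L),
                paste0(strrep(".", 25L), "(((((....)))))",
                       strrep(".", 21L)))
  expect_null(locateStar(q, 1L, 21L))
})

test_that("enumerateCandidates slides with step 1 and assigns arms", {
  p <- perfectHairpin(stem = 40L, loop = 6L)   # n = 86
  an <- annotateAnatomy(p)
  cc <- enumerateCandidates(p, 21L, an)
  ## starts are consecutive where the star is defined
  expect_true(all(diff(cc$mirna_start) == 1L))
  expect_identical(cc$window_len, rep(21L, nrow(cc)))
  expect_identical(attr(cc, "dropped") + nrow(cc), length(p) - 21L + 1L)
  loopStart <- terminalLoop(an)[1L]
  expect_identical(cc$arm, ifelse(cc$mirna_start < loopStart, "5p", "3p"))
  ## too-short sequence yields an empty frame
  expect_identical(nrow(enumerateCandidates(perfectHairpin(8L, 4L), 21L)), 0L)
})

test_that("filterCandidates removes loop-spanning and bulge-touching windows", {
  p <- perfectHairpin(stem = 40L, loop = 12L)  # big loop
  an <- annotateAnatomy(p)
  cc <- enumerateCandidates(p, 21L, an)
  f <- filterCandidates(cc, an, filterThresholds())
  loop <- terminalLoop(an)
  ov <- function(s) max(0L, min(s + 20L, loop[2L]) - max(s, loop[1L]) + 1L)
  ## every removed-by-loop candidate exceeds the 6-nt overlap on one of
  ## its windows; every survivor does not
  for (i in seq_len(nrow(f)))
    expect_lte(max(ov(f$mirna_start[i]), ov(f$star_start[i])), 6L)
  expect_identical(sum(attr(f, "removed")), nrow(cc) - nrow(f))
  expect_gt(attr(f, "removed")[["loop"]], 0L)
})

test_that("filterCandidates drops windows on big unmatched ends", {
  ## 10-nt dangling 5' end
  str <- paste0(strrep(".", 10L), strrep("(", 30L), "....",
                strrep(")", 30L))
  seq <- paste0(strrep("A", 10L),
                strrep("G", 30L), "AAAA", strrep("C", 30L))
  p <- PremiRNA("dangle", seq, str)
  an <- annotateAnatomy(p)
  cc <- enumerateCandidates(p, 21L, an)
  f <- filterCandidates(cc, an, filterThresholds())
  ## no surviving miRNA window touches the unmatched end [1, 10]
  expect_true(all(f$mirna_start > 10L))
  expect_gt(attr(f, "removed")[["unmatched"]], 0L)
})

test_that("labelCandidates marks annotated starts as real", {
  p <- perfectHairpin(stem = 40L, loop = 6L)
  cc <- enumerateCandidates(p, 21L)
  lab <- labelCandidates(cc, c(5L), length(p))
  expect_identical(lab$label[lab$mirna_start == 5L], "real")
  expect_true(all(lab$label[lab$mirna_start != 5L] == "pseudo"))
  expect_error(labelCandidates(cc, 1000L, length(p)), "annotation error")
})
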