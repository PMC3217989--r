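## Shared deterministic toy objects for the test suite.

RC <- c(A = "U", U = "A", G = "C", C = "G")

revComp <- function(x) {
  paste(rev(RC[strsplit(x, "")[[1L]]]), collapse = "")
}

## A perfect hairpin: `stem` paired positions, a `loop`-nt terminal loop,
## no bulges or mismatches. Deterministic sequence.
perfectHairpin <- function(stem = 30L, loop = 4L, id = "toy") {
  top <- paste(rep(c("G", "A", "C", "U"), length.out = stem), collapse = "")
  loopSeq <- strrep("A", loop)
  seq <- paste0(top, loopSeq, revComp(top))
  str <- paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
  PremiRNA(id, seq, str)
}

## Folding backend stub: everything unpaired, energy = -length/10.
## Deterministic, no external dependency.
flatBackend <- function() {
  f <- function(seqs, constraints = NULL)
    data.frame(structure = strrep(".", nchar(seqs)),
               mfe = -nchar(seqs) / 10)
  makeFoldBackend(fold = f, foldConstrained = function(seqs, constraints)
    f(seqs), name = "flat-stub")
}

## Small labelled feature table (with stubbed energies) for subset and
## encoding tests: n hairpins under the default plant configuration.
toyFeatureTable <- function(n = 6L, seed = 101L, cfg = featureConfig()) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    tabs <- lapply(seq_len(n), function(i) {
      h <- sampleHairpin(synthParams(), sprintf("t%02d", i))
      an <- annotateAnatomy(h$pre)
      cc <- enumerateCandidates(h$pre, 21L, an)
      cc <- filterCandidates(cc, an, filterThresholds())
      cc <- labelCandidates(cc, h$starts, length(h$pre))
      extractFeatureTable(cc, h$pre, cfg, flatBackend(), an,
                          mfe = length(cfg$mfe_flanks) > 0L)
    })
    do.call(rbind, tabs)
  })
}
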