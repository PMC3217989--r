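Package: mirpos
Title: Mature miRNA Position Prediction in pre-miRNA Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the start position of the mature miRNA within a
    pre-miRNA hairpin by scoring candidate miRNA:miRNA* duplexes with a
    support vector machine. Two coupled windows slide along the hairpin
    to enumerate duplex candidates; each candidate is described by
    position-specific sequence/structure symbols, local triplet
    structure frequencies, duplex minimum free energies computed with a
    non-pairing linker, 5' end stability codes and the distance to the
    terminal loop. Informative features are ranked by information gain,
    and the extreme real:pseudo class imbalance is handled by a
    two-stage representative negative-sample selection: k-nearest
    neighbour density condensation followed by iterative selection of
    the negatives that most mislead the current model. Includes
    position-deviation evaluation protocols (mean absolute deviation,
    functional-strand accuracy, cumulative distance distributions,
    grouped cross-validation) and a synthetic hairpin generator with
    planted duplexes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071,
    jsonlite
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
SystemRequirements: ViennaRNA RNAfold (for thermodynamic folding and
    the default duplex energy features; the pipeline runs without it
    when use_mfe = FALSE)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
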