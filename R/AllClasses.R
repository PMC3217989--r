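#' @import methods
NULL

#' PremiRNA: a pre-miRNA hairpin record
#'
#' Holds one pre-miRNA: identifier, RNA sequence, dot-bracket secondary
#' structure, optional minimum free energy and the pair table derived from
#' the structure. All coordinates in this package are 1-based and
#' inclusive (miRBase convention).
#'
#' @slot id single identifier string.
#' @slot sequence RNA sequence over A, C, G, U (and N for unresolved
#'   positions in synthetic records).
#' @slot structure dot-bracket string, same length as the sequence.
#' @slot mfe minimum free energy in kcal/mol, or NA when the structure was
#'   not obtained from a thermodynamic folder.
#' @slot pairTable integer vector: \code{pairTable[i]} is the partner of
#'   position i, or NA when i is unpaired.
#'
#' @seealso [PremiRNA()], [annotateAnatomy()], [enumerateCandidates()]
#' @exportClass PremiRNA
setClass("PremiRNA",
  representation(
    id = "character",
    sequence = "character",
    structure = "character",
    mfe = "numeric",
    pairTable = "integer"
  )
)

setValidity("PremiRNA", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be a single string")
  if (length(object@sequence) != 1L || length(object@structure) != 1L)
    msg <- c(msg, "'sequence' and 'structure' must be single strings")
  n <- nchar(object@sequence)
  if (nchar(object@structure) != n)
    msg <- c(msg, "structure length must equal sequence length")
  if (length(object@pairTable) != n)
    msg <- c(msg, "pair table length must equal sequence length")
  pt <- object@pairTable
  paired <- which(!is.na(pt))
  if (length(paired) && !all(pt[pt[paired]] == paired))
    msg <- c(msg, "pair table must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Construct a PremiRNA object
#'
#' Builds the pair table from the dot-bracket structure and validates the
#' record. If no structure is supplied the sequence is folded with the
#' given backend.
#'
#' @param id identifier.
#' @param sequence RNA (or DNA; T is converted to U) sequence string.
#' @param structure dot-bracket string, or NULL to fold \code{sequence}.
#' @param mfe minimum free energy (kcal/mol), optional.
#' @param backend folding backend used when \code{structure} is NULL; see
#'   [viennaBackend()].
#' @return A [PremiRNA-class] object.
#' @examples
#' p <- PremiRNA("toy", "GGGGAAAACCCC", "((((....))))")
#' pairTable(p)
#' @export
PremiRNA <- function(id, sequence, structure = NULL, mfe = NA_real_,
                     backend = NULL) {
  sequence <- normalizeRna(sequence)
  if (is.null(structure)) {
    if (is.null(backend)) backend <- viennaBackend()
    fold <- foldSequence(sequence, backend)
    structure <- fold$structure
    mfe <- fold$mfe
  }
  new("PremiRNA", id = as.character(id), sequence = sequence,
      structure = structure, mfe = as.numeric(mfe),
      pairTable = buildPairTable(structure))
}

#' @describeIn PremiRNA-class display a short summary
#' @param object a PremiRNA object
#' @export
setMethod("show", "PremiRNA", function(object) {
  n <- nchar(object@sequence)
  cat("PremiRNA object '", object@id, "' (", n, " nt)\n", sep = "")
  cat("  sequence:  ", abbrevSeq(object@sequence), "\n", sep = "")
  cat("  structure: ", abbrevSeq(object@structure), "\n", sep = "")
  if (!is.na(object@mfe))
    cat("  mfe: ", format(object@mfe), " kcal/mol\n", sep = "")
  invisible(NULL)
})

abbrevSeq <- function(x, width = 60L) {
  if (nchar(x) <= width) x else paste0(substr(x, 1L, width - 3L), "...")
}

#' @rdname PremiRNA-class
#' @export
setGeneric("premirnaId", function(object) standardGeneric("premirnaId"))
#' @rdname PremiRNA-class
#' @export
setMethod("premirnaId", "PremiRNA", function(object) object@id)

#' @rdname PremiRNA-class
#' @export
setGeneric("hairpinSequence", function(object) standardGeneric("hairpinSequence"))
#' @rdname PremiRNA-class
#' @export
setMethod("hairpinSequence", "PremiRNA", function(object) object@sequence)

#' @rdname PremiRNA-class
#' @export
setGeneric("hairpinStructure", function(object) standardGeneric("hairpinStructure"))
#' @rdname PremiRNA-class
#' @export
setMethod("hairpinStructure", "PremiRNA", function(object) object@structure)

#' @rdname PremiRNA-class
#' @export
setGeneric("pairTable", function(object) standardGeneric("pairTable"))
#' @rdname PremiRNA-class
#' @export
setMethod("pairTable", "PremiRNA", function(object) object@pairTable)

#' @rdname PremiRNA-class
#' @export
setGeneric("hairpinMfe", function(object) standardGeneric("hairpinMfe"))
#' @rdname PremiRNA-class
#' @export
setMethod("hairpinMfe", "PremiRNA", function(object) object@mfe)

#' @rdname PremiRNA-class
#' @param x a PremiRNA object
#' @export
setMethod("length", "PremiRNA", function(x) nchar(x@sequence))

#' HairpinAnatomy: structural regions of a hairpin
#'
#' Describes the anatomy of a hairpin as 1-based inclusive spans:
#' the terminal loop, the two arms, bulges (unpaired on exactly one
#' strand), internal loops (unpaired on both strands, stored one side per
#' span; non-terminal hairpin loops of branched structures are classified
#' here as well) and the unmatched terminal ends. Spans are 2-column
#' matrices (start, end); empty categories are 0-row matrices.
#'
#' @slot terminalLoop integer (start, end) of the terminal loop.
#' @slot arm5 integer (start, end) of the 5' arm (may be zero-length).
#' @slot arm3 integer (start, end) of the 3' arm.
#' @slot bulges integer matrix of one-sided unpaired spans.
#' @slot internalLoops integer matrix of two-sided unpaired spans.
#' @slot unmatchedEnds integer matrix of terminal unpaired spans.
#' @slot nLoops number of hairpin loops found in the structure; values
#'   above 1 indicate a branched structure.
#' @exportClass HairpinAnatomy
setClass("HairpinAnatomy",
  representation(
    terminalLoop = "integer",
    arm5 = "integer",
    arm3 = "integer",
    bulges = "matrix",
    internalLoops = "matrix",
    unmatchedEnds = "matrix",
    nLoops = "integer"
  )
)

#' @describeIn HairpinAnatomy-class display a summary
#' @param object a HairpinAnatomy object
#' @export
setMethod("show", "HairpinAnatomy", function(object) {
  cat("HairpinAnatomy\n")
  cat("  terminal loop: [", object@terminalLoop[1L], ", ",
      object@terminalLoop[2L], "]\n", sep = "")
  cat("  bulges: ", nrow(object@bulges),
      "  internal loops: ", nrow(object@internalLoops),
      "  unmatched ends: ", nrow(object@unmatchedEnds), "\n", sep = "")
  if (object@nLoops > 1L)
    cat("  branched structure (", object@nLoops, " hairpin loops)\n", sep = "")
  invisible(NULL)
})

#' @rdname HairpinAnatomy-class
#' @export
setGeneric("terminalLoop", function(object) standardGeneric("terminalLoop"))
#' @rdname HairpinAnatomy-class
#' @export
setMethod("terminalLoop", "HairpinAnatomy", function(object) object@terminalLoop)

#' TrainedModel: a fitted RBF-SVM duplex ranking model
#'
#' Stores the support vectors, the dual coefficients (alpha_i z_i), the
#' bias, the kernel parameters and the feature subset + encoding needed to
#' score new miRNA:miRNA* candidates. Scoring through [decisionValues()]
#' is a plain kernel expansion, so a model reloaded from disk reproduces
#' scores exactly.
#'
#' @slot sv numeric matrix of support vectors (rows).
#' @slot coefs numeric vector alpha_i z_i, one per support vector.
#' @slot b intercept of the decision function.
#' @slot gamma RBF kernel width.
#' @slot cost soft-margin penalty C.
#' @slot subset feature subset with encoding specification (as produced by
#'   [composeSubset()]).
#' @slot config candidate/feature configuration (see [featureConfig()]).
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(
    sv = "matrix",
    coefs = "numeric",
    b = "numeric",
    gamma = "numeric",
    cost = "numeric",
    subset = "list",
    config = "list"
  )
)

setValidity("TrainedModel", function(object) {
  msg <- character()
  if (nrow(object@sv) != length(object@coefs))
    msg <- c(msg, "one coefficient per support vector required")
  if (length(object@gamma) != 1L || object@gamma <= 0)
    msg <- c(msg, "gamma must be a single positive number")
  if (length(object@cost) == 1L && is.finite(object@cost) &&
      any(abs(object@coefs) > object@cost + 1e-8))
    msg <- c(msg, "|alpha_i| must not exceed C")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainedModel-class display a summary
#' @param object a TrainedModel object
#' @export
setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel (RBF-SVM duplex ranker)\n")
  cat("  support vectors: ", nrow(object@sv),
      "  dimension: ", ncol(object@sv), "\n", sep = "")
  cat("  C = ", format(object@cost), ",  gamma = ", format(object@gamma),
      "\n", sep = "")
  cat("  features: ", length(object@subset$features),
      " (", object@subset$provenance, ")\n", sep = "")
  invisible(NULL)
})
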