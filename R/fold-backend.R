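## Folding backend contract.
##
## A backend is a list of class "foldBackend" with elements
##   name:            backend label recorded in outputs
##   fold(seqs):      character vector -> data.frame(structure, mfe)
##   foldConstrained(seqs, constraints): as fold(), with per-sequence
##       constraint strings ('x' forces a position unpaired, '.' leaves it
##       free); used for duplex energies with a non-pairing linker.

#' Thermodynamic folding backend (ViennaRNA RNAfold)
#'
#' Returns a folding backend that shells out to the \code{RNAfold}
#' executable for minimum free energy structures, including
#' hard-constrained folds in which selected positions are forced to stay
#' unpaired. Sequences are folded in batch through a single process call.
#'
#' @param rnafold path to the RNAfold executable.
#' @return An object of class \code{foldBackend}.
#' @seealso [foldSequence()], [mfeFeatures()]
#' @export
viennaBackend <- function(rnafold = Sys.which("RNAfold")) {
  if (!nzchar(rnafold))
    stop("folding backend unavailable: RNAfold executable not found; ",
         "supply a backend implementing fold()/foldConstrained() instead")
  run <- function(seqs, constraints = NULL) {
    if (length(seqs) == 0L)
      return(data.frame(structure = character(), mfe = numeric()))
    ids <- sprintf("s%06d", seq_along(seqs))
    lines <- if (is.null(constraints)) {
      as.vector(rbind(paste0(">", ids), seqs))
    } else {
      stopifnot(length(constraints) == length(seqs),
                nchar(constraints) == nchar(seqs))
      as.vector(rbind(paste0(">", ids), seqs, constraints))
    }
    inp <- tempfile("rnafold_", fileext = ".fa")
    on.exit(unlink(inp), add = TRUE)
    writeLines(lines, inp)
    args <- c("--noPS", if (!is.null(constraints)) "-C", "--infile", inp)
    out <- suppressWarnings(system2(rnafold, args, stdout = TRUE, stderr = FALSE))
    st <- attr(out, "status")
    if (!is.null(st) && st != 0L)
      stop("RNAfold exited with status ", st)
    parseRnafoldOutput(out, length(seqs))
  }
  structure(list(
    name = "vienna-rnafold",
    fold = function(seqs) run(seqs),
    foldConstrained = function(seqs, constraints) run(seqs, constraints)
  ), class = "foldBackend")
}

parseRnafoldOutput <- function(lines, n) {
  sl <- grep("^[.()]+\\s+\\(", lines, value = TRUE)
  if (length(sl) != n)
    stop("unexpected RNAfold output: got ", length(sl),
         " structures for ", n, " sequences")
  m <- regmatches(sl, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)", sl))
  data.frame(
    structure = vapply(m, `[`, character(1L), 2L),
    mfe = as.numeric(vapply(m, `[`, character(1L), 3L))
  )
}

#' Build a folding backend from plain R functions
#'
#' Convenience wrapper mostly used to inject deterministic folding rules
#' (for example a fixed structure, or simple base-pair maximisation) where
#' thermodynamic folding is not wanted.
#'
#' @param fold function(seqs) returning data.frame(structure, mfe).
#' @param foldConstrained function(seqs, constraints); defaults to
#'   \code{fold} ignoring the constraints.
#' @param name backend label.
#' @return An object of class \code{foldBackend}.
#' @export
makeFoldBackend <- function(fold, foldConstrained = NULL, name = "custom") {
  if (is.null(foldConstrained))
    foldConstrained <- function(seqs, constraints) fold(seqs)
  structure(list(name = name, fold = fold, foldConstrained = foldConstrained),
            class = "foldBackend")
}

#' Fold an RNA sequence
#'
#' Predicts the minimum free energy secondary structure of one sequence
#' with the given backend.
#'
#' @param sequence RNA sequence string (nonempty).
#' @param backend a folding backend; default [viennaBackend()].
#' @return list with elements \code{structure} (dot-bracket) and
#'   \code{mfe} (kcal/mol).
#' @examples
#' \dontrun{
#' foldSequence("GGGGAAAACCCC")
#' }
#' @export
foldSequence <- function(sequence, backend = viennaBackend()) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  res <- backend$fold(sequence)
  if (nchar(res$structure[1L]) != nchar(sequence))
    stop("backend returned a structure of different length than the sequence")
  list(structure = res$structure[1L], mfe = res$mfe[1L])
}
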