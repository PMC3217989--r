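## FASTA / Vienna input-output and sequence normalization.

normalizeRna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Read pre-miRNA sequences from FASTA
#'
#' Reads a FASTA file, uppercases, converts T to U and drops records that
#' are empty or contain characters outside {A, C, G, U} (IUPAC ambiguity
#' codes are not handled; such records are skipped with a warning).
#'
#' @param path path to a FASTA file.
#' @return Named character vector of RNA sequences (names are the record
#'   ids, first whitespace-delimited token of the header), in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), f)
#' readHairpinFasta(f)
#' @export
readHairpinFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- normalizeRna(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  bad <- !grepl("^[ACGU]+$", seqs)
  if (any(bad)) {
    warning("skipping ", sum(bad), " record(s) with empty sequence or ",
            "non-ACGU characters: ", paste(ids[bad], collapse = ", "))
    seqs <- seqs[!bad]
  }
  seqs
}

#' Read and write Vienna records
#'
#' The Vienna format stores one record as three lines: ">id", the
#' sequence, and the dot-bracket structure optionally followed by the
#' energy in parentheses, e.g. \code{"((..)) (-1.20)"}.
#'
#' @param path file path.
#' @return \code{readVienna} returns a list of [PremiRNA-class] objects.
#' @export
readVienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop("malformed Vienna file: expected records of 3 lines")
  out <- list()
  for (i in seq(1L, length(lines), by = 3L)) {
    if (!startsWith(lines[i], ">"))
      stop("malformed Vienna record at line ", i, ": missing '>' header")
    id <- sub("\\s.*$", "", sub("^>", "", lines[i]))
    seq <- normalizeRna(trimws(lines[i + 1L]))
    sl <- trimws(lines[i + 2L])
    m <- regmatches(sl, regexec("^([.()]+)(\\s+\\(\\s*(-?[0-9.]+)\\s*\\))?$", sl))[[1L]]
    if (length(m) == 0L)
      stop("malformed structure line for record '", id, "'")
    mfe <- if (nzchar(m[4L])) as.numeric(m[4L]) else NA_real_
    out[[length(out) + 1L]] <- PremiRNA(id, seq, m[2L], mfe)
  }
  out
}

#' @rdname readVienna
#' @param x a [PremiRNA-class] object or list of them.
#' @return \code{writeVienna} returns \code{path}, invisibly.
#' @export
writeVienna <- function(x, path) {
  if (is(x, "PremiRNA")) x <- list(x)
  lines <- unlist(lapply(x, function(p) {
    sl <- hairpinStructure(p)
    if (!is.na(hairpinMfe(p)))
      sl <- sprintf("%s (%.2f)", sl, hairpinMfe(p))
    c(paste0(">", premirnaId(p)), hairpinSequence(p), sl)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a mature miRNA annotation table
#'
#' Tab-separated table with columns \code{premirna_id},
#' \code{mirna_start} (1-based start of the mature miRNA in the hairpin)
#' and optionally \code{mirna_name}.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns premirna_id, mirna_start, mirna_name.
#' @export
readAnnotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("premirna_id", "mirna_start")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  ann$mirna_start <- as.integer(ann$mirna_start)
  if (anyNA(ann$mirna_start) || any(ann$mirna_start < 1L))
    stop("mirna_start must be positive integers (1-based)")
  if (is.null(ann$mirna_name)) ann$mirna_name <- NA_character_
  ann[c("premirna_id", "mirna_start", "mirna_name")]
}

#' Write a mature miRNA annotation table
#'
#' @param ann data.frame with columns premirna_id, mirna_start and
#'   optionally mirna_name.
#' @param path output path.
#' @export
writeAnnotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
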