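## Dot-bracket parsing and hairpin anatomy.

#' Build a pair table from a dot-bracket structure
#'
#' @param structure dot-bracket string over "(", ")" and ".".
#' @return Integer vector with \code{pt[i]} = partner of position i
#'   (1-based) or NA for unpaired positions.
#' @examples
#' buildPairTable("((..))")
#' @export
buildPairTable <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop("invalid structure character '", chars[bad[1L]],
         "' at position ", bad[1L])
  n <- length(chars)
  pt <- rep(NA_integer_, n)
  stack <- integer(0L)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L)
        stop("unbalanced structure: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i
      pt[i] <- j
    }
  }
  if (length(stack))
    stop("unbalanced structure: unmatched '(' at position ", stack[1L])
  pt
}

unpairedRuns <- function(pt) {
  r <- rle(is.na(pt))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

emptySpan <- function() {
  matrix(integer(0L), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

#' Annotate the anatomy of a hairpin
#'
#' Identifies the terminal loop, arms, bulges, internal loops and
#' unmatched terminal ends of a [PremiRNA-class] from its pair table. For
#' branched structures (more than one hairpin loop) the loop enclosed by
#' the largest number of pairs is taken as the terminal loop and a
#' warning is emitted; loops of the other branches are reported among the
#' internal loops.
#'
#' @param pre a [PremiRNA-class] object with at least one base pair.
#' @return A [HairpinAnatomy-class] object.
#' @examples
#' p <- PremiRNA("h", "GGGAAAACCC", "(((....)))")
#' annotateAnatomy(p)
#' @export
annotateAnatomy <- function(pre) {
  pt <- pairTable(pre)
  n <- length(pt)
  paired <- which(!is.na(pt))
  if (length(paired) == 0L)
    stop("no hairpin: structure of '", premirnaId(pre), "' has no base pairs")

  runs <- unpairedRuns(pt)

  ## hairpin loops: unpaired runs directly closed by a pair
  isLoop <- logical(nrow(runs))
  depth <- integer(nrow(runs))
  open <- which(!is.na(pt) & pt > seq_len(n))
  for (k in seq_len(nrow(runs))) {
    u <- runs[k, 1L]; v <- runs[k, 2L]
    if (u > 1L && v < n && !is.na(pt[u - 1L]) && pt[u - 1L] == v + 1L) {
      isLoop[k] <- TRUE
      depth[k] <- sum(open < u & pt[open] > v)
    }
  }
  if (!any(isLoop))
    stop("no hairpin: structure of '", premirnaId(pre),
         "' has no loop closed by a base pair")
  nLoops <- sum(isLoop)
  if (nLoops > 1L)
    warning("branched structure in '", premirnaId(pre), "': ", nLoops,
            " hairpin loops; using the most deeply enclosed one")
  term <- which(isLoop)[which.max(depth[isLoop])]
  loopSpan <- runs[term, , drop = TRUE]

  bulges <- emptySpan()
  iloops <- emptySpan()
  ends <- emptySpan()
  for (k in seq_len(nrow(runs))) {
    if (k == term) next
    u <- runs[k, 1L]; v <- runs[k, 2L]
    if (u == 1L || v == n) {
      ends <- rbind(ends, runs[k, ])
    } else if (isLoop[k]) {
      iloops <- rbind(iloops, runs[k, ])
    } else {
      gap <- pt[u - 1L] - pt[v + 1L] - 1L
      if (!is.na(gap) && gap == 0L) {
        bulges <- rbind(bulges, runs[k, ])
      } else {
        iloops <- rbind(iloops, runs[k, ])
      }
    }
  }

  new("HairpinAnatomy",
      terminalLoop = as.integer(loopSpan),
      arm5 = c(1L, as.integer(loopSpan[1L]) - 1L),
      arm3 = c(as.integer(loopSpan[2L]) + 1L, n),
      bulges = bulges, internalLoops = iloops, unmatchedEnds = ends,
      nLoops = as.integer(nLoops))
}
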