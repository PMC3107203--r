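# IUPAC nucleotide degeneracy tables and mismatch counting.
#
# The scanner's match semantics are deliberately simple and explicit: a
# concrete base matches a consensus position iff it belongs to that
# position's allowed set. 'N' in a scanned window is treated as a concrete
# unknown: it matches only consensus columns whose allowed set is the full
# {A,C,G,T} (i.e. an N column).

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# reverse lookup: sorted base set pasted with "" -> code
.IUPAC_CODE_OF <- local({
  keys <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  setNames(names(.IUPAC_SETS), keys)
})

#' Allowed base sets of an IUPAC consensus string
#'
#' @param code a string over the 15-letter IUPAC nucleotide alphabet.
#' @return a list with one character vector of concrete bases per position.
#' @export
iupac_allowed_sets <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  chars <- strsplit(toupper(code), "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(.IUPAC_SETS)
  if (any(bad)) {
    stop("illegal IUPAC code '", chars[which(bad)[1]], "' at position ",
         which(bad)[1])
  }
  unname(.IUPAC_SETS[chars])
}

#' IUPAC code for a set of concrete bases
#'
#' @param bases character vector over \{A,C,G,T\}; duplicates allowed.
#' @return the single IUPAC letter denoting exactly that set.
#' @export
iupac_code_for <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("empty base set has no IUPAC code")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("base set must be over {A,C,G,T}, got: ",
         paste(bases, collapse = ","))
  }
  .IUPAC_CODE_OF[[paste(sort(bases), collapse = "")]]
}

#' An IUPAC degenerate consensus
#'
#' Carries the code string together with the per-position allowed base sets.
#'
#' @param code consensus string over the IUPAC alphabet.
#' @return an object of class \code{iupac_consensus} with elements
#'   \code{code} and \code{allowed}.
#' @export
iupac_consensus <- function(code) {
  allowed <- iupac_allowed_sets(code)
  structure(list(code = toupper(code), allowed = allowed),
            class = "iupac_consensus")
}

#' @export
print.iupac_consensus <- function(x, ...) {
  cat("IUPAC consensus: ", x$code, " (length ", length(x$allowed), ")\n",
      sep = "")
  invisible(x)
}

#' @export
length.iupac_consensus <- function(x) length(x$allowed)

as_consensus <- function(x) {
  if (inherits(x, "iupac_consensus")) x else iupac_consensus(x)
}

#' Count mismatches of a concrete window against an IUPAC consensus
#'
#' A position mismatches when the window base is outside the consensus
#' allowed set at that position. \code{N} in the window matches only
#' \code{N} columns.
#'
#' @param window DNA string over \{A,C,G,T,N\}, same length as the consensus.
#' @param consensus an \code{\link{iupac_consensus}} or code string.
#' @return integer mismatch count.
#' @export
iupac_mismatch_count <- function(window, consensus) {
  consensus <- as_consensus(consensus)
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(chars) != length(consensus$allowed)) {
    stop("window length (", length(chars), ") != consensus length (",
         length(consensus$allowed), ")")
  }
  n_allowed <- lengths(consensus$allowed)
  sum(vapply(seq_along(chars), function(i) {
    b <- chars[i]
    if (b == "N") n_allowed[i] < 4L else !(b %in% consensus$allowed[[i]])
  }, logical(1)))
}

#' Reverse complement of a DNA string
#'
#' Supports the full IUPAC alphabet plus gaps.
#'
#' @param seq a single DNA string.
#' @return the reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNTGCAYRSWMKVHDBN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}
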