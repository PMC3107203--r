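# Bipartite -35/-10 promoter model: degenerate consensus, invariant
# positions, per-column information content.

#' Construct a promoter alignment
#'
#' @param rows equal-length DNA strings (gap character '-' allowed).
#' @param labels one label per row (gene ids); defaults to names of
#'   \code{rows} or row1..rowN.
#' @param element_span 0-based half-open column interval \code{c(start, end)}
#'   delimiting the -35 element within the alignment; defaults to the full
#'   width.
#' @return an object of class \code{promoter_alignment}.
#' @export
promoter_alignment <- function(rows, labels = NULL, element_span = NULL) {
  rows <- toupper(rows)
  if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows must have equal length")
  if (is.null(labels)) {
    labels <- if (!is.null(names(rows))) names(rows)
      else paste0("row", seq_along(rows))
  }
  if (is.null(element_span)) element_span <- c(0L, w)
  element_span <- as.integer(element_span)
  if (element_span[1] < 0L || element_span[2] > w ||
      element_span[1] >= element_span[2]) {
    stop("element_span must lie within [0, ", w, ")")
  }
  structure(list(labels = as.character(labels), rows = unname(rows),
                 width = w, element_span = element_span),
            class = "promoter_alignment")
}

# character matrix view of the alignment (rows x columns)
.aln_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
}

#' Build the IUPAC consensus of the -35 element
#'
#' Per column, the emitted code denotes exactly the set of distinct bases
#' observed, so every input row matches the consensus with zero mismatches.
#'
#' @param alignment a \code{\link{promoter_alignment}}; only the columns in
#'   \code{element_span} are used, and they must be gap-free.
#' @return an \code{\link{iupac_consensus}}.
#' @export
build_consensus <- function(alignment) {
  stopifnot(inherits(alignment, "promoter_alignment"))
  m <- .aln_matrix(alignment)
  span <- (alignment$element_span[1] + 1L):alignment$element_span[2]
  m <- m[, span, drop = FALSE]
  if (any(m == "-")) stop("gap inside the -35 element span")
  codes <- apply(m, 2L, function(col) iupac_code_for(unique(col)))
  iupac_consensus(paste(codes, collapse = ""))
}

#' Columns where all rows share one base
#'
#' @param alignment a \code{\link{promoter_alignment}}; the scan is over the
#'   \code{element_span} columns and indices are reported relative to the
#'   span start (0-based), matching consensus positions.
#' @return integer vector of 0-based invariant positions within the element.
#' @export
invariant_positions <- function(alignment) {
  stopifnot(inherits(alignment, "promoter_alignment"))
  m <- .aln_matrix(alignment)
  span <- (alignment$element_span[1] + 1L):alignment$element_span[2]
  m <- m[, span, drop = FALSE]
  if (any(m == "-")) stop("gap inside the -35 element span")
  inv <- apply(m, 2L, function(col) length(unique(col)) == 1L)
  which(inv) - 1L
}

#' Construct a bipartite -35/-10 promoter model
#'
#' The model is the -35 degenerate consensus plus the requirement of an
#' anchor base (default G) in the -10 region, separated from the -35 element
#' by a spacer. Spacer convention: the number of nucleotides strictly
#' between the last base of the -35 element and the anchor base.
#'
#' @param minus35 an \code{\link{iupac_consensus}} or code string.
#' @param invariant_positions 0-based positions within the -35 element that
#'   the filter cascade requires to match exactly.
#' @param minus10_anchor single required base in the -10 region (default "G").
#' @param spacer_min,spacer_max allowed spacer range in nt (defaults 16, 18).
#' @param max_mismatches mismatch budget for the raw scan (default 2).
#' @return an object of class \code{bipartite_motif}.
#' @export
bipartite_motif <- function(minus35, invariant_positions = integer(),
                            minus10_anchor = "G",
                            spacer_min = 16L, spacer_max = 18L,
                            max_mismatches = 2L) {
  minus35 <- as_consensus(minus35)
  invariant_positions <- sort(unique(as.integer(invariant_positions)))
  k <- length(minus35$allowed)
  if (length(invariant_positions) &&
      (min(invariant_positions) < 0L || max(invariant_positions) >= k)) {
    stop("invariant_positions must be 0-based indices into the -35 element")
  }
  stopifnot(spacer_min <= spacer_max, max_mismatches >= 0L,
            minus10_anchor %in% c("A", "C", "G", "T"))
  structure(list(minus35 = minus35,
                 invariant_positions = invariant_positions,
                 minus10_anchor = minus10_anchor,
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 spacer_convention = "nt strictly between -35 end and anchor",
                 max_mismatches = as.integer(max_mismatches)),
            class = "bipartite_motif")
}

#' Build a full model from a promoter alignment
#'
#' Convenience wrapper: consensus and invariant positions from the
#' alignment's -35 element span, other parameters as given.
#'
#' @inheritParams bipartite_motif
#' @param alignment a \code{\link{promoter_alignment}}.
#' @return a \code{bipartite_motif}.
#' @export
motif_from_alignment <- function(alignment, minus10_anchor = "G",
                                 spacer_min = 16L, spacer_max = 18L,
                                 max_mismatches = 2L) {
  bipartite_motif(build_consensus(alignment),
                  invariant_positions(alignment),
                  minus10_anchor, spacer_min, spacer_max, max_mismatches)
}

#' @export
print.bipartite_motif <- function(x, ...) {
  cat("bipartite promoter model\n",
      "  -35 consensus : ", x$minus35$code, "\n",
      "  invariant pos : ",
      if (length(x$invariant_positions))
        paste(x$invariant_positions, collapse = ",") else "(none)", "\n",
      "  -10 anchor    : ", x$minus10_anchor,
      " at spacer ", x$spacer_min, "-", x$spacer_max, " nt\n",
      "  budget        : ", x$max_mismatches, " mismatches\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize a motif model as JSON
#'
#' @param model a \code{bipartite_motif}.
#' @param path JSON file.
#' @export
write_motif_json <- function(model, path) {
  stopifnot(inherits(model, "bipartite_motif"))
  obj <- list(minus35 = model$minus35$code,
              invariant_positions = model$invariant_positions,
              minus10_anchor = model$minus10_anchor,
              spacer_min = model$spacer_min,
              spacer_max = model$spacer_max,
              spacer_convention = model$spacer_convention,
              max_mismatches = model$max_mismatches)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_motif_json
#' @export
read_motif_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bipartite_motif(obj$minus35, obj$invariant_positions %||% integer(),
                  obj$minus10_anchor, obj$spacer_min, obj$spacer_max,
                  obj$max_mismatches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Information content of an alignment column
#'
#' Uncorrected Shannon information: 2 - H2(base frequencies). Gaps are
#' excluded from the counts. No small-sample correction is applied (WebLogo
#' applies one); the uncorrected value is closed-form testable.
#'
#' @param counts named counts over \{A,C,G,T\} (or a character vector of the
#'   column's bases, which is tabulated).
#' @return information content in bits, in [0, 2].
#' @export
information_content <- function(counts) {
  if (is.character(counts)) {
    counts <- table(factor(counts[counts != "-"], levels = c("A", "C", "G", "T")))
  }
  counts <- as.numeric(counts)
  total <- sum(counts)
  if (total <= 0) stop("empty column: no bases to score")
  p <- counts[counts > 0] / total
  2 + sum(p * log2(p))
}

#' Per-column statistics of a promoter alignment
#'
#' @param alignment a \code{\link{promoter_alignment}} (all columns, not
#'   just the -35 element).
#' @return data.frame with one row per column: \code{column_index} (0-based),
#'   counts \code{A,C,G,T}, \code{gaps}, \code{information_content}.
#' @export
logo_table <- function(alignment) {
  stopifnot(inherits(alignment, "promoter_alignment"))
  m <- .aln_matrix(alignment)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    cnt <- table(factor(col, levels = c("A", "C", "G", "T", "-")))
    data.frame(column_index = j - 1L,
               A = as.integer(cnt[["A"]]), C = as.integer(cnt[["C"]]),
               G = as.integer(cnt[["G"]]), T = as.integer(cnt[["T"]]),
               gaps = as.integer(cnt[["-"]]),
               information_content =
                 if (sum(cnt[c("A", "C", "G", "T")]) > 0)
                   information_content(col) else NA_real_)
  })
  do.call(rbind, rows)
}
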