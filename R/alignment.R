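# Pairwise protein similarity (local alignment + Karlin-Altschul E-value
# estimate) and a small deterministic progressive multiple aligner used for
# CRD alignments.

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Local pairwise protein similarity with an E-value estimate
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps, defaults open 11 /
#' extend 1) scored in bits via the Karlin-Altschul transformation
#' S' = (lambda * S - ln K) / ln 2 with the standard gapped BLOSUM62
#' parameters lambda = 0.267, K = 0.041, and E = m * n * 2^(-S'). This is a
#' documented approximation to BLASTP, not a reimplementation of it: the
#' search space defaults to the product of the two sequence lengths (BLASTP
#' uses edge-corrected database sizes), so absolute E-values differ from a
#' database search while separating homologs from unrelated sequences at
#' the thresholds used here (1e-4, 2e-10).
#'
#' @param a,b amino-acid strings (nonempty).
#' @param gap_open,gap_extend positive gap costs.
#' @param lambda,K Karlin-Altschul parameters.
#' @param search_space override for m * n.
#' @return list with \code{score} (raw), \code{bits}, \code{evalue}.
#' @export
pairwise_similarity <- function(a, b, gap_open = 11, gap_extend = 1,
                                lambda = 0.267, K = 0.041,
                                search_space = NULL) {
  stopifnot(nzchar(a), nzchar(b))
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = .blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  bits <- (lambda * s - log(K)) / log(2)
  mn <- if (is.null(search_space)) as.numeric(nchar(a)) * nchar(b)
    else as.numeric(search_space)
  list(score = s, bits = bits, evalue = mn * 2^(-bits))
}

# ---- progressive multiple alignment -------------------------------------

# Needleman-Wunsch of one sequence against a profile (list of columns).
# Linear gap penalty; column-vs-residue score is the mean BLOSUM62 score
# over the column's rows, gaps in the column scoring `gap`. Tie-break order
# when traceback scores are equal: diagonal, then up (consume profile
# column), then left (consume residue). Deterministic by construction.
.nw_profile <- function(profile_cols, seq_chars, gap = -8) {
  B <- .blosum62()
  np <- length(profile_cols); ns <- length(seq_chars)
  col_score <- function(col, r) {
    v <- vapply(col, function(x) if (x == "-") gap else B[x, r], numeric(1))
    mean(v)
  }
  S <- matrix(0, np + 1L, ns + 1L)
  S[, 1] <- gap * (0:np)
  S[1, ] <- gap * (0:ns)
  P <- matrix(0L, np + 1L, ns + 1L)  # 1 diag, 2 up, 3 left
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in seq_len(np)) {
    for (j in seq_len(ns)) {
      d <- S[i, j] + col_score(profile_cols[[i]], seq_chars[j])
      u <- S[i, j + 1L] + gap
      l <- S[i + 1L, j] + gap
      best <- max(d, u, l)
      S[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (d >= u && d >= l) 1L
        else if (u >= l) 2L else 3L
    }
  }
  # traceback -> aligned profile-column indices (0 = new gap column) and
  # aligned residue indices (0 = gap in the new row)
  pi <- np + 1L; pj <- ns + 1L
  cols <- integer(); res <- integer()
  while (pi > 1L || pj > 1L) {
    mv <- P[pi, pj]
    if (mv == 1L) {
      cols <- c(pi - 1L, cols); res <- c(pj - 1L, res)
      pi <- pi - 1L; pj <- pj - 1L
    } else if (mv == 2L) {
      cols <- c(pi - 1L, cols); res <- c(0L, res)
      pi <- pi - 1L
    } else {
      cols <- c(0L, cols); res <- c(pj - 1L, res)
      pj <- pj - 1L
    }
  }
  list(cols = cols, res = res, score = S[np + 1L, ns + 1L])
}

#' Progressive multiple alignment of protein sequences
#'
#' Sequences are joined in input order: the first seeds the profile and each
#' subsequent sequence is globally aligned to the growing profile
#' (Needleman-Wunsch, BLOSUM62 column means, linear gap penalty). The result
#' is deterministic given the input order and row order is preserved. This
#' deliberately does not reproduce ClustalX's guide tree; column-level
#' conclusions that depend on the exact tree should be checked for
#' robustness.
#'
#' @param seqs named character vector of at least 2 amino-acid sequences.
#' @param gap linear gap penalty per aligned column (default -8).
#' @return named character vector of equal-length gapped rows.
#' @export
align_proteins <- function(seqs, gap = -8) {
  if (length(seqs) < 2L) stop("alignment needs at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  rows <- list(strsplit(toupper(seqs[[1]]), "", fixed = TRUE)[[1]])
  for (s in seq_along(seqs)[-1]) {
    chars <- strsplit(toupper(seqs[[s]]), "", fixed = TRUE)[[1]]
    width <- length(rows[[1]])
    profile_cols <- lapply(seq_len(width), function(j) {
      vapply(rows, `[[`, "", j)
    })
    aln <- .nw_profile(profile_cols, chars, gap = gap)
    rows <- lapply(rows, function(r) {
      ifelse(aln$cols == 0L, "-", r[pmax(aln$cols, 1L)])
    })
    rows[[length(rows) + 1L]] <- ifelse(aln$res == 0L, "-",
                                        chars[pmax(aln$res, 1L)])
  }
  setNames(vapply(rows, paste, "", collapse = ""), names(seqs))
}

#' Default functional-similarity groups for amino acids
#'
#' \{ILVM\} \{FWY\} \{KRH\} \{DE\} \{ST\} \{NQ\} \{AG\} \{C\} \{P\};
#' anything else forms its own singleton group.
#'
#' @return named character vector mapping residue -> group label.
#' @export
default_similarity_groups <- function() {
  groups <- list(ILVM = c("I", "L", "V", "M"), FWY = c("F", "W", "Y"),
                 KRH = c("K", "R", "H"), DE = c("D", "E"),
                 ST = c("S", "T"), NQ = c("N", "Q"), AG = c("A", "G"),
                 C = "C", P = "P")
  out <- character()
  for (g in names(groups)) out[groups[[g]]] <- g
  out
}

#' Conservation-class parameters
#'
#' @param min_count minimum count of the modal residue (or modal similarity
#'   group) for the "conserved" (resp. "similar") class. If NULL it is
#'   derived from \code{min_fraction} of the row count at call time; the
#'   default fraction 11/21 matches a rule of "at least 11 of 21 sequences".
#' @param min_fraction fraction of rows when \code{min_count} is NULL.
#' @param similarity_groups residue -> group map, see
#'   \code{\link{default_similarity_groups}}.
#' @return an object of class \code{conservation_params}.
#' @export
conservation_params <- function(min_count = NULL, min_fraction = 11 / 21,
                                similarity_groups = default_similarity_groups()) {
  structure(list(min_count = min_count, min_fraction = min_fraction,
                 similarity_groups = similarity_groups),
            class = "conservation_params")
}

#' Classify alignment columns by conservation
#'
#' Per column: \code{invariant} when all rows carry the same residue with no
#' gaps; else \code{conserved} when the modal residue count reaches the
#' threshold; else \code{similar} when the modal similarity-group count
#' reaches it; else \code{none}. Gaps never count toward residues or groups.
#'
#' @param alignment named character vector of equal-length gapped rows.
#' @param params a \code{\link{conservation_params}}.
#' @return data.frame with \code{column_index} (0-based),
#'   \code{modal_residue}, \code{modal_count}, \code{modal_group},
#'   \code{modal_group_count}, \code{gap_count},
#'   \code{conservation_class}.
#' @export
conservation_classes <- function(alignment, params = conservation_params()) {
  stopifnot(length(alignment) >= 2L,
            length(unique(nchar(alignment))) == 1L)
  n <- length(alignment)
  min_count <- params$min_count
  if (is.null(min_count)) min_count <- ceiling(params$min_fraction * n)
  if (min_count > n) stop("min_count exceeds the number of rows")
  groups <- params$similarity_groups
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    gap_count <- sum(col == "-")
    if (length(res) == n && length(unique(res)) == 1L) {
      cls <- "invariant"
    } else {
      cls <- "none"
    }
    tab <- if (length(res)) sort(table(res), decreasing = TRUE) else NULL
    modal_res <- if (!is.null(tab)) names(tab)[1] else NA_character_
    modal_count <- if (!is.null(tab)) as.integer(tab[1]) else 0L
    grp <- groups[res]
    grp[is.na(grp)] <- res[is.na(grp)]  # singleton group for unknowns
    gtab <- if (length(grp)) sort(table(grp), decreasing = TRUE) else NULL
    modal_grp <- if (!is.null(gtab)) names(gtab)[1] else NA_character_
    modal_gcount <- if (!is.null(gtab)) as.integer(gtab[1]) else 0L
    if (cls == "none") {
      if (modal_count >= min_count) cls <- "conserved"
      else if (modal_gcount >= min_count) cls <- "similar"
    }
    data.frame(column_index = j - 1L, modal_residue = modal_res,
               modal_count = modal_count, modal_group = modal_grp,
               modal_group_count = modal_gcount, gap_count = gap_count,
               conservation_class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
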