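# Genome-wide bipartite motif scan and the three-stage filter cascade.
#
# Hit coordinate convention: `minus35_start` is the 0-based forward-genome
# coordinate of the FIRST base of the -35 element in scan orientation. For a
# + strand hit the element occupies [minus35_start, minus35_start + k); for
# a - strand hit it occupies [minus35_start - k + 1, minus35_start + 1) and
# is read right-to-left on the complementary strand.

.empty_hits <- function() {
  data.frame(contig_id = character(), minus35_start = integer(),
             strand = character(), mismatches = integer(),
             spacer_len = integer(), minus10_pos = integer(),
             window_seq = character(), stringsAsFactors = FALSE)
}

# per-window mismatch counts against the consensus on one character vector,
# via k shifted logical membership vectors (O(k * L), fully vectorized)
.window_mismatches <- function(chars, allowed) {
  L <- length(chars); k <- length(allowed)
  if (L < k) return(integer())
  M <- integer(L - k + 1L)
  for (j in seq_len(k)) {
    ok <- if (length(allowed[[j]]) == 4L) rep(TRUE, L)
      else chars %in% allowed[[j]]
    M <- M + !ok[j:(j + L - k)]
  }
  M
}

#' Scan a genome for the -35 degenerate consensus
#'
#' Every window on each requested strand whose IUPAC mismatch count is at
#' most the model's budget is reported exactly once; overlapping hits are
#' all kept. Minus-strand hits are found on the reverse complement and
#' reported in forward genomic coordinates with \code{strand == "-"}.
#'
#' @param genome a \code{\link{genome_record}}.
#' @param model a \code{\link{bipartite_motif}}.
#' @param strands "both" (default), "+" or "-".
#' @return a data.frame of hits sorted by (contig, coordinate, strand) with
#'   columns \code{contig_id}, \code{minus35_start}, \code{strand},
#'   \code{mismatches}, \code{spacer_len}, \code{minus10_pos} (both NA until
#'   \code{\link{check_minus10}}), \code{window_seq} (scan orientation).
#' @export
scan_genome <- function(genome, model, strands = c("both", "+", "-")) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(model, "bipartite_motif"))
  strands <- match.arg(strands)
  allowed <- model$minus35$allowed
  k <- length(allowed)
  if (genome$length < k) stop("genome shorter than the consensus")
  budget <- model$max_mismatches
  out <- list()

  if (strands %in% c("both", "+")) {
    chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
    M <- .window_mismatches(chars, allowed)
    idx <- which(M <= budget)
    if (length(idx)) {
      out$fwd <- data.frame(
        contig_id = genome$id, minus35_start = idx - 1L, strand = "+",
        mismatches = M[idx], spacer_len = NA_integer_,
        minus10_pos = NA_integer_,
        window_seq = substring(genome$seq, idx, idx + k - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "-")) {
    rc <- revcomp(genome$seq)
    chars <- strsplit(rc, "", fixed = TRUE)[[1]]
    M <- .window_mismatches(chars, allowed)
    idx <- which(M <= budget)
    if (length(idx)) {
      L <- genome$length
      out$rev <- data.frame(
        contig_id = genome$id,
        minus35_start = L - idx + 1L - 1L,  # forward coord of first scan base
        strand = "-", mismatches = M[idx], spacer_len = NA_integer_,
        minus10_pos = NA_integer_,
        window_seq = substring(rc, idx, idx + k - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$contig_id, hits$minus35_start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# base at forward 0-based position `pos` (with circular wrap if allowed);
# NA_character_ when out of range
.base_at <- function(genome, pos) {
  L <- genome$length
  if (pos < 0L || pos >= L) {
    if (!genome$circular) return(NA_character_)
    pos <- pos %% L
  }
  substr(genome$seq, pos + 1L, pos + 1L)
}

#' Locate the -10 anchor downstream of each hit
#'
#' Searches spacers from \code{spacer_min} up to \code{spacer_max} (the
#' spacer is the number of nucleotides strictly between the last base of the
#' -35 element and the anchor) and records the smallest qualifying spacer
#' with the anchor base present in hit orientation. Windows running past a
#' linear contig end leave the anchor absent; circular genomes wrap.
#'
#' @param hits a hit data.frame from \code{\link{scan_genome}}.
#' @param genome the scanned \code{\link{genome_record}}.
#' @param model the \code{\link{bipartite_motif}}.
#' @return the hits with \code{spacer_len} and \code{minus10_pos} (forward
#'   genomic coordinate of the anchor base) filled where found.
#' @export
check_minus10 <- function(hits, genome, model) {
  if (!nrow(hits)) return(hits)
  k <- length(model$minus35$allowed)
  anchor <- model$minus10_anchor
  anchor_rc <- revcomp(anchor)
  for (i in seq_len(nrow(hits))) {
    plus <- hits$strand[i] == "+"
    last35 <- if (plus) hits$minus35_start[i] + k - 1L
      else hits$minus35_start[i] - k + 1L
    for (sp in model$spacer_min:model$spacer_max) {
      pos <- if (plus) last35 + 1L + sp else last35 - 1L - sp
      b <- .base_at(genome, pos)
      if (is.na(b)) next
      if ((plus && b == anchor) || (!plus && b == anchor_rc)) {
        hits$spacer_len[i] <- sp
        hits$minus10_pos[i] <- if (pos < 0L || pos >= genome$length)
          pos %% genome$length else pos
        break
      }
    }
  }
  hits
}

#' Assign each hit to its nearest downstream gene
#'
#' The nearest gene whose translational start lies downstream of the hit in
#' the hit's orientation, within \code{max_distance}, is assigned. The
#' distance is the number of nucleotides strictly between the last base of
#' the -35 element and the gene's first coding base. Genes on either strand
#' are considered; \code{strand_ok} records whether the hit and gene strands
#' agree. Ties are broken toward the gene start with the smaller genomic
#' coordinate.
#'
#' @param hits hit data.frame from \code{\link{scan_genome}}.
#' @param annotations a \code{\link{gene_annotation}} table.
#' @param max_distance maximum hit-to-start distance in nt (default 300).
#' @return hits with added columns \code{downstream_gene},
#'   \code{distance_to_start}, \code{strand_ok}.
#' @export
assign_downstream_gene <- function(hits, annotations, max_distance = 300L) {
  hits$downstream_gene <- NA_character_
  hits$distance_to_start <- NA_integer_
  hits$strand_ok <- FALSE
  if (!nrow(hits)) return(hits)
  # translational start: first coding base in reading orientation
  tx_start <- ifelse(annotations$strand == "+", annotations$start,
                     annotations$end - 1L)
  for (i in seq_len(nrow(hits))) {
    ann <- annotations$contig_id == hits$contig_id[i]
    if (!any(ann)) next
    k <- nchar(hits$window_seq[i])
    plus <- hits$strand[i] == "+"
    last35 <- if (plus) hits$minus35_start[i] + k - 1L
      else hits$minus35_start[i] - k + 1L
    d <- if (plus) tx_start - last35 - 1L else last35 - tx_start - 1L
    ok <- ann & d >= 0L & d <= max_distance
    if (!any(ok)) next
    cand <- which(ok)
    # equidistant tie-break: gene with the smaller genomic start coordinate
    best <- cand[order(d[cand], annotations$start[cand],
                       annotations$gene_id[cand])][1]
    hits$downstream_gene[i] <- annotations$gene_id[best]
    hits$distance_to_start[i] <- d[best]
    hits$strand_ok[i] <- annotations$strand[best] == hits$strand[i]
  }
  hits
}

# does the window satisfy every invariant -35 position exactly?
.invariants_ok <- function(window_seq, model) {
  inv <- model$invariant_positions
  if (!length(inv)) return(rep(TRUE, length(window_seq)))
  allowed <- model$minus35$allowed
  vapply(window_seq, function(w) {
    chars <- strsplit(w, "", fixed = TRUE)[[1]]
    all(vapply(inv, function(p) chars[p + 1L] %in% allowed[[p + 1L]],
               logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Apply the three-stage filter cascade
#'
#' Stages, in order: (1) downstream-gene assignment and strand orientation;
#' (2) exact match at the invariant -35 positions; (3) -10 anchor within the
#' spacer window. All three flags are computed for every candidate
#' regardless of earlier failures, so the report can say why each candidate
#' fell out. \code{final} requires all three plus an assigned gene.
#'
#' @param hits raw hits from \code{\link{scan_genome}}.
#' @param model the \code{\link{bipartite_motif}}.
#' @param genome the scanned \code{\link{genome_record}} (needed for the
#'   -10 anchor search when hits lack it).
#' @param annotations a \code{\link{gene_annotation}} table.
#' @param max_distance see \code{\link{assign_downstream_gene}}.
#' @return an object of class \code{regulon_report}: list with
#'   \code{model} (consensus summary), \code{candidates} (per-hit flags) and
#'   \code{counts} (raw / oriented / invariants / final), monotonically
#'   non-increasing.
#' @export
filter_candidates <- function(hits, model, genome, annotations,
                              max_distance = 300L) {
  if (nrow(hits) && all(is.na(hits$spacer_len))) {
    hits <- check_minus10(hits, genome, model)
  }
  cand <- assign_downstream_gene(hits, annotations, max_distance)
  if (nrow(cand)) {
    cand$invariants_ok <- .invariants_ok(cand$window_seq, model)
    cand$minus10_ok <- !is.na(cand$spacer_len)
    cand$final <- cand$strand_ok & !is.na(cand$downstream_gene) &
      cand$invariants_ok & cand$minus10_ok
  } else {
    cand$invariants_ok <- logical()
    cand$minus10_ok <- logical()
    cand$final <- logical()
  }
  assigned <- cand$strand_ok & !is.na(cand$downstream_gene)
  counts <- c(raw = nrow(cand),
              oriented = sum(assigned),
              invariants = sum(assigned & cand$invariants_ok),
              final = sum(cand$final))
  structure(list(model = list(minus35 = model$minus35$code,
                              invariant_positions = model$invariant_positions,
                              minus10_anchor = model$minus10_anchor,
                              spacer = c(model$spacer_min, model$spacer_max),
                              max_mismatches = model$max_mismatches),
                 candidates = cand, counts = counts),
            class = "regulon_report")
}

#' @export
print.regulon_report <- function(x, ...) {
  cat("regulon scan report (-35 ", x$model$minus35, ")\n", sep = "")
  cat("  raw hits            :", x$counts[["raw"]], "\n")
  cat("  oriented + assigned :", x$counts[["oriented"]], "\n")
  cat("  + invariant -35 pos :", x$counts[["invariants"]], "\n")
  cat("  + -10 anchor (final):", x$counts[["final"]], "\n")
  invisible(x)
}

#' Write hits or candidates as TSV
#'
#' @param hits a hit/candidate data.frame.
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "")
}

#' Write a regulon report as JSON
#'
#' @param report a \code{regulon_report}.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  obj <- list(model = report$model,
              counts = as.list(report$counts),
              candidates = report$candidates)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
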