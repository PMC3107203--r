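# Genome and annotation I/O, upstream-region extraction.
#
# Internal coordinate convention: 0-based, half-open [start, end).
# File interfaces keep each format's native convention (GFF3/GenBank are
# 1-based inclusive); conversion happens exactly once, at read time.

#' Construct a genome record
#'
#' @param id contig/replicon identifier (nonempty).
#' @param seq DNA string over \{A,C,G,T,N\}; lowercase is uppercased.
#' @param circular logical; circular replicons let the -10 anchor search
#'   wrap past the end.
#' @return an object of class \code{genome_record} with fields \code{id},
#'   \code{seq}, \code{length}, \code{circular}.
#' @export
genome_record <- function(id, seq, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("illegal character '", substr(seq, bad, bad),
         "' at offset ", bad, " in record '", id, "'")
  }
  structure(list(id = id, seq = seq, length = nchar(seq),
                 circular = isTRUE(circular)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("genome_record '", x$id, "': ", x$length, " nt",
      if (x$circular) " (circular)" else "", "\n", sep = "")
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file; one \code{genome_record} per entry, in file order.
#' @param circular logical, recycled across records.
#' @return list of \code{genome_record}.
#' @export
read_genome <- function(path, circular = FALSE) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  circular <- rep_len(circular, length(set))
  lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), circular = circular[i])
  })
}

#' Construct a gene annotation table
#'
#' @param gene_id,contig_id character vectors.
#' @param start,end 0-based half-open coordinates.
#' @param strand "+" or "-".
#' @param product optional description.
#' @return a \code{data.frame} of class \code{gene_annotation}, sorted by
#'   (contig_id, start).
#' @export
gene_annotation <- function(gene_id, contig_id, start, end, strand,
                            product = NA_character_) {
  stopifnot(length(gene_id) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(start >= end)) {
    stop("annotation coordinates must satisfy 0 <= start < end")
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1])
  }
  ann <- data.frame(gene_id = as.character(gene_id),
                    contig_id = as.character(contig_id),
                    start = start, end = end,
                    strand = as.character(strand),
                    product = rep_len(as.character(product), length(gene_id)),
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$contig_id, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read gene annotations from GFF3 or GenBank
#'
#' GFF3 is parsed with \pkg{rtracklayer}; GenBank flat files with a minimal
#' in-package reader restricted to simple and \code{complement()} locations.
#' 1-based inclusive file coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path annotation file.
#' @param feature_types feature types to retain (GFF3 column 3 / GenBank
#'   feature keys).
#' @param format "auto" sniffs from the extension and file head.
#' @return a \code{gene_annotation} data.frame sorted by (contig_id, start).
#' @export
read_annotations <- function(path, feature_types = c("gene", "CDS"),
                             format = c("auto", "gff3", "genbank")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
      else if (ext %in% c("gb", "gbk", "gbff", "genbank")) "genbank"
      else {
        head1 <- readLines(path, n = 1L, warn = FALSE)
        if (length(head1) && grepl("^##gff", head1)) "gff3"
        else if (length(head1) && grepl("^LOCUS", head1)) "genbank"
        else stop("cannot determine annotation dialect of: ", path)
      }
  }
  if (format == "gff3") .read_gff3(path, feature_types)
  else .read_genbank(path, feature_types)
}

.read_gff3 <- function(path, feature_types) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse failure for ", path,
                                          ": ", conditionMessage(e)))
  keep <- as.character(gr$type) %in% feature_types
  gr <- gr[keep]
  if (length(gr) == 0L) {
    return(gene_annotation(character(), character(), integer(), integer(),
                           character()))
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  if (!is.null(gr$locus_tag)) ids <- ifelse(is.na(ids), gr$locus_tag, ids)
  if (!is.null(gr$Name)) ids <- ifelse(is.na(ids), gr$Name, ids)
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  product <- if (!is.null(gr$product)) as.character(gr$product) else NA_character_
  gene_annotation(gene_id = as.character(ids),
                  contig_id = as.character(GenomicRanges::seqnames(gr)),
                  start = BiocGenerics::start(gr) - 1L,
                  end = BiocGenerics::end(gr),
                  strand = strand, product = product)
}

# Minimal GenBank flat-file feature reader. Handles `123..456` and
# `complement(123..456)` locations only; join()/order() features error,
# matching the package's stated non-goal of spliced locations.
.read_genbank <- function(path, feature_types) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file: ", path)
  }
  contig <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[1])
  feat_from <- which(grepl("^FEATURES", lines))
  feat_to <- which(grepl("^(ORIGIN|CONTIG|//)", lines))
  feat_to <- if (length(feat_to)) min(feat_to[feat_to > feat_from[1]]) else length(lines) + 1L
  if (!length(feat_from)) stop("no FEATURES table in ", path)
  block <- lines[(feat_from[1] + 1L):(feat_to - 1L)]

  # a feature header line has the key in columns 6-20
  is_header <- grepl("^\\s{5}\\S", block)
  keys <- trimws(substr(block[is_header], 1, 20))
  locs <- trimws(substr(block[is_header], 21, nchar(block[is_header])))
  hdr_idx <- which(is_header)

  out <- list()
  for (i in seq_along(hdr_idx)) {
    if (!keys[i] %in% feature_types) next
    loc <- locs[i]
    qual_lines <- if (i < length(hdr_idx)) {
      block[(hdr_idx[i] + 1L):(hdr_idx[i + 1L] - 1L)]
    } else block[-seq_len(hdr_idx[i])]
    if (grepl("join|order", loc)) {
      stop("spliced GenBank location not supported: ", loc)
    }
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    if (length(nums) != 2L) stop("unparseable GenBank location: ", loc)
    s1 <- as.integer(nums[1]); s2 <- as.integer(nums[2])
    if (s1 > s2) stop("GenBank record error: start > end in ", loc)
    get_qual <- function(name) {
      m <- grep(paste0('^\\s+/', name, '="?'), qual_lines, value = TRUE)
      if (!length(m)) return(NA_character_)
      sub('"?$', "", sub(paste0('^\\s+/', name, '="?'), "", m[1]))
    }
    gid <- get_qual("locus_tag")
    if (is.na(gid)) gid <- get_qual("gene")
    if (is.na(gid)) gid <- paste0(keys[i], "_", s1)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid, contig_id = contig, start = s1 - 1L, end = s2,
      strand = strand, product = get_qual("product"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(gene_annotation(character(), character(), integer(), integer(),
                           character()))
  }
  tab <- do.call(rbind, out)
  # gene + CDS for the same locus share a locus_tag; keep first occurrence
  tab <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  gene_annotation(tab$gene_id, tab$contig_id, tab$start, tab$end,
                  tab$strand, tab$product)
}

#' Extract strand-aware upstream regions
#'
#' For a + strand gene at [start, end) the upstream interval is
#' [max(0, start - requested_len), start), read on the + strand; for a -
#' strand gene it is [end, min(L, end + requested_len)),
#' reverse-complemented so the returned sequence runs toward the gene start.
#' With \code{truncate_at_neighbor} the interval is additionally clipped at
#' the nearest boundary of any other annotated gene, on either strand.
#'
#' @param genome a \code{genome_record}.
#' @param annotations a \code{gene_annotation} table.
#' @param gene_ids genes to extract for; all must be annotated.
#' @param requested_len maximum upstream length (default 300 nt).
#' @param truncate_at_neighbor clip at neighboring gene boundaries.
#' @return a \code{data.frame} with one row per gene: \code{gene_id},
#'   \code{seq} (reading orientation), \code{contig_id}, \code{start},
#'   \code{end}, \code{strand}, \code{requested_len},
#'   \code{truncated_by_neighbor}. Zero-length regions are emitted with an
#'   empty \code{seq} and a warning, never dropped.
#' @export
extract_upstream <- function(genome, annotations, gene_ids,
                             requested_len = 300L,
                             truncate_at_neighbor = TRUE) {
  stopifnot(inherits(genome, "genome_record"), requested_len >= 1L)
  requested_len <- as.integer(requested_len)
  missing_ids <- setdiff(gene_ids, annotations$gene_id)
  if (length(missing_ids)) {
    stop("gene_id not found in annotations: ",
         paste(missing_ids, collapse = ", "))
  }
  L <- genome$length
  rows <- lapply(gene_ids, function(gid) {
    g <- annotations[annotations$gene_id == gid, ]
    if (g$contig_id != genome$id) {
      stop("gene '", gid, "' is annotated on contig '", g$contig_id,
           "', not on genome '", genome$id, "'")
    }
    others <- annotations[annotations$gene_id != gid &
                            annotations$contig_id == genome$id, ]
    truncated <- FALSE
    if (g$strand == "+") {
      lo <- max(0L, g$start - requested_len); hi <- g$start
      if (truncate_at_neighbor && nrow(others)) {
        # keep only intergenic DNA adjacent to the gene start: clip past the
        # rightmost base covered by any other gene intersecting the window
        hit <- others$start < hi & others$end > lo
        if (any(hit)) {
          lo <- min(hi, max(lo, max(others$end[hit])))
          truncated <- TRUE
        }
      }
    } else {
      lo <- g$end; hi <- min(L, g$end + requested_len)
      if (truncate_at_neighbor && nrow(others)) {
        hit <- others$end > lo & others$start < hi
        if (any(hit)) {
          hi <- max(lo, min(hi, min(others$start[hit])))
          truncated <- TRUE
        }
      }
    }
    seq <- if (hi > lo) substr(genome$seq, lo + 1L, hi) else ""
    if (!nzchar(seq)) {
      warning("zero-length upstream region for gene '", gid, "'")
    }
    if (g$strand == "-" && nzchar(seq)) seq <- revcomp(seq)
    data.frame(gene_id = gid, seq = seq, contig_id = genome$id,
               start = lo, end = hi, strand = g$strand,
               requested_len = requested_len,
               truncated_by_neighbor = truncated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or a data.frame with \code{gene_id}
#'   and \code{seq} columns (as returned by \code{\link{extract_upstream}}).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$gene_id)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read aligned or unaligned sequences from FASTA as a character vector
#'
#' @param path FASTA file.
#' @return named character vector (uppercased).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}
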