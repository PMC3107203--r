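# Gene-neighborhood (synteny) comparison around anchor sigma-factor genes.

#' Synteny comparison parameters
#'
#' @param flank_genes genes taken on each side of the anchor (default 2,
#'   "two upstream and two downstream").
#' @param similarity_evalue_max E-value cutoff for a flank pair to count as
#'   homologous (default 1e-4).
#' @param extend_on_match widen the window by one gene per side while new
#'   passing pairs keep appearing.
#' @param extend_cap maximum flank width reached by extension (default 5).
#' @return an object of class \code{synteny_params}.
#' @export
synteny_params <- function(flank_genes = 2L, similarity_evalue_max = 1e-4,
                           extend_on_match = FALSE, extend_cap = 5L) {
  stopifnot(flank_genes >= 1L, extend_cap >= flank_genes)
  structure(list(flank_genes = as.integer(flank_genes),
                 similarity_evalue_max = similarity_evalue_max,
                 extend_on_match = isTRUE(extend_on_match),
                 extend_cap = as.integer(extend_cap)),
            class = "synteny_params")
}

#' Extract the gene neighborhood around an anchor gene
#'
#' Flank genes are taken in genomic (coordinate) order on the anchor's
#' contig, independent of strand, at offsets -flank..-1, +1..+flank (no
#' zero). Contig edges yield a truncated neighborhood with a warning.
#'
#' @param annotations a \code{\link{gene_annotation}} table.
#' @param proteins named character vector: gene_id -> protein sequence.
#' @param anchor_gene_id the anchor.
#' @param params a \code{\link{synteny_params}}.
#' @param flank override of \code{params$flank_genes} (used by extension).
#' @return object of class \code{neighborhood}: list with \code{anchor_id}
#'   and \code{flanks} (data.frame offset, gene_id, strand, seq).
#' @export
extract_neighborhood <- function(annotations, proteins, anchor_gene_id,
                                 params = synteny_params(), flank = NULL) {
  if (!anchor_gene_id %in% annotations$gene_id) {
    stop("anchor gene '", anchor_gene_id, "' not in annotations")
  }
  flank <- if (is.null(flank)) params$flank_genes else as.integer(flank)
  a <- annotations[annotations$gene_id == anchor_gene_id, ]
  ctg <- annotations[annotations$contig_id == a$contig_id, ]
  ctg <- ctg[order(ctg$start), , drop = FALSE]
  pos <- which(ctg$gene_id == anchor_gene_id)
  offsets <- setdiff(seq(-flank, flank), 0L)
  idx <- pos + offsets
  keep <- idx >= 1L & idx <= nrow(ctg)
  if (!all(keep)) {
    warning("neighborhood of '", anchor_gene_id,
            "' truncated at a contig edge")
  }
  offsets <- offsets[keep]; idx <- idx[keep]
  gene_ids <- ctg$gene_id[idx]
  missing_prot <- setdiff(gene_ids, names(proteins))
  if (length(missing_prot)) {
    stop("no protein sequence for flank gene(s): ",
         paste(missing_prot, collapse = ", "))
  }
  flanks <- data.frame(offset = offsets, gene_id = gene_ids,
                       strand = ctg$strand[idx],
                       seq = unname(proteins[gene_ids]),
                       stringsAsFactors = FALSE)
  structure(list(anchor_id = anchor_gene_id, flanks = flanks,
                 truncated = !all(keep)),
            class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat("neighborhood of '", x$anchor_id, "': offsets ",
      paste(x$flanks$offset, collapse = ","), "\n", sep = "")
  invisible(x)
}

# greedy best-first matching between two flank tables; each protein used
# once; ties broken by smaller |offsetA| + |offsetB|, then offsetA, offsetB
.greedy_match <- function(fa, fb, evalue_max) {
  if (!nrow(fa) || !nrow(fb)) {
    return(data.frame(offsetA = integer(), offsetB = integer(),
                      geneA = character(), geneB = character(),
                      score = numeric(), bits = numeric(),
                      evalue = numeric(), passes = logical(),
                      stringsAsFactors = FALSE))
  }
  pairs <- expand.grid(i = seq_len(nrow(fa)), j = seq_len(nrow(fb)))
  sims <- Map(function(i, j) pairwise_similarity(fa$seq[i], fb$seq[j]),
              pairs$i, pairs$j)
  pairs$score <- vapply(sims, `[[`, 0, "score")
  pairs$bits <- vapply(sims, `[[`, 0, "bits")
  pairs$evalue <- vapply(sims, `[[`, 0, "evalue")
  ord <- order(-pairs$score,
               abs(fa$offset[pairs$i]) + abs(fb$offset[pairs$j]),
               fa$offset[pairs$i], fb$offset[pairs$j])
  pairs <- pairs[ord, , drop = FALSE]
  used_a <- logical(nrow(fa)); used_b <- logical(nrow(fb))
  sel <- integer()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      sel <- c(sel, r)
    }
  }
  sub <- pairs[sel, , drop = FALSE]
  data.frame(offsetA = fa$offset[sub$i], offsetB = fb$offset[sub$j],
             geneA = fa$gene_id[sub$i], geneB = fb$gene_id[sub$j],
             score = sub$score, bits = sub$bits, evalue = sub$evalue,
             passes = sub$evalue <= evalue_max, stringsAsFactors = FALSE)
}

#' Compare two anchor neighborhoods
#'
#' Greedy best-score one-to-one matching between the flank proteins of the
#' two neighborhoods; a pair passes when its E-value is at or below the
#' threshold, and the block is conserved when at least one pair passes.
#' With \code{extend_on_match}, the window widens by one gene per side
#' (up to \code{extend_cap}) while each widening adds a new passing pair;
#' extension needs the annotation/protein context arguments.
#'
#' @param na,nb \code{\link{extract_neighborhood}} results.
#' @param params a \code{\link{synteny_params}}.
#' @param context_a,context_b optional lists
#'   \code{list(annotations=, proteins=)} enabling extension.
#' @return object of class \code{synteny_block}: list with \code{anchorA},
#'   \code{anchorB}, \code{pairs} (matched pair table), \code{conserved},
#'   \code{flank_used}.
#' @export
compare_neighborhoods <- function(na, nb, params = synteny_params(),
                                  context_a = NULL, context_b = NULL) {
  stopifnot(inherits(na, "neighborhood"), inherits(nb, "neighborhood"))
  evmax <- params$similarity_evalue_max
  pairs <- .greedy_match(na$flanks, nb$flanks, evmax)
  flank_used <- params$flank_genes
  if (params$extend_on_match && any(pairs$passes)) {
    if (is.null(context_a) || is.null(context_b)) {
      warning("extend_on_match requires context_a/context_b; skipping ",
              "extension")
    } else {
      repeat {
        if (flank_used >= params$extend_cap) break
        wider <- flank_used + 1L
        na2 <- extract_neighborhood(context_a$annotations,
                                    context_a$proteins, na$anchor_id,
                                    params, flank = wider)
        nb2 <- extract_neighborhood(context_b$annotations,
                                    context_b$proteins, nb$anchor_id,
                                    params, flank = wider)
        pairs2 <- .greedy_match(na2$flanks, nb2$flanks, evmax)
        if (sum(pairs2$passes) > sum(pairs$passes)) {
          pairs <- pairs2; flank_used <- wider
        } else break
      }
    }
  }
  structure(list(anchorA = na$anchor_id, anchorB = nb$anchor_id,
                 pairs = pairs, conserved = any(pairs$passes),
                 flank_used = flank_used),
            class = "synteny_block")
}

#' @export
print.synteny_block <- function(x, ...) {
  cat("synteny block ", x$anchorA, " vs ", x$anchorB, ": ",
      sum(x$pairs$passes), "/", nrow(x$pairs), " passing pairs; conserved=",
      x$conserved, "\n", sep = "")
  invisible(x)
}

#' Write matched synteny pairs as TSV
#'
#' @param block a \code{synteny_block}.
#' @param path output file.
#' @export
write_synteny_tsv <- function(block, path) {
  tab <- block$pairs
  tab$anchorA <- block$anchorA
  tab$anchorB <- block$anchorB
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
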