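# Seeded synthetic genomes, annotations and proteomes with planted ground
# truth. Everything is a pure function of the configuration (seed included):
# per-feature RNG substreams are derived from the seed and a feature tag, so
# adding one kind of feature never shifts the draws of another.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# deterministic 31-bit substream seed from (seed, tag)
.substream <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(tag)) h <- (h * 31 + v) %% 2147483647
  set.seed(as.integer(h))
  invisible(h)
}

.random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.random_protein <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe the conditions the recovery tests assume: a high-GC
#' (0.69, myxobacteria-like) background genome of 30 kb carrying 5 true
#' planted promoters (mismatch counts cycling through 0,1,2, both strands,
#' spacers cycling through 16-18), 2 wrong-strand plants, 2 near-miss
#' decoys one mismatch over budget, and 5 promoter-less decoy genes. The
#' proteome side plants one CorE-like sigma factor (38-residue tail with 6
#' Cys) among 50 i.i.d. decoy proteins.
#'
#' @param seed integer master seed; every draw is derived from it.
#' @param genome_len background genome length (nt).
#' @param gc_fraction background GC content in [0, 1].
#' @param n_true_promoters,true_mismatches,true_strands,true_spacers planted
#'   true sites; vectors are recycled to \code{n_true_promoters}.
#' @param n_wrong_strand plants whose motif is on the strand opposite their
#'   gene.
#' @param n_near_miss decoy motif instances with budget + 1 mismatches.
#' @param n_decoy_genes genes with no planted promoter.
#' @param gene_len_range sampled uniformly per gene.
#' @param n_decoy_proteins,protein_len_range i.i.d. decoy proteome.
#' @param crd_tail_len,crd_cys planted CRD tail geometry.
#' @param n_planted_sigma planted sigma-factor homologs of the template.
#' @param template_identity expected residue identity of planted homologs
#'   to the internal template.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L, genome_len = 30000L,
                              gc_fraction = 0.69,
                              n_true_promoters = 5L,
                              true_mismatches = c(0L, 1L, 2L),
                              true_strands = c("+", "-"),
                              true_spacers = c(16L, 17L, 18L),
                              n_wrong_strand = 2L, n_near_miss = 2L,
                              n_decoy_genes = 5L,
                              gene_len_range = c(600L, 1500L),
                              n_decoy_proteins = 50L,
                              protein_len_range = c(120L, 300L),
                              crd_tail_len = 38L, crd_cys = 6L,
                              n_planted_sigma = 1L,
                              template_identity = 0.75) {
  stopifnot(genome_len >= 1000L, gc_fraction >= 0, gc_fraction <= 1,
            n_true_promoters >= 0L, n_wrong_strand >= 0L,
            n_near_miss >= 0L, n_decoy_genes >= 0L,
            crd_cys <= crd_tail_len)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a background genome
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{genome} (a \code{\link{genome_record}}) and
#'   \code{truth} (seed bookkeeping).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .substream(config$seed, "genome")
  seq <- .random_dna(config$genome_len, config$gc_fraction)
  list(genome = genome_record(sprintf("synthetic_%d", config$seed), seq),
       truth = list(seed = config$seed, genome_len = config$genome_len,
                    gc_fraction = config$gc_fraction))
}

# one concrete realization of the consensus (a zero-mismatch instance)
.realize_consensus <- function(model) {
  vapply(model$minus35$allowed, function(s) sample(s, 1L)[[1]], "")
}

# apply `m` mismatches at non-invariant, mismatchable positions
.mutate_instance <- function(chars, model, m, protect_invariants = TRUE) {
  if (m == 0L) return(chars)
  allowed <- model$minus35$allowed
  mutable <- which(lengths(allowed) < 4L)  # N columns cannot mismatch
  if (protect_invariants) {
    mutable <- setdiff(mutable, model$invariant_positions + 1L)
  }
  if (length(mutable) < m) {
    stop("cannot place ", m, " mismatches: only ", length(mutable),
         " mutable non-invariant positions")
  }
  pos <- sample(mutable, m)
  for (p in pos) {
    bad <- setdiff(c("A", "C", "G", "T"), allowed[[p]])
    chars[p] <- sample(bad, 1L)
  }
  chars
}

# spacer sequence of length sp with no anchor base anywhere, so the planted
# anchor at spacer sp is the smallest qualifying one
.spacer_seq <- function(sp, anchor, gc) {
  if (sp <= 0L) return(character())
  bases <- setdiff(c("A", "C", "G", "T"), anchor)
  sample(bases, sp, replace = TRUE)
}

#' Plant promoters, genes and decoys into a background genome
#'
#' Builds, per planted feature, a self-contained cassette (motif instance,
#' spacer, -10 anchor, filler, gene) and writes the cassettes into
#' well-separated slots of the background so that downstream-gene
#' assignment cannot cross features. True sites have their mismatches at
#' non-invariant positions, the anchor at the recorded spacer (and nowhere
#' earlier), and their gene on the matching strand within assignment range.
#' Wrong-strand plants pair a valid motif with a gene annotated on the
#' opposite strand; near-miss decoys carry budget + 1 mismatches and no
#' gene.
#'
#' @param genome a background \code{\link{genome_record}} (from
#'   \code{\link{simulate_genome}}).
#' @param model the \code{\link{bipartite_motif}} being planted.
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{genome} (sequence with cassettes written in),
#'   \code{annotations} (a \code{\link{gene_annotation}}) and \code{truth}
#'   (data.frame of planted features: type, minus35_start, strand,
#'   mismatches, spacer, target_gene, distance).
#' @export
plant_regulon <- function(genome, model, config) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(model, "bipartite_motif"),
            inherits(config, "simulation_config"))
  .substream(config$seed, "regulon")
  k <- length(model$minus35$allowed)
  gc <- config$gc_fraction
  anchor <- model$minus10_anchor

  n_true <- config$n_true_promoters
  types <- c(rep("true", n_true),
             rep("wrong_strand", config$n_wrong_strand),
             rep("near_miss", config$n_near_miss),
             rep("decoy_gene", config$n_decoy_genes))
  n_cass <- length(types)
  if (!n_cass) stop("nothing to plant")
  mm <- rep_len(config$true_mismatches, max(1L, n_true))
  strands <- rep_len(config$true_strands, max(1L, n_true))
  spacers <- rep_len(config$true_spacers, max(1L, n_true))

  # cassette builder: returns string plus relative truth
  build <- function(type, i) {
    glen <- sample(config$gene_len_range[1]:config$gene_len_range[2], 1L)
    if (type == "true" || type == "wrong_strand") {
      m <- if (type == "true") mm[i] else sample(0:model$max_mismatches, 1L)
      sp <- if (type == "true") spacers[i] else sample(model$spacer_min:model$spacer_max, 1L)
      inst <- paste(.mutate_instance(.realize_consensus(model), model, m),
                    collapse = "")
      filler_len <- sample(10:60, 1L)
      if (type == "wrong_strand") glen <- sample(120:220, 1L)
      gene_seq <- .random_dna(glen, gc)
      fwd <- paste0(inst, paste(.spacer_seq(sp, anchor, gc), collapse = ""),
                    anchor, .random_dna(filler_len, gc), gene_seq)
      if (type == "true") {
        gene_strand <- strands[i]
        # distance from -35 end to the gene's first coding base
        d <- sp + 1L + filler_len
        if (gene_strand == "+") {
          list(seq = fwd, motif_rel = 0L, motif_strand = "+",
               gene_rel = c(k + sp + 1L + filler_len, nchar(fwd)),
               gene_strand = "+", mismatches = m, spacer = sp, dist = d)
        } else {
          # mirror the whole cassette so the motif reads on -
          rc <- revcomp(fwd)
          n <- nchar(fwd)
          # motif first scan base at forward offset n-1 within cassette
          list(seq = rc, motif_rel = n - 1L, motif_strand = "-",
               gene_rel = c(0L, glen), gene_strand = "-",
               mismatches = m, spacer = sp, dist = d)
        }
      } else {
        # valid + motif, but the gene is annotated on the - strand; its
        # translational start (right edge) is downstream of the element
        d <- filler_len + glen - 1L + sp + 1L
        list(seq = fwd, motif_rel = 0L, motif_strand = "+",
             gene_rel = c(k + sp + 1L + filler_len, nchar(fwd)),
             gene_strand = "-", mismatches = m, spacer = sp, dist = d)
      }
    } else if (type == "near_miss") {
      inst <- paste(.mutate_instance(.realize_consensus(model), model,
                                     model$max_mismatches + 1L,
                                     protect_invariants = FALSE),
                    collapse = "")
      list(seq = inst, motif_rel = 0L, motif_strand = "+",
           gene_rel = NULL, gene_strand = NA_character_,
           mismatches = model$max_mismatches + 1L, spacer = NA_integer_,
           dist = NA_integer_)
    } else {  # decoy_gene
      list(seq = .random_dna(glen, gc), motif_rel = NULL,
           motif_strand = NA_character_, gene_rel = c(0L, glen),
           gene_strand = sample(c("+", "-"), 1L),
           mismatches = NA_integer_, spacer = NA_integer_,
           dist = NA_integer_)
    }
  }

  idx_within <- unlist(lapply(unique(types), function(t) {
    seq_len(sum(types == t))
  }))
  cassettes <- Map(build, types, idx_within)
  cass_len <- vapply(cassettes, function(c) nchar(c$seq), integer(1))
  # slot placement: even slots with >= 400 nt of untouched background
  # between cassettes so assignment cannot cross features
  slot <- config$genome_len %/% n_cass
  if (any(cass_len + 450L > slot)) {
    stop("genome too short to pack ", n_cass, " cassettes; increase ",
         "genome_len")
  }
  offsets <- vapply(seq_len(n_cass), function(i) {
    jitter_max <- slot - cass_len[i] - 420L
    (i - 1L) * slot + 20L + sample.int(max(1L, jitter_max), 1L)
  }, integer(1))

  seq <- genome$seq
  truth_rows <- list()
  ann_rows <- list()
  gene_i <- 0L
  for (i in seq_len(n_cass)) {
    cst <- cassettes[[i]]
    off <- offsets[i]
    substr(seq, off + 1L, off + cass_len[i]) <- cst$seq
    gid <- NA_character_
    if (!is.null(cst$gene_rel)) {
      gene_i <- gene_i + 1L
      gid <- sprintf("SYNGENE_%04d", gene_i)
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene_id = gid, start = off + cst$gene_rel[1],
        end = off + cst$gene_rel[2], strand = cst$gene_strand,
        stringsAsFactors = FALSE)
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      type = types[i],
      minus35_start = if (!is.null(cst$motif_rel)) off + cst$motif_rel
        else NA_integer_,
      strand = cst$motif_strand, mismatches = cst$mismatches,
      spacer = cst$spacer, target_gene = gid, distance = cst$dist,
      stringsAsFactors = FALSE)
  }
  ann_tab <- do.call(rbind, ann_rows)
  annotations <- gene_annotation(ann_tab$gene_id, genome$id, ann_tab$start,
                                 ann_tab$end, ann_tab$strand)
  truth <- do.call(rbind, truth_rows)
  truth$seed <- config$seed
  list(genome = genome_record(genome$id, seq, circular = genome$circular),
       annotations = annotations, truth = truth)
}

# point-mutate a protein to approximately the requested identity
.mutate_protein <- function(seq, identity) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_mut <- round((1 - identity) * length(chars))
  if (n_mut > 0L) {
    pos <- sample(length(chars), n_mut)
    for (p in pos) chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# a Cys-rich tail of given length with exactly `cys` Cys
.crd_tail <- function(tail_len, cys) {
  chars <- sample(setdiff(.AA20, "C"), tail_len, replace = TRUE)
  if (cys > 0L) chars[sample(tail_len, cys)] <- "C"
  paste(chars, collapse = "")
}

#' Simulate a proteome with planted CRD sigma factors
#'
#' Decoy proteins are i.i.d. over the 20 amino acids. An internal
#' sigma-factor template (170 residues: sigma2 at 10-70, sigma4 at 120-170)
#' is generated from the seed; each planted protein is a point-mutated copy
#' of the template body (at \code{template_identity}) carrying a fresh tail
#' of \code{crd_tail_len} residues with exactly \code{crd_cys} Cys after
#' the sigma4 end. Domain spans are recorded for every planted protein.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param tag extra substream tag so multiple proteomes from one seed are
#'   independent (used by the synteny pair generator).
#' @param cys_override optional vector of Cys counts, one per planted
#'   protein (recycled), replacing \code{config$crd_cys}.
#' @return list with \code{proteins} (list of
#'   \code{\link{sigma_factor_record}}), \code{query} (the un-mutated
#'   template with its CorE-like tail), and \code{truth} (planted ids and
#'   Cys counts).
#' @export
simulate_proteomes <- function(config, tag = "proteome",
                               cys_override = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  .substream(config$seed, tag)
  body_len <- 170L
  sigma2 <- c(10L, 70L); sigma4 <- c(120L, 170L)  # sigma4 ends the body
  template_body <- .random_protein(body_len)
  query_tail <- .crd_tail(config$crd_tail_len, config$crd_cys)
  query <- sigma_factor_record("SIGMA_QUERY",
                               paste0(template_body, query_tail),
                               sigma2, sigma4)
  n_planted <- config$n_planted_sigma
  cys <- if (is.null(cys_override)) rep(config$crd_cys, n_planted)
    else rep_len(as.integer(cys_override), n_planted)
  planted <- lapply(seq_len(n_planted), function(i) {
    body <- .mutate_protein(template_body, config$template_identity)
    tail <- .crd_tail(config$crd_tail_len, cys[i])
    sigma_factor_record(sprintf("SIGMA_PLANT_%02d", i),
                        paste0(body, tail), sigma2, sigma4)
  })
  decoys <- lapply(seq_len(config$n_decoy_proteins), function(i) {
    len <- sample(config$protein_len_range[1]:config$protein_len_range[2], 1L)
    sigma_factor_record(sprintf("DECOY_%03d", i), .random_protein(len))
  })
  truth <- data.frame(
    protein_id = vapply(planted, `[[`, "", "protein_id"),
    cys_count = cys, tail_len = config$crd_tail_len,
    stringsAsFactors = FALSE)
  list(proteins = c(planted, decoys), query = query, truth = truth)
}

#' Simulate a pair of genomes with (or without) a conserved anchor
#' neighborhood
#'
#' Each side gets an anchor gene with \code{flank} genes on each side.
#' When \code{conserved}, flank proteins of genome B are point-mutated
#' copies of their genome-A counterparts (identity
#' \code{template_identity}); otherwise both sides are independent random
#' proteins.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param conserved plant homologous flanks?
#' @param flank genes per side (default 2).
#' @return list with \code{a} and \code{b}, each
#'   \code{list(annotations, proteins, anchor_id)}, and \code{truth}
#'   (logical \code{conserved}, homolog offset map).
#' @export
simulate_synteny_pair <- function(config, conserved = TRUE, flank = 2L) {
  stopifnot(inherits(config, "simulation_config"))
  .substream(config$seed, paste0("synteny_", conserved))
  n <- 2L * flank + 1L
  mk_side <- function(contig, prefix, protein_fn) {
    starts <- seq(0L, by = 1200L, length.out = n)
    ids <- sprintf("%s_%02d", prefix, seq_len(n))
    ann <- gene_annotation(ids, contig, starts, starts + 900L,
                           rep(c("+", "-"), length.out = n))
    prot <- vapply(seq_len(n), protein_fn, "")
    names(prot) <- ids
    list(annotations = ann, proteins = prot,
         anchor_id = ids[flank + 1L])
  }
  lens <- sample(150:250, n, replace = TRUE)
  a_prots <- vapply(lens, .random_protein, "")
  a <- mk_side("ctgA", "GA", function(i) a_prots[i])
  b <- if (conserved) {
    mk_side("ctgB", "GB",
            function(i) .mutate_protein(a_prots[i], config$template_identity))
  } else {
    mk_side("ctgB", "GB",
            function(i) .random_protein(sample(150:250, 1L)))
  }
  list(a = a, b = b,
       truth = list(conserved = conserved, seed = config$seed,
                    homolog_offsets = if (conserved)
                      setdiff(seq(-flank, flank), 0L) else integer()))
}

#' Write a simulated regulon scenario to files
#'
#' Emits genome FASTA, GFF3 annotations, and the truth table as TSV plus a
#' JSON config echo.
#'
#' @param sim result of \code{\link{plant_regulon}}.
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  write_fasta(setNames(sim$genome$seq, sim$genome$id), fa)
  gff <- file.path(dir, "genes.gff3")
  ann <- sim$annotations
  lines <- c("##gff-version 3",
             sprintf("%s\tcorescan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     ann$contig_id, ann$start + 1L, ann$end, ann$strand,
                     ann$gene_id))
  writeLines(lines, gff)
  truth <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(genome = fa, annotations = gff, truth = truth))
}
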