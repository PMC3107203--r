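# genome scanning, -10 anchor search, gene assignment, filter cascade

test_that("planted exact elements are found on both strands", {
  cons <- "GAACTT"
  bg <- paste(rep("C", 100), collapse = "")
  seq <- paste0(substr(bg, 1, 40), "GAACTT", substr(bg, 1, 54))
  g <- genome_record("ctg", seq)
  m <- bipartite_motif(cons, max_mismatches = 0)
  h <- scan_genome(g, m, strands = "+")
  expect_equal(nrow(h), 1L)
  expect_equal(h$minus35_start, 40L)
  expect_equal(h$mismatches, 0L)

  seq2 <- paste0(substr(bg, 1, 40), revcomp("GAACTT"), substr(bg, 1, 54))
  g2 <- genome_record("ctg", seq2)
  h2 <- scan_genome(g2, m)
  h2 <- h2[h2$strand == "-", ]
  expect_equal(nrow(h2), 1L)
  # first base in scan orientation = rightmost forward coordinate
  expect_equal(h2$minus35_start, 45L)
  expect_equal(h2$window_seq, "GAACTT")
})

test_that("scan equals the brute-force oracle on random genomes", {
  set.seed(21)
  for (rep_i in 1:5) {
    seq <- random_dna(10000, gc = 0.65)
    g <- genome_record("g", seq)
    cons <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N"), 7,
                         replace = TRUE), collapse = "")
    for (budget in 0:2) {
      m <- bipartite_motif(cons, max_mismatches = budget)
      got <- scan_genome(g, m)
      want <- oracle_scan(seq, cons, budget)
      expect_equal(hitset_key(got), hitset_key(want))
    }
  }
})

test_that("strand symmetry and budget monotonicity hold", {
  set.seed(22)
  seq <- random_dna(5000)
  g <- genome_record("g", seq)
  grc <- genome_record("g", revcomp(seq))
  m <- bipartite_motif("RAACTH", max_mismatches = 1)
  h <- scan_genome(g, m)
  hrc <- scan_genome(grc, m)
  L <- nchar(seq)
  # a + hit at p maps to a - hit at L-1-p in the reverse complement
  key <- function(df) sort(sprintf("%d/%s/%d", df$minus35_start, df$strand,
                                   df$mismatches))
  mirrored <- data.frame(
    minus35_start = L - 1L - hrc$minus35_start,
    strand = ifelse(hrc$strand == "+", "-", "+"),
    mismatches = hrc$mismatches)
  expect_equal(key(h), key(mirrored))

  m0 <- bipartite_motif("RAACTH", max_mismatches = 0)
  m2 <- bipartite_motif("RAACTH", max_mismatches = 2)
  h0 <- scan_genome(g, m0); h2 <- scan_genome(g, m2)
  expect_true(all(hitset_key(h0) %in% hitset_key(h2)))
  expect_true(all(hitset_key(h) %in% hitset_key(h2)))
})

test_that("check_minus10 picks the smallest qualifying spacer", {
  m <- bipartite_motif("GAACTT", spacer_min = 16, spacer_max = 18)
  pad <- function(n) paste(rep("A", n), collapse = "")
  # anchor exactly at spacer 17
  seq <- paste0(pad(10), "GAACTT", pad(17), "G", pad(30))
  g <- genome_record("ctg", seq)
  h <- scan_genome(g, m, strands = "+")
  h <- check_minus10(h[h$minus35_start == 10L, ], g, m)
  expect_equal(h$spacer_len, 17L)
  expect_equal(h$minus10_pos, 10L + 6L + 17L)

  # anchors at spacers 16 and 18: smallest wins
  seq2 <- paste0(pad(10), "GAACTT", pad(16), "G", "A", "G", pad(30))
  g2 <- genome_record("ctg", seq2)
  h2 <- scan_genome(g2, m, strands = "+")
  h2 <- check_minus10(h2[h2$minus35_start == 10L, ], g2, m)
  expect_equal(h2$spacer_len, 16L)

  # anchor only at spacer 19: absent
  seq3 <- paste0(pad(10), "GAACTT", pad(19), "G", pad(30))
  g3 <- genome_record("ctg", seq3)
  h3 <- scan_genome(g3, m, strands = "+")
  h3 <- check_minus10(h3[h3$minus35_start == 10L, ], g3, m)
  expect_true(is.na(h3$spacer_len))

  # linear contig end: absent; circular: wraps
  seq4 <- paste0(pad(10), "GAACTT", pad(5))
  g4 <- genome_record("ctg", seq4)
  h4 <- scan_genome(g4, m, strands = "+")
  h4 <- check_minus10(h4[h4$minus35_start == 10L, ], g4, m)
  expect_true(is.na(h4$spacer_len))
  # circular genome of 25 nt: anchor for spacer 16 wraps to position
  # (15 + 1 + 16) %% 25 = 7, which is planted as G
  seq5 <- paste0(pad(7), "G", pad(2), "GAACTT", pad(9))
  g5 <- genome_record("ctg", seq5, circular = TRUE)
  h5 <- scan_genome(g5, m, strands = "+")
  h5 <- check_minus10(h5[h5$minus35_start == 10L, ], g5, m)
  expect_equal(h5$spacer_len, 16L)
  expect_equal(h5$minus10_pos, 7L)
})

test_that("downstream assignment: orientation, distance, tie-break", {
  m <- bipartite_motif("GAACTT")
  pad <- function(n) paste(rep("T", n), collapse = "")
  seq <- paste0(pad(10), "GAACTT", pad(50), pad(400))
  g <- genome_record("ctg", seq)
  h <- scan_genome(g, m, strands = "+")
  h <- h[h$minus35_start == 10L, ]

  ann <- gene_annotation("gA", "ctg", 66L, 200L, "+")
  c1 <- assign_downstream_gene(h, ann, max_distance = 300L)
  expect_equal(c1$downstream_gene, "gA")
  expect_equal(c1$distance_to_start, 66L - 15L - 1L)
  expect_true(c1$strand_ok)

  # wrong strand gene: assigned but flagged
  ann2 <- gene_annotation("gB", "ctg", 20L, 80L, "-")
  c2 <- assign_downstream_gene(h, ann2, max_distance = 300L)
  expect_equal(c2$downstream_gene, "gB")
  expect_false(c2$strand_ok)

  # nothing within range
  ann3 <- gene_annotation("gC", "ctg", 350L, 400L, "+")
  c3 <- assign_downstream_gene(h, ann3, max_distance = 300L)
  expect_true(is.na(c3$downstream_gene))

  # equidistant starts: smaller genomic coordinate wins
  ann4 <- gene_annotation(c("near1", "near2"), "ctg", c(66L, 30L),
                          c(200L, 67L), c("+", "-"))
  c4 <- assign_downstream_gene(h, ann4, max_distance = 300L)
  expect_equal(c4$downstream_gene, "near2")
})

test_that("filter cascade flags and stage counts match hand enumeration", {
  # constructed 20-hit fixture: all 8 flag combinations, at least twice each
  m <- bipartite_motif("GAACTT", invariant_positions = c(0, 1, 2),
                       spacer_min = 16, spacer_max = 18,
                       max_mismatches = 2)
  pad <- function(n, b = "T") paste(rep(b, n), collapse = "")
  combos <- expand.grid(strand_ok = c(TRUE, FALSE),
                        inv_ok = c(TRUE, FALSE),
                        m10_ok = c(TRUE, FALSE))
  combos <- combos[rep(seq_len(nrow(combos)), length.out = 20), ]
  slots <- list()
  truth <- combos
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    # window: invariant positions 0-2 are GAA; break position 0 if !inv_ok
    win <- if (co$inv_ok) "GAACAT" else "TAACTT"  # 1 or 2 mismatches
    sp_block <- if (co$m10_ok) paste0(pad(16, "A"), "G", pad(10, "A"))
      else pad(27, "A")
    cassette <- paste0(win, sp_block, pad(20, "A"))
    slots[[i]] <- list(cassette = cassette,
                       gene_strand = if (co$strand_ok) "+" else "-")
  }
  gap <- pad(500, "C")  # C-rich spacer: no GAACTT-like windows, no genes
  seq <- gap
  starts <- integer(nrow(combos))
  ann_rows <- list()
  for (i in seq_along(slots)) {
    starts[i] <- nchar(seq)
    seq <- paste0(seq, slots[[i]]$cassette)
    gene_start <- nchar(seq)
    seq <- paste0(seq, pad(120, "A"))
    ann_rows[[i]] <- data.frame(gene_id = sprintf("g%02d", i),
                                start = gene_start, end = gene_start + 120L,
                                strand = slots[[i]]$gene_strand)
    seq <- paste0(seq, gap)
  }
  ann_tab <- do.call(rbind, ann_rows)
  ann <- gene_annotation(ann_tab$gene_id, "ctg", ann_tab$start,
                         ann_tab$end, ann_tab$strand)
  g <- genome_record("ctg", seq)
  hits <- scan_genome(g, m, strands = "+")
  hits <- hits[hits$minus35_start %in% starts, ]
  expect_equal(nrow(hits), 20L)
  rep_ <- filter_candidates(hits, m, g, ann, max_distance = 300L)
  cand <- rep_$candidates[order(rep_$candidates$minus35_start), ]
  expect_equal(cand$strand_ok, truth$strand_ok)
  expect_equal(cand$invariants_ok, truth$inv_ok)
  expect_equal(cand$minus10_ok, truth$m10_ok)
  expect_equal(cand$final, truth$strand_ok & truth$inv_ok & truth$m10_ok)
  # stage counts by direct truth-table enumeration
  expect_equal(unname(rep_$counts["raw"]), 20L)
  expect_equal(unname(rep_$counts["oriented"]), sum(truth$strand_ok))
  expect_equal(unname(rep_$counts["invariants"]),
               sum(truth$strand_ok & truth$inv_ok))
  expect_equal(unname(rep_$counts["final"]),
               sum(truth$strand_ok & truth$inv_ok & truth$m10_ok))
  expect_true(all(diff(unname(rep_$counts)) <= 0))
})

test_that("hit TSV round trip and report JSON are written", {
  set.seed(23)
  g <- genome_record("g", random_dna(3000))
  m <- bipartite_motif("GAACTT", max_mismatches = 2)
  h <- scan_genome(g, m)
  f <- tempfile(fileext = ".tsv")
  write_hits_tsv(h, f)
  back <- read_hits_tsv(f)
  expect_equal(back$minus35_start, h$minus35_start)
  expect_equal(back$strand, h$strand)
  ann <- gene_annotation("g1", "g", 1000L, 2000L, "+")
  rep_ <- filter_candidates(h, m, g, ann)
  jf <- tempfile(fileext = ".json")
  write_report_json(rep_, jf)
  obj <- jsonlite::read_json(jf)
  expect_equal(obj$counts$raw, nrow(h))
})
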