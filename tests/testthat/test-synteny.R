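# neighborhood extraction, pairwise similarity, synteny comparison

test_that("neighborhood offsets are genomic-order, strand-independent", {
  ids <- paste0("g", 1:7)
  ann <- gene_annotation(ids, "c", seq(0, by = 1000, length.out = 7),
                         seq(800, by = 1000, length.out = 7),
                         rep(c("+", "-"), length.out = 7))
  prot <- setNames(vapply(1:7, function(i)
    paste(rep("MKVLDE", 20), collapse = ""), ""), ids)
  nb <- extract_neighborhood(ann, prot, "g4")
  expect_equal(nb$flanks$offset, c(-2L, -1L, 1L, 2L))
  expect_equal(nb$flanks$gene_id, c("g2", "g3", "g5", "g6"))

  # shuffled annotation input yields the identical neighborhood
  shuf <- ann[sample(nrow(ann)), ]
  shuf <- gene_annotation(shuf$gene_id, shuf$contig_id, shuf$start,
                          shuf$end, shuf$strand)
  nb2 <- extract_neighborhood(shuf, prot, "g4")
  expect_equal(nb2$flanks, nb$flanks)

  # anchor at the contig edge: truncated with a warning
  expect_warning(nbe <- extract_neighborhood(ann, prot, "g1"), "truncated")
  expect_equal(nbe$flanks$offset, c(1L, 2L))
  expect_error(extract_neighborhood(ann, prot, "zz"), "not in annotations")
})

test_that("pairwise similarity separates self-matches from decoys", {
  set.seed(51)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  s <- paste(sample(aa, 100, replace = TRUE), collapse = "")
  self <- pairwise_similarity(s, s)
  expect_lt(self$evalue, 1e-20)
  for (i in 1:5) {
    u <- paste(sample(aa, 100, replace = TRUE), collapse = "")
    v <- paste(sample(aa, 100, replace = TRUE), collapse = "")
    expect_gt(pairwise_similarity(u, v)$evalue, 1e-4)
    # symmetry
    expect_equal(pairwise_similarity(u, v)$score,
                 pairwise_similarity(v, u)$score)
  }
})

test_that("identical neighborhoods give 4/4 passing pairs; decoys give 0", {
  cfg <- simulation_config(seed = 9)
  sp <- simulate_synteny_pair(cfg, conserved = TRUE)
  na <- extract_neighborhood(sp$a$annotations, sp$a$proteins, sp$a$anchor_id)
  nb <- extract_neighborhood(sp$b$annotations, sp$b$proteins, sp$b$anchor_id)
  blk <- compare_neighborhoods(na, nb)
  expect_true(blk$conserved)
  expect_equal(sum(blk$pairs$passes), 4L)
  # homologs pair up at matching offsets
  expect_equal(sort(blk$pairs$offsetA), sort(blk$pairs$offsetB))

  sp0 <- simulate_synteny_pair(cfg, conserved = FALSE)
  nb0 <- extract_neighborhood(sp0$b$annotations, sp0$b$proteins,
                              sp0$b$anchor_id)
  blk0 <- compare_neighborhoods(na, nb0)
  expect_false(blk0$conserved)
  expect_equal(sum(blk0$pairs$passes), 0L)
})

test_that("one shared protein among four yields exactly one passing pair", {
  set.seed(52)
  mk <- function(prefix, shared_at, shared_seq) {
    ids <- sprintf("%s%d", prefix, 1:5)
    ann <- gene_annotation(ids, "c", seq(0, by = 1000, length.out = 5),
                           seq(800, by = 1000, length.out = 5),
                           rep("+", 5))
    prot <- setNames(vapply(1:5, function(i) random_protein(180), ""), ids)
    prot[shared_at] <- shared_seq
    list(ann = ann, prot = prot, anchor = ids[3])
  }
  random_protein <- function(n) {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    paste(sample(aa, n, replace = TRUE), collapse = "")
  }
  shared <- random_protein(180)
  a <- mk("a", 2, shared)   # offset -1
  b <- mk("b", 5, shared)   # offset +2
  na <- extract_neighborhood(a$ann, a$prot, a$anchor)
  nb <- extract_neighborhood(b$ann, b$prot, b$anchor)
  blk <- compare_neighborhoods(na, nb)
  expect_equal(sum(blk$pairs$passes), 1L)
  hit <- blk$pairs[blk$pairs$passes, ]
  expect_equal(c(hit$offsetA, hit$offsetB), c(-1L, 2L))
})

test_that("comparison is symmetric and matching is one-to-one", {
  cfg <- simulation_config(seed = 10)
  sp <- simulate_synteny_pair(cfg, conserved = TRUE)
  na <- extract_neighborhood(sp$a$annotations, sp$a$proteins, sp$a$anchor_id)
  nb <- extract_neighborhood(sp$b$annotations, sp$b$proteins, sp$b$anchor_id)
  ab <- compare_neighborhoods(na, nb)
  ba <- compare_neighborhoods(nb, na)
  key <- function(p) sort(sprintf("%d:%d", p$offsetA, p$offsetB))
  keyT <- function(p) sort(sprintf("%d:%d", p$offsetB, p$offsetA))
  expect_equal(key(ab$pairs[ab$pairs$passes, ]),
               keyT(ba$pairs[ba$pairs$passes, ]))
  expect_false(any(duplicated(ab$pairs$geneA)))
  expect_false(any(duplicated(ab$pairs$geneB)))
})

test_that("extension widens the window while new passing pairs appear", {
  cfg <- simulation_config(seed = 11)
  sp <- simulate_synteny_pair(cfg, conserved = TRUE, flank = 3L)
  pr <- synteny_params(flank_genes = 2L, extend_on_match = TRUE,
                       extend_cap = 3L)
  na <- extract_neighborhood(sp$a$annotations, sp$a$proteins,
                             sp$a$anchor_id, pr)
  nb <- extract_neighborhood(sp$b$annotations, sp$b$proteins,
                             sp$b$anchor_id, pr)
  blk <- compare_neighborhoods(na, nb, pr,
                               context_a = list(annotations = sp$a$annotations,
                                                proteins = sp$a$proteins),
                               context_b = list(annotations = sp$b$annotations,
                                                proteins = sp$b$proteins))
  expect_equal(blk$flank_used, 3L)
  expect_equal(sum(blk$pairs$passes), 6L)
  expect_warning(compare_neighborhoods(na, nb, pr), "context")
})
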