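# CRD detection, census, CRD alignment, conservation classes

make_sigma <- function(id, tail, body_len = 150) {
  set.seed(sum(utf8ToInt(id)))
  body <- paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                       body_len, replace = TRUE), collapse = "")
  sigma_factor_record(id, paste0(body, tail),
                      sigma2_span = c(10, 60),
                      sigma4_span = c(100, body_len))
}

test_that("find_crd counts tail Cys exactly under both policies", {
  tail38 <- paste0(strrep("A", 4), "C", strrep("L", 2), "C",
                   strrep("G", 4), "C", "C", strrep("V", 10), "C",
                   strrep("S", 12), "C")
  expect_equal(nchar(tail38), 38L)
  p <- make_sigma("corelike", tail38)
  crd <- find_crd(p, crd_criteria())
  expect_equal(crd$tail_len, 38L)
  expect_equal(crd$cys_count, 6L)
  expect_true(crd$is_crd)
  expect_equal(crd$tail_start, 151L)

  # fallback policy uses the last k residues
  p2 <- sigma_factor_record("nodoms", paste0(strrep("A", 100), tail38))
  crd2 <- find_crd(p2, crd_criteria(tail_policy = "last_k_residues",
                                    tail_k = 38))
  expect_equal(crd2$cys_count, 6L)
  expect_error(find_crd(p2, crd_criteria()), "no sigma4")

  # planting k Cys yields cys_count == k, boundary at min_cys
  for (k in c(0L, 3L, 4L, 6L, 10L)) {
    chars <- rep("A", 40)
    if (k > 0) chars[seq_len(k) * 4L] <- "C"
    pk <- make_sigma(paste0("plant", k), paste(chars, collapse = ""))
    crdk <- find_crd(pk, crd_criteria())
    expect_equal(crdk$cys_count, k)
    expect_equal(crdk$is_crd, k >= 4L)
  }
})

test_that("census keeps exactly the planted homolog and labels failures", {
  cfg <- simulation_config(seed = 5)
  pr <- simulate_proteomes(cfg)
  cen <- crd_census(pr$proteins, pr$query)
  expect_equal(cen$protein_id[cen$pass], "SIGMA_PLANT_01")
  expect_true(all(cen$reason[!cen$pass] %in% c("homology", "domains", "tail")))

  # query included in the input reports itself (self-similarity passes)
  cen2 <- crd_census(c(list(pr$query), pr$proteins), pr$query)
  expect_true("SIGMA_QUERY" %in% cen2$protein_id[cen2$pass])

  # planted homolog with a Cys-free tail is excluded with reason "tail"
  pr3 <- simulate_proteomes(cfg, cys_override = 0L)
  cen3 <- crd_census(pr3$proteins, pr3$query)
  row <- cen3[cen3$protein_id == "SIGMA_PLANT_01", ]
  expect_false(row$pass)
  expect_equal(row$reason, "tail")

  # query without a CRD is rejected outright
  qbad <- sigma_factor_record("q", paste0(strrep("A", 150), strrep("L", 30)),
                              sigma4_span = c(100, 150))
  expect_error(crd_census(pr$proteins, qbad), "no CRD")
})

test_that("align_proteins: identity, documented score, N identical rows", {
  a <- align_proteins(c(x = "MKVLW", y = "MKVLW"))
  expect_equal(unname(a), c("MKVLW", "MKVLW"))

  # "ACDE" vs "ACE": one gap column; NW with BLOSUM62 and linear gap -8
  # gives AC-E (score 4 + 9 - 8 + 5 = 10, enumerated by hand)
  a2 <- align_proteins(c(x = "ACDE", y = "ACE"))
  expect_equal(unname(a2), c("ACDE", "AC-E"))

  a3 <- align_proteins(setNames(rep("MKVDEW", 4), paste0("s", 1:4)))
  expect_equal(unname(a3), rep("MKVDEW", 4))
  expect_error(align_proteins(c(x = "MKV")), "at least 2")
})

test_that("align_crds aligns the extracted tails, preserving order", {
  tails <- c("CAAACAAC", "CAAACAC", "CAAACAAC")
  prots <- Map(function(i, t) make_sigma(paste0("p", i), t),
               1:3, tails)
  aln <- align_crds(prots, crd_criteria(min_cys = 1))
  expect_equal(names(aln), c("p1", "p2", "p3"))
  expect_equal(length(unique(nchar(aln))), 1L)
  expect_equal(gsub("-", "", aln[["p2"]]), tails[2])
})

test_that("conservation classes match hand enumeration on a toy alignment", {
  # 5 rows; min_count 3
  aln <- c("CLIKA", "CLLRA", "CIVKA", "CLLKC", "C-MRA")
  #  col0: all C, no gaps            -> invariant
  #  col1: L,L,I,L,-  modal L=3      -> conserved
  #  col2: I,L,V,L,M  modal L=2 but group ILVM=5 -> similar
  #  col3: K,R,K,K,R  modal K=3      -> conserved
  #  col4: A,A,A,C,A  modal A=4      -> conserved
  cc <- conservation_classes(aln, conservation_params(min_count = 3))
  expect_equal(cc$conservation_class,
               c("invariant", "conserved", "similar", "conserved",
                 "conserved"))
  expect_equal(cc$modal_count[1], 5L)
  expect_equal(cc$gap_count[2], 1L)

  # a gap blocks "invariant" even when all residues agree
  cc2 <- conservation_classes(c("CA", "CA", "C-"),
                              conservation_params(min_count = 3))
  expect_equal(cc2$conservation_class[2], "none")

  # >= 11 of 21 rule on a 21-row column
  rows21 <- c(rep("L", 11), c("A", "C", "D", "E", "F", "G", "H", "I",
                              "K", "M"))
  aln21 <- vapply(rows21, function(r) r, "")
  cc3 <- conservation_classes(unname(aln21), conservation_params())
  expect_equal(cc3$conservation_class, "conserved")
  rows21b <- c(rep("L", 10), c("A", "C", "D", "E", "F", "G", "H", "W",
                               "K", "P", "R"))
  cc4 <- conservation_classes(unname(vapply(rows21b, identity, "")),
                              conservation_params())
  expect_equal(cc4$conservation_class, "none")
})

test_that("conservation classes are invariant to row permutation", {
  set.seed(31)
  aa <- c("A", "C", "D", "E", "L", "I", "V", "K", "R", "S")
  for (i in 1:10) {
    rows <- vapply(1:8, function(.)
      paste(sample(aa, 12, replace = TRUE), collapse = ""), "")
    p <- conservation_params(min_count = 4)
    c1 <- conservation_classes(rows, p)
    c2 <- conservation_classes(sample(rows), p)
    expect_equal(c1$conservation_class, c2$conservation_class)
  }
  rows_id <- rep("CLWKDE", 5)
  cid <- conservation_classes(rows_id, conservation_params(min_count = 3))
  expect_true(all(cid$conservation_class == "invariant"))
})
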