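# Independent oracles for the test suite. These deliberately avoid the
# package's own IUPAC tables and scanner code paths: the degeneracy table is
# restated here and windows are scored one at a time by substring.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

oracle_mismatches <- function(window, code) {
  w <- strsplit(window, "")[[1]]
  cc <- strsplit(code, "")[[1]]
  stopifnot(length(w) == length(cc))
  n <- 0L
  for (i in seq_along(w)) {
    allowed <- ORACLE_IUPAC[[cc[i]]]
    hit <- if (w[i] == "N") length(allowed) == 4L else w[i] %in% allowed
    if (!hit) n <- n + 1L
  }
  n
}

# brute-force all-windows scan on both strands; returns data.frame
# (minus35_start, strand, mismatches) under the package's coordinate
# convention (minus35_start = forward coord of first base in scan
# orientation)
oracle_scan <- function(seq, code, budget) {
  k <- nchar(code)
  L <- nchar(seq)
  rows <- list()
  for (s in 0:(L - k)) {
    win <- substr(seq, s + 1L, s + k)
    mm <- oracle_mismatches(win, code)
    if (mm <= budget) {
      rows[[length(rows) + 1L]] <- data.frame(
        minus35_start = s, strand = "+", mismatches = mm)
    }
  }
  rc <- oracle_revcomp(seq)
  for (s in 0:(L - k)) {
    win <- substr(rc, s + 1L, s + k)
    mm <- oracle_mismatches(win, code)
    if (mm <= budget) {
      rows[[length(rows) + 1L]] <- data.frame(
        minus35_start = L - 1L - s, strand = "-", mismatches = mm)
    }
  }
  if (!length(rows)) {
    return(data.frame(minus35_start = integer(), strand = character(),
                      mismatches = integer()))
  }
  do.call(rbind, rows)
}

# faster brute-force oracle: materializes every window as a row of a
# character matrix and tests per-column membership against its own table;
# same contract as oracle_scan, used where many genomes are scanned
oracle_scan_fast <- function(seq, code, budget) {
  k <- nchar(code)
  cc <- strsplit(code, "")[[1]]
  one_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    L <- length(chars)
    idx <- outer(0:(L - k), 1:k, "+")
    W <- matrix(chars[idx], nrow = L - k + 1L)
    mm <- integer(nrow(W))
    for (j in 1:k) {
      allowed <- ORACLE_IUPAC[[cc[j]]]
      colj <- W[, j]
      ok <- ifelse(colj == "N", length(allowed) == 4L, colj %in% allowed)
      mm <- mm + !ok
    }
    mm
  }
  L <- nchar(seq)
  mm_f <- one_strand(seq)
  mm_r <- one_strand(oracle_revcomp(seq))
  rbind(
    data.frame(minus35_start = which(mm_f <= budget) - 1L, strand = "+",
               mismatches = mm_f[mm_f <= budget]),
    data.frame(minus35_start = L - which(mm_r <= budget) + 1L - 1L,
               strand = "-", mismatches = mm_r[mm_r <= budget]))
}

# canonical string form of a hit set, for exact set comparison
hitset_key <- function(df) {
  sort(sprintf("%d/%s/%d", df$minus35_start, df$strand, df$mismatches))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
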