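# Cys-rich C-terminal domain (CRD) detection and the sigma-factor census.
#
# ECF sigma factors consist of the sigma2 and sigma4 regions only; a small
# group carries an extra C-terminal extension after sigma4 (38 residues with
# 6 Cys in the founding member) whose Cys content is the classification
# criterion implemented here.

#' Construct a sigma-factor protein record
#'
#' @param protein_id accession or locus tag.
#' @param seq amino-acid sequence.
#' @param sigma2_span,sigma4_span optional 1-based inclusive residue
#'   intervals \code{c(start, end)} of the sigma2 / sigma4 domains.
#' @return an object of class \code{sigma_factor_record}.
#' @export
sigma_factor_record <- function(protein_id, seq, sigma2_span = NULL,
                                sigma4_span = NULL) {
  stopifnot(nzchar(protein_id), is.character(seq), nzchar(seq))
  seq <- toupper(seq)
  n <- nchar(seq)
  chk <- function(span, name) {
    if (is.null(span)) return(NULL)
    span <- as.integer(span)
    if (length(span) != 2L || span[1] < 1L || span[2] > n ||
        span[1] > span[2]) {
      stop(name, " span out of range for '", protein_id, "'")
    }
    span
  }
  sigma2_span <- chk(sigma2_span, "sigma2")
  sigma4_span <- chk(sigma4_span, "sigma4")
  if (!is.null(sigma2_span) && !is.null(sigma4_span) &&
      sigma2_span[2] >= sigma4_span[1]) {
    stop("sigma2 must precede sigma4 in '", protein_id, "'")
  }
  structure(list(protein_id = protein_id, seq = seq,
                 sigma2_span = sigma2_span, sigma4_span = sigma4_span),
            class = "sigma_factor_record")
}

#' CRD classification criteria
#'
#' @param min_cys minimum Cys count in the tail (default 4, "at least 4 Cys
#'   in the C terminus").
#' @param tail_policy "after_sigma4": the tail is everything after the
#'   sigma4 domain end (requires the span); "last_k_residues": the last
#'   \code{tail_k} residues (fallback when no domain coordinates exist).
#' @param tail_k tail length for the fallback policy (default 45, covering
#'   the 38-residue founding CRD with margin).
#' @param homology_evalue_max E-value cutoff for the census homology
#'   pre-filter (default 2e-10).
#' @param require_sigma_domains census drops proteins lacking both domain
#'   spans when TRUE.
#' @param allow_fallback permit last_k fallback for proteins without a
#'   sigma4 span under the after_sigma4 policy.
#' @return an object of class \code{crd_criteria}.
#' @export
crd_criteria <- function(min_cys = 4L,
                         tail_policy = c("after_sigma4", "last_k_residues"),
                         tail_k = 45L, homology_evalue_max = 2e-10,
                         require_sigma_domains = FALSE,
                         allow_fallback = FALSE) {
  tail_policy <- match.arg(tail_policy)
  stopifnot(min_cys >= 1L, tail_k >= 1L)
  structure(list(min_cys = as.integer(min_cys), tail_policy = tail_policy,
                 tail_k = as.integer(tail_k),
                 homology_evalue_max = homology_evalue_max,
                 require_sigma_domains = isTRUE(require_sigma_domains),
                 allow_fallback = isTRUE(allow_fallback)),
            class = "crd_criteria")
}

#' Detect a Cys-rich C-terminal domain on one protein
#'
#' The tail runs from just after the sigma4 domain (or the last
#' \code{tail_k} residues under the fallback policy) to the final residue;
#' Cys are counted within it and the protein is classified CRD-positive
#' when the count reaches \code{min_cys}.
#'
#' @param protein a \code{\link{sigma_factor_record}}.
#' @param criteria a \code{\link{crd_criteria}}.
#' @return a one-row data.frame: \code{protein_id}, \code{tail_start}
#'   (1-based), \code{tail_len}, \code{cys_count}, \code{cys_positions}
#'   (comma-joined 1-based indices), \code{is_crd}.
#' @export
find_crd <- function(protein, criteria = crd_criteria()) {
  stopifnot(inherits(protein, "sigma_factor_record"),
            inherits(criteria, "crd_criteria"))
  n <- nchar(protein$seq)
  if (criteria$tail_policy == "after_sigma4") {
    if (is.null(protein$sigma4_span)) {
      if (!criteria$allow_fallback) {
        stop("no sigma4 coordinates for '", protein$protein_id,
             "' and fallback not allowed")
      }
      tail_start <- max(1L, n - criteria$tail_k + 1L)
    } else {
      tail_start <- protein$sigma4_span[2] + 1L
    }
  } else {
    tail_start <- max(1L, n - criteria$tail_k + 1L)
  }
  tail_len <- max(0L, n - tail_start + 1L)
  tail_seq <- if (tail_len > 0L) substr(protein$seq, tail_start, n) else ""
  cys_rel <- if (nzchar(tail_seq)) {
    which(strsplit(tail_seq, "", fixed = TRUE)[[1]] == "C")
  } else integer()
  cys_pos <- cys_rel + tail_start - 1L
  data.frame(protein_id = protein$protein_id,
             tail_start = if (tail_len > 0L) tail_start else NA_integer_,
             tail_len = tail_len, cys_count = length(cys_pos),
             cys_positions = paste(cys_pos, collapse = ","),
             is_crd = length(cys_pos) >= criteria$min_cys,
             stringsAsFactors = FALSE)
}

#' Census of CRD-bearing sigma factors in a proteome
#'
#' Each protein is compared with the query by local alignment
#' (\code{\link{pairwise_similarity}}); those passing the E-value cutoff,
#' carrying sigma domains when required, and whose tail passes
#' \code{\link{find_crd}} make the census. Every input protein is reported
#' with the reason it failed ("homology", "domains", "tail") or "" when it
#' passed; passing rows sort first, by similarity (bits, descending).
#'
#' @param proteins list of \code{\link{sigma_factor_record}}.
#' @param query a CRD-bearing \code{\link{sigma_factor_record}}.
#' @param criteria a \code{\link{crd_criteria}}.
#' @return data.frame: \code{find_crd} columns plus \code{bits},
#'   \code{evalue}, \code{pass}, \code{reason}.
#' @export
crd_census <- function(proteins, query, criteria = crd_criteria()) {
  stopifnot(inherits(query, "sigma_factor_record"))
  qcrd <- find_crd(query, criteria)
  if (!qcrd$is_crd) stop("query protein has no CRD under these criteria")
  rows <- lapply(proteins, function(p) {
    stopifnot(inherits(p, "sigma_factor_record"))
    sim <- pairwise_similarity(p$seq, query$seq)
    reason <- ""
    if (sim$evalue > criteria$homology_evalue_max) {
      reason <- "homology"
    } else if (criteria$require_sigma_domains &&
               (is.null(p$sigma2_span) || is.null(p$sigma4_span))) {
      reason <- "domains"
    }
    tail_row <- tryCatch(find_crd(p, criteria), error = function(e) NULL)
    if (is.null(tail_row)) {
      tail_row <- data.frame(protein_id = p$protein_id,
                             tail_start = NA_integer_, tail_len = 0L,
                             cys_count = NA_integer_, cys_positions = "",
                             is_crd = FALSE, stringsAsFactors = FALSE)
      if (reason == "") reason <- "domains"
    } else if (reason == "" && !tail_row$is_crd) {
      reason <- "tail"
    }
    cbind(tail_row,
          data.frame(bits = sim$bits, evalue = sim$evalue,
                     pass = reason == "", reason = reason,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$pass, -out$bits), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align the CRD tails of a set of proteins
#'
#' Extracts each protein's tail per the criteria and runs the progressive
#' aligner (\code{\link{align_proteins}}).
#'
#' @param proteins list of \code{\link{sigma_factor_record}} (>= 2).
#' @param criteria a \code{\link{crd_criteria}}.
#' @return named character vector of equal-length gapped rows, input order.
#' @export
align_crds <- function(proteins, criteria = crd_criteria()) {
  if (length(proteins) < 2L) stop("CRD alignment needs at least 2 proteins")
  tails <- vapply(proteins, function(p) {
    row <- find_crd(p, criteria)
    if (row$tail_len == 0L) stop("empty tail for '", p$protein_id, "'")
    substr(p$seq, row$tail_start, nchar(p$seq))
  }, "")
  names(tails) <- vapply(proteins, `[[`, "", "protein_id")
  align_proteins(tails)
}

#' Read a sigma2/sigma4 domain coordinate table
#'
#' TSV with columns protein_id, sigma2_start, sigma2_end, sigma4_start,
#' sigma4_end (1-based inclusive; empty/NA allowed).
#'
#' @param path TSV file.
#' @return data.frame keyed by protein_id.
#' @export
read_domain_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("protein_id", "sigma2_start", "sigma2_end",
            "sigma4_start", "sigma4_end")
  if (!all(need %in% names(tab))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Build sigma-factor records from sequences plus a domain table
#'
#' @param seqs named character vector of protein sequences.
#' @param domains optional data.frame from \code{\link{read_domain_table}}.
#' @return list of \code{\link{sigma_factor_record}}.
#' @export
sigma_records_from_fasta <- function(seqs, domains = NULL) {
  lapply(names(seqs), function(id) {
    s2 <- s4 <- NULL
    if (!is.null(domains)) {
      row <- domains[domains$protein_id == id, ]
      if (nrow(row) == 1L) {
        if (!is.na(row$sigma2_start)) s2 <- c(row$sigma2_start, row$sigma2_end)
        if (!is.na(row$sigma4_start)) s4 <- c(row$sigma4_start, row$sigma4_end)
      }
    }
    sigma_factor_record(id, seqs[[id]], s2, s4)
  })
}
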