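---
title: "corescan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corescan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corescan)
```

## The model

ECF σ factors recognize promoters through two contacts: the σ4 region reads
a −35 box and the σ2 region reads a −10 box. `corescan` represents such a
site as a *bipartite motif*:

* a −35 element given as a degenerate IUPAC consensus, where each column's
  allowed set is exactly the set of bases observed in the training
  alignment (so every training promoter matches with zero mismatches);
* a subset of *invariant* columns — those where all training promoters
  agree — that the filter cascade requires to match exactly;
* a single required anchor base (default G) standing in for the conserved
  core of the −10 box;
* a spacer constraint between the two.

Matching is by explicit mismatch counting, not by a position-weight matrix:
a window base mismatches a column iff it lies outside the column's allowed
set, and a raw hit is any window within `max_mismatches` (default 2) on
either strand. This replaces PWM log-odds scoring deliberately: the
original screen was defined in terms of a mismatch budget, and counting is
exactly testable against a brute-force oracle.

`N` in a scanned genome is treated as a concrete unknown: it matches only
columns whose allowed set is the full `{A,C,G,T}`. This is conservative —
an ambiguous base never rescues a hit.

### Spacer convention

"A distance of 16–18 residues" between the boxes is ambiguous about
endpoints. The package fixes one convention and stores it in the model:
**the spacer is the number of nucleotides strictly between the last base of
the −35 element and the anchor base**. With spacer 16, the anchor sits 17
positions after the element's last base. When several spacers in
`[spacer_min, spacer_max]` would qualify, the smallest wins — a documented,
deterministic tie-break. Both bounds are ordinary arguments, so a user who
believes the original count included an endpoint can shift the window by
one without touching code.

### Filter cascade

Raw hits pass three predicates, applied in a fixed order but all always
evaluated:

1. **orientation/assignment** — the nearest translational start downstream
   of the hit in the hit's orientation, within `max_distance` (default
   300 nt), is assigned; the hit must lie on the assigned gene's strand.
   Distance is counted from the element's last base to the gene's first
   coding base; equidistant starts resolve to the gene with the smaller
   genomic start coordinate.
2. **invariants** — the window must match every invariant −35 column.
3. **−10 anchor** — the anchor base must occur within the spacer window
   (wrapping around the origin for genomes flagged circular; falling off
   the end of a linear contig means "absent").

Stage counts are monotone by construction and the per-candidate flag table
is the primary output: the original procedure's manual inspection is
replaced by predicates whose individual verdicts are visible.

Two conventions are choices, not published facts: the raw scan counts both
strands and keeps overlapping windows (the downstream orientation filter
implies an orientation-agnostic scan), and `max_distance = 300` nt bounds
promoter-to-start distance (the original manual screen states no cutoff).
The default upstream window in `extract_upstream` (300 nt) is likewise a
choice covering a bacterial promoter/RBS span; all are arguments.

## CRD detection and census

The founding member of the CRD subfamily carries a 38-residue C-terminal
extension after σ4 containing 6 Cys. The classifier is the simple rule that
generalized: **at least `min_cys = 4` Cys in the C-terminal tail**. The
tail is everything after the σ4 domain end when domain coordinates are
supplied; without them, the fallback is the last `tail_k = 45` residues
(covering the 38-residue prototype with margin). σ2/σ4 detection itself is
*not* re-implemented: profile-HMM domain calling is mature external
infrastructure, and the scientific content here is the Cys rule. Domain
coordinates enter as a plain TSV.

The census pre-filters a proteome by local-alignment similarity to a query
(BLOSUM62, gap open 11 / extend 1) with a Karlin–Altschul E-value
estimate: S′ = (λS − ln K)/ln 2 with the standard gapped BLOSUM62
parameters λ = 0.267, K = 0.041, and E = m·n·2^(−S′) over the product of
the two sequence lengths. This approximates BLASTP's statistics but not its
edge corrections or database-scaled search space, so absolute E-values
differ from a real database search; at the thresholds used (2e-10 for the
census, 1e-4 for synteny) the separation between homologs and unrelated
sequences is orders of magnitude wide, which the decoy tests verify
empirically.

CRD tails are aligned with a progressive profile aligner: sequences join in
input order, each aligned to the growing profile by Needleman–Wunsch with
BLOSUM62 column-mean scores and a *linear* gap penalty of −8 per column,
diagonal-preferring tie-breaks. Linear gaps keep every score hand-checkable
(the test suite includes a by-hand dynamic-programming case). This is not
ClustalX: no guide tree is estimated, and column-level conclusions that are
sensitive to the exact tree (e.g. *which* columns come out invariant in a
reference alignment) should be checked for robustness rather than assumed.

Conservation classes per column, in precedence order: `invariant` (all rows
one residue, no gaps), `conserved` (modal residue count ≥ threshold),
`similar` (modal similarity-group count ≥ threshold), `none`. The default
threshold is the fraction 11/21, matching a rule of "at least 11 of 21
sequences" and scaling to other alignment sizes via `ceiling`. The
similarity grouping — {ILVM} {FWY} {KRH} {DE} {ST} {NQ} {AG} {C} {P} — is a
standard physicochemical partition chosen here because the original figure
does not define its own; it is a `conservation_params` argument.

## Synteny

A neighborhood is the `flank_genes = 2` genes on each side of an anchor in
genomic order, strand-ignored (gene order, not orientation, is the signal).
Two neighborhoods are compared by scoring all flank-protein pairs and
matching greedily, best score first, each protein used at most once; ties
break toward smaller |offset|, then input order. A block is conserved when
at least one pair passes E ≤ 1e-4. Optional extension widens the window one
gene per side while each widening adds a new passing pair, capped at 5
genes per side — the original analysis "extended to other genes within the
same region" without stating how far, so the cap is a configurable bound.

## The synthetic world

The generators state a fixed world; their defaults are not tuned to tests.

* Background genomes: i.i.d. bases at `gc_fraction = 0.69` — the GC content
  of myxobacterial genomes, the setting that motivated the model — over
  30 kb by default (large enough to carry all cassettes with ≥ 400 nt of
  untouched background between them, small enough for fast suites).
* Planted true promoters: 5 per genome; mismatch counts cycle 0,1,2 (all
  within budget), strands alternate, spacers cycle 16,17,18. Mismatched
  bases are drawn uniformly from outside the column's allowed set, at
  positions sampled without replacement among non-invariant columns; the
  planted spacer region contains no anchor base before the planted one, so
  the recorded spacer is exactly what the scanner must report.
* Decoys: near-miss motifs at budget + 1 mismatches (never a raw hit at
  their site), wrong-strand plants (valid motif, gene annotated opposite —
  these must appear in raw hits and fail only the orientation flag), and
  promoter-less genes.
* Proteomes: 50 decoy proteins i.i.d. over the 20 amino acids, one planted
  σ-factor-like protein per proteome by default — a point-mutated copy
  (identity 0.75) of a seeded 170-residue template with σ2 at 10–70, σ4 at
  120–170, carrying a fresh 38-residue tail with exactly 6 Cys. 0.75
  identity over ~170 residues gives E-values far below 2e-10 while i.i.d.
  decoys sit far above it.
* Synteny pairs: five-gene neighborhoods whose flank proteins either are
  mutated copies across genomes (conserved) or independent (not).

Determinism: one integer seed drives everything; each feature class derives
its own RNG substream from `(seed, tag)`, so adding one kind of planted
feature never shifts another's draws, and identical configs give
byte-identical output.

What a green test does establish: the scanner is exactly equivalent to
brute force; the cascade implements its three predicates; planted features
are recovered with recall 1.0 and decoys fail for the designed reason; the
CRD rule is count-exact. What it does not establish: performance on real
genomes — i.i.d. backgrounds have no repeats, skews, or compositional
structure, annotations are never wrong, and planted homology has no domain
architecture. In particular the number of *chance* finals in a random
genome (see the README example) is a property of the synthetic background,
not a prediction about any real genome.

## Numerical and degenerate-input choices

* Information content is the uncorrected 2 − H₂ (bits); WebLogo's
  small-sample correction is omitted so values are closed-form testable
  (an all-G column is exactly 2.0; a 3:1 column is 1.1887219). Gaps are
  excluded from column counts.
* Zero-length upstream regions (gene at a contig edge or fully crowded by
  a neighbor) are emitted with an empty sequence and a warning — never
  silently dropped.
* Coordinates are 0-based half-open internally; GFF3/GenBank interfaces
  convert at the boundary. Minus-strand hits report the forward-genome
  coordinate of the element's first base *in scan orientation*.
* GenBank parsing covers simple and `complement()` locations only; spliced
  (`join`) features error out rather than being misread.

## Known limitations

* E-values are approximations; do not compare them with published BLASTP
  numbers, only with thresholds within this package.
* The progressive aligner is O(profile × sequence) per join with no
  refinement; for the ≤ tens of short CRD tails it targets this is ample,
  for hundreds of long proteins it is not the right tool.
* The scanner holds one contig's character vector in memory (fine for
  bacterial genomes).
* No statistical significance is attached to motif hits; the cascade's
  counts are descriptive, and a final candidate is a *candidate*, exactly
  as in the original screen, where the last step was biological judgment.
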