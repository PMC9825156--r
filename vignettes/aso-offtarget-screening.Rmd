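---
title: "Methods: hybridization-dependent off-target screening and motif auditing for ASOs"
author: "asoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybridization-dependent off-target screening and motif auditing for ASOs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asoscan)
```

## The problem

An antisense oligonucleotide (ASO) is designed against one RNA, but a
short complementary sequence can occur, exactly or approximately,
elsewhere in the transcriptome. Two distinct failure modes matter when an
ASO shows unexpected activity:

* **Hybridization-dependent off-targets** — transcripts carrying sites
  partially or fully complementary to the ASO, which can be silenced or
  otherwise engaged by base pairing. These are predictable from sequence.
* **Hybridization-independent effects** — activity driven by the
  oligonucleotide's chemistry and sequence composition rather than base
  pairing, notably protein binding to guanosine-rich motifs on
  phosphorothioate (PS) backbones. These are not predictable from target
  complementarity, but the risk motifs themselves are detectable in the
  ASO sequence.

`asoscan` implements both screens, plus the design-panel generators
(micro-walks, length series, mismatch variants) used to probe a candidate
hotspot, and a synthetic-data module that makes the entire pipeline
testable against planted ground truth.

## The pairing score

The core statistic is an ungapped, antiparallel pairing score. An ASO
$a_0 a_1 \ldots a_{L-1}$ (5'→3') is laid against an equal-length window
$w_0 \ldots w_{L-1}$ of the sense strand so that ASO position $i$ opposes
window position $L-1-i$, and

$$S(a, w) \;=\; \sum_{i=0}^{L-1} M\!\left[a_i,\; w_{L-1-i}\right],$$

where $M$ is a $4 \times 4$ matrix of pairing values indexed by (ASO
base, opposing target base). Gaps are never considered: candidate sites
are ungapped duplexes with mismatches. Every window at stride 1 is
scored, and windows with $S \ge$ a threshold (default **40**, the
conventional candidate call, inclusive) are reported as candidate sites.

Every matrix must satisfy a structural invariant enforced by
`scoring_matrix()`: for each ASO base, the Watson–Crick complement entry
is strictly the row maximum and positive. This guarantees the *supremum
property*: the maximum attainable score of an ASO,
`max_score(aso) = sum of complement entries`, is reached by exactly one
window — the ASO's reverse complement — and by no other. The property is
what makes "score relative to maximum" meaningful in reports, and it is
verified exhaustively in the test suite (all ASOs up to 6 nt against all
$4^L$ windows).

### The default matrix

Per-ASO matrices are configuration (`read_matrix()` loads a 5×5 TSV grid
and any function accepts one); the shipped default encodes the
qualitative structure such matrices share:

| pair type | entries | value |
|---|---|---|
| match, A:T | (A,T), (T,A) | +2 |
| match, G:C | (C,G), (G,C) | +3 |
| wobble | (G,T), (T,G) | +1 |
| purine·purine mismatch | (A,A), (A,G), (G,A), (G,G) | −3 |
| other mismatch | all remaining | −2 |

Matches are upweighted with G:C above A:T, and mismatches are penalized
variably by base composition, purine–purine clashes hardest, with G:T/T:G
wobbles in between. Two consequences worth knowing: a 20-nt ASO with $g$
G/C bases has `max_score` $= 40 + g$, so any GC-containing 20-mer can
lose a mismatch or two and still clear the ≥40 call — mismatched
candidate sites are expected, not an artifact; and a single substitution
anywhere in a perfect window strictly lowers the score (match > wobble >
mismatch in every row), which the suite checks exhaustively for 20-nt
ASOs. The default is deliberately *not* treated as truth anywhere:
study-specific matrices override it per ASO via the manifest's
`matrix_id` column.

Wobble-scored positions count as mismatches in `mismatch_positions`
(display follows the "mismatched relative to the ASO" convention) but
are tallied separately in `n_wobble`.

## From sites to genes to biology

* `scan_transcriptome()` applies the window scan to every (ASO, sequence)
  pair, optionally restricted to an expressed-gene set. Expression is an
  explicit input — a gene list, or a TPM table thresholded at
  `min_tpm = 5`, a conventional expressed-gene cutoff — because the right
  criterion is study-specific.
* `collapse_to_genes()` reduces sites to one record per (ASO, gene) with
  the best score, site count and best-site coordinates; ties break by
  smallest start, then seq_id, keeping output deterministic.
* `mutual_targets()` computes all $2^k - 1$ exclusive Venn regions over
  per-ASO candidate gene sets. A gene in the full intersection — carrying
  above-threshold sites for every ASO — is a *mutual* candidate, the kind
  that could explain a shared phenotype across unrelated sequences.
* `score_cdf()` reports, per gene category and score cutoff, the
  fraction of genes *not* called at that cutoff (strictly below it), the
  standard way to visualize how quickly candidates vanish as the
  threshold rises.
* `deg_flag()` crosses candidates with a differential-expression table:
  flagged iff present with `padj < alpha` (default 0.05, the usual
  adjusted-p convention — recorded in the run log as an assumption);
  genes absent from the table are `not_tested`, never flagged.
  `deg_shared_counts()` gives upset-style exclusive region counts over
  per-group DEG sets, by `padj < alpha` or by top-`n` smallest p-values
  (top-200 being a common reporting choice).
* `find_tandem_repeats()` is an exact, left-anchored greedy scan for
  maximal arrays of a repeat unit (≥ `min_units` copies), covering the
  GAA-repeat risk question (genes carrying long GAA arrays are potential
  off-targets of repeat-directed strategies) without a BLAST dependency.

Coordinates are 0-based half-open everywhere in tables; rendered report
text uses 1-based inclusive coordinates and says so.

## Motif audit and design panels

`audit_aso()` applies a closed rule vocabulary: `G_RUN` (maximal runs of
≥4 G), `CCGG`, `CpG`, `TGC`, `TCC` (literal occurrences), and
`TERMINAL_3P_G` (the 3' end is ≥2 consecutive G, threshold k=2 because
"terminal guanosines" implies plural with no count fixed). `G4_TRACTS`
(four ≥3-G tracts with 1–7 nt loops, the classical quadruplex pattern) is
available but off by default: short ASOs that show G-rich-motif effects
typically carry a plain run, and the four-tract pattern is a stricter,
structure-motivated rule. Flags mark sequences deserving extra controls;
they are not activity predictions — these motifs are context dependent.

`microwalk_panel()` (2-nt steps up to ±16 by default, 17 ASOs when all
windows fit), `length_panel()` (one ASO per length, 18–24 nt being a
typical series, sharing an anchored terminus) and `mismatch_panel()`
(variants at listed 0-based positions) generate the standard design
panels. The default mismatch substitution is the complement of the
original base — it guarantees loss of pairing at that position whatever
the opposing strand — and published variants with known substitution
bases can be supplied explicitly. Out-of-bounds micro-walk offsets and
lengths are skipped with warnings (a hotspot near a sequence end still
yields the feasible panel); errors are reserved for impossible requests.

## Synthetic data and what tests do (and do not) show

`make_transcriptome()` draws i.i.d. bases at a controlled GC content.
`plant_sites()` overwrites windows with the ASO's reverse complement and
corrupts chosen positions to the complement of the planted base — a
guaranteed mismatch under any matrix — then records each site's
construction score *recomputed from the final sequence*, so the truth
manifest is redundant with the emitted files, never authoritative.
`make_deg_table()` generates DEG tables directly (padj ~ U(0, 0.01) for
DEGs vs U(0.2, 1) otherwise; |log2FC| ~ N(2, 0.5) vs N(0, 0.2)) with a
controlled shared core across groups.

`make_figure9_scenario()` assembles the canonical two-ASO test: one
shared perfect-site target gene, 3 and 15 additional singly mismatched
candidates (20-nt ASOs drawn with exactly 10 G/C so `max_score` is 50
and one planted mismatch leaves 44–46, safely above 40), and a DEG table
flagging exactly 3 of the 18 non-target candidates. Sixty genes of
600–1200 nt keep the scan fast while making a chance ≥40 background hit
(which would need a near-perfect 20-mer complement) vanishingly
unlikely, so planted-truth comparisons are exact.

What the generator does *not* emulate: real transcript structure (UTRs,
splicing, isoform overlap), non-uniform base composition, paralogy, and
the read-count noise behind real DEG calls. Green tests therefore
demonstrate that the machinery is correct — recall of planted truth,
oracle equivalence of the scan, exact set algebra — not that any
particular biological transcriptome would yield these counts; with real
data the candidate lists depend on the chosen transcriptome, expression
set and per-ASO matrices.

All generators are pure functions of (parameters, seed) under a fixed
RNG contract (R's Mersenne-Twister, Rejection sampling, Inversion
normals), which each truth manifest echoes.

## Numerical and design choices

* Scores are summed exactly as given (integers by default; decimal
  matrices are accepted unchanged). No floating-point tolerance is
  needed anywhere in calling: the threshold comparison is `>=` on exact
  sums, and the boundary (a site scoring exactly the threshold is
  called; one point below is not) is tested explicitly.
* Determinism is a contract: hit tables are sorted (aso_id, seq_id,
  start), panels are generated in fixed offset/length order, and
  `run_scan()` re-runs are byte-identical — the provenance hash in every
  output header covers the analysis configuration but deliberately not
  the output path.
* Records shorter than the ASO, empty hit tables, single-member
  categories and zero-DEG groups are all defined, tested paths rather
  than errors; empty *inputs* (no ASOs, no sequences, empty categories)
  error loudly.
* Sense strand only by default (ASOs bind RNA); genomic inputs can be
  handled by scanning the reverse complement records explicitly.
* Candidate counts are reported both as sites and as genes: the two
  differ whenever a gene carries several sites, and reports keep both
  visible (`n_sites` per gene summary) rather than arbitrating.
* Problem sizes in the shipped analyses — a 60-gene scenario for the
  scan stages and a 3000-gene universe for the DEG set algebra — were
  chosen as the smallest sizes at which every structural feature of the
  design (18 candidate genes, disjoint group-specific DEG sets around a
  690-gene core) fits with room to spare.

## Known limitations

No thermodynamics (ΔG, melting, structure accessibility): the pairing
score is a composition-aware complementarity count, not a stability
model. No gapped alignment; bulged sites are out of scope. No chemistry
modeling — PS/MOE/PMO annotations are carried as opaque text. The motif
rules flag sequence features only; they cannot say which motif-bearing
ASO will actually misbehave in a given cell type.
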