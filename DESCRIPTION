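Package: asoscan
Title: Hybridization-Dependent Off-Target Scanning and Motif Auditing for Antisense Oligonucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Screens antisense oligonucleotides (ASOs) for hybridization-dependent
    off-target binding sites in a transcriptome using a mismatch-aware, ungapped
    pairing score driven by a configurable 4x4 base-pair scoring matrix. Collapses
    candidate sites to genes, intersects candidate sets across ASOs (mutual
    targets), computes score cumulative distributions, finds exact tandem repeats
    (e.g. GAA arrays), and integrates pre-computed differential-expression tables.
    Also audits ASO sequences for hybridization-independent G-rich risk motifs
    (G-runs, G-quadruplex tract patterns, CCGG, CpG, TGC, TCC, 3'-terminal
    guanosines) and generates design panels (micro-walk tilings, length series,
    mismatch variants). A synthetic-data module plants complementary sites and
    differential-expression structure with a full truth manifest so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
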