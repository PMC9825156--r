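#!/usr/bin/env Rscript
# Stage 2 — hybridization-dependent off-target scan.
#
# Reads the stage-1 files back from disk (exercising the same readers a
# real study would use), scans both ASOs over every expressed gene at
# pairing score >= 40, collapses sites to genes, and writes the hit
# table, gene summaries, rendered top-hit alignments, per-ASO score CDF
# and the mutual-target (Venn) report to results/scan/.

suppressPackageStartupMessages(library(asoscan))
sim <- "results/simulation"
if (!dir.exists(sim)) stop("run analysis/01_simulate.R first")

res <- run_scan(list(
  asos = file.path(sim, "asos.tsv"),
  fasta = file.path(sim, "transcriptome.fa"),
  matrix = file.path(sim, "matrix.tsv"),
  expressed = file.path(sim, "expressed_genes.txt"),
  deg = list(treated = file.path(sim, "deg_treated.csv")),
  threshold = 40,
  out = "results/scan"
))

counts <- table(res$summaries$aso_id)
cat("candidate genes per ASO (incl. intended target):\n")
print(counts)
cat("mutual targets:", paste(res$venn$shared, collapse = ", "), "\n")
cat("of the", sum(counts) - 2 * length(res$venn$shared),
    "non-shared candidates,",
    sum(res$deg_flags$treated$deg_status == "flagged" &
          !res$deg_flags$treated$gene_id %in% res$venn$shared),
    "are differentially expressed\n")
cat("artifacts in results/scan\n")
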