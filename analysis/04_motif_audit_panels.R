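#!/usr/bin/env Rscript
# Stage 4 — risk-motif audit and design panels.
#
# Audits the simulated ASOs (plus constructed G-rich examples) for
# hybridization-independent risk motifs, designs a 2-nt micro-walk and an
# 18-24 nt length series around a hotspot, generates single-mismatch
# variants of one ASO, and scans a GAA-repeat-bearing gene for tandem
# arrays. Artifacts land in results/design/.

suppressPackageStartupMessages(library(asoscan))
seed <- as.integer(Sys.getenv("ASOSCAN_SEED", "1"))
out <- "results/design"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

bundle <- make_figure9_scenario(seed)

# motif audit of the scenario ASOs plus two constructed motif carriers
examples <- rbind(
  bundle$asos[, c("aso_id", "sequence", "chemistry", "matrix_id")],
  aso_record("G4_tail_example", paste0(strrep("ACTA", 4), "GGGG"),
             chemistry = "PS/MOE steric blocker"),
  aso_record("CCGG_example", "ATTACCGGATTAATTA",
             chemistry = "PS/MOE steric blocker")
)
audit <- run_audit(list(asos = examples, out = out))
cat("motif flags found:\n")
print(table(audit$aso_id, audit$motif_name))

# micro-walk and length series around the planted ASO_A site
target_seq <- bundle$records[bundle$records$gene_id ==
                               bundle$truth$shared_target_gene, ]
site <- bundle$truth$planted_sites
site_a <- site[site$aso_id == "ASO_A" & site$n_mismatches == 0, ]
walk <- run_design(list(mode = "microwalk", region = target_seq,
                        center_start = site_a$start, length = 20,
                        out = file.path(out, "microwalk")))
lens <- run_design(list(mode = "length_series", region = target_seq,
                        anchor_start = site_a$start, lengths = 18:24,
                        out = file.path(out, "length_series")))
cat("micro-walk:", nrow(walk), "ASOs; length series:", nrow(lens),
    "ASOs\n")

# single-mismatch variants across the first 10 positions of ASO_A
vars <- run_design(list(mode = "mismatch", parent = bundle$asos[1, ],
                        position_sets = as.list(0:9),
                        out = file.path(out, "mismatch")))
cat("mismatch variants:", nrow(vars),
    "(all Hamming distance 1 from parent)\n")

# GAA-array risk scan on a repeat-bearing version of one gene
recs <- plant_tandem_repeat(bundle$records, "G0030", 200, "GAA", 8)
rep_hits <- find_tandem_repeats(as.list(recs[recs$gene_id == "G0030", ]),
                                "GAA", min_units = 6)
write.table(rep_hits, file.path(out, "gaa_repeats.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("GAA arrays (>= 6 units) found:", nrow(rep_hits), "at",
    paste(rep_hits$start, collapse = ","), "\n")
cat("artifacts in", out, "\n")
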