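test_that("audit_aso flags CCGG with its CpG core at the right intervals", {
  fl <- audit_aso(list(aso_id = "x", sequence = "TTCCGGTT"),
                  rules = c("CCGG", "CpG"))
  expect_equal(fl$motif_name, c("CCGG", "CpG"))
  expect_equal(fl$start, c(2L, 3L))
  expect_equal(fl$end, c(6L, 5L))
  # the full rule set additionally sees the TCC at offset 1
  full <- audit_aso(list(aso_id = "x", sequence = "TTCCGGTT"))
  expect_equal(full$motif_name, c("TCC", "CCGG", "CpG"))
})

test_that("a 3'-terminal GGGG raises both G_RUN and TERMINAL_3P_G", {
  aso <- list(aso_id = "s30like", sequence = paste0(strrep("ACTA", 4), "GGGG"))
  fl <- audit_aso(aso)
  grun <- fl[fl$motif_name == "G_RUN", ]
  expect_equal(nrow(grun), 1L)
  expect_equal(grun$end, 20L)
  expect_equal(grun$detail, "run_length=4")
  term <- fl[fl$motif_name == "TERMINAL_3P_G", ]
  expect_equal(term$start, 16L)
  expect_equal(term$detail, "k=4")
})

test_that("motif-free sequences yield zero flags and bad rules error", {
  expect_equal(nrow(audit_aso(list(aso_id = "x", sequence = "ACACACAC"))), 0L)
  expect_error(audit_aso(list(aso_id = "x", sequence = "ACACACAC"),
                         rules = "NOPE"), "unknown motif rule")
})

test_that("every flag is self-verifying against its motif definition", {
  withr::with_seed(19, {
    for (i in 1:30) {
      seq <- random_dna(sample(12:30, 1), gc = 0.6)
      fl <- audit_aso(list(aso_id = "r", sequence = seq),
                      rules = c(default_motif_rules(), "G4_TRACTS"))
      for (k in seq_len(nrow(fl))) {
        piece <- substr(seq, fl$start[k] + 1L, fl$end[k])
        switch(fl$motif_name[k],
          G_RUN = {
            expect_match(piece, "^G{4,}$")
            # maximality: not extendable either way
            if (fl$start[k] > 0)
              expect_false(substr(seq, fl$start[k], fl$start[k]) == "G")
            if (fl$end[k] < nchar(seq))
              expect_false(substr(seq, fl$end[k] + 1L, fl$end[k] + 1L) == "G")
          },
          G4_TRACTS = expect_match(piece, "^G{3,}([ACT]{1,7}G{3,}){3}$"),
          CCGG = expect_equal(piece, "CCGG"),
          CpG = expect_equal(piece, "CG"),
          TGC = expect_equal(piece, "TGC"),
          TCC = expect_equal(piece, "TCC"),
          TERMINAL_3P_G = {
            expect_match(piece, "^G{2,}$")
            expect_equal(fl$end[k], nchar(seq))
          })
      }
    }
  })
})

test_that("G4_TRACTS detects the four-tract quadruplex pattern only when enabled", {
  q <- list(aso_id = "q", sequence = "GGGTTGGGTAGGGTTAGGG")
  expect_equal(nrow(audit_aso(q)[audit_aso(q)$motif_name == "G4_TRACTS", ]), 0L)
  fl <- audit_aso(q, rules = "G4_TRACTS")
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$start, 0L)
  expect_equal(fl$end, 19L)
})

test_that("repeated literal occurrences are all reported", {
  fl <- audit_aso(list(aso_id = "x", sequence = "ATCCCA"), rules = "TCC")
  expect_equal(fl$start, 1L)
  fl2 <- audit_aso(list(aso_id = "x", sequence = "TCCTCCA"), rules = "TCC")
  expect_equal(fl2$start, c(0L, 3L))
  fl3 <- audit_aso(list(aso_id = "x", sequence = "ACGCGCGT"), rules = "CpG")
  expect_equal(fl3$start, c(1L, 3L, 5L))
})

test_that("mismatch_panel applies the complement rule with exact Hamming distance", {
  parent <- list(aso_id = "P", sequence = "ACGT")
  v <- mismatch_panel(parent, list(1L))
  expect_equal(v$sequence, "AGGT")        # C -> G
  expect_equal(v$aso_id, "P_m1")

  v4 <- mismatch_panel(parent, list(0L, 1L, 2L, 3L))
  expect_equal(nrow(v4), 4L)
  expect_false(any(duplicated(v4$sequence)))
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_true(all(vapply(v4$sequence, hamming, numeric(1),
                         b = parent$sequence) == 1))
  expect_false(parent$sequence %in% v4$sequence)

  # multi-position sets
  v2 <- mismatch_panel(parent, list(c(0L, 3L)))
  expect_equal(hamming(v2$sequence, parent$sequence), 2)
  expect_equal(v2$aso_id, "P_m0,3")

  expect_error(mismatch_panel(parent, list(integer())), "empty")
  expect_error(mismatch_panel(parent, list(c(1L, 1L))), "duplicate")
  expect_error(mismatch_panel(parent, list(9L)), "out of range")
})

test_that("every mismatch variant scores below the parent's maximum on its own site", {
  withr::with_seed(23, {
    parent <- list(aso_id = "P", sequence = random_dna(20))
    site <- oracle_revcomp(parent$sequence)
    mx <- max_score(parent$sequence)
    v <- mismatch_panel(parent, as.list(0:19))
    for (i in seq_len(nrow(v))) {
      expect_lt(score_window(v$sequence[i], site)$score, mx)
    }
  })
})

test_that("microwalk_panel tiles 17 ASOs of exact reverse-complement windows", {
  withr::with_seed(29, {
    region <- tiny_record(random_dna(120), id = "hotspot")
    panel <- microwalk_panel(region, center_start = 50, length = 20,
                             step = 2, max_offset = 16)
    expect_equal(nrow(panel), 17L)
    expect_equal(panel$offset, seq(-16L, 16L, 2L))
    expect_true(any(panel$aso_id == "hotspot+0"))
    for (i in seq_len(nrow(panel))) {
      src <- substr(region$sequence, panel$source_start[i] + 1L,
                    panel$source_start[i] + 20L)
      expect_identical(panel$sequence[i], oracle_revcomp(src))
      # scan oracle: each ASO hits its design window at max_score
      h <- scan_record(panel[i, ], region,
                       threshold = max_score(panel$sequence[i]))
      expect_equal(h$start, panel$source_start[i])
    }
    # regeneration is deterministic and duplicate-free
    expect_identical(panel, microwalk_panel(region, 50, 20, 2, 16))
    expect_false(any(duplicated(panel$aso_id)))
  })
})

test_that("microwalk_panel skips out-of-bounds offsets with a warning", {
  region <- tiny_record(strrep("ACGT", 20), id = "edge")   # 80 nt
  w <- testthat::capture_warnings(
    panel <- microwalk_panel(region, center_start = 4, length = 20,
                             step = 2, max_offset = 16))
  expect_length(w, 6L)                   # offsets -16 ... -6
  expect_match(w, "out of bounds", all = TRUE)
  expect_equal(panel$offset, seq(-4L, 16L, 2L))
  expect_error(microwalk_panel(region, 0, 100), "exceeds region length")
})

test_that("length_panel emits one ASO per feasible length at the anchor", {
  withr::with_seed(31, {
    region <- tiny_record(random_dna(200), id = "S30r")
    panel <- length_panel(region, anchor_start = 60, lengths = 18:24)
    expect_equal(nrow(panel), 7L)
    expect_equal(panel$aso_id, sprintf("S30r_L%d", 18:24))
    for (i in seq_len(nrow(panel))) {
      src <- substr(region$sequence, 61, 60 + panel$length[i])
      expect_identical(panel$sequence[i], oracle_revcomp(src))
    }
    # shared 3' terminus when the end is anchored
    pend <- length_panel(region, anchor_start = 100, lengths = c(18, 20),
                         anchor_end_fixed = TRUE)
    expect_equal(pend$source_start + pend$length, c(100L, 100L))

    # a length of 20 at the anchor reproduces the 20-nt parent window ASO
    p20 <- length_panel(region, 60, 20)
    expect_identical(p20$sequence,
                     oracle_revcomp(substr(region$sequence, 61, 80)))

    expect_error(length_panel(region, 60, c(7, 20)), "\\[8, 50\\]")
    w <- testthat::capture_warnings(length_panel(region, 190, c(18, 20)))
    expect_length(w, 2L)
    expect_match(w, "out of bounds", all = TRUE)
  })
})
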