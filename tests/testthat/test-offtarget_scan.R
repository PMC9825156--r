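test_that("scan_record finds planted perfect sites and matches brute force", {
  aso <- list(aso_id = "a", sequence = "ACGT")
  rec <- tiny_record("TTTTACGTTTTT")
  h <- scan_record(aso, rec, threshold = 10)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 4L)
  expect_equal(h$end, 8L)
  expect_equal(h$score, 10)
  expect_equal(h$window_sequence, "ACGT")

  # lowered threshold: identical to exhaustive enumeration of all windows
  h5 <- scan_record(aso, rec, threshold = 5)
  o5 <- oracle_scan("ACGT", rec$sequence, default_matrix(), 5)
  expect_equal(h5$start, o5$start)
  expect_equal(h5$score, o5$score)
})

test_that("scan_record matches the brute-force oracle on random inputs", {
  mat <- default_matrix()
  withr::with_seed(101, {
    for (i in 1:30) {
      L <- sample(4:8, 1)
      aso <- list(aso_id = "a", sequence = random_dna(L))
      seq <- random_dna(sample(50:400, 1))
      thr <- sample(0:max_score(aso$sequence, mat), 1)
      got <- scan_record(aso, tiny_record(seq), mat, thr)
      want <- oracle_scan(aso$sequence, seq, mat, thr)
      expect_equal(got$start, want$start)
      expect_equal(got$score, want$score)
      expect_true(all(got$score >= thr))
      expect_true(all(got$score <= max_score(aso$sequence, mat)))
    }
  })
})

test_that("a record shorter than the ASO yields no hits plus a warning", {
  aso <- list(aso_id = "a", sequence = strrep("ACGT", 5))
  expect_warning(h <- scan_record(aso, tiny_record("ACGTACGTAC")),
                 "shorter than ASO")
  expect_equal(nrow(h), 0L)
})

test_that("scan_transcriptome respects the expression filter and errors on empty input", {
  withr::with_seed(5, {
    recs <- make_transcriptome(10, c(200, 300), seed = 5)
    aso <- aso_record("a1", random_dna(20))
    planted <- plant_sites(recs, aso,
                           data.frame(gene_id = "G0003", position = 50L))
    hits <- scan_transcriptome(aso, planted$records,
                               threshold = max_score(aso$sequence))
    expect_equal(hits$gene_id, "G0003")
    expect_equal(hits$start, 50L)

    # excluding the planted gene removes the hit
    h2 <- scan_transcriptome(aso, planted$records,
                             threshold = max_score(aso$sequence),
                             expressed = setdiff(recs$gene_id, "G0003"))
    expect_equal(nrow(h2), 0L)

    # threshold above max_score warns and yields nothing
    expect_warning(
      h3 <- scan_transcriptome(aso, planted$records,
                               threshold = max_score(aso$sequence) + 1),
      "exceeds max_score")
    expect_equal(nrow(h3), 0L)
  })
  expect_error(scan_transcriptome(data.frame(), data.frame()), "empty")
})

test_that("two identical runs produce byte-identical hit tables", {
  b <- make_figure9_scenario(21)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  for (f in c(f1, f2)) {
    hits <- scan_transcriptome(b$asos, b$records, b$matrix, b$threshold,
                               b$expressed)
    write.table(hits, f, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  expect_identical(readLines(f1), readLines(f2))
})

test_that("collapse_to_genes keeps best score, site count, and tie rules", {
  hits <- rbind(
    data.frame(aso_id = "a", seq_id = "t1", gene_id = "g1", start = 10L,
               end = 14L, score = 41, max_score = 50, n_mismatches = 1L,
               mismatch_positions = "0", n_wobble = 0L,
               window_sequence = "ACGT", matrix = "m"),
    data.frame(aso_id = "a", seq_id = "t1", gene_id = "g1", start = 40L,
               end = 44L, score = 44, max_score = 50, n_mismatches = 0L,
               mismatch_positions = "", n_wobble = 0L,
               window_sequence = "ACGT", matrix = "m")
  )
  s <- collapse_to_genes(hits)
  expect_equal(nrow(s), 1L)
  expect_equal(s$best_score, 44)
  expect_equal(s$n_sites, 2L)
  expect_equal(s$start, 40L)

  # equal scores: smallest start wins
  hits$score <- c(44, 44)
  s2 <- collapse_to_genes(hits)
  expect_equal(s2$start, 10L)

  expect_equal(nrow(collapse_to_genes(empty <- hits[0, ])), 0L)
})

test_that("mutual_targets reports region counts summing to the union", {
  mt <- mutual_targets(list(
    a = c("FXN", "X1", "X2", "X3"),
    b = c("FXN", paste0("Y", 1:15))
  ))
  expect_equal(mt$shared, "FXN")
  full <- mt$regions$count[mt$regions$groups == "a&b"]
  expect_equal(full, 1L)
  expect_equal(sum(mt$regions$count), mt$union_size)
  expect_equal(mt$union_size, 19L)

  # disjoint sets: empty full intersection
  mt2 <- mutual_targets(list(a = "p", b = "q"))
  expect_length(mt2$shared, 0)

  # three random sets: 7 regions, counts sum to |union|, each region
  # matches brute-force membership enumeration
  withr::with_seed(9, {
    sets <- lapply(1:3, function(i) sample(paste0("g", 1:30), sample(5:20, 1)))
    names(sets) <- c("a", "b", "c")
    mt3 <- mutual_targets(sets)
    expect_equal(nrow(mt3$regions), 7L)
    uni <- unique(unlist(sets))
    expect_equal(sum(mt3$regions$count), length(uni))
    for (i in seq_len(nrow(mt3$regions))) {
      ing <- strsplit(mt3$regions$groups[i], "&", fixed = TRUE)[[1]]
      outg <- setdiff(names(sets), ing)
      n <- sum(vapply(uni, function(g) {
        all(vapply(ing, function(s) g %in% sets[[s]], logical(1))) &&
          !any(vapply(outg, function(s) g %in% sets[[s]], logical(1)))
      }, logical(1)))
      expect_equal(mt3$regions$count[i], n)
    }
  })
  expect_error(mutual_targets(list(a = "x")), "at least 2")
})

test_that("score_cdf uses strict below-cutoff counting and is monotone", {
  # one gene at score 40: not-matched fractions 0, 0, 1 over grid 39,40,41
  cdf <- score_cdf(c(g1 = 40), c(g1 = "cat"), c(39, 40, 41))
  expect_equal(cdf$fraction_not_matched, c(0, 0, 1))

  # grid entirely above all scores: every fraction is 1
  cdf2 <- score_cdf(c(g1 = 10, g2 = 20), c(g1 = "c", g2 = "c"), c(30, 40))
  expect_equal(cdf2$fraction_not_matched, c(1, 1))

  withr::with_seed(33, {
    genes <- paste0("g", 1:40)
    best <- setNames(sample(10:60, 40, replace = TRUE), genes)
    cats <- setNames(sample(c("u", "v"), 40, replace = TRUE), genes)
    grid <- sort(sample(5:65, 12))
    got <- score_cdf(best, cats, grid)
    for (i in seq_len(nrow(got))) {
      members <- names(cats)[cats == got$category[i]]
      expect_equal(got$fraction_not_matched[i],
                   mean(best[members] < got$cutoff[i]))
    }
    for (lab in unique(cats)) {
      fr <- got$fraction_not_matched[got$category == lab]
      expect_true(all(diff(fr) >= 0))
      expect_true(all(fr >= 0 & fr <= 1))
    }
  })
  expect_error(score_cdf(c(g1 = 1), setNames(character(), character()),
                         1:3), "non-empty")
})

test_that("top_hits ranks by descending score with gene_id tie-break", {
  s <- data.frame(aso_id = "a", gene_id = c("gB", "gA", "gC"),
                  best_score = c(44, 44, 50))
  got <- top_hits(s, 2)
  expect_equal(got$gene_id, c("gC", "gA"))
  expect_equal(nrow(top_hits(s, 10)), 3L)   # n beyond list: whole list
  expect_error(top_hits(s, 0), ">= 1")
})

test_that("find_tandem_repeats calls maximal GAA arrays exactly", {
  r <- tiny_record(paste0("TT", strrep("GAA", 6), "TT"))
  got <- find_tandem_repeats(r, "GAA", 6)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 2L)
  expect_equal(got$n_units, 6L)

  # below threshold: nothing
  expect_equal(nrow(find_tandem_repeats(tiny_record(strrep("GAA", 5)),
                                        "GAA", 6)), 0L)

  # 7 copies: one maximal interval, not two overlapping calls
  got7 <- find_tandem_repeats(tiny_record(strrep("GAA", 7)), "GAA", 6)
  expect_equal(nrow(got7), 1L)
  expect_equal(got7$n_units, 7L)
  expect_equal(got7$end - got7$start, 21L)

  # random sequences against the brute-force enumerator
  withr::with_seed(77, {
    for (i in 1:20) {
      seq <- paste(sample(c("G", "A", "T"), 200, replace = TRUE,
                          prob = c(0.45, 0.45, 0.1)), collapse = "")
      mu <- sample(2:4, 1)
      got <- find_tandem_repeats(tiny_record(seq), "GAA", mu)
      want <- oracle_tandem(seq, "GAA", mu)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_units, want$n_units)
    }
  })
  expect_error(find_tandem_repeats(tiny_record("ACGT"), "GXA", 2),
               "non-ACGT")
  expect_error(find_tandem_repeats(tiny_record("ACGT"), "GA", 1), ">= 2")
})

test_that("deg_flag separates flagged, not-flagged and not-tested genes", {
  s <- data.frame(aso_id = "a", gene_id = paste0("g", 1:4),
                  best_score = 41:44)
  deg <- data.frame(gene_id = c("g1", "g2", "g3"),
                    log2FC = c(2, -1, 0.1),
                    pvalue = c(1e-5, 0.002, 0.7),
                    padj = c(1e-4, 0.01, 0.9))
  out <- deg_flag(s, deg, alpha = 0.05)
  expect_equal(out$deg_status, c("flagged", "flagged", "not_flagged",
                                 "not_tested"))
  expect_equal(attr(out, "n_flagged"), 2L)

  # boundary: alpha close to 1 flags every tested gene
  out2 <- deg_flag(s, deg, alpha = 1 - 1e-9)
  expect_equal(sum(out2$deg_status == "flagged"), 3L)
  expect_equal(out2$deg_status[4], "not_tested")  # absent stays untested
  expect_error(deg_flag(s, deg, alpha = 0), "\\(0, 1\\)")
})

test_that("deg_shared_counts honors alpha, top_n and identical tables", {
  withr::with_seed(55, {
    genes <- paste0("g", 1:1000)
    sim <- make_deg_table(genes, c("x", "y", "z"), 100, shared_core = 40,
                          seed = 8)
    got <- deg_shared_counts(sim$tables, alpha = 0.05)
    expect_equal(got$regions$count[got$regions$groups == "x&y&z"], 40L)
    expect_equal(sum(got$regions$count), got$union_size)

    # top_n selection: exactly top_n genes per group
    got200 <- deg_shared_counts(sim$tables, top_n = 200)
    expect_true(all(lengths(got200$sets) == 200L))

    # identical tables: everything in the full intersection
    same <- list(a = sim$tables$x, b = sim$tables$x)
    gs <- deg_shared_counts(same, alpha = 0.05)
    expect_equal(gs$regions$count[gs$regions$groups == "a&b"], 100L)
    expect_equal(sum(gs$regions$count[gs$regions$degree == 1]), 0L)
  })
})
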