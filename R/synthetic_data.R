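#' Generate a synthetic transcriptome
#'
#' Draws `n_genes` sequences of i.i.d. bases with the requested GC
#' content — P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2 — and lengths
#' uniform over `length_range`. Background sequence is deliberately
#' structure-free (no repeats, no splice structure) so that chance
#' pairing-score hits are quantifiable and planted-site tests can be made
#' deterministic. Gene ids are `G0001...` with sequence ids `T0001...`.
#'
#' @param n_genes number of genes (>= 1).
#' @param length_range integer length interval in nt, e.g. `c(500, 1500)`.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed; generation is a pure function of
#'   (parameters, seed) under the package RNG contract.
#' @return sequence-record data.frame as from [read_fasta()].
#' @export
make_transcriptome <- function(n_genes, length_range = c(500L, 1500L),
                               gc = 0.5, seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (!(gc > 0 && gc < 1)) stop("gc must be in (0, 1)", call. = FALSE)
  if (length(length_range) != 2L || length_range[[1L]] > length_range[[2L]] ||
      length_range[[1L]] < 1L) {
    stop("degenerate length_range", call. = FALSE)
  }
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    lens <- sample.int(length_range[[2L]] - length_range[[1L]] + 1L,
                       n_genes, replace = TRUE) + length_range[[1L]] - 1L
    seqs <- vapply(lens, function(len) {
      paste(sample(DNA_BASES, len, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1L))
    data.frame(
      seq_id = sprintf("T%04d", seq_len(n_genes)),
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      sequence = seqs,
      description = sprintf("gene=G%04d", seq_len(n_genes)),
      stringsAsFactors = FALSE
    )
  })
}

#' Plant ASO-complementary sites into sequences
#'
#' At each placement the target window is overwritten with the reverse
#' complement of the ASO (a perfect site), then each listed ASO-coordinate
#' position is corrupted to the complement of the planted base — a
#' guaranteed mismatch whatever the scoring matrix. The construction score
#' of every site is recomputed from the final sequence text with
#' [score_window()], so the returned truth manifest is redundant with the
#' emitted sequences, never authoritative over them. Bases outside the
#' declared intervals are never touched.
#'
#' @param records sequence-record data.frame.
#' @param aso one-row data.frame or list with `aso_id` and `sequence`.
#' @param placements data.frame with columns `gene_id`, `position`
#'   (0-based window start) and optionally `mismatch_positions`
#'   (comma-joined 0-based ASO coordinates, `""` for a perfect site).
#' @param matrix scoring matrix used to record construction scores.
#' @return list with `records` (modified) and `manifest` (data.frame:
#'   `aso_id`, `gene_id`, `seq_id`, `start`, `n_mismatches`,
#'   `mismatch_positions`, `construction_score`).
#' @export
plant_sites <- function(records, aso, placements,
                        matrix = default_matrix()) {
  aso <- as.list(aso)
  assert_dna(aso$sequence, "ASO sequence")
  L <- nchar(aso$sequence)
  if (is.null(placements$mismatch_positions)) {
    placements$mismatch_positions <- ""
  }
  # overlap check per sequence
  for (g in unique(placements$gene_id)) {
    pos <- sort(placements$position[placements$gene_id == g])
    if (length(pos) > 1L && any(diff(pos) < L)) {
      stop("overlapping placements in gene ", g, call. = FALSE)
    }
  }
  manifest <- list()
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    k <- match(p$gene_id, records$gene_id)
    if (is.na(k)) stop("unknown gene_id in placement: ", p$gene_id,
                       call. = FALSE)
    n <- nchar(records$sequence[[k]])
    if (p$position < 0L || p$position + L > n) {
      stop("placement out of bounds: gene ", p$gene_id, " position ",
           p$position, call. = FALSE)
    }
    chars <- seq_chars(records$sequence[[k]])
    site <- seq_chars(revcomp(aso$sequence))
    chars[(p$position + 1L):(p$position + L)] <- site
    mm <- p$mismatch_positions
    mm <- if (is.na(mm) || !nzchar(mm)) integer() else
      as.integer(strsplit(mm, ",", fixed = TRUE)[[1L]])
    if (any(mm < 0L | mm >= L)) {
      stop("mismatch position out of ASO range in placement for gene ",
           p$gene_id, call. = FALSE)
    }
    for (m in mm) {
      j <- p$position + L - m             # 1-based seq position opposing ASO position m
      chars[[j]] <- COMPLEMENT[[chars[[j]]]]
    }
    records$sequence[[k]] <- paste(chars, collapse = "")
    win <- substr(records$sequence[[k]], p$position + 1L, p$position + L)
    ws <- score_window(aso$sequence, win, matrix)
    manifest[[i]] <- data.frame(
      aso_id = aso$aso_id, gene_id = p$gene_id,
      seq_id = records$seq_id[[k]], start = as.integer(p$position),
      n_mismatches = length(mm),
      mismatch_positions = paste(sort(mm), collapse = ","),
      construction_score = ws$score, stringsAsFactors = FALSE
    )
  }
  list(records = records,
       manifest = do.call(rbind, c(list(NULL), manifest)))
}

#' Inject an exact tandem-repeat array into one sequence
#'
#' Overwrites the window starting at `position` with `n_units` exact
#' copies of `unit` (e.g. a GAA array), for exercising the repeat finder
#' on otherwise repeat-free background.
#'
#' @param records sequence-record data.frame.
#' @param gene_id gene to modify.
#' @param position 0-based start of the array.
#' @param unit repeat unit (default "GAA").
#' @param n_units number of copies.
#' @return modified records data.frame.
#' @export
plant_tandem_repeat <- function(records, gene_id, position, unit = "GAA",
                                n_units = 6L) {
  assert_dna(unit, "repeat unit")
  k <- match(gene_id, records$gene_id)
  if (is.na(k)) stop("unknown gene_id: ", gene_id, call. = FALSE)
  arr <- strrep(unit, n_units)
  n <- nchar(records$sequence[[k]])
  if (position < 0L || position + nchar(arr) > n) {
    stop("repeat array out of bounds", call. = FALSE)
  }
  s <- records$sequence[[k]]
  records$sequence[[k]] <- paste0(
    substr(s, 1L, position), arr,
    substr(s, position + nchar(arr) + 1L, n)
  )
  records
}

#' Simulate per-group differential-expression tables
#'
#' Builds one DEG table per treatment group over a common gene universe
#' with a controlled sharing structure: every group's DEG set is a common
#' core of `shared_core` genes plus `n_deg_per_group - shared_core`
#' group-exclusive genes, so the full-intersection upset region equals
#' `shared_core` exactly. Significance is generated directly rather than
#' through a count model — the pipeline consumes DEG tables, it never fits
#' them: DEGs get padj ~ U(0, 0.01) and |log2FC| ~ N(2, 0.5) with random
#' sign; non-DEGs get padj ~ U(0.2, 1) and log2FC ~ N(0, 0.2). Raw
#' p-values are drawn below their adjusted values.
#'
#' @param genes character vector of gene ids.
#' @param groups character vector of >= 2 group labels.
#' @param n_deg_per_group DEGs per group.
#' @param shared_core size of the cross-group common core.
#' @param seed integer seed.
#' @return list with `tables` (named list of DEG data.frames) and `truth`
#'   (list: `core`, per-group DEG sets).
#' @export
make_deg_table <- function(genes, groups, n_deg_per_group,
                           shared_core = 0L, seed = 1L) {
  k <- length(groups)
  if (k < 1L) stop("need at least one group", call. = FALSE)
  if (shared_core > n_deg_per_group || n_deg_per_group > length(genes)) {
    stop("need shared_core <= n_deg_per_group <= number of genes",
         call. = FALSE)
  }
  n_specific <- n_deg_per_group - shared_core
  if (shared_core + k * n_specific > length(genes)) {
    stop("gene universe too small for disjoint group-specific DEG sets",
         call. = FALSE)
  }
  with_seed(seed, {
    core <- if (shared_core > 0L) sample(genes, shared_core) else character()
    pool <- setdiff(genes, core)
    deg_sets <- list()
    for (g in groups) {
      spec <- if (n_specific > 0L) sample(pool, n_specific) else character()
      pool <- setdiff(pool, spec)
      deg_sets[[g]] <- c(core, spec)
    }
    tables <- lapply(groups, function(g) {
      is_deg <- genes %in% deg_sets[[g]]
      padj <- ifelse(is_deg, runif(length(genes), 0, 0.01),
                     runif(length(genes), 0.2, 1))
      pvalue <- padj * runif(length(genes), 0.05, 1)
      l2fc <- ifelse(
        is_deg,
        sample(c(-1, 1), length(genes), replace = TRUE) *
          rnorm(length(genes), 2, 0.5),
        rnorm(length(genes), 0, 0.2)
      )
      data.frame(gene_id = genes, log2FC = l2fc, pvalue = pvalue,
                 padj = padj, stringsAsFactors = FALSE)
    })
    names(tables) <- groups
    list(tables = tables,
         truth = list(core = sort(core),
                      deg_sets = lapply(deg_sets, sort)))
  })
}

#' Two-ASO off-target scenario with one shared target
#'
#' Builds the canonical end-to-end test scenario: a synthetic
#' transcriptome in which two 20-nt ASOs share exactly one perfect-site
#' target gene (the intended target, planted for both ASOs), while one ASO
#' additionally has 3 and the other 15 singly mismatched candidate genes
#' whose construction scores still clear the call threshold of 40. A
#' single-group DEG table marks exactly 3 of the 18 non-target candidates
#' (plus the target itself) as differentially expressed. Everything
#' planted is recorded in the truth manifest, and every manifest number is
#' recomputable from the emitted sequences.
#'
#' Both ASOs are drawn with exactly 10 G/C among 20 bases, so their
#' maximum score under the default matrix is 50 and a single planted
#' mismatch leaves a site at 44--46, comfortably above threshold 40.
#'
#' @param seed integer seed.
#' @param n_genes transcriptome size (default 60).
#' @return bundle list: `asos`, `records`, `matrix`, `threshold` (40),
#'   `expressed`, `deg` (named list with one `treated` table), `truth`.
#' @export
make_figure9_scenario <- function(seed = 1L, n_genes = 60L) {
  threshold <- 40
  mat <- default_matrix()
  n_cand <- c(ASO_A = 3L, ASO_B = 15L)
  if (n_genes < 1L + sum(n_cand) + 5L) {
    stop("n_genes too small for the scenario", call. = FALSE)
  }
  with_seed(seed, {
    records <- make_transcriptome(n_genes, c(600L, 1200L), gc = 0.5,
                                  seed = sample.int(2^31 - 1L, 1L))
    make_aso <- function(id) {
      bases <- c(sample(c("G", "C"), 10L, replace = TRUE),
                 sample(c("A", "T"), 10L, replace = TRUE))
      aso_record(id, paste(sample(bases), collapse = ""))
    }
    asos <- rbind(make_aso("ASO_A"), make_aso("ASO_B"))
    target_gene <- records$gene_id[[1L]]

    # perfect sites for both ASOs on the shared target gene
    pl_a <- data.frame(gene_id = target_gene, position = 50L,
                       mismatch_positions = "", stringsAsFactors = FALSE)
    pl_b <- data.frame(gene_id = target_gene, position = 120L,
                       mismatch_positions = "", stringsAsFactors = FALSE)

    # disjoint singly mismatched candidate genes per ASO
    cand_a <- records$gene_id[2:(1L + n_cand[["ASO_A"]])]
    cand_b <- records$gene_id[(2L + n_cand[["ASO_A"]]):(1L + sum(n_cand))]
    mk_pl <- function(genes) data.frame(
      gene_id = genes,
      position = sample(100:400, length(genes)),
      mismatch_positions = as.character(sample(0:19, length(genes),
                                               replace = TRUE)),
      stringsAsFactors = FALSE
    )
    pl_a <- rbind(pl_a, mk_pl(cand_a))
    pl_b <- rbind(pl_b, mk_pl(cand_b))

    res_a <- plant_sites(records, asos[1L, ], pl_a, mat)
    res_b <- plant_sites(res_a$records, asos[2L, ], pl_b, mat)
    records <- res_b$records
    manifest <- rbind(res_a$manifest, res_b$manifest)
    stopifnot(all(manifest$construction_score >= threshold))

    # DEG table: the target responds, and exactly 3 of the 18 non-target
    # candidates are differentially expressed
    deg_cands <- sample(c(cand_a, cand_b), 3L)
    extra <- sample(setdiff(records$gene_id,
                            c(target_gene, cand_a, cand_b)), 5L)
    deg_genes <- c(target_gene, deg_cands, extra)
    is_deg <- records$gene_id %in% deg_genes
    padj <- ifelse(is_deg, runif(n_genes, 0, 0.01), runif(n_genes, 0.2, 1))
    deg <- data.frame(
      gene_id = records$gene_id,
      log2FC = ifelse(is_deg,
                      sample(c(-1, 1), n_genes, replace = TRUE) *
                        rnorm(n_genes, 2, 0.5),
                      rnorm(n_genes, 0, 0.2)),
      pvalue = padj * runif(n_genes, 0.05, 1),
      padj = padj, stringsAsFactors = FALSE
    )

    truth <- list(
      seed = seed,
      rng = rng_contract(),
      parameters = list(n_genes = n_genes, aso_length = 20L, gc = 0.5,
                        threshold = threshold,
                        n_candidates = as.list(n_cand)),
      shared_target_gene = target_gene,
      candidate_genes = list(ASO_A = cand_a, ASO_B = cand_b),
      planted_sites = manifest,
      planted_degs = list(treated = sort(deg_genes)),
      deg_flagged_candidates = sort(deg_cands)
    )
    list(asos = asos, records = records, matrix = mat,
         threshold = threshold, expressed = records$gene_id,
         deg = list(treated = deg), truth = truth)
  })
}

#' Write a scenario bundle to disk
#'
#' Emits the exact formats the pipeline reads: FASTA, ASO manifest TSV,
#' scoring-matrix TSV, expressed-gene list, per-group DEG CSVs, and the
#' truth manifest as JSON.
#'
#' @param bundle as returned by [make_figure9_scenario()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "transcriptome.fa"),
    asos = file.path(dir, "asos.tsv"),
    matrix = file.path(dir, "matrix.tsv"),
    expressed = file.path(dir, "expressed_genes.txt"),
    truth = file.path(dir, "truth_manifest.json")
  )
  write_fasta(bundle$records, paths[["fasta"]])
  write_aso_manifest(bundle$asos, paths[["asos"]])
  write_matrix(bundle$matrix, paths[["matrix"]])
  writeLines(bundle$expressed, paths[["expressed"]])
  for (g in names(bundle$deg)) {
    p <- file.path(dir, paste0("deg_", g, ".csv"))
    utils::write.csv(bundle$deg[[g]], p, row.names = FALSE, quote = FALSE)
    paths[[paste0("deg_", g)]] <- p
  }
  jsonlite::write_json(bundle$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
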