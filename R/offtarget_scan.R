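#' Scan one sequence for candidate ASO binding sites
#'
#' Slides an ASO-length window along the sense strand at stride 1, scores
#' every window with [score_window()] against the ASO, and returns exactly
#' the windows with pairing score greater than or equal to `threshold`
#' (inclusive call, as in "score >= 40"). Windows may overlap; all are
#' reported, sorted by start. Gaps are never considered: candidate sites
#' are ungapped duplexes with mismatches only.
#'
#' @param aso one-row data.frame or named list with `aso_id` and
#'   `sequence` (see [aso_record()]).
#' @param record one-row data.frame or named list with `seq_id`,
#'   `sequence` and optionally `gene_id` (defaults to `seq_id`).
#' @param matrix a `scoring_matrix`.
#' @param threshold minimum pairing score to call a candidate site
#'   (default 40, the conventional call threshold; always revisit it when
#'   changing the matrix scale).
#' @return data.frame of hits with columns `aso_id`, `seq_id`, `gene_id`,
#'   `start`, `end` (0-based half-open on the sense sequence), `score`,
#'   `max_score`, `n_mismatches`, `mismatch_positions` (comma-joined
#'   0-based ASO coordinates), `n_wobble`, `window_sequence`, `matrix`.
#'   A record shorter than the ASO yields zero rows with a warning.
#' @export
scan_record <- function(aso, record, matrix = default_matrix(),
                        threshold = 40) {
  aso <- as.list(aso); record <- as.list(record)
  gene_id <- if (!is.null(record$gene_id)) record$gene_id else record$seq_id
  aso_seq <- aso$sequence
  seq_str <- record$sequence
  assert_dna(aso_seq, "ASO sequence")
  assert_dna(seq_str, paste0("sequence '", record$seq_id, "'"))
  L <- nchar(aso_seq)
  n <- nchar(seq_str)
  if (n < L) {
    warning("record '", record$seq_id, "' (", n,
            " nt) is shorter than ASO '", aso$aso_id, "' (", L,
            " nt); no windows scanned", call. = FALSE)
    return(empty_hits())
  }
  sidx <- seq_index(seq_str)
  ridx <- rev(seq_index(aso_seq))     # ASO read 3'->5' along the sense strand
  nwin <- n - L + 1L
  scores <- numeric(nwin)
  for (j in seq_len(L)) {
    row <- matrix[ridx[[j]], ]
    scores <- scores + row[sidx[seq.int(j, j + nwin - 1L)]]
  }
  starts <- which(scores >= threshold)
  if (length(starts) == 0L) return(empty_hits())
  mx <- max_score(aso_seq, matrix)
  rows <- lapply(starts, function(s) {
    win <- substr(seq_str, s, s + L - 1L)
    ws <- score_window(aso_seq, win, matrix)
    data.frame(
      aso_id = aso$aso_id, seq_id = record$seq_id, gene_id = gene_id,
      start = s - 1L, end = s - 1L + L,
      score = ws$score, max_score = mx,
      n_mismatches = length(ws$mismatch_positions),
      mismatch_positions = paste(ws$mismatch_positions, collapse = ","),
      n_wobble = ws$n_wobble, window_sequence = win,
      matrix = matrix_name(matrix), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(
    aso_id = character(), seq_id = character(), gene_id = character(),
    start = integer(), end = integer(), score = numeric(),
    max_score = numeric(), n_mismatches = integer(),
    mismatch_positions = character(), n_wobble = integer(),
    window_sequence = character(), matrix = character(),
    stringsAsFactors = FALSE
  )
}

#' Scan a transcriptome with a panel of ASOs
#'
#' Runs [scan_record()] over every (ASO, sequence) pair, optionally
#' restricted to sequences whose gene is in an expressed-gene set, and
#' returns the union of hits in deterministic (aso_id, seq_id, start)
#' order. Expressed genes absent from the FASTA are not an error; they are
#' counted and reported via the `n_expressed_missing` attribute.
#'
#' @param asos data.frame of ASO records ([read_aso_manifest()]).
#' @param records data.frame of sequence records ([read_fasta()]).
#' @param matrices named list of `scoring_matrix` objects keyed by
#'   `matrix_id`; must contain a `default` entry used for ASOs without a
#'   `matrix_id`. A single `scoring_matrix` is accepted and used for all.
#' @param threshold candidate-call score threshold (inclusive).
#' @param expressed optional character vector of expressed gene ids; when
#'   given, only records whose `gene_id` is in the set are scanned.
#' @return hit data.frame as in [scan_record()].
#' @export
scan_transcriptome <- function(asos, records, matrices = default_matrix(),
                               threshold = 40, expressed = NULL) {
  if (!is.data.frame(asos) || nrow(asos) == 0L) {
    stop("ASO list is empty", call. = FALSE)
  }
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("sequence set is empty", call. = FALSE)
  }
  if (inherits(matrices, "scoring_matrix")) {
    matrices <- list(default = matrices)
  }
  if (!"default" %in% names(matrices)) {
    stop("matrices must include a 'default' entry", call. = FALSE)
  }
  n_missing <- 0L
  if (!is.null(expressed)) {
    n_missing <- length(setdiff(expressed, records$gene_id))
    records <- records[records$gene_id %in% expressed, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(asos))) {
    aso <- asos[i, ]
    mid <- aso$matrix_id
    m <- if (is.null(mid) || is.na(mid) || !nzchar(mid)) {
      matrices$default
    } else if (mid %in% names(matrices)) {
      matrices[[mid]]
    } else {
      stop("no scoring matrix registered for matrix_id '", mid, "'",
           call. = FALSE)
    }
    if (threshold > max_score(aso$sequence, m)) {
      warning("threshold ", threshold, " exceeds max_score of ASO '",
              aso$aso_id, "' (", max_score(aso$sequence, m),
              "); it can yield no hits", call. = FALSE)
    }
    for (k in seq_len(nrow(records))) {
      out[[length(out) + 1L]] <-
        scan_record(aso, records[k, ], m, threshold)
    }
  }
  hits <- do.call(rbind, c(list(empty_hits()), out))
  hits <- hits[order(hits$aso_id, hits$seq_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "threshold") <- threshold
  attr(hits, "n_expressed_missing") <- n_missing
  hits
}

#' Collapse candidate sites to gene-level summaries
#'
#' One summary per (aso_id, gene_id): the best (maximum) pairing score over
#' the gene's sites, the site count, and the coordinates of the best hit.
#' Best-score ties are broken by smallest start, then lexicographic seq_id.
#'
#' @param hits hit data.frame from [scan_transcriptome()].
#' @return data.frame with columns `aso_id`, `gene_id`, `best_score`,
#'   `n_sites`, `seq_id`, `start`, `end`, `window_sequence`,
#'   `mismatch_positions`, `n_mismatches`, `max_score`, `matrix` (the
#'   best hit's fields).
#' @export
collapse_to_genes <- function(hits) {
  if (nrow(hits) == 0L) {
    out <- hits[, c("aso_id", "gene_id", "score", "n_mismatches", "seq_id",
                    "start", "end", "window_sequence", "mismatch_positions",
                    "max_score", "matrix")]
    names(out)[names(out) == "score"] <- "best_score"
    out$n_sites <- integer()
    return(out[, gene_summary_cols()])
  }
  key <- paste(hits$aso_id, hits$gene_id, sep = "\r")
  parts <- split(seq_len(nrow(hits)), key)
  rows <- lapply(parts, function(idx) {
    h <- hits[idx, , drop = FALSE]
    h <- h[order(-h$score, h$start, h$seq_id), , drop = FALSE]
    best <- h[1L, ]
    data.frame(
      aso_id = best$aso_id, gene_id = best$gene_id,
      best_score = best$score, n_sites = nrow(h),
      seq_id = best$seq_id, start = best$start, end = best$end,
      window_sequence = best$window_sequence,
      mismatch_positions = best$mismatch_positions,
      n_mismatches = best$n_mismatches,
      max_score = best$max_score, matrix = best$matrix,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aso_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, gene_summary_cols()]
}

gene_summary_cols <- function() {
  c("aso_id", "gene_id", "best_score", "n_sites", "seq_id", "start", "end",
    "window_sequence", "mismatch_positions", "n_mismatches", "max_score",
    "matrix")
}

# Exclusive region counts over k named sets (Venn / upset algebra).
# Returns a data.frame covering all 2^k - 1 nonempty group combinations.
region_counts <- function(sets) {
  k <- length(sets)
  nms <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- as.logical(unlist(combos[i, ]))
    if (length(universe) == 0L) {
      n <- 0L; genes <- character()
    } else {
      sel <- rowSums(member[, inc, drop = FALSE]) == sum(inc) &
        rowSums(member[, !inc, drop = FALSE]) == 0L
      genes <- universe[sel]
      n <- length(genes)
    }
    data.frame(groups = paste(nms[inc], collapse = "&"),
               degree = sum(inc), count = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$degree, out$groups), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "union_size") <- length(universe)
  out
}

#' Mutual-target report across ASOs
#'
#' Given per-ASO candidate gene sets, computes every exclusive Venn region
#' count (all 2^k - 1 combinations) and the explicit list of genes shared
#' by every ASO — the mutual hybridization-dependent targets.
#'
#' @param per_aso_gene_sets named list (aso_id -> character vector of
#'   gene ids); at least 2 sets.
#' @return list with `regions` (data.frame: `groups`, `degree`, `count`),
#'   `shared` (sorted character vector of genes in the full intersection),
#'   and `union_size`.
#' @export
mutual_targets <- function(per_aso_gene_sets) {
  if (!is.list(per_aso_gene_sets) || length(per_aso_gene_sets) < 2L ||
      is.null(names(per_aso_gene_sets)) ||
      any(!nzchar(names(per_aso_gene_sets)))) {
    stop("need a named list of at least 2 gene sets", call. = FALSE)
  }
  regions <- region_counts(per_aso_gene_sets)
  shared <- sort(Reduce(intersect, per_aso_gene_sets))
  list(regions = regions, shared = shared,
       union_size = attr(regions, "union_size"))
}

#' Cumulative fraction of genes below a pairing-score cutoff
#'
#' For each category and each cutoff c in the grid, reports the fraction of
#' the category's genes whose best score is strictly below c — i.e. the
#' fraction of genes that are *not* called matches at that cutoff
#' (candidate calls being score >= cutoff). Genes listed in `categories`
#' with no score in `best_scores_by_gene` never reach any cutoff and count
#' as unmatched everywhere.
#'
#' @param best_scores_by_gene named numeric vector, gene_id -> best score.
#' @param categories named character vector, gene_id -> category label.
#' @param grid numeric vector of cutoffs, sorted ascending.
#' @return data.frame with columns `category`, `cutoff`,
#'   `fraction_not_matched`; monotone nondecreasing in `cutoff` within
#'   each category, bounded in [0, 1].
#' @export
score_cdf <- function(best_scores_by_gene, categories, grid) {
  if (length(categories) == 0L || is.null(names(categories))) {
    stop("categories must be a non-empty named vector", call. = FALSE)
  }
  if (is.unsorted(grid)) stop("grid must be sorted ascending", call. = FALSE)
  labs <- unique(unname(categories))
  rows <- lapply(labs, function(lab) {
    genes <- names(categories)[categories == lab]
    if (length(genes) == 0L) {
      stop("empty category: ", lab, call. = FALSE)
    }
    sc <- best_scores_by_gene[genes]
    sc[is.na(sc)] <- -Inf               # no site at all
    frac <- vapply(grid, function(c) mean(sc < c), numeric(1L))
    data.frame(category = lab, cutoff = grid, fraction_not_matched = frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top candidate genes ranked by pairing score
#'
#' @param summaries gene summaries from [collapse_to_genes()].
#' @param n number of genes to keep (default 6); ties in `best_score` are
#'   broken by gene_id.
#' @return the first `min(n, nrow)` summaries in descending best_score.
#' @export
top_hits <- function(summaries, n = 6L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  out <- summaries[order(-summaries$best_score, summaries$gene_id), ,
                   drop = FALSE]
  out <- utils::head(out, n)
  rownames(out) <- NULL
  out
}

#' Find exact tandem repeats of a unit
#'
#' Left-anchored greedy scan for maximal runs of at least `min_units`
#' consecutive exact copies of `unit` on the sense strand (e.g. GAA arrays,
#' the repeat expanded in Friedreich's ataxia). Runs are maximal: a 7-copy
#' array is one interval, never several overlapping calls.
#'
#' @param record one-row data.frame or list with `seq_id` and `sequence`.
#' @param unit repeat unit, DNA alphabet.
#' @param min_units minimum copy number to report (>= 2).
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `unit`, `n_units`.
#' @export
find_tandem_repeats <- function(record, unit, min_units = 6L) {
  record <- as.list(record)
  assert_dna(unit, "repeat unit")
  if (min_units < 2L) stop("min_units must be >= 2", call. = FALSE)
  assert_dna(record$sequence, paste0("sequence '", record$seq_id, "'"))
  pat <- paste0("(?:", unit, "){", min_units, ",}")
  m <- gregexpr(pat, record$sequence, perl = TRUE)[[1L]]
  if (m[[1L]] < 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), unit = character(),
                      n_units = integer(), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  n_units <- as.integer(len %/% nchar(unit))
  data.frame(
    seq_id = record$seq_id,
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + n_units * nchar(unit),
    unit = unit, n_units = n_units, stringsAsFactors = FALSE
  )
}

#' Flag candidate off-target genes that are differentially expressed
#'
#' Annotates gene-level candidates with their differential-expression
#' status: `flagged` when the gene is in the DEG table with adjusted
#' p-value below `alpha`, `not_flagged` when tested but not significant,
#' and `not_tested` when absent from the table (never flagged). This is
#' the step that asks whether candidate hybridization-dependent off-target
#' transcripts actually changed expression.
#'
#' @param summaries gene summaries from [collapse_to_genes()].
#' @param deg DEG data.frame (`gene_id`, `log2FC`, `pvalue`, `padj`).
#' @param alpha adjusted-p significance threshold in (0, 1); default 0.05.
#' @return `summaries` with added `log2FC`, `padj` and `deg_status`
#'   columns; the number of flagged candidates is
#'   `sum(out$deg_status == "flagged")` and is also stored in the
#'   `n_flagged` attribute.
#' @export
deg_flag <- function(summaries, deg, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  idx <- match(summaries$gene_id, deg$gene_id)
  out <- summaries
  out$log2FC <- deg$log2FC[idx]
  out$padj <- deg$padj[idx]
  out$deg_status <- ifelse(
    is.na(idx), "not_tested",
    ifelse(!is.na(out$padj) & out$padj < alpha, "flagged", "not_flagged")
  )
  attr(out, "n_flagged") <- sum(out$deg_status == "flagged")
  out
}

#' Shared-DEG region counts across treatment groups
#'
#' Builds each group's DEG set — genes with `padj < alpha`, or when
#' `top_n` is given the `top_n` genes with the smallest raw p-values (the
#' "top DEGs" convention) — and reports exclusive upset-style region
#' counts for every nonempty combination of groups.
#'
#' @param deg_tables named list (group label -> DEG data.frame).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param top_n optional integer; overrides the alpha rule with a
#'   smallest-p selection of exactly `top_n` genes per group.
#' @return list with `regions` (data.frame `groups`, `degree`, `count`),
#'   `sets` (the per-group DEG sets) and `union_size`.
#' @export
deg_shared_counts <- function(deg_tables, alpha = 0.05, top_n = NULL) {
  if (!is.list(deg_tables) || length(deg_tables) < 2L ||
      is.null(names(deg_tables))) {
    stop("need a named list of at least 2 DEG tables", call. = FALSE)
  }
  sets <- lapply(deg_tables, function(tab) {
    if (!is.null(top_n)) {
      tab <- tab[order(tab$pvalue, tab$gene_id), , drop = FALSE]
      utils::head(tab$gene_id, top_n)
    } else {
      tab$gene_id[!is.na(tab$padj) & tab$padj < alpha]
    }
  })
  regions <- region_counts(sets)
  list(regions = regions, sets = sets,
       union_size = attr(regions, "union_size"))
}
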