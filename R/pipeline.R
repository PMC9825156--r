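#' Render a candidate site as a fixed-width alignment block
#'
#' Shows the duplex in ASO orientation: the ASO 5'->3' on the first line
#' and the reverse complement of the sense-strand window beneath it, so
#' matched columns carry identical letters. Mismatched columns (which
#' include wobbles, following the "mismatched relative to the ASO"
#' display convention) are lowercased in the target line and marked with a
#' `^` rail. Plain text only — no color codes — so rendered reports are
#' byte-stable.
#'
#' @param hit one hit row from [scan_record()].
#' @param aso one-row data.frame or list with `aso_id` and `sequence`.
#' @return character vector of three lines.
#' @export
render_alignment <- function(hit, aso) {
  hit <- as.list(hit); aso <- as.list(aso)
  L <- nchar(aso$sequence)
  if (nchar(hit$window_sequence) != L) {
    stop("hit window length (", nchar(hit$window_sequence),
         ") does not match ASO length (", L, ")", call. = FALSE)
  }
  mm <- hit$mismatch_positions
  mm <- if (is.null(mm) || is.na(mm) || !nzchar(mm)) integer() else
    as.integer(strsplit(as.character(mm), ",", fixed = TRUE)[[1L]])
  if (any(mm < 0L | mm >= L)) {
    stop("mismatch positions outside the ASO", call. = FALSE)
  }
  tgt <- seq_chars(revcomp(hit$window_sequence))
  rail <- rep(" ", L)
  for (p in mm) {
    tgt[[p + 1L]] <- tolower(tgt[[p + 1L]])
    rail[[p + 1L]] <- "^"
  }
  pre1 <- sprintf("%-12s 5'-", aso$aso_id)
  pre2 <- sprintf("%-12s 3'-", hit$seq_id)
  c(
    paste0(pre1, aso$sequence, "-3'"),
    paste0(pre2, paste(tgt, collapse = ""), "-5'"),
    paste0(strrep(" ", nchar(pre1)), paste(rail, collapse = ""))
  )
}

# ---- orchestration helpers -------------------------------------------------

provenance_header <- function(config, matrix_names, threshold) {
  # the output location must not change the config hash, or re-runs into
  # different directories would not be byte-identical
  config <- config[setdiff(names(config), "out")]
  cfg_file <- tempfile()
  jsonlite::write_json(config[order(names(config))], cfg_file,
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  sprintf("# asoscan %s | matrix=%s | threshold=%s | config_md5=%s",
          as.character(utils::packageVersion("asoscan")),
          paste(matrix_names, collapse = ","), format(threshold), hash)
}

write_tsv_with_header <- function(df, path, header) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines(header, con)
  close(con)
  suppressWarnings(
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE)
  )
  file.rename(tmp, path)
  invisible(path)
}

# Read a TSV written by write_tsv_with_header, returning the data frame
# with the parsed header line as the "provenance" attribute.
read_tsv_report <- function(path) {
  hdr <- readLines(path, n = 1L)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "provenance") <- sub("^#\\s*", "", hdr)
  df
}

default_run_config <- function() {
  list(threshold = 40, alpha = 0.05, top_n = 6L, min_tpm = 5,
       deg_top_n = 200L, motif_rules = default_motif_rules(),
       strand = "sense")
}

merge_config <- function(config) {
  cfg <- default_run_config()
  cfg[names(config)] <- config
  cfg
}

#' Run the off-target scan stage
#'
#' Orchestrates one full scan: reads the ASO manifest, FASTA and optional
#' expression / DEG inputs (in-memory data frames are also accepted),
#' scans every ASO over every (expressed) sequence at the configured
#' threshold, and writes the stage artifacts to `config$out`:
#' `hits.tsv`, `gene_summaries.tsv`, `top_hits.txt` (rendered
#' alignments), `cdf.tsv`, `venn.json` (when >= 2 ASOs),
#' `deg_flags_<group>.tsv` (when DEG tables are given), `run_log.txt` and
#' `effective_config.json`. Every output carries a provenance header, the
#' run log records each default that stood in for an unstated analysis
#' choice, and outputs are written atomically; partial outputs are removed
#' on failure.
#'
#' @param config named list: `asos`, `fasta` (paths or data frames),
#'   optional `matrix` (path or `scoring_matrix`), `expressed` (path or
#'   character vector), `deg` (path/data.frame or named list of them),
#'   `threshold` (default 40), `alpha` (0.05), `top_n` (6), `min_tpm`
#'   (5), `out` (output directory, required).
#' @return invisibly, a list with the in-memory `hits`, `summaries`,
#'   `venn`, `cdf`, `deg_flags` and the output paths.
#' @export
run_scan <- function(config) {
  cfg <- merge_config(config)
  if (is.null(cfg$out)) stop("config$out (output directory) is required",
                             call. = FALSE)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  on_fail <- function(e) {
    unlink(written)
    stop("run_scan failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    asos <- if (is.data.frame(cfg$asos)) cfg$asos else
      read_aso_manifest(cfg$asos)
    records <- if (is.data.frame(cfg$fasta)) cfg$fasta else
      read_fasta(cfg$fasta)
    mat <- if (is.null(cfg$matrix)) {
      note("default applied: scoring matrix = ", matrix_name(default_matrix()),
           " (no per-ASO matrix supplied)")
      default_matrix()
    } else if (inherits(cfg$matrix, "scoring_matrix")) cfg$matrix else
      read_matrix(cfg$matrix)
    expressed <- NULL
    if (!is.null(cfg$expressed)) {
      expressed <- if (is.character(cfg$expressed) &&
                       length(cfg$expressed) == 1L &&
                       file.exists(cfg$expressed)) {
        note("expression filter: file ", cfg$expressed,
             " (min_tpm=", cfg$min_tpm, " when TPM column present)")
        read_expressed_genes(cfg$expressed, cfg$min_tpm)
      } else cfg$expressed
    } else {
      note("default applied: no expression filter; scanning every sequence")
    }
    note("threshold = ", cfg$threshold, " (inclusive: score >= threshold)")
    note("strand mode = ", cfg$strand, " (ASOs bind RNA; sense only)")

    hits <- scan_transcriptome(asos, records, mat, cfg$threshold, expressed)
    if (attr(hits, "n_expressed_missing") > 0L) {
      note("expressed genes absent from FASTA (ignored): ",
           attr(hits, "n_expressed_missing"))
    }
    summaries <- collapse_to_genes(hits)
    hdr <- provenance_header(
      cfg[setdiff(names(cfg), c("asos", "fasta", "deg", "matrix"))],
      matrix_name(mat), cfg$threshold)

    p_hits <- file.path(cfg$out, "hits.tsv")
    write_tsv_with_header(hits, p_hits, hdr); written <- c(written, p_hits)
    p_sum <- file.path(cfg$out, "gene_summaries.tsv")
    write_tsv_with_header(summaries, p_sum, hdr); written <- c(written, p_sum)

    # rendered top hits per ASO
    p_top <- file.path(cfg$out, "top_hits.txt")
    top_lines <- hdr
    for (aid in asos$aso_id) {
      sub <- summaries[summaries$aso_id == aid, , drop = FALSE]
      tops <- top_hits(sub, cfg$top_n)
      top_lines <- c(top_lines, "", paste0("== ", aid, ": top ",
                                           nrow(tops), " candidate genes =="))
      for (i in seq_len(nrow(tops))) {
        h <- tops[i, ]
        top_lines <- c(
          top_lines,
          sprintf("%s  gene=%s  score=%s/%s  sites=%d  at %s:%d-%d (1-based inclusive)",
                  h$aso_id, h$gene_id, format(h$best_score),
                  format(h$max_score), h$n_sites, h$seq_id,
                  h$start + 1L, h$end),
          render_alignment(h, asos[asos$aso_id == aid, ]), "")
      }
    }
    tmp <- paste0(p_top, ".tmp"); writeLines(top_lines, tmp)
    file.rename(tmp, p_top); written <- c(written, p_top)

    # score CDF over all scanned genes, one category per ASO
    scanned_genes <- if (is.null(expressed)) unique(records$gene_id) else
      intersect(unique(records$gene_id), expressed)
    cdf_parts <- lapply(asos$aso_id, function(aid) {
      sub <- summaries[summaries$aso_id == aid, , drop = FALSE]
      best <- setNames(sub$best_score, sub$gene_id)
      grid <- seq(0, max(vapply(asos$sequence, max_score, numeric(1L),
                                matrix = mat)) + 1, by = 1)
      score_cdf(best, setNames(rep(aid, length(scanned_genes)),
                               scanned_genes), grid)
    })
    cdf <- do.call(rbind, cdf_parts)
    p_cdf <- file.path(cfg$out, "cdf.tsv")
    write_tsv_with_header(cdf, p_cdf, hdr); written <- c(written, p_cdf)

    venn <- NULL
    if (nrow(asos) >= 2L) {
      sets <- lapply(asos$aso_id, function(a) {
        unique(summaries$gene_id[summaries$aso_id == a])
      })
      names(sets) <- asos$aso_id
      venn <- mutual_targets(sets)
      p_venn <- file.path(cfg$out, "venn.json")
      jsonlite::write_json(
        list(provenance = sub("^#\\s*", "", hdr),
             regions = venn$regions, shared = venn$shared,
             union_size = venn$union_size),
        p_venn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <- c(written, p_venn)
    } else {
      note("single ASO: no mutual-target report")
    }

    deg_flags <- list()
    if (!is.null(cfg$deg)) {
      note("default applied: DEG significance = padj < alpha, alpha = ",
           cfg$alpha)
      degs <- cfg$deg
      if (is.data.frame(degs) || is.character(degs)) degs <- list(treated = degs)
      for (g in names(degs)) {
        tab <- if (is.data.frame(degs[[g]])) degs[[g]] else
          read_deg_table(degs[[g]])
        fl <- deg_flag(summaries, tab, cfg$alpha)
        deg_flags[[g]] <- fl
        p <- file.path(cfg$out, paste0("deg_flags_", g, ".tsv"))
        write_tsv_with_header(fl, p, hdr); written <- c(written, p)
        note("group ", g, ": ", attr(fl, "n_flagged"),
             " of ", nrow(fl), " gene-level candidates flagged as DEGs")
      }
    }

    p_cfg <- file.path(cfg$out, "effective_config.json")
    jsonlite::write_json(
      cfg[setdiff(names(cfg), c("asos", "fasta", "deg", "matrix", "out"))],
      p_cfg, auto_unbox = TRUE, force = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p_cfg)

    p_log <- file.path(cfg$out, "run_log.txt")
    writeLines(c(hdr, log_lines), p_log); written <- c(written, p_log)

    invisible(list(hits = hits, summaries = summaries, venn = venn,
                   cdf = cdf, deg_flags = deg_flags, paths = written))
  }, error = on_fail)
}

#' Run the motif-audit stage
#'
#' @param config named list: `asos` (path or data.frame), optional
#'   `rules` (default [default_motif_rules()]), `out` directory.
#' @return invisibly, the audit report data.frame.
#' @export
run_audit <- function(config) {
  cfg <- merge_config(config)
  if (is.null(cfg$out)) stop("config$out is required", call. = FALSE)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  asos <- if (is.data.frame(cfg$asos)) cfg$asos else
    read_aso_manifest(cfg$asos)
  rules <- if (is.null(cfg$rules)) default_motif_rules() else cfg$rules
  report <- audit_panel(asos, rules)
  hdr <- provenance_header(list(rules = rules), "none", NA)
  write_tsv_with_header(report, file.path(cfg$out, "audit_report.tsv"), hdr)
  invisible(report)
}

#' Run the panel-design stage
#'
#' Dispatches on `config$mode`: `"microwalk"` (needs `region`,
#' `center_start`, `length`, optional `step`, `max_offset`),
#' `"length_series"` (needs `region`, `anchor_start`, `lengths`, optional
#' `anchor_end_fixed`) or `"mismatch"` (needs `parent`, `position_sets`).
#'
#' @param config named list as above plus `out` directory.
#' @return invisibly, the panel manifest data.frame.
#' @export
run_design <- function(config) {
  cfg <- merge_config(config)
  if (is.null(cfg$out)) stop("config$out is required", call. = FALSE)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  panel <- switch(
    cfg$mode,
    microwalk = microwalk_panel(
      cfg$region, cfg$center_start, cfg$length,
      step = if (is.null(cfg$step)) 2L else cfg$step,
      max_offset = if (is.null(cfg$max_offset)) 16L else cfg$max_offset),
    length_series = length_panel(
      cfg$region, cfg$anchor_start, cfg$lengths,
      anchor_end_fixed = isTRUE(cfg$anchor_end_fixed)),
    mismatch = mismatch_panel(cfg$parent, cfg$position_sets),
    stop("unknown design mode: ", cfg$mode, call. = FALSE)
  )
  hdr <- provenance_header(cfg[c("mode")], "none", NA)
  write_tsv_with_header(panel, file.path(cfg$out, "panel_manifest.tsv"), hdr)
  invisible(panel)
}

#' Run the simulation stage
#'
#' Generates the two-ASO shared-target scenario with
#' [make_figure9_scenario()] and writes the full bundle plus truth
#' manifest to `config$out`.
#'
#' @param config named list: `seed` (required), optional `n_genes`,
#'   `out` directory.
#' @return invisibly, the bundle list with a `paths` element.
#' @export
run_simulate <- function(config) {
  cfg <- merge_config(config)
  if (is.null(cfg$out)) stop("config$out is required", call. = FALSE)
  if (is.null(cfg$seed)) stop("config$seed is required", call. = FALSE)
  n_genes <- if (is.null(cfg$n_genes)) 60L else cfg$n_genes
  bundle <- make_figure9_scenario(cfg$seed, n_genes)
  bundle$paths <- write_scenario(bundle, cfg$out)
  invisible(bundle)
}
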