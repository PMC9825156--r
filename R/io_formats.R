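#' Read a transcript FASTA file
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) into a data frame of
#' sequence records. Sequences are normalized to the DNA alphabet: lowercase
#' is folded to uppercase and U (RNA alphabet) becomes T, because the scan
#' operates on the sense-strand DNA representation. The gene identifier is
#' taken from a `gene=` token in the header description when present,
#' otherwise it defaults to the sequence id so that gene-level collapse is
#' always possible. Descriptions are preserved verbatim but never
#' interpreted beyond `gene=`.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return data.frame with columns `seq_id`, `gene_id`, `sequence`,
#'   `description` (empty string when the header has no description).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 gene=G1", "acgu"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  headers <- names(set)
  seq_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  dup <- seq_id[duplicated(seq_id)]
  if (length(dup) > 0L) {
    stop("duplicate seq_id in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  sequence <- normalize_seq(as.character(set))
  for (i in seq_along(sequence)) {
    if (!nzchar(sequence[[i]])) {
      stop("empty sequence for record '", seq_id[[i]], "'", call. = FALSE)
    }
    off <- first_bad_offset(sequence[[i]])
    if (off >= 0L) {
      stop("non-ACGTU character in record '", seq_id[[i]],
           "' at offset ", off, call. = FALSE)
    }
  }
  gene_id <- ifelse(
    grepl("(^|\\s)gene=\\S+", description),
    sub("^(?:.*\\s)?gene=(\\S+).*$", "\\1", description, perl = TRUE),
    seq_id
  )
  data.frame(
    seq_id = seq_id, gene_id = gene_id, sequence = unname(sequence),
    description = description, stringsAsFactors = FALSE
  )
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: headers are `seq_id gene=<gene_id>` plus the
#' stored description (the `gene=` token is re-emitted only when gene_id
#' differs from seq_id and the description does not already carry one).
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("seq_id", "sequence") %in% names(records)))
  gene_id <- if ("gene_id" %in% names(records)) records$gene_id else records$seq_id
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- records$seq_id
  need_gene <- gene_id != records$seq_id & !grepl("(^|\\s)gene=", desc)
  hdr <- ifelse(need_gene, paste0(hdr, " gene=", gene_id), hdr)
  hdr <- ifelse(nzchar(desc), paste(hdr, desc), hdr)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' Needed throughout because an ASO is antisense to its target RNA: the
#' perfectly complementary sense-strand site is the reverse complement of
#' the ASO sequence.
#'
#' @param sequence character vector of DNA strings over \{A,C,G,T\}.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("AAAC") # "GTTT"
#' @export
revcomp <- function(sequence) {
  vapply(sequence, function(s) {
    assert_dna(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1L), USE.NAMES = FALSE)
}

#' Read an ASO manifest
#'
#' Tab-separated file with header columns `aso_id`, `sequence` and optional
#' `chemistry` (free-text, e.g. "PS/MOE steric blocker") and `matrix_id`
#' (reference to a per-ASO scoring matrix). Sequences are normalized as in
#' [read_fasta()] and must be 8--50 nt (hard validation bounds around the
#' 18--24 nt oligos typically screened).
#'
#' @param path path to the TSV manifest.
#' @return data.frame with columns `aso_id`, `sequence`, `chemistry`,
#'   `matrix_id` (NA when absent).
#' @export
read_aso_manifest <- function(path) {
  if (!file.exists(path)) stop("ASO manifest not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character")
  req <- c("aso_id", "sequence")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop("ASO manifest missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("ASO manifest has no rows: ", path, call. = FALSE)
  dup <- tab$aso_id[duplicated(tab$aso_id)]
  if (length(dup) > 0L) {
    stop("duplicate aso_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  tab$sequence <- normalize_seq(tab$sequence)
  for (i in seq_len(nrow(tab))) {
    validate_aso(tab$sequence[[i]], tab$aso_id[[i]])
  }
  tab$chemistry <- if ("chemistry" %in% names(tab)) tab$chemistry else NA_character_
  tab$matrix_id <- if ("matrix_id" %in% names(tab)) tab$matrix_id else NA_character_
  tab[, c("aso_id", "sequence", "chemistry", "matrix_id")]
}

# shared ASO validation: alphabet + length bounds
validate_aso <- function(sequence, aso_id = "<aso>") {
  assert_dna(sequence, what = paste0("ASO '", aso_id, "' sequence"))
  n <- nchar(sequence)
  if (n < 8L || n > 50L) {
    stop("ASO '", aso_id, "' length ", n, " outside [8, 50]", call. = FALSE)
  }
  invisible(sequence)
}

#' Construct an ASO record
#'
#' Convenience constructor for a single validated oligonucleotide record in
#' the same shape as one row of [read_aso_manifest()].
#'
#' @param aso_id identifier.
#' @param sequence DNA sequence, 5'->3', 8--50 nt.
#' @param chemistry optional free-text chemistry annotation.
#' @param matrix_id optional per-ASO scoring-matrix reference.
#' @return one-row data.frame.
#' @export
aso_record <- function(aso_id, sequence, chemistry = NA_character_,
                       matrix_id = NA_character_) {
  sequence <- normalize_seq(sequence)
  validate_aso(sequence, aso_id)
  data.frame(aso_id = aso_id, sequence = sequence, chemistry = chemistry,
             matrix_id = matrix_id, stringsAsFactors = FALSE)
}

#' Write an ASO manifest (or panel manifest) to TSV
#'
#' @param asos data.frame with at least `aso_id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aso_manifest <- function(asos, path) {
  stopifnot(all(c("aso_id", "sequence") %in% names(asos)))
  write.table(asos, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a differential-expression table
#'
#' CSV or TSV (sniffed from the header line) with required columns
#' `gene_id`, `log2FC`, `pvalue`, `padj`; one record per gene.
#'
#' @param path input path.
#' @return data.frame with the four required columns.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop("DEG table not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  req <- c("gene_id", "log2FC", "pvalue", "padj")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop("DEG table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("DEG table has duplicated gene_id entries", call. = FALSE)
  }
  bad_p <- !is.na(tab$pvalue) & (tab$pvalue < 0 | tab$pvalue > 1)
  bad_q <- !is.na(tab$padj) & (tab$padj < 0 | tab$padj > 1)
  if (any(bad_p) || any(bad_q)) {
    stop("DEG table has p-values outside [0, 1]", call. = FALSE)
  }
  tab[, req]
}

#' Read an expression table or expressed-gene list
#'
#' Either a two-column table `gene_id`, `TPM` (genes with TPM > `min_tpm`
#' are kept) or a headerless one-column list of gene ids.
#'
#' @param path input path.
#' @param min_tpm expression cutoff applied when a TPM column is present
#'   (default 5, a conventional expressed-gene threshold).
#' @return character vector of expressed gene ids.
#' @export
read_expressed_genes <- function(path, min_tpm = 5) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  if (grepl("gene_id", hdr)) {
    sep <- if (grepl("\t", hdr)) "\t" else ","
    tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
    if ("TPM" %in% names(tab)) {
      return(unique(tab$gene_id[!is.na(tab$TPM) & tab$TPM > min_tpm]))
    }
    return(unique(tab$gene_id))
  }
  unique(trimws(readLines(path)))
}
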