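#' Motif rule vocabulary
#'
#' The closed set of hybridization-independent risk motifs the auditor can
#' flag. These are sequence features repeatedly associated in the ASO
#' literature with protein binding, toxicity or hybridization-independent
#' activity, especially on phosphorothioate backbones:
#'
#' * `G_RUN` — maximal run of >= 4 consecutive guanosines (the classic
#'   "G4" motif as a contiguous run).
#' * `G4_TRACTS` — four runs of >= 3 G separated by 1--7 nt loops, the
#'   classical intramolecular G-quadruplex pattern. Off by default: most
#'   short ASOs showing G-rich activity carry a plain run, and the tract
#'   pattern is a stricter, structure-motivated rule.
#' * `CCGG` — literal CCGG, all occurrences.
#' * `CpG` — every CG dinucleotide.
#' * `TGC`, `TCC` — literal trinucleotides, all occurrences (overlaps
#'   included).
#' * `TERMINAL_3P_G` — the ASO ends in >= 2 consecutive guanosines; the
#'   run length k is reported in `detail`.
#'
#' @return character vector of the default-enabled rule names (all rules
#'   except `G4_TRACTS`).
#' @export
default_motif_rules <- function() {
  c("G_RUN", "CCGG", "CpG", "TGC", "TCC", "TERMINAL_3P_G")
}

ALL_MOTIF_RULES <- c("G_RUN", "G4_TRACTS", "CCGG", "CpG", "TGC", "TCC",
                     "TERMINAL_3P_G")

# all (possibly overlapping) occurrences of a literal pattern;
# returns 0-based starts
literal_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
  if (m[[1L]] < 0L) integer() else as.integer(m) - 1L
}

motif_flag_row <- function(motif_name, start, end, detail = "") {
  data.frame(motif_name = motif_name, start = as.integer(start),
             end = as.integer(end), detail = as.character(detail),
             stringsAsFactors = FALSE)
}

#' Audit an ASO for hybridization-independent risk motifs
#'
#' Scans a single ASO sequence for the enabled motif rules (see
#' [default_motif_rules()]) and returns one flag per occurrence with its
#' 0-based half-open interval on the ASO. The presence of a motif marks a
#' sequence worth extra control experiments, not a prediction of activity:
#' these motifs are context dependent.
#'
#' @param aso one-row data.frame or list with `aso_id` and `sequence`.
#' @param rules character vector of rule names to apply; unknown names are
#'   an error.
#' @return data.frame with columns `aso_id`, `motif_name`, `start`, `end`,
#'   `detail`, sorted by `start` then `motif_name`.
#' @examples
#' audit_aso(aso_record("a1", "TTCCGGTTTTTT"))
#' @export
audit_aso <- function(aso, rules = default_motif_rules()) {
  aso <- as.list(aso)
  seq <- aso$sequence
  assert_dna(seq, "ASO sequence")
  bad <- setdiff(rules, ALL_MOTIF_RULES)
  if (length(bad) > 0L) {
    stop("unknown motif rule(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  L <- nchar(seq)
  flags <- list()
  add <- function(f) flags[[length(flags) + 1L]] <<- f

  if ("G_RUN" %in% rules) {
    m <- gregexpr("G{4,}", seq)[[1L]]
    if (m[[1L]] > 0L) {
      for (i in seq_along(m)) {
        len <- attr(m, "match.length")[[i]]
        add(motif_flag_row("G_RUN", m[[i]] - 1L, m[[i]] - 1L + len,
                           paste0("run_length=", len)))
      }
    }
  }
  if ("G4_TRACTS" %in% rules) {
    m <- gregexpr("G{3,}(?:[ACT]{1,7}G{3,}){3}", seq, perl = TRUE)[[1L]]
    if (m[[1L]] > 0L) {
      for (i in seq_along(m)) {
        len <- attr(m, "match.length")[[i]]
        add(motif_flag_row("G4_TRACTS", m[[i]] - 1L, m[[i]] - 1L + len,
                           "tracts=4"))
      }
    }
  }
  for (lit in intersect(c("CCGG", "TGC", "TCC"), rules)) {
    for (s in literal_starts(seq, lit)) {
      add(motif_flag_row(lit, s, s + nchar(lit), ""))
    }
  }
  if ("CpG" %in% rules) {
    for (s in literal_starts(seq, "CG")) {
      add(motif_flag_row("CpG", s, s + 2L, ""))
    }
  }
  if ("TERMINAL_3P_G" %in% rules) {
    m <- regexpr("G+$", seq)
    k <- if (m > 0L) attr(m, "match.length") else 0L
    if (k >= 2L) {
      add(motif_flag_row("TERMINAL_3P_G", L - k, L, paste0("k=", k)))
    }
  }
  if (length(flags) == 0L) {
    out <- motif_flag_row(character(), integer(), integer(), character())
  } else {
    out <- do.call(rbind, flags)
    out <- out[order(out$start, out$motif_name), , drop = FALSE]
  }
  out <- cbind(aso_id = rep(aso$aso_id, nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Audit a panel of ASOs
#'
#' @param asos data.frame of ASO records.
#' @inheritParams audit_aso
#' @return row-bound audit report for all ASOs.
#' @export
audit_panel <- function(asos, rules = default_motif_rules()) {
  out <- do.call(rbind, lapply(seq_len(nrow(asos)), function(i) {
    audit_aso(asos[i, ], rules)
  }))
  rownames(out) <- NULL
  out
}
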