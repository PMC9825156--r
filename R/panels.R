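#' Micro-walk panel around a target hotspot
#'
#' Tiles ASOs across a hotspot by shifting a fixed-length window in small
#' increments: for every offset in `-max_offset, ..., +max_offset` in
#' steps of `step`, the window `[center_start + offset, +length)` of the
#' sense-strand region is taken and its reverse complement emitted as the
#' ASO (5'->3'). Offsets whose window leaves the region are skipped with a
#' warning rather than erroring, so a hotspot near a sequence end still
#' yields the feasible part of the walk. With the defaults (2 nt steps up
#' to 16 nt each way) a fully interior hotspot yields 17 ASOs.
#'
#' @param region one-row data.frame or list with `seq_id` and `sequence`.
#' @param center_start 0-based start of the central (offset 0) window.
#' @param length ASO length in nt.
#' @param step walk step in nt (default 2).
#' @param max_offset maximum shift in each direction in nt (default 16).
#' @param id_prefix prefix for variant ids; defaults to the region
#'   `seq_id`. Ids are suffixed with the signed offset (`"+2"`, `"-16"`).
#' @return ASO manifest data.frame with panel columns `parent_id`,
#'   `mode`, `offset`, `source_start`.
#' @export
microwalk_panel <- function(region, center_start, length, step = 2L,
                            max_offset = 16L, id_prefix = NULL) {
  region <- as.list(region)
  assert_dna(region$sequence, paste0("region '", region$seq_id, "'"))
  n <- nchar(region$sequence)
  if (length > n) {
    stop("ASO length ", length, " exceeds region length ", n, call. = FALSE)
  }
  if (is.null(id_prefix)) id_prefix <- region$seq_id
  offsets <- seq.int(-max_offset, max_offset, by = step)
  rows <- list()
  k <- 0L
  for (off in offsets) {
    s <- center_start + off               # 0-based window start
    if (s < 0L || s + length > n) {
      warning("micro-walk offset ", sprintf("%+d", off),
              " is out of bounds for region '", region$seq_id,
              "'; skipped", call. = FALSE)
      next
    }
    win <- substr(region$sequence, s + 1L, s + length)
    k <- k + 1L
    rows[[k]] <- data.frame(
      aso_id = sprintf("%s%+d", id_prefix, off),
      sequence = revcomp(win),
      chemistry = NA_character_, matrix_id = NA_character_,
      parent_id = id_prefix, mode = "microwalk",
      offset = off, source_start = s, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Length-series panel at an anchored terminus
#'
#' Emits one ASO per requested length, all sharing one anchored end of the
#' source window. When `anchor_end_fixed = FALSE` (default) the windows
#' share their 0-based start `anchor_start` and grow rightwards; when
#' `TRUE`, `anchor_start` is interpreted as the shared (exclusive) end
#' coordinate and windows grow leftwards. Each ASO is the reverse
#' complement of its window. Ids are suffixed `_L<length>`.
#'
#' @param region one-row data.frame or list with `seq_id` and `sequence`.
#' @param anchor_start 0-based anchored coordinate (window start, or
#'   shared end when `anchor_end_fixed`).
#' @param lengths integer vector of ASO lengths, each in [8, 50].
#' @param anchor_end_fixed logical; which terminus is anchored.
#' @param id_prefix prefix for variant ids; defaults to the region seq_id.
#' @return ASO manifest data.frame with panel columns `parent_id`,
#'   `mode`, `length`, `source_start`. Out-of-bounds lengths are skipped
#'   with a warning.
#' @export
length_panel <- function(region, anchor_start, lengths,
                         anchor_end_fixed = FALSE, id_prefix = NULL) {
  region <- as.list(region)
  assert_dna(region$sequence, paste0("region '", region$seq_id, "'"))
  if (any(lengths < 8L | lengths > 50L)) {
    stop("lengths must lie within [8, 50]", call. = FALSE)
  }
  n <- nchar(region$sequence)
  if (is.null(id_prefix)) id_prefix <- region$seq_id
  rows <- list()
  for (len in lengths) {
    s <- if (anchor_end_fixed) anchor_start - len else anchor_start
    if (s < 0L || s + len > n) {
      warning("length ", len, " window is out of bounds for region '",
              region$seq_id, "'; skipped", call. = FALSE)
      next
    }
    win <- substr(region$sequence, s + 1L, s + len)
    rows[[length(rows) + 1L]] <- data.frame(
      aso_id = sprintf("%s_L%d", id_prefix, len),
      sequence = revcomp(win),
      chemistry = NA_character_, matrix_id = NA_character_,
      parent_id = id_prefix, mode = "length_series",
      length = len, source_start = s, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mismatch-variant panel
#'
#' Generates point-mutated variants of a parent ASO, one variant per
#' position set. At each listed 0-based position the base is replaced
#' according to `substitution_rule`; the default rule substitutes the
#' complement of the original base, which guarantees loss of pairing at
#' that duplex position whatever the target is. Variant ids are the parent
#' id plus `"_m"` and the comma-joined positions; the Hamming distance of
#' each variant to the parent equals its position-set size. To reproduce a
#' published mismatch panel whose substitution bases are known, pass those
#' bases via a custom rule.
#'
#' @param parent one-row data.frame or list with `aso_id` and `sequence`.
#' @param position_sets list of integer vectors of 0-based positions; no
#'   duplicates within a set, all within the ASO.
#' @param substitution_rule either `"complement"` (default) or a
#'   `function(base, position)` returning the replacement base.
#' @return ASO manifest data.frame with panel columns `parent_id`,
#'   `mode`, `positions`.
#' @export
mismatch_panel <- function(parent, position_sets,
                           substitution_rule = "complement") {
  parent <- as.list(parent)
  seq <- parent$sequence
  assert_dna(seq, "parent ASO sequence")
  L <- nchar(seq)
  subfun <- if (identical(substitution_rule, "complement")) {
    function(base, position) COMPLEMENT[[base]]
  } else if (is.function(substitution_rule)) {
    substitution_rule
  } else {
    stop("substitution_rule must be \"complement\" or a function",
         call. = FALSE)
  }
  rows <- list()
  for (ps in position_sets) {
    if (length(ps) == 0L) stop("empty position set", call. = FALSE)
    if (anyDuplicated(ps)) {
      stop("duplicate positions in a set: ", paste(ps, collapse = ","),
           call. = FALSE)
    }
    if (any(ps < 0L | ps >= L)) {
      stop("position out of range [0, ", L - 1L, "]: ",
           paste(ps, collapse = ","), call. = FALSE)
    }
    chars <- seq_chars(seq)
    for (p in ps) {
      repl <- subfun(chars[[p + 1L]], p)
      if (repl == chars[[p + 1L]]) {
        stop("substitution rule returned the original base at position ", p,
             call. = FALSE)
      }
      chars[[p + 1L]] <- repl
    }
    rows[[length(rows) + 1L]] <- data.frame(
      aso_id = paste0(parent$aso_id, "_m", paste(ps, collapse = ",")),
      sequence = paste(chars, collapse = ""),
      chemistry = NA_character_, matrix_id = NA_character_,
      parent_id = parent$aso_id, mode = "mismatch",
      positions = paste(ps, collapse = ","), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
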