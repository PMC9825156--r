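#' The default base-pair scoring matrix
#'
#' A 4x4 matrix of pairing values indexed by (ASO base, opposing target
#' base). Complementary matches are upweighted, with G:C pairs scored above
#' A:T, mismatches are penalized variably by base composition
#' (purine-purine clashes hardest), and G:T / T:G wobbles sit between
#' mismatch and match:
#'
#' * matches: A:T = T:A = +2, C:G = G:C = +3
#' * wobbles: G:T = T:G = +1
#' * purine-purine mismatches (A:A, A:G, G:A, G:G) = -3
#' * all remaining mismatches = -2
#'
#' This is a documented stand-in with the stated qualitative structure;
#' study-specific per-ASO matrices can be loaded with [read_matrix()] and
#' passed anywhere a matrix argument is accepted. With this matrix a 20-nt
#' ASO containing G/C has a maximum score above 40, so singly mismatched
#' sites can still clear the conventional >= 40 candidate-call threshold.
#'
#' @param name matrix name recorded in outputs for provenance.
#' @return a `scoring_matrix`: numeric 4x4 matrix, rows = ASO base,
#'   columns = target base, with a `name` attribute.
#' @examples
#' default_matrix()["C", "G"] # +3
#' @export
default_matrix <- function(name = "default-v1") {
  m <- matrix(-2, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  m["A", "T"] <- 2; m["T", "A"] <- 2
  m["C", "G"] <- 3; m["G", "C"] <- 3
  m["G", "T"] <- 1; m["T", "G"] <- 1
  for (a in c("A", "G")) for (b in c("A", "G")) m[a, b] <- -3
  scoring_matrix(m, name = name)
}

#' Construct and validate a scoring matrix
#'
#' Enforces the structural invariants every pairing matrix must satisfy:
#' all 16 (ASO base, target base) entries present and numeric, and for each
#' ASO base the complement-match entry is strictly the row maximum and
#' positive, so a perfect complement can never be out-scored by any other
#' opposing base.
#'
#' @param values numeric 4x4 matrix with dimnames A,C,G,T (rows = ASO
#'   base, columns = target base).
#' @param name matrix name for provenance.
#' @return validated `scoring_matrix` object.
#' @export
scoring_matrix <- function(values, name = "unnamed") {
  if (!is.matrix(values) || !is.numeric(values) ||
      any(dim(values) != c(4L, 4L))) {
    stop("scoring matrix must be a numeric 4x4 matrix", call. = FALSE)
  }
  if (is.null(dimnames(values)) ||
      !identical(sort(rownames(values)), DNA_BASES) ||
      !identical(sort(colnames(values)), DNA_BASES)) {
    stop("scoring matrix must have rownames and colnames A,C,G,T",
         call. = FALSE)
  }
  values <- values[DNA_BASES, DNA_BASES]
  if (anyNA(values)) stop("scoring matrix has missing cells", call. = FALSE)
  for (a in DNA_BASES) {
    comp <- COMPLEMENT[[a]]
    match_val <- values[a, comp]
    others <- values[a, setdiff(DNA_BASES, comp)]
    if (match_val <= 0) {
      stop("match entry (", a, ",", comp, ") must be positive", call. = FALSE)
    }
    if (any(others >= match_val)) {
      stop("row-max invariant violated for ASO base ", a,
           ": complement match (", a, ",", comp,
           ") must strictly exceed every other entry in that row",
           call. = FALSE)
    }
  }
  structure(values, name = name, class = c("scoring_matrix", "matrix", "array"))
}

#' Read a scoring matrix from TSV
#'
#' Expected layout: a 5x5 grid whose first header row names the target
#' bases A,C,G,T (corner cell blank) and whose four data rows are labeled
#' by the ASO base. Cells may be integer or decimal and are used exactly as
#' given.
#'
#' @param path path to the matrix TSV.
#' @param name matrix name; defaults to the file name without extension.
#' @return validated `scoring_matrix`.
#' @export
read_matrix <- function(path, name = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  tab <- read.delim(path, row.names = 1L, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) != 4L) {
    stop("scoring matrix file must have 4 data rows (A,C,G,T), found ",
         nrow(tab), ": ", path, call. = FALSE)
  }
  if (ncol(tab) != 4L) {
    stop("scoring matrix file must have 4 target-base columns, found ",
         ncol(tab), ": ", path, call. = FALSE)
  }
  vals <- as.matrix(tab)
  if (!is.numeric(vals)) {
    stop("scoring matrix has non-numeric cells: ", path, call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  scoring_matrix(vals, name = name)
}

#' Write a scoring matrix to TSV
#'
#' @param matrix a `scoring_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  df <- as.data.frame(unclass(matrix))
  write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

matrix_name <- function(matrix) {
  nm <- attr(matrix, "name")
  if (is.null(nm)) "unnamed" else nm
}

#' Pairing score of an ASO against one target window
#'
#' Scores an antiparallel, ungapped duplex between an ASO (5'->3') and an
#' equal-length sense-strand target window (5'->3'): ASO position i pairs
#' with window position L-1-i, and the score is the sum over positions of
#' the matrix entry for (ASO base, opposing target base). Mismatch
#' positions are reported in ASO coordinates (0-based) wherever the
#' opposing base is not the Watson-Crick complement of the ASO base;
#' wobble-scored positions (G:T, T:G under the default matrix) therefore
#' count as mismatches for display but are tallied separately.
#'
#' @param aso_sequence ASO DNA sequence, 5'->3'.
#' @param target_window sense-strand DNA window of equal length, 5'->3'.
#' @param matrix a `scoring_matrix` (default [default_matrix()]).
#' @return list with `score`, `mismatch_positions` (0-based integer
#'   vector, ASO coordinates) and `n_wobble`.
#' @examples
#' score_window("ACGT", "ACGT")$score # 10: the window is the ASO's revcomp
#' score_window("ACGT", "ACGA")       # score 5, mismatch at ASO position 0
#' @export
score_window <- function(aso_sequence, target_window, matrix = default_matrix()) {
  assert_dna(aso_sequence, "ASO sequence")
  assert_dna(target_window, "target window")
  L <- nchar(aso_sequence)
  if (nchar(target_window) != L) {
    stop("ASO (", L, " nt) and target window (", nchar(target_window),
         " nt) must have equal length", call. = FALSE)
  }
  a <- seq_index(aso_sequence)
  w <- rev(seq_index(target_window))       # opposing base per ASO position
  vals <- matrix[cbind(a, w)]
  mism <- which(w != 5L - a) - 1L          # complement(i) = 5 - i in A..T coding
  wob <- sum((a == 3L & w == 4L) | (a == 4L & w == 3L))
  list(score = sum(vals),
       mismatch_positions = as.integer(mism),
       n_wobble = as.integer(wob))
}

#' Maximum attainable pairing score of an ASO
#'
#' The score of the ASO against its own reverse complement, i.e. the sum of
#' complement-match entries over the ASO's bases. By the row-max invariant
#' of [scoring_matrix()] this is the supremum of [score_window()] over all
#' possible windows, and it is attained only by the exact
#' reverse-complement window.
#'
#' @inheritParams score_window
#' @return numeric score.
#' @examples
#' max_score("ACGT") # 10
#' @export
max_score <- function(aso_sequence, matrix = default_matrix()) {
  assert_dna(aso_sequence, "ASO sequence")
  a <- seq_index(aso_sequence)
  sum(matrix[cbind(a, 5L - a)])
}
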