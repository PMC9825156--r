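#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom tools md5sum
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Fix the PRNG contract for all generators: Mersenne-Twister with
# Rejection sampling and Inversion normals, restoring caller state.
with_seed <- function(seed, code) {
  withr::with_seed(
    seed, code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

rng_contract <- function() {
  "R Mersenne-Twister (normal.kind=Inversion, sample.kind=Rejection)"
}

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and converts U to T. Does not validate.
#' @param x character vector of sequences.
#' @return character vector.
#' @keywords internal
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

# 0-based offset of the first character outside {A,C,G,T}, or -1L
first_bad_offset <- function(seq) {
  bad <- regexpr("[^ACGT]", seq)
  if (bad < 0L) -1L else as.integer(bad) - 1L
}

assert_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  off <- first_bad_offset(seq)
  if (off >= 0L) {
    stop(
      what, " contains non-ACGT character '",
      substr(seq, off + 1L, off + 1L), "' at offset ", off,
      call. = FALSE
    )
  }
  invisible(seq)
}

# Split a DNA string into a character vector of bases
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# Integer encoding A=1 C=2 G=3 T=4 for fast matrix lookup
seq_index <- function(seq) {
  match(seq_chars(seq), DNA_BASES)
}
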