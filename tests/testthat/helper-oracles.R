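# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized scan path: windows are materialized one by one and
# scored by direct 16-entry lookups so the two routes share no code.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

# direct lookup score of one window (antiparallel duplex convention)
oracle_score <- function(aso, window, mat) {
  a <- strsplit(aso, "")[[1L]]
  w <- rev(strsplit(window, "")[[1L]])
  s <- 0
  for (i in seq_along(a)) s <- s + mat[a[[i]], w[[i]]]
  s
}

# brute-force scan: materialize every window, score, filter
oracle_scan <- function(aso, seq, mat, threshold) {
  L <- nchar(aso)
  n <- nchar(seq)
  if (n < L) return(data.frame(start = integer(), score = numeric()))
  starts <- integer()
  scores <- numeric()
  for (s in seq_len(n - L + 1L)) {
    win <- substr(seq, s, s + L - 1L)
    sc <- oracle_score(aso, win, mat)
    if (sc >= threshold) {
      starts <- c(starts, s - 1L)   # 0-based
      scores <- c(scores, sc)
    }
  }
  data.frame(start = starts, score = scores)
}

# all DNA strings of length L, in a fixed order
all_kmers <- function(L) {
  if (L == 1L) return(BASES)
  do.call(paste0, expand.grid(rep(list(BASES), L))[, L:1, drop = FALSE])
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(COMP[strsplit(x, "")[[1L]]]), collapse = "")
}

# brute-force maximal tandem-repeat intervals: enumerate every qualifying
# substring of exact unit copies, then keep the non-extendable ones
oracle_tandem <- function(seq, unit, min_units) {
  u <- nchar(unit)
  n <- nchar(seq)
  runs <- list()
  for (s in seq_len(n)) {
    k <- 0L
    while (s + (k + 1L) * u - 1L <= n &&
           substr(seq, s + k * u, s + (k + 1L) * u - 1L) == unit) {
      k <- k + 1L
    }
    if (k >= min_units) {
      left_ext <- s > u &&
        substr(seq, s - u, s - 1L) == unit
      if (!left_ext) {
        runs[[length(runs) + 1L]] <-
          data.frame(start = s - 1L, end = s - 1L + k * u, n_units = k)
      }
    }
  }
  if (length(runs) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      n_units = integer()))
  }
  out <- do.call(rbind, runs)
  out <- out[order(out$start), , drop = FALSE]
  # left-anchored greedy non-overlap filter
  keep <- logical(nrow(out))
  last_end <- -1L
  for (i in seq_len(nrow(out))) {
    if (out$start[[i]] >= last_end) {
      keep[[i]] <- TRUE
      last_end <- out$end[[i]]
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

tiny_record <- function(seq, id = "s1", gene = id) {
  list(seq_id = id, gene_id = gene, sequence = seq)
}
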