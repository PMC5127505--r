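# Independent alignment oracles. Both implement the same move set as the
# production aligner but by entirely different routes:
#  - enumerate_alignment_scores: plain exhaustive recursion over every
#    possible move sequence (no memoization, no matrices) - feasible for
#    references up to ~4 codons;
#  - suffix_best_score: a literal top-down suffix recursion with an
#    environment cache, for 6-codon references.

enumerate_alignment_scores <- function(core, codons, m = 1L, mm = -1L, g = -2L) {
  L <- nchar(core)
  C <- length(codons)
  best <- -Inf
  rec <- function(i, j, acc) {
    if (i > C && j > L) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= C && j + 2L <= L) {
      obs <- substr(core, j, j + 2L)
      rec(i + 1L, j + 3L, acc + if (obs == codons[i]) m else mm)
    }
    if (i <= C) {
      rec(i + 1L, j, acc + g)             # delete 3 nt (whole codon)
      if (j <= L) rec(i + 1L, j + 1L, acc + g)   # delete 2 nt
      if (j + 1L <= L) rec(i + 1L, j + 2L, acc + g)  # delete 1 nt
    }
    for (k in 1:3) {                      # insert k read nt
      if (j + k - 1L <= L) rec(i, j + k, acc + g)
    }
    invisible(NULL)
  }
  rec(1L, 1L, 0L)
  best
}

suffix_best_score <- function(core, codons, m = 1L, mm = -1L, g = -2L) {
  L <- nchar(core)
  C <- length(codons)
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > C && j > L) return(0)
    cand <- c()
    if (i <= C && j + 2L <= L) {
      obs <- substr(core, j, j + 2L)
      cand <- c(cand, f(i + 1L, j + 3L) + if (obs == codons[i]) m else mm)
    }
    if (i <= C) {
      cand <- c(cand, f(i + 1L, j) + g)
      if (j <= L) cand <- c(cand, f(i + 1L, j + 1L) + g)
      if (j + 1L <= L) cand <- c(cand, f(i + 1L, j + 2L) + g)
    }
    for (k in 1:3) if (j + k - 1L <= L) cand <- c(cand, f(i, j + k) + g)
    res <- if (length(cand)) max(cand) else -Inf
    memo[[key]] <- res
    res
  }
  f(1L, 1L)
}

# All cores reachable from `seq` by one edit under the aligner's move set.
single_edit_cores <- function(seq, bases = c("A", "C", "G", "T")) {
  L <- nchar(seq)
  out <- character()
  for (p in seq_len(L)) {
    for (b in setdiff(bases, substr(seq, p, p))) {
      s <- seq
      substr(s, p, p) <- b
      out <- c(out, s)
    }
  }
  for (p in seq_len(L)) {          # deletions of length 1-3 at each start
    for (len in 1:3) {
      if (p + len - 1L > L) next
      out <- c(out, paste0(substr(seq, 1, p - 1L), substr(seq, p + len, L)))
    }
  }
  ins <- c(bases, as.vector(outer(bases, bases, paste0)))
  ins <- c(ins, as.vector(outer(ins[5:20], bases, paste0)))
  for (p in 0:L) {
    for (x in ins) {
      out <- c(out, paste0(substr(seq, 1, p), x, substr(seq, p + 1L, L)))
    }
  }
  unique(out)
}
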