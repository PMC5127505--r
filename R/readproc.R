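# Codon-aware variant calling from pooled amplicon reads:
#   1. merge read pairs, requiring both flanks to match wild type perfectly;
#   2. align the core against the reference in codon units by dynamic
#      programming (match/mismatch per codon, constant penalty for 1-3 nt
#      insertions or deletions);
#   3. accept only substitutions whose observed codons belong to the
#      expected (programmed + spike-in) codon set, which screens out
#      sequencing errors.

#' Alignment scoring scheme for codon-unit dynamic programming
#'
#' An exact three-letter codon match scores `codon_match`; a codon with at
#' least one mismatched letter scores `codon_mismatch`; an insertion or
#' deletion of one, two or three letters scores the constant `indel`.
#' Defaults (+1, -1, -2) make a single codon substitution outscore any
#' indel-pair explanation of the same core, keeping substitution calls
#' canonical.
#'
#' @param codon_match positive integer (default +1).
#' @param codon_mismatch negative integer (default -1).
#' @param indel negative integer, constant for lengths 1-3 (default -2).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(codon_match = 1L, codon_mismatch = -1L, indel = -2L) {
  if (codon_match <= 0) stop("codon_match must be positive")
  if (codon_mismatch >= 0) stop("codon_mismatch must be negative")
  if (indel >= 0) stop("indel must be negative")
  structure(list(codon_match = as.integer(codon_match),
                 codon_mismatch = as.integer(codon_mismatch),
                 indel = as.integer(indel)),
            class = "scoring_scheme")
}

#' Merge an innie read pair and verify flanks against wild type
#'
#' Mate 2 is reverse-complemented, then both mates must contain the
#' `flank_len`-nt anchors of the upstream and downstream flanks as exact
#' matches (any flank mismatch is a rejection, per the perfect-flank rule),
#' and the cores extracted from the two mates must agree at every position.
#'
#' @param read1,read2 nucleotide strings (mate 2 in sequencer orientation).
#' @param ref an [amplicon_reference()].
#' @param flank_len anchor length checked on each side (default 15).
#' @return A list of class `merged_read` with either `core_sequence` or
#'   `reject_reason` (`flank_mismatch`, `overlap_disagreement`,
#'   `no_overlap`) set.
#' @export
merge_and_verify <- function(read1, read2, ref, flank_len = 15L) {
  res <- merge_pairs(read1, read2, ref, flank_len)
  out <- list(core_sequence = if (is.na(res$reject[1])) res$core[1] else NULL,
              read_id = NULL,
              reject_reason = if (is.na(res$reject[1])) NULL else res$reject[1])
  class(out) <- "merged_read"
  out
}

# Vectorized pair merging. Returns data.frame(core, reject).
merge_pairs <- function(reads1, reads2, ref, flank_len = 15L) {
  up <- ref$upstream_flank
  dn <- ref$downstream_flank
  if (nchar(up) < flank_len || nchar(dn) < flank_len)
    stop("flank_len exceeds available flank sequence")
  up_anchor <- substr(up, nchar(up) - flank_len + 1L, nchar(up))
  dn_anchor <- substr(dn, 1L, flank_len)
  s1 <- toupper(reads1)
  s2 <- revcomp(toupper(reads2))

  core_of <- function(s) {
    a <- regexpr(up_anchor, s, fixed = TRUE)
    b <- regexpr(dn_anchor, s, fixed = TRUE)
    start <- ifelse(a > 0, a + flank_len, NA_integer_)
    end <- ifelse(b > 0, b - 1L, NA_integer_)
    ok <- !is.na(start) & !is.na(end) & end >= start - 1L
    core <- rep(NA_character_, length(s))
    core[ok] <- substr(s[ok], start[ok], end[ok])
    list(core = core,
         found = a > 0 & b > 0,
         ordered = ok)
  }
  c1 <- core_of(s1)
  c2 <- core_of(s2)
  reject <- rep(NA_character_, length(s1))
  reject[!(c1$found & c2$found)] <- "flank_mismatch"
  bad_order <- is.na(reject) & !(c1$ordered & c2$ordered)
  reject[bad_order] <- "no_overlap"
  disagree <- is.na(reject) & c1$core != c2$core
  reject[disagree] <- "overlap_disagreement"
  core <- ifelse(is.na(reject), c1$core, NA_character_)
  data.frame(core = core, reject = reject, stringsAsFactors = FALSE)
}

#' Globally align a core sequence to the reference in codon units
#'
#' The dynamic-programming lattice indexes the reference in codons and the
#' read in nucleotides. Moves: consume one reference codon against three
#' read nucleotides (exact codon match scores `codon_match`, otherwise
#' `codon_mismatch`); delete 1-3 letters of a reference codon (one codon
#' consumed against 2-0 read nucleotides) at the constant `indel` penalty;
#' insert 1-3 read nucleotides at the constant `indel` penalty. Traceback
#' ties prefer codon substitution over indels, deletions over insertions and
#' longer indels over shorter, giving a deterministic optimum.
#'
#' @param core nucleotide string between the flanks.
#' @param ref an [amplicon_reference()].
#' @param scheme a [scoring_scheme()].
#' @param band maximum allowed `abs(nchar(core) - nchar(coding))` (default 9);
#'   beyond it the core is reported unalignable.
#' @return A list of class `alignment_result` with `score` (integer) and
#'   `edits` (data.frame `type` in sub/ins/del, `codon_index`, `length`,
#'   `observed_codon`), or with `unalignable = TRUE` when the band is
#'   exceeded.
#' @export
codon_align <- function(core, ref, scheme = scoring_scheme(), band = 9L) {
  core <- toupper(core)
  L <- nchar(core)
  C <- length(ref$codons)
  if (abs(L - 3L * C) > band) {
    return(structure(list(score = NA_integer_,
                          edits = empty_edits(), unalignable = TRUE),
                     class = "alignment_result"))
  }
  m <- scheme$codon_match; mm <- scheme$codon_mismatch; g <- scheme$indel
  read <- strsplit(core, "")[[1]]
  NEG <- -.Machine$integer.max %/% 4L
  S <- matrix(NEG, nrow = C + 1L, ncol = L + 1L)
  # move code: 0 none, 1 diag, 2 del3, 3 del2, 4 del1, 5 ins3, 6 ins2, 7 ins1
  M <- matrix(0L, nrow = C + 1L, ncol = L + 1L)
  S[1L, 1L] <- 0L
  for (i in 0:C) {
    for (j in 0:L) {
      if (i == 0L && j == 0L) next
      best <- NEG; mv <- 0L
      if (i >= 1L && j >= 3L) {
        obs <- paste(read[(j - 2L):j], collapse = "")
        sc <- S[i, j - 2L] + if (obs == ref$codons[i]) m else mm
        if (sc > best) { best <- sc; mv <- 1L }
      }
      if (i >= 1L) {                       # del3: skip whole codon
        sc <- S[i, j + 1L] + g
        if (sc > best) { best <- sc; mv <- 2L }
      }
      if (i >= 1L && j >= 1L) {            # del2: codon vs 1 read nt
        sc <- S[i, j] + g
        if (sc > best) { best <- sc; mv <- 3L }
      }
      if (i >= 1L && j >= 2L) {            # del1: codon vs 2 read nt
        sc <- S[i, j - 1L] + g
        if (sc > best) { best <- sc; mv <- 4L }
      }
      if (j >= 3L) {                       # ins3
        sc <- S[i + 1L, j - 2L] + g
        if (sc > best) { best <- sc; mv <- 5L }
      }
      if (j >= 2L) {                       # ins2
        sc <- S[i + 1L, j - 1L] + g
        if (sc > best) { best <- sc; mv <- 6L }
      }
      if (j >= 1L) {                       # ins1
        sc <- S[i + 1L, j] + g
        if (sc > best) { best <- sc; mv <- 7L }
      }
      S[i + 1L, j + 1L] <- best
      M[i + 1L, j + 1L] <- mv
    }
  }
  # traceback
  edits <- list()
  i <- C; j <- L
  while (i > 0L || j > 0L) {
    mv <- M[i + 1L, j + 1L]
    if (mv == 1L) {
      obs <- paste(read[(j - 2L):j], collapse = "")
      if (obs != ref$codons[i])
        edits[[length(edits) + 1L]] <- data.frame(
          type = "sub", codon_index = i, length = 3L, observed_codon = obs)
      i <- i - 1L; j <- j - 3L
    } else if (mv %in% c(2L, 3L, 4L)) {
      len <- c(3L, 2L, 1L)[mv - 1L]
      edits[[length(edits) + 1L]] <- data.frame(
        type = "del", codon_index = i, length = len,
        observed_codon = NA_character_)
      i <- i - 1L; j <- j - (3L - len)
    } else if (mv %in% c(5L, 6L, 7L)) {
      len <- c(3L, 2L, 1L)[mv - 4L]
      edits[[length(edits) + 1L]] <- data.frame(
        type = "ins", codon_index = i, length = len,
        observed_codon = NA_character_)
      j <- j - len
    } else stop("traceback failure")
  }
  edits <- if (length(edits)) do.call(rbind, rev(edits)) else empty_edits()
  structure(list(score = S[C + 1L, L + 1L], edits = edits,
                 unalignable = FALSE),
            class = "alignment_result")
}

empty_edits <- function() {
  data.frame(type = character(), codon_index = integer(),
             length = integer(), observed_codon = character())
}

#' Identify the variant carried by an aligned core
#'
#' A core with zero edits is wild type. Cores whose edits are exclusively
#' codon substitutions drawn from the expected codon set (programmed library
#' plus spike-ins) are accepted as `single` or `multiple` calls; any indel,
#' any unexpected codon, or an unalignable core is rejected with the
#' corresponding reason — this is what separates real programmed variants
#' from sequencing errors.
#'
#' @param aln an `alignment_result` from [codon_align()].
#' @param ref an [amplicon_reference()].
#' @param evs an [expected_variant_set()].
#' @return A list of class `variant_call` with `status` (`wildtype`,
#'   `single`, `multiple`, `rejected`), optional `reason` (`unexpected_codon`,
#'   `indel`, `unalignable`), `substitutions` data.frame (`codon_index`,
#'   `residue`, `wt_codon`, `observed_codon`, `wt_aa`, `mut_aa`,
#'   `variant_id`) and the combined `variant_id`.
#' @export
call_variant <- function(aln, ref, evs) {
  lk <- whitelist_lookup(evs)
  call_variant_impl(aln, ref, lk)
}

call_variant_impl <- function(aln, ref, lk) {
  rejected <- function(reason) {
    structure(list(status = "rejected", reason = reason,
                   substitutions = empty_subs(), variant_id = NA_character_),
              class = "variant_call")
  }
  if (isTRUE(aln$unalignable)) return(rejected("unalignable"))
  ed <- aln$edits
  if (any(ed$type %in% c("ins", "del"))) return(rejected("indel"))
  if (nrow(ed) == 0L) {
    return(structure(list(status = "wildtype", reason = NULL,
                          substitutions = empty_subs(), variant_id = "WT"),
                     class = "variant_call"))
  }
  subs <- vector("list", nrow(ed))
  for (k in seq_len(nrow(ed))) {
    i <- ed$codon_index[k]
    obs <- ed$observed_codon[k]
    ids <- lk[[as.character(i)]]
    vid <- if (!is.null(ids)) unname(ids[obs]) else NA_character_
    if (is.null(vid) || is.na(vid)) return(rejected("unexpected_codon"))
    subs[[k]] <- data.frame(
      codon_index = i, residue = ref$residues[i], wt_codon = ref$codons[i],
      observed_codon = obs, wt_aa = ref$aa[i],
      mut_aa = substr(vid, nchar(vid), nchar(vid)), variant_id = vid)
  }
  subs <- do.call(rbind, subs)
  id <- if (nrow(subs) == 1L) subs$variant_id else canonical_multi_id(subs$variant_id)
  structure(list(status = if (nrow(subs) == 1L) "single" else "multiple",
                 reason = NULL, substitutions = subs, variant_id = id),
            class = "variant_call")
}

empty_subs <- function() {
  data.frame(codon_index = integer(), residue = integer(),
             wt_codon = character(), observed_codon = character(),
             wt_aa = character(), mut_aa = character(),
             variant_id = character())
}

#' Tally variant calls into an allele count table
#'
#' @param calls data.frame with columns `variant_id`, `status`, `reason`
#'   (one row per read), or a list of `variant_call` objects.
#' @param sample,condition,replicate,role labels attached to every row.
#' @return A list of class `allele_counts` with `counts` (data.frame
#'   `sample`, `condition`, `replicate`, `role`, `variant_id`, `count` over
#'   accepted calls including `"WT"`), `rejected` (counts per reason) and
#'   `total` (accepted + rejected = number of input calls).
#' @export
count_alleles <- function(calls, sample = "sample", condition = "cond",
                          replicate = 1L, role = "selected") {
  if (!is.data.frame(calls)) {
    calls <- data.frame(
      variant_id = vapply(calls, function(x) x$variant_id %||% NA_character_, ""),
      status = vapply(calls, `[[`, "", "status"),
      reason = vapply(calls, function(x) x$reason %||% NA_character_, ""))
  }
  acc <- calls[calls$status != "rejected", , drop = FALSE]
  rej <- calls[calls$status == "rejected", , drop = FALSE]
  tab <- table(acc$variant_id)
  counts <- data.frame(sample = sample, condition = condition,
                       replicate = replicate, role = role,
                       variant_id = names(tab), count = as.integer(tab))
  rejected <- table(factor(rej$reason,
                           levels = c("flank_mismatch", "overlap_disagreement",
                                      "no_overlap", "unexpected_codon",
                                      "indel", "unalignable")))
  structure(list(counts = counts,
                 rejected = stats::setNames(as.integer(rejected), names(rejected)),
                 total = nrow(calls)),
            class = "allele_counts")
}

#' Call variants for a whole FASTQ pair
#'
#' Runs the full caller — pair merging with perfect-flank verification,
#' codon-unit alignment, expected-codon identification — over every read
#' pair of a sample. Cores whose length matches the reference and whose
#' optimal explanation is guaranteed to be substitution-only take a fast
#' vectorized path; all other cores go through the full dynamic program.
#'
#' @param fastq1,fastq2 FASTQ paths (mate 1 / mate 2).
#' @param ref an [amplicon_reference()].
#' @param evs an [expected_variant_set()].
#' @param scheme a [scoring_scheme()].
#' @param flank_len perfect-match anchor length (default 15).
#' @param band alignment band (default 9).
#' @param sample,condition,replicate,role sample labels for the count table.
#' @return An `allele_counts` object (see [count_alleles()]).
#' @export
call_fastq <- function(fastq1, fastq2, ref, evs, scheme = scoring_scheme(),
                       flank_len = 15L, band = 9L, sample = "sample",
                       condition = "cond", replicate = 1L, role = "selected") {
  r1 <- as.character(Biostrings::readDNAStringSet(fastq1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fastq2, format = "fastq"))
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  merged <- merge_pairs(r1, r2, ref, flank_len)
  calls <- call_cores(merged$core, ref, evs, scheme, band)
  calls$status[!is.na(merged$reject)] <- "rejected"
  calls$reason[!is.na(merged$reject)] <- merged$reject[!is.na(merged$reject)]
  calls$variant_id[!is.na(merged$reject)] <- NA_character_
  count_alleles(calls, sample, condition, replicate, role)
}

# Vectorized calling over a vector of cores (NA cores allowed; they come
# back as rejected placeholders and are overwritten by the merge reason).
call_cores <- function(cores, ref, evs, scheme = scoring_scheme(), band = 9L) {
  lk <- whitelist_lookup(evs)
  n <- length(cores)
  status <- rep("rejected", n)
  reason <- rep("unalignable", n)
  vid <- rep(NA_character_, n)

  uc <- unique(cores[!is.na(cores)])
  if (length(uc) == 0L)
    return(data.frame(variant_id = vid, status = status, reason = reason))

  C <- length(ref$codons)
  m <- scheme$codon_match; mm <- scheme$codon_mismatch; g <- scheme$indel
  res_status <- rep(NA_character_, length(uc))
  res_reason <- rep(NA_character_, length(uc))
  res_vid <- rep(NA_character_, length(uc))

  eq_len <- nchar(uc) == 3L * C
  if (any(eq_len)) {
    idx <- which(eq_len)
    sub_cores <- uc[idx]
    # codon matrix: one column per codon position
    obs <- vapply(seq_len(C), function(i)
      substr(sub_cores, 3L * i - 2L, 3L * i), character(length(sub_cores)))
    obs <- matrix(obs, nrow = length(sub_cores))
    mismatch <- sweep(obs, 2L, ref$codons, FUN = "!=")
    k <- rowSums(mismatch)
    # substitution-only explanation is provably optimal when its score beats
    # the best conceivable indel-bearing alignment (which spends >= 2 indel
    # penalties and loses >= 1 diagonal step)
    safe <- (C - k) * m + k * mm >= (C - 1) * m + 2 * g
    for (t in seq_along(idx)) {
      if (!safe[t]) next
      u <- idx[t]
      if (k[t] == 0L) {
        res_status[u] <- "wildtype"; res_vid[u] <- "WT"
        next
      }
      pos <- which(mismatch[t, ])
      ids <- character(length(pos))
      ok <- TRUE
      for (q in seq_along(pos)) {
        cand <- lk[[as.character(pos[q])]]
        v <- if (!is.null(cand)) unname(cand[obs[t, pos[q]]]) else NA_character_
        if (is.na(v)) { ok <- FALSE; break }
        ids[q] <- v
      }
      if (!ok) {
        res_status[u] <- "rejected"; res_reason[u] <- "unexpected_codon"
      } else if (length(ids) == 1L) {
        res_status[u] <- "single"; res_vid[u] <- ids
      } else {
        res_status[u] <- "multiple"; res_vid[u] <- canonical_multi_id(ids)
      }
    }
  }
  # everything unresolved goes through the full DP
  todo <- which(is.na(res_status))
  for (u in todo) {
    aln <- codon_align(uc[u], ref, scheme, band)
    cl <- call_variant_impl(aln, ref, lk)
    res_status[u] <- cl$status
    res_reason[u] <- cl$reason %||% NA_character_
    res_vid[u] <- cl$variant_id
  }
  hit <- match(cores, uc)
  has <- !is.na(hit)
  status[has] <- res_status[hit[has]]
  reason[has] <- res_reason[hit[has]]
  vid[has] <- res_vid[hit[has]]
  data.frame(variant_id = vid, status = status, reason = reason)
}
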