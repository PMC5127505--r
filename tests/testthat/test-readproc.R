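test_that("a perfect wild-type pair merges to the reference core", {
  p <- pair_for_core(default_ref$coding_sequence)
  m <- merge_and_verify(p$r1, p$r2, default_ref)
  expect_null(m$reject_reason)
  expect_equal(m$core_sequence, default_ref$coding_sequence)
})

test_that("a single mismatch inside a flank anchor rejects the pair", {
  p <- pair_for_core(default_ref$coding_sequence)
  r1 <- p$r1
  pos <- nchar(default_ref$upstream_flank)  # last base of the upstream anchor
  substr(r1, pos, pos) <- if (substr(r1, pos, pos) == "A") "C" else "A"
  m <- merge_and_verify(r1, p$r2, default_ref)
  expect_equal(m$reject_reason, "flank_mismatch")
})

test_that("mates disagreeing within the core are rejected", {
  core2 <- default_ref$coding_sequence
  substr(core2, 10, 10) <- if (substr(core2, 10, 10) == "A") "G" else "A"
  p1 <- pair_for_core(default_ref$coding_sequence)
  p2 <- pair_for_core(core2)
  m <- merge_and_verify(p1$r1, p2$r2, default_ref)
  expect_equal(m$reject_reason, "overlap_disagreement")
})

test_that("identity alignment scores all codon matches with no edits", {
  a <- codon_align(default_ref$coding_sequence, default_ref)
  expect_equal(a$score, 31L)
  expect_equal(nrow(a$edits), 0L)
})

test_that("one substituted codon costs exactly one mismatch", {
  id <- programmed_at(default_evs, 12L)
  a <- codon_align(core_for(id), default_ref)
  expect_equal(a$score, 30L - 1L)
  expect_equal(a$edits$type, "sub")
  expect_equal(a$edits$codon_index, 12L)
})

test_that("a 3-nt deletion costs one constant indel penalty", {
  core <- paste(default_ref$codons[-12], collapse = "")
  a <- codon_align(core, default_ref)
  expect_equal(a$score, 30L - 2L)
  expect_equal(a$edits$type, "del")
  expect_equal(a$edits$length, 3L)
})

test_that("1- and 2-nt deletions are single indel events", {
  core <- default_ref$coding_sequence
  for (len in 1:2) {
    trimmed <- paste0(substr(core, 1, 33), substr(core, 34 + len, nchar(core)))
    a <- codon_align(trimmed, default_ref)
    expect_equal(a$score, 30L - 2L)
    expect_true("del" %in% a$edits$type)
  }
})

test_that("cores beyond the length band are unalignable", {
  a <- codon_align(substr(default_ref$coding_sequence, 1, 60), default_ref,
                   band = 9L)
  expect_true(a$unalignable)
  cl <- call_variant(a, default_ref, default_evs)
  expect_equal(cl$status, "rejected")
  expect_equal(cl$reason, "unalignable")
})

test_that("variant calls map codon edits to residue numbers", {
  a0 <- codon_align(default_ref$coding_sequence, default_ref)
  expect_equal(call_variant(a0, default_ref, default_evs)$status, "wildtype")

  id <- programmed_at(default_evs, 10L)  # residue 1085
  cl <- call_variant(codon_align(core_for(id), default_ref),
                     default_ref, default_evs)
  expect_equal(cl$status, "single")
  expect_equal(cl$substitutions$residue,
               default_ref$first_residue_number + 10L - 1L)
  expect_equal(cl$variant_id, id)
})

test_that("unprogrammed codons (sequencing errors) are rejected", {
  core <- default_ref$coding_sequence
  # GCT -> GAT at codon 1: aspartate is programmed via GAC, not GAT
  substr(core, 2, 2) <- "A"
  cl <- call_variant(codon_align(core, default_ref), default_ref, default_evs)
  expect_equal(cl$status, "rejected")
  expect_equal(cl$reason, "unexpected_codon")
})

test_that("indel-bearing cores are rejected for counting", {
  core <- paste(default_ref$codons[-5], collapse = "")
  cl <- call_variant(codon_align(core, default_ref), default_ref, default_evs)
  expect_equal(cl$status, "rejected")
  expect_equal(cl$reason, "indel")
})

test_that("single-nucleotide errors are rejected at >= 99% under a distance-2 whitelist", {
  # The rejection guarantee holds when every whitelisted codon is >= 2
  # changes from its wild-type codon. Methionine and tryptophan have a
  # single codon, so a handful of positions cannot satisfy this; restrict
  # the whitelist to the distance->=2 entries (the vast majority) as the
  # guarantee's premise requires.
  ham <- function(a, b) mapply(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b)
  prog <- default_evs$programmed
  prog2 <- prog[ham(prog$mut_codon, default_ref$codons[prog$codon_index]) >= 2, ]
  evs2 <- expected_variant_set(prog2, default_evs$excluded,
                               default_evs$spike_ins[0, ], default_ref)
  set.seed(42)
  n <- 500L
  core <- default_ref$coding_sequence
  L <- nchar(core)
  cores <- vapply(seq_len(n), function(i) {
    p <- sample.int(L, 1)
    s <- core
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, p, p)), 1)
    s
  }, "")
  calls <- codonscan:::call_cores(cores, default_ref, evs2)
  expect_gte(mean(calls$status == "rejected"), 0.99)
  # with the full default whitelist the only leaks are codons that no
  # synonym can place 2 changes from wild type (single-codon amino acids
  # and wobble pairs); errors are still overwhelmingly rejected
  calls_full <- codonscan:::call_cores(cores, default_ref, default_evs)
  expect_gte(mean(calls_full$status == "rejected"), 0.9)
})

test_that("allele counting conserves reads across accepted and rejected", {
  calls <- data.frame(
    variant_id = c(rep("WT", 100), rep("H1085Y", 50), rep(NA, 10)),
    status = c(rep("wildtype", 100), rep("single", 50), rep("rejected", 10)),
    reason = c(rep(NA, 150), rep("unexpected_codon", 10)))
  ac <- count_alleles(calls, sample = "s1")
  got <- setNames(ac$counts$count, ac$counts$variant_id)
  expect_equal(got[["WT"]], 100L)
  expect_equal(got[["H1085Y"]], 50L)
  expect_equal(unname(ac$rejected["unexpected_codon"]), 10L)
  expect_equal(sum(ac$counts$count) + sum(ac$rejected), ac$total)
})

test_that("score decomposition holds for mixed-edit alignments", {
  # one substitution + one codon deletion
  codons <- default_ref$codons
  codons[7] <- default_evs$programmed$mut_codon[
    default_evs$programmed$codon_index == 7][1]
  core <- paste(codons[-20], collapse = "")
  a <- codon_align(core, default_ref)
  n_sub <- sum(a$edits$type == "sub")
  n_indel <- sum(a$edits$type != "sub")
  n_match <- 31L - n_sub - sum(a$edits$type == "del")
  expect_equal(a$score, n_match * 1L + n_sub * -1L + n_indel * -2L)
})
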