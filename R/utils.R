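`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible per-stage seed from a global seed
#'
#' Pipeline stages draw their own random numbers; deriving each stage's seed
#' deterministically from the single user-facing seed keeps every stage
#' individually re-runnable without sharing RNG state.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage (e.g. `"simulate"`).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

#' Parse variant identifiers of the form H1085Y (singles, '+'-joined multiples)
#'
#' @param ids character vector of variant ids; `"WT"` is allowed and yields a
#'   zero-row entry.
#' @return A data.frame with columns `id`, `wt_aa`, `residue`, `mut_aa`, one
#'   row per single substitution (multiples contribute several rows).
#' @export
parse_variant_id <- function(ids) {
  parts <- strsplit(ids, "+", fixed = TRUE)
  out <- lapply(seq_along(ids), function(k) {
    ps <- parts[[k]]
    ps <- ps[ps != "WT"]
    if (length(ps) == 0L) {
      return(data.frame(id = character(), wt_aa = character(),
                        residue = integer(), mut_aa = character()))
    }
    m <- regmatches(ps, regexec("^([A-Z*])([0-9]+)([A-Z*])$", ps))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad)) stop("malformed variant id: ", paste(ps[bad], collapse = ", "))
    data.frame(
      id = rep(ids[k], length(ps)),
      wt_aa = vapply(m, `[`, "", 2L),
      residue = as.integer(vapply(m, `[`, "", 3L)),
      mut_aa = vapply(m, `[`, "", 4L)
    )
  })
  do.call(rbind, out)
}

#' Canonical id for a multi-substitution variant
#'
#' Substitutions are ordered by residue number, then by mutant amino acid, and
#' joined with `+`, so that the same combination always maps to one id.
#'
#' @param single_ids character vector of single-substitution ids.
#' @return A single character id.
#' @export
canonical_multi_id <- function(single_ids) {
  p <- parse_variant_id(single_ids)
  o <- order(p$residue, p$mut_aa)
  paste(single_ids[o], collapse = "+")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
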