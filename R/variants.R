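# The programmed library: which mutant codon encodes each amino-acid
# substitution at each position, which substitutions were deliberately left
# out of synthesis, and which excluded variants were spiked back in as
# internal controls.

#' Construct an expected variant set
#'
#' @param programmed data.frame with columns `codon_index`, `residue`,
#'   `wt_aa`, `mut_aa`, `wt_codon`, `mut_codon`, `variant_id`: one row per
#'   programmed single-codon substitution.
#' @param excluded data.frame with columns `residue`, `mut_aa`, `variant_id`:
#'   substitutions deliberately left out of library synthesis.
#' @param spike_ins data.frame with columns `variant_id`, `codon_index`,
#'   `residue`, `wt_aa`, `mut_aa`, `mut_codon`, `fraction`: excluded variants
#'   added back to the pool at known fractions as controls.
#' @param ref the [amplicon_reference()] the set belongs to.
#' @return An object of class `expected_variant_set`.
#' @export
expected_variant_set <- function(programmed, excluded, spike_ins, ref) {
  stopifnot(is.data.frame(programmed), is.data.frame(excluded),
            is.data.frame(spike_ins))
  wt <- ref$codons[programmed$codon_index]
  if (any(programmed$mut_codon == wt))
    stop("programmed mutant codons must differ from the wild-type codon")
  if (any(paste(excluded$residue, excluded$mut_aa) %in%
          paste(programmed$residue, programmed$mut_aa)))
    stop("excluded variants must be absent from the programmed set")
  if (nrow(spike_ins) > 0) {
    if (any(spike_ins$fraction <= 0 | spike_ins$fraction >= 1) ||
        sum(spike_ins$fraction) >= 1)
      stop("spike-in fractions must lie in (0,1) and sum to < 1")
  }
  structure(list(programmed = programmed, excluded = excluded,
                 spike_ins = spike_ins, ref = ref),
            class = "expected_variant_set")
}

#' @export
print.expected_variant_set <- function(x, ...) {
  cat(sprintf(
    "expected_variant_set: %d programmed substitutions, %d excluded, %d spike-ins\n",
    nrow(x$programmed), nrow(x$excluded), nrow(x$spike_ins)))
  invisible(x)
}

# Pick the programmed codon for a substitution: the first synonym at Hamming
# distance >= 2 from the wild-type codon, falling back to the most distant
# synonym. Keeping programmed codons >= 2 changes away from wild type means a
# single sequencing error on a wild-type read can never land on a whitelisted
# codon, which is what lets the caller reject errors.
choose_mutant_codon <- function(wt_codon, mut_aa) {
  syns <- codon_synonyms(mut_aa)
  d <- vapply(syns, hamming, 0, b = wt_codon)
  ok <- syns[d >= 2]
  if (length(ok) > 0) ok[[1]] else syns[[which.max(d)]]
}

#' Build the default expected variant set for a reference
#'
#' Programs every amino-acid substitution (19 per position) at every codon,
#' minus the excluded list. The default exclusions are the five
#' well-characterized substitutions that are spiked back into the pool as
#' controls: H1085Y, H1085Q, F1086S, G1097D and E1103G (loss-of-function
#' anchors H1085Y/H1085Q/F1086S; gain-of-function anchors G1097D/E1103G).
#'
#' @param ref an [amplicon_reference()].
#' @param excluded data.frame(`residue`, `mut_aa`) of substitutions withheld
#'   from synthesis; defaults to the five spike-in controls.
#' @param spike_in_ids character vector of excluded variant ids re-added as
#'   spike-ins (must be a subset of the exclusions).
#' @param spike_in_fraction pool fraction given to each spike-in
#'   (default 0.01).
#' @return An [expected_variant_set()].
#' @examples
#' evs <- make_variant_set(make_reference())
#' nrow(evs$programmed)
#' @export
make_variant_set <- function(ref,
                             excluded = NULL,
                             spike_in_ids = c("H1085Y", "H1085Q", "F1086S",
                                              "G1097D", "E1103G"),
                             spike_in_fraction = 0.01) {
  aa20 <- names(preferred_codon)
  n <- length(ref$codons)
  if (is.null(excluded)) {
    p <- parse_variant_id(spike_in_ids)
    excluded <- data.frame(residue = p$residue, mut_aa = p$mut_aa)
  }
  excluded$variant_id <- paste0(
    ref$aa[match(excluded$residue, ref$residues)], excluded$residue, excluded$mut_aa)

  rows <- list()
  for (i in seq_len(n)) {
    wt_aa <- ref$aa[i]
    res <- ref$residues[i]
    for (m in setdiff(aa20, wt_aa)) {
      if (any(excluded$residue == res & excluded$mut_aa == m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        codon_index = i, residue = res, wt_aa = wt_aa, mut_aa = m,
        wt_codon = ref$codons[i],
        mut_codon = choose_mutant_codon(ref$codons[i], m),
        variant_id = paste0(wt_aa, res, m)
      )
    }
  }
  programmed <- do.call(rbind, rows)

  spikes <- excluded[excluded$variant_id %in% spike_in_ids, , drop = FALSE]
  if (nrow(spikes) < length(spike_in_ids))
    stop("spike-ins must come from the excluded list")
  idx <- match(spikes$residue, ref$residues)
  spike_ins <- data.frame(
    variant_id = spikes$variant_id,
    codon_index = idx,
    residue = spikes$residue,
    wt_aa = ref$aa[idx],
    mut_aa = spikes$mut_aa,
    mut_codon = vapply(seq_len(nrow(spikes)), function(k)
      choose_mutant_codon(ref$codons[idx[k]], spikes$mut_aa[k]), ""),
    fraction = rep(spike_in_fraction, nrow(spikes))
  )
  expected_variant_set(programmed, excluded, spike_ins, ref)
}

# All accepted (whitelisted) codons per codon index: programmed plus
# spike-in codons.
whitelist_table <- function(evs) {
  w <- rbind(
    data.frame(codon_index = evs$programmed$codon_index,
               mut_codon = evs$programmed$mut_codon,
               variant_id = evs$programmed$variant_id),
    data.frame(codon_index = evs$spike_ins$codon_index,
               mut_codon = evs$spike_ins$mut_codon,
               variant_id = evs$spike_ins$variant_id)
  )
  unique(w)
}

#' Write / read the expected-codon whitelist as TSV
#'
#' Columns: `codon_index`, `mut_codon`, `variant_id`. The whitelist is the
#' union of programmed and spike-in codons and is what the variant caller
#' checks observed codons against.
#'
#' @param evs an [expected_variant_set()].
#' @param path TSV path.
#' @export
write_whitelist <- function(evs, path) {
  write_tsv_plain(whitelist_table(evs), path)
  invisible(path)
}

#' @rdname write_whitelist
#' @param ref reference used to reconstruct wild-type annotation.
#' @export
read_whitelist <- function(path, ref) {
  w <- read_tsv_plain(path)
  stopifnot(all(c("codon_index", "mut_codon", "variant_id") %in% names(w)))
  idx <- w$codon_index
  p <- parse_variant_id(w$variant_id)
  programmed <- data.frame(
    codon_index = idx, residue = ref$residues[idx], wt_aa = ref$aa[idx],
    mut_aa = p$mut_aa[match(w$variant_id, p$id)],
    wt_codon = ref$codons[idx], mut_codon = w$mut_codon,
    variant_id = w$variant_id
  )
  expected_variant_set(programmed,
                       excluded = data.frame(residue = integer(),
                                             mut_aa = character(),
                                             variant_id = character()),
                       spike_ins = data.frame(variant_id = character(),
                                              codon_index = integer(),
                                              residue = integer(),
                                              wt_aa = character(),
                                              mut_aa = character(),
                                              mut_codon = character(),
                                              fraction = numeric()),
                       ref = ref)
}

# Lookup helpers -------------------------------------------------------------

# named list: codon_index -> named character vector mut_codon -> variant_id
whitelist_lookup <- function(evs) {
  w <- whitelist_table(evs)
  split_ids <- split(seq_len(nrow(w)), w$codon_index)
  lk <- lapply(split_ids, function(ii) {
    v <- w$variant_id[ii]
    names(v) <- w$mut_codon[ii]
    v
  })
  lk
}
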