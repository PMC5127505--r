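# Shared fixtures: small references and variant sets built in code.

tiny_ref <- function(n_codons = 5L, first_residue = 101L) {
  aa <- c("M", "H", "F", "G", "E", "K")[seq_len(n_codons)]
  make_reference(amino_acids = paste(aa, collapse = ""),
                 first_residue_number = first_residue)
}

tiny_evs <- function(ref = tiny_ref()) {
  make_variant_set(ref, excluded = data.frame(residue = integer(),
                                              mut_aa = character()),
                   spike_in_ids = character(0))
}

default_ref <- make_reference()
default_evs <- make_variant_set(default_ref)

# ids of a few programmed variants at given codon indices
programmed_at <- function(evs, codon_index, n = 1L) {
  ids <- evs$programmed$variant_id[evs$programmed$codon_index == codon_index]
  head(ids, n)
}

# build a core sequence carrying the given programmed variant ids
core_for <- function(ids, ref = default_ref, evs = default_evs) {
  codons <- ref$codons
  w <- rbind(evs$programmed[c("codon_index", "mut_codon", "variant_id")],
             evs$spike_ins[c("codon_index", "mut_codon", "variant_id")])
  for (id in ids) {
    row <- w[w$variant_id == id, ][1, ]
    codons[row$codon_index] <- row$mut_codon
  }
  paste(codons, collapse = "")
}

# wrap a core in flanks to make a perfect read pair
pair_for_core <- function(core, ref = default_ref) {
  amp <- paste0(ref$upstream_flank, core, ref$downstream_flank)
  list(r1 = amp, r2 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(amp))))
}

adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
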