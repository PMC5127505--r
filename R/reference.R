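# Amplicon reference: the wild-type coding sequence of the mutagenized
# region plus flanking sequence and the residue-numbering offset that maps
# codon 1 onto the protein coordinate system.

#' Construct an amplicon reference
#'
#' @param coding_sequence wild-type coding sequence of the mutagenized region
#'   (A/C/G/T, length divisible by 3, no internal stop codon).
#' @param first_residue_number residue number of codon 1 (default 1076, the
#'   first trigger-loop residue of Rpb1).
#' @param upstream_flank,downstream_flank constant flanking sequence on each
#'   side of the coding region; at least 15 nt each, used for perfect-match
#'   read anchoring.
#' @return An object of class `amplicon_reference` with fields
#'   `coding_sequence`, `first_residue_number`, `upstream_flank`,
#'   `downstream_flank`, plus derived `codons`, `aa` (translation) and
#'   `residues` (residue numbers per codon).
#' @export
amplicon_reference <- function(coding_sequence, first_residue_number = 1076L,
                               upstream_flank, downstream_flank) {
  coding_sequence <- toupper(coding_sequence)
  upstream_flank <- toupper(upstream_flank)
  downstream_flank <- toupper(downstream_flank)
  for (s in c(coding_sequence, upstream_flank, downstream_flank)) {
    if (grepl("[^ACGT]", s)) stop("reference sequences must contain only A, C, G, T")
  }
  if (nchar(coding_sequence) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3")
  if (nchar(upstream_flank) < 15L || nchar(downstream_flank) < 15L)
    stop("flanks must be at least 15 nt")
  n <- nchar(coding_sequence) %/% 3L
  codons <- substring(coding_sequence, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- translate_codons(codons)
  if (any(aa == "*")) stop("coding sequence contains an internal stop codon")
  structure(list(
    coding_sequence = coding_sequence,
    first_residue_number = as.integer(first_residue_number),
    upstream_flank = upstream_flank,
    downstream_flank = downstream_flank,
    codons = codons,
    aa = aa,
    residues = as.integer(first_residue_number) + seq_len(n) - 1L
  ), class = "amplicon_reference")
}

#' Translate a vector of codons with the standard genetic code
#' @param codons character vector of 3-nt codons.
#' @return Character vector of one-letter amino acids (`*` for stop).
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[toupper(codons)])
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("amplicon_reference: %d codons, residues %d-%d\n",
              length(x$codons), x$residues[1], x$residues[length(x$residues)]))
  cat(" translation:", paste(x$aa, collapse = ""), "\n")
  invisible(x)
}

# One representative (roughly yeast-preferred) codon per amino acid; used to
# construct the synthetic wild-type sequence and as the head of the synonym
# list when choosing programmed mutant codons.
preferred_codon <- c(
  A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "TTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

codon_synonyms <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  cods <- names(gc)[gc == aa]
  # keep the preferred codon first, rest in fixed alphabetical order
  pref <- preferred_codon[[aa]]
  c(pref, sort(setdiff(cods, pref)))
}

# Wild-type amino acids of the trigger-loop region at their published
# positions. Residues not individually named in the source literature carry
# fixed synthetic placeholders (marked FALSE in `known`); the packaged default
# reference is therefore a synthetic stand-in that preserves positional
# semantics, and any real reference can be supplied as FASTA + offset.
tl_wt_aa <- function() {
  aa <- c(
    "A",  # 1076
    "G",  # 1077 synthetic placeholder
    "Q",  # 1078
    "M",  # 1079
    "T",  # 1080
    "L",  # 1081
    "N",  # 1082
    "T",  # 1083 synthetic placeholder
    "S",  # 1084 synthetic placeholder
    "H",  # 1085
    "F",  # 1086
    "A",  # 1087
    "G",  # 1088
    "V",  # 1089
    "A",  # 1090
    "S",  # 1091
    "K",  # 1092
    "K",  # 1093
    "V",  # 1094
    "N",  # 1095 synthetic placeholder
    "S",  # 1096
    "G",  # 1097
    "E",  # 1098 synthetic placeholder
    "P",  # 1099
    "I",  # 1100 synthetic placeholder
    "L",  # 1101
    "D",  # 1102 synthetic placeholder
    "E",  # 1103
    "T",  # 1104 synthetic placeholder
    "A",  # 1105 synthetic placeholder
    "R"   # 1106 synthetic placeholder
  )
  names(aa) <- 1076:1106
  aa
}

#' Build an amplicon reference from configuration
#'
#' Either an explicit nucleotide `coding_sequence` or an `amino_acids` string
#' (back-translated with one fixed representative codon per residue) can be
#' supplied. With no arguments the packaged default is returned: a 31-codon
#' amplicon spanning trigger-loop residues 1076-1106 whose translation carries
#' the wild-type identities at the positions characterized in the literature
#' and fixed synthetic placeholders elsewhere.
#'
#' @param coding_sequence optional explicit coding sequence.
#' @param amino_acids optional amino-acid string to back-translate.
#' @param first_residue_number residue number of the first codon.
#' @param upstream_flank,downstream_flank flanking sequences; packaged
#'   synthetic defaults are used when omitted.
#' @return An [amplicon_reference()].
#' @examples
#' ref <- make_reference()
#' length(ref$codons)  # 31
#' @export
make_reference <- function(coding_sequence = NULL, amino_acids = NULL,
                           first_residue_number = 1076L,
                           upstream_flank = NULL, downstream_flank = NULL) {
  up <- upstream_flank %||% "TCGGAGATTCACCGTAGGCAACGATTCTCC"
  dn <- downstream_flank %||% "GGATCCTTAGCACGTTCAACGCTGGTTGAG"
  if (is.null(coding_sequence)) {
    aa <- if (is.null(amino_acids)) paste(tl_wt_aa(), collapse = "") else toupper(amino_acids)
    aas <- strsplit(aa, "")[[1]]
    if (!all(aas %in% names(preferred_codon)))
      stop("amino-acid string contains unsupported letters")
    coding_sequence <- paste(preferred_codon[aas], collapse = "")
  }
  amplicon_reference(coding_sequence, first_residue_number, up, dn)
}

#' Write / read an amplicon reference as FASTA
#'
#' The FASTA holds three records (`upstream_flank`, `coding`, and
#' `downstream_flank`); the residue offset is carried in the `coding` header
#' as `offset=<n>`.
#'
#' @param ref an [amplicon_reference()].
#' @param path output / input FASTA path.
#' @return `write_reference_fasta` returns `path` invisibly;
#'   `read_reference_fasta` returns an [amplicon_reference()].
#' @export
write_reference_fasta <- function(ref, path) {
  seqs <- Biostrings::DNAStringSet(c(ref$upstream_flank, ref$coding_sequence,
                                     ref$downstream_flank))
  names(seqs) <- c("upstream_flank",
                   sprintf("coding offset=%d", ref$first_residue_number),
                   "downstream_flank")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  coding_i <- grep("^coding", nm)
  if (length(coding_i) != 1L) stop("FASTA must contain exactly one 'coding' record")
  off <- sub(".*offset=([0-9]+).*", "\\1", nm[coding_i])
  amplicon_reference(
    as.character(seqs[[coding_i]]),
    first_residue_number = as.integer(off),
    upstream_flank = as.character(seqs[[grep("^upstream", nm)]]),
    downstream_flank = as.character(seqs[[grep("^downstream", nm)]])
  )
}
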