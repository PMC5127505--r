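# Synthetic screen generator: class-structured true enrichment effects,
# pooled selection by multinomial resampling, PCR template switching at the
# molecule level, and paired-end FASTQ rendering with sequencing error.

#' Default growth-condition panel of the simulated screen
#'
#' Seven conditions with class-specific phenotype signatures (galactose,
#' mycophenolic acid, the Spt reporter, manganese, formamide, caffeine,
#' cycloheximide) plus seven generic stress conditions with no class effect.
#' @return Character vector of 14 condition names.
#' @export
default_conditions <- function() {
  c("Gal", "MPA", "Spt", "Mn", "Formamide", "Caffeine", "Cyclohex",
    "HighTemp", "LowTemp", "NaCl", "HU", "Raff", "EtOH", "Glycerol")
}

# Qualitative condition signatures of the three mutant classes, in log2
# enrichment units with |effect| = 2 for strong phenotypes:
#   Class 1 (loss of function): strong galactose resistance, slight MPA
#     resistance, formamide hypersensitivity.
#   Class 2: weak galactose resistance, slight formamide resistance.
#   Class 3 (gain of function): galactose resistance, Spt- (growth on the
#     lysine reporter), MPA / Mn / caffeine / cycloheximide sensitivity.
# Magnitudes are free parameters of the generator; only the signs are
# anchored to the screen's reported class signatures.

#' Default class-by-condition true-effect table
#'
#' Mean true log2 enrichment per mutant class and condition. Class 1
#' (loss of function): strong galactose resistance, slight MPA resistance,
#' formamide hypersensitivity. Class 2: weak galactose resistance, slight
#' formamide resistance. Class 3 (gain of function): galactose resistance,
#' Spt- reporter growth, MPA / Mn / caffeine / cycloheximide sensitivity.
#' Strong phenotypes use |effect| = 2 log2 units; a `Neutral` row is all
#' zero.
#'
#' @param conditions condition names (default [default_conditions()]).
#' @return Numeric matrix, 4 classes x conditions.
#' @export
default_class_effects <- function(conditions = default_conditions()) {
  m <- matrix(0, nrow = 4, ncol = length(conditions),
              dimnames = list(c("Class1", "Class2", "Class3", "Neutral"),
                              conditions))
  set_if <- function(cls, cond, val) {
    j <- intersect(cond, conditions)
    m[cls, j] <<- val
  }
  set_if("Class1", "Gal", 2); set_if("Class1", "MPA", 1)
  set_if("Class1", "Formamide", -2)
  set_if("Class2", "Gal", 1); set_if("Class2", "Formamide", 1)
  set_if("Class3", "Gal", 2); set_if("Class3", "Spt", 2)
  set_if("Class3", "MPA", -2); set_if("Class3", "Mn", -2)
  set_if("Class3", "Caffeine", -2); set_if("Class3", "Cyclohex", -2)
  m
}

#' Configuration of class-structured true effects
#'
#' Defines the generative model for per-variant, per-condition true log2
#' enrichment effects: each variant belongs to one of three phenotype classes
#' or to a neutral remainder, and its effects are the class's condition
#' signature plus Gaussian per-cell noise.
#'
#' @param conditions ordered character vector of condition names (default 14).
#' @param class_effects numeric matrix class x condition of mean true log2
#'   enrichments; rownames are class names, the last class is expected to be
#'   `"Neutral"` with zero effects.
#' @param class_proportions named numeric vector of variant fractions per
#'   class (must sum to 1).
#' @param noise_sd standard deviation of per-variant-per-condition effect
#'   noise (log2 units, default 0.3).
#' @param seed integer seed for class assignment and noise.
#' @return An object of class `class_profile_config`.
#' @export
class_profile_config <- function(conditions = default_conditions(),
                                 class_effects = default_class_effects(conditions),
                                 class_proportions = c(Class1 = 0.35, Class2 = 0.30,
                                                       Class3 = 0.25, Neutral = 0.10),
                                 noise_sd = 0.3, seed = 1L) {
  if (anyDuplicated(conditions)) stop("conditions must be unique")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(names(class_proportions) %in% rownames(class_effects)))
    stop("every class in class_proportions needs a row in class_effects")
  structure(list(conditions = conditions, class_effects = class_effects,
                 class_proportions = class_proportions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "class_profile_config")
}

# Spike-in controls carry known phenotype classes and anchor cluster naming.
spike_in_classes <- function() {
  c(H1085Y = "Class1", H1085Q = "Class1", F1086S = "Class1",
    G1097D = "Class3", E1103G = "Class3")
}

#' Draw class labels and true effects for a set of variants
#'
#' Spike-in control variants present among `variant_ids` receive their known
#' classes (loss-of-function spike-ins H1085Y/H1085Q/F1086S are Class 1;
#' gain-of-function spike-ins G1097D/E1103G are Class 3); all other variants
#' are assigned classes at the configured proportions.
#'
#' @param variant_ids character vector of pooled variant ids (no `"WT"`).
#' @param config a [class_profile_config()].
#' @return List with `effects` (variant x condition numeric matrix of true
#'   log2 enrichments) and `classes` (named character vector).
#' @export
simulate_true_effects <- function(variant_ids, config = class_profile_config()) {
  set.seed(config$seed)
  anchors <- spike_in_classes()
  classes <- stats::setNames(rep(NA_character_, length(variant_ids)), variant_ids)
  is_anchor <- variant_ids %in% names(anchors)
  classes[is_anchor] <- anchors[variant_ids[is_anchor]]
  free <- which(!is_anchor)
  classes[free] <- sample(names(config$class_proportions), length(free),
                          replace = TRUE, prob = config$class_proportions)
  eff <- config$class_effects[classes, , drop = FALSE]
  eff <- eff + matrix(stats::rnorm(length(eff), 0, config$noise_sd),
                      nrow = nrow(eff))
  dimnames(eff) <- list(variant_ids, config$conditions)
  list(effects = eff, classes = classes)
}

#' Bundle everything the pooled-selection simulator needs
#'
#' @param pool_fractions named vector of unselected pool fractions per
#'   variant (see [make_library()]); wild type implicitly holds
#'   `1 - sum(pool_fractions)`.
#' @param true_effects variant x condition matrix of true log2 enrichments;
#'   wild type is fixed at effect 0.
#' @param depth reads per sample.
#' @param n_replicates independent biological replicates (default 3).
#' @param pool_condition name of the unselected (transformed pool) sample
#'   condition (default `"SC-Leu"`).
#' @param error_rate per-nucleotide substitution error probability for read
#'   rendering.
#' @param template_switch_rate probability that a read is a PCR chimera of
#'   two pool molecules.
#' @param pcr_mode `"regular"` or `"emulsion"`; emulsion divides the switch
#'   rate by `switch_suppression`.
#' @param switch_suppression fold suppression of template switching by
#'   emulsion PCR (default 2.5).
#' @param seed integer seed.
#' @return An object of class `simulated_screen`.
#' @export
simulated_screen <- function(pool_fractions, true_effects, depth = 1e5,
                             n_replicates = 3L, pool_condition = "SC-Leu",
                             error_rate = 0.001, template_switch_rate = 0,
                             pcr_mode = c("emulsion", "regular"),
                             switch_suppression = 2.5, seed = 1L) {
  pcr_mode <- match.arg(pcr_mode)
  if (any(pool_fractions < 0) || sum(pool_fractions) > 1 + 1e-12)
    stop("pool fractions must be non-negative and sum to <= 1")
  if (depth <= 0) stop("depth must be positive")
  for (r in c(error_rate, template_switch_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  missing_eff <- setdiff(names(pool_fractions), rownames(true_effects))
  if (length(missing_eff))
    stop("true effects missing for pooled variants: ",
         paste(utils::head(missing_eff, 3), collapse = ", "))
  structure(list(pool_fractions = pool_fractions, true_effects = true_effects,
                 depth = as.integer(depth), n_replicates = as.integer(n_replicates),
                 pool_condition = pool_condition, error_rate = error_rate,
                 template_switch_rate = template_switch_rate, pcr_mode = pcr_mode,
                 switch_suppression = switch_suppression, seed = as.integer(seed)),
            class = "simulated_screen")
}

#' Simulate pooled selection as per-sample multinomial read counts
#'
#' Unselected samples are multinomial draws from the pool composition;
#' selected samples draw from frequencies proportional to
#' `pool_fraction * 2^effect`, renormalized with the wild-type effect fixed
#' at 0 so that enrichment is always relative to wild type.
#'
#' @param screen a [simulated_screen()].
#' @return Long data.frame with columns `sample`, `condition`, `replicate`,
#'   `role` (`unselected`/`selected`), `variant_id` (including `"WT"`),
#'   `count`. Per-sample counts sum to `depth`.
#' @export
simulate_selection <- function(screen) {
  fr <- screen$pool_fractions
  wt <- 1 - sum(fr)
  ids <- c(names(fr), "WT")
  conds <- colnames(screen$true_effects)
  out <- list()
  for (r in seq_len(screen$n_replicates)) {
    set.seed(derive_seed(screen$seed, paste0("pool_rep", r)))
    cnt <- as.vector(stats::rmultinom(1, screen$depth, c(fr, wt)))
    out[[length(out) + 1L]] <- data.frame(
      sample = sprintf("%s_rep%d", screen$pool_condition, r),
      condition = screen$pool_condition, replicate = r, role = "unselected",
      variant_id = ids, count = cnt)
    for (cond in conds) {
      w <- fr * 2^screen$true_effects[names(fr), cond]
      p <- c(w, wt)  # wild-type effect fixed at 0
      p <- p / sum(p)
      set.seed(derive_seed(screen$seed, paste0(cond, "_rep", r)))
      cnt <- as.vector(stats::rmultinom(1, screen$depth, p))
      out[[length(out) + 1L]] <- data.frame(
        sample = sprintf("%s_rep%d", cond, r),
        condition = cond, replicate = r, role = "selected",
        variant_id = ids, count = cnt)
    }
  }
  do.call(rbind, out)
}

# map single-substitution variant id -> codon index, for all singles known
# to the expected variant set
single_position_map <- function(evs) {
  c(stats::setNames(evs$programmed$codon_index, evs$programmed$variant_id),
    stats::setNames(evs$spike_ins$codon_index, evs$spike_ins$variant_id))
}

#' Apply PCR template switching to a sample's molecule counts
#'
#' Each read is, with the effective switch probability, a single-crossover
#' recombinant of two independently drawn pool molecules. When the two
#' parents are single-substitution variants at distinct codons the chimera is
#' observed as a double mutant (the crossover is taken to fall between the
#' two mutated codons); in every other pairing the chimera is
#' indistinguishable from its first parent. Emulsion PCR divides the switch
#' rate by `suppression`.
#'
#' @param counts named integer vector of molecule counts (including `"WT"`).
#' @param evs an [expected_variant_set()] used to place single substitutions.
#' @param rate template-switch probability per read (regular-PCR scale).
#' @param pcr_mode `"regular"` or `"emulsion"`.
#' @param suppression emulsion-PCR fold suppression (default 2.5).
#' @param seed integer seed.
#' @return Named integer vector of counts with chimeric doubles added;
#'   total count is conserved.
#' @export
apply_template_switching <- function(counts, evs, rate,
                                     pcr_mode = c("regular", "emulsion"),
                                     suppression = 2.5, seed = 1L) {
  pcr_mode <- match.arg(pcr_mode)
  if (rate < 0 || rate > 1) stop("switch rate must lie in [0, 1]")
  p <- if (pcr_mode == "emulsion") rate / suppression else rate
  if (p == 0) return(counts)
  set.seed(seed)
  depth <- sum(counts)
  n_sw <- stats::rbinom(1, depth, p)
  if (n_sw == 0) return(counts)
  freqs <- counts / depth
  pos <- single_position_map(evs)
  ids <- names(counts)
  p1 <- sample(ids, n_sw, replace = TRUE, prob = freqs)
  p2 <- sample(ids, n_sw, replace = TRUE, prob = freqs)
  i1 <- pos[p1]; i2 <- pos[p2]
  is_double <- !is.na(i1) & !is.na(i2) & i1 != i2 &
    !grepl("+", p1, fixed = TRUE) & !grepl("+", p2, fixed = TRUE)
  if (!any(is_double)) return(counts)
  d1 <- p1[is_double]; d2 <- p2[is_double]
  j1 <- i1[is_double]; j2 <- i2[is_double]
  # canonical double id: substitutions ordered by position along the gene
  dbl <- ifelse(j1 < j2, paste(d1, d2, sep = "+"), paste(d2, d1, sep = "+"))
  # each double event converts one parent-1 molecule into the chimera
  dec <- table(d1)
  avail <- pmin(as.integer(dec), counts[names(dec)])
  short <- as.integer(dec) - avail
  counts[names(dec)] <- counts[names(dec)] - avail
  # drop (rare) events whose parent pool is exhausted, keeping totals exact
  if (any(short > 0)) {
    drop_ids <- names(dec)[short > 0]
    drop_n <- stats::setNames(short[short > 0], drop_ids)
    keep <- rep(TRUE, length(dbl))
    for (id in drop_ids) {
      kk <- which(d1 == id)
      keep[kk[seq_len(drop_n[[id]])]] <- FALSE
    }
    dbl <- dbl[keep]
  }
  add <- table(dbl)
  new_ids <- setdiff(names(add), names(counts))
  if (length(new_ids))
    counts <- c(counts, stats::setNames(integer(length(new_ids)), new_ids))
  counts[names(add)] <- counts[names(add)] + as.integer(add)
  counts
}

# Build the amplicon core sequence for a variant id ("WT", single, or
# '+'-joined multiple), given the whitelist codons.
variant_core <- function(id, ref, codon_by_id_pos) {
  codons <- ref$codons
  if (id != "WT") {
    p <- parse_variant_id(id)
    idx <- p$residue - ref$first_residue_number + 1L
    for (k in seq_len(nrow(p))) {
      key <- paste0(p$id[k], "@", idx[k])
      single <- paste0(p$wt_aa[k], p$residue[k], p$mut_aa[k])
      cod <- codon_by_id_pos[[single]]
      if (is.null(cod)) stop("no programmed codon for ", single)
      codons[idx[k]] <- cod
    }
  }
  paste(codons, collapse = "")
}

codon_by_single_id <- function(evs) {
  w <- whitelist_table(evs)
  as.list(stats::setNames(w$mut_codon, w$variant_id))
}

inject_errors <- function(seqs, rate, bases = c("A", "C", "G", "T")) {
  if (rate <= 0) return(seqs)
  L <- nchar(seqs)
  k <- stats::rbinom(length(seqs), L, rate)
  hit <- which(k > 0)
  for (i in hit) {
    pos <- sample.int(L[i], k[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Render a sample's counts as paired-end FASTQ
#'
#' Each molecule yields one read pair spanning both flanks and the full
#' coding region: mate 1 is the amplicon top strand, mate 2 the reverse
#' complement of the bottom strand, so the mates overlap across the entire
#' core. Template switching (if requested) is applied to the molecule counts
#' first, then per-nucleotide substitution errors are drawn independently for
#' each mate. Base qualities are constant (`I`, Phred+33).
#'
#' @param counts named integer vector of molecule counts (including `"WT"`).
#' @param ref an [amplicon_reference()].
#' @param evs an [expected_variant_set()].
#' @param fastq1,fastq2 output FASTQ paths.
#' @param error_rate per-nucleotide substitution probability (default 0.001).
#' @param template_switch_rate chimera probability per read (default 0).
#' @param pcr_mode `"regular"` or `"emulsion"`.
#' @param switch_suppression emulsion fold suppression (default 2.5).
#' @param seed integer seed; identical seeds give byte-identical FASTQ.
#' @param sample_id prefix used in read names.
#' @return Invisibly, the post-switching molecule counts actually rendered.
#' @export
simulate_reads <- function(counts, ref, evs, fastq1, fastq2,
                           error_rate = 0.001, template_switch_rate = 0,
                           pcr_mode = c("regular", "emulsion"),
                           switch_suppression = 2.5, seed = 1L,
                           sample_id = "sample") {
  pcr_mode <- match.arg(pcr_mode)
  if (error_rate < 0 || error_rate > 1) stop("error rate must lie in [0, 1]")
  counts <- apply_template_switching(counts, evs, template_switch_rate,
                                     pcr_mode, switch_suppression,
                                     seed = derive_seed(seed, "switch"))
  counts <- counts[counts > 0]
  cods <- codon_by_single_id(evs)
  cores <- vapply(names(counts), variant_core, "", ref = ref,
                  codon_by_id_pos = cods)
  set.seed(derive_seed(seed, "reads"))
  identity <- sample(rep.int(names(counts), counts))
  amplicon <- paste0(ref$upstream_flank, cores[identity], ref$downstream_flank)
  r1 <- inject_errors(amplicon, error_rate)
  r2 <- inject_errors(revcomp(amplicon), error_rate)
  qual <- strrep("I", nchar(amplicon[1] %||% ""))
  nm <- sprintf("@%s_read%06d", sample_id, seq_along(identity))
  if (length(identity)) {
    writeLines(as.vector(rbind(nm, r1, "+", qual)), fastq1)
    writeLines(as.vector(rbind(nm, r2, "+", qual)), fastq2)
  } else {
    writeLines(character(), fastq1); writeLines(character(), fastq2)
  }
  invisible(counts)
}

#' Simulate a whole landscape screen at the count level
#'
#' Convenience generator reproducing the study conditions of the clustering
#' analysis: a chosen number of single-substitution variants (spike-ins
#' included) with class-structured true effects across the configured
#' conditions, pooled and selected at a given depth with replicates.
#'
#' @param n_variants number of pooled single variants including the five
#'   spike-ins (default 412, the size of the clustered variant set).
#' @param config a [class_profile_config()].
#' @param depth reads per sample (default 1e5).
#' @param n_replicates biological replicates (default 3).
#' @param wt_fraction wild-type pool fraction (default 0.1).
#' @param seed integer seed.
#' @param ref,evs reference and variant set; packaged defaults when omitted.
#' @return List with `screen` ([simulated_screen()]), `counts` (long counts
#'   from [simulate_selection()]), `classes`, `effects`, `ref`, `evs`.
#' @export
simulate_landscape_screen <- function(n_variants = 412L,
                                      config = class_profile_config(),
                                      depth = 1e5, n_replicates = 3L,
                                      wt_fraction = 0.1, seed = 1L,
                                      ref = make_reference(),
                                      evs = make_variant_set(ref)) {
  spikes <- evs$spike_ins$variant_id
  if (n_variants < length(spikes) + 3L) stop("n_variants too small")
  set.seed(derive_seed(seed, "pick_variants"))
  others <- sample(evs$programmed$variant_id, n_variants - length(spikes))
  ids <- c(sort(others), spikes)
  s_tot <- sum(evs$spike_ins$fraction)
  fr <- c(stats::setNames(rep((1 - wt_fraction - s_tot) / length(others),
                              length(others)), sort(others)),
          stats::setNames(evs$spike_ins$fraction, spikes))
  cfg <- config
  cfg$seed <- derive_seed(seed, "effects")
  te <- simulate_true_effects(ids, cfg)
  screen <- simulated_screen(fr, te$effects, depth = depth,
                             n_replicates = n_replicates,
                             seed = derive_seed(seed, "selection"))
  counts <- simulate_selection(screen)
  list(screen = screen, counts = counts, classes = te$classes,
       effects = te$effects, ref = ref, evs = evs)
}

#' Write / read the per-sample sheet
#'
#' Columns: `sample`, `condition`, `replicate`, `role`
#' (`unselected`/`selected`), `fastq1`, `fastq2`.
#'
#' @param sheet data.frame in the layout above.
#' @param path TSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  need <- c("sample", "condition", "replicate", "role", "fastq1", "fastq2")
  stopifnot(all(need %in% names(sheet)))
  write_tsv_plain(sheet[need], path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  read_tsv_plain(path)
}
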