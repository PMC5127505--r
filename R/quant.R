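# From allele counts to phenotypic / fitness scores:
#   frequency = count / mapped reads per sample;
#   score     = log2(f_mut,sel / f_mut,unsel) - log2(f_wt,sel / f_wt,unsel);
#   read-count filters (200 reads in the transformed pool, 50 reads in both
#   the selected and unselected sample of a comparison);
#   replicate medians; lethality cutoff calibrated on known viable / lethal
#   variants.

#' Read-count filter configuration
#'
#' @param min_pool_reads a variant must reach this many reads in the
#'   transformed-pool sample to be scored at all (default 200).
#' @param min_condition_reads a variant-condition score is masked when the
#'   read count is below this in *both* the selected and the unselected
#'   sample (default 50). Set `rule = "either"` for the stricter variant
#'   that masks when either side is below the threshold.
#' @param pool_condition_name condition name of the transformed pool
#'   (default `"SC-Leu"`).
#' @param rule `"both"` (default) or `"either"`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_pool_reads = 200L, min_condition_reads = 50L,
                          pool_condition_name = "SC-Leu",
                          rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (min_pool_reads < 0 || min_condition_reads < 0)
    stop("filter thresholds must be >= 0")
  structure(list(min_pool_reads = as.integer(min_pool_reads),
                 min_condition_reads = as.integer(min_condition_reads),
                 pool_condition_name = pool_condition_name, rule = rule),
            class = "filter_config")
}

#' Allele frequencies from a count table
#'
#' Frequency is count divided by the sample's mapped (accepted) reads:
#' the sum over all accepted variant rows including wild type.
#'
#' @param counts long data.frame with columns `sample`, `variant_id`,
#'   `count` (additional label columns are carried through).
#' @return The input with `freq` and per-sample `total` columns appended.
#' @export
allele_frequencies <- function(counts) {
  tot <- tapply(counts$count, counts$sample, sum)
  if (any(tot == 0)) stop("sample with zero mapped reads: ",
                          paste(names(tot)[tot == 0], collapse = ", "))
  counts$total <- as.vector(tot[counts$sample])
  counts$freq <- counts$count / counts$total
  counts
}

#' Log-ratio phenotypic score
#'
#' `log2(fm_sel / fm_unsel) - log2(fw_sel / fw_unsel)`: the change in mutant
#' allele frequency under selection, normalized to the wild-type change.
#' Positive scores mean enrichment relative to wild type.
#'
#' @param fm_sel,fm_unsel mutant frequency in the selected / unselected
#'   sample (must be > 0; use pseudocounted counts upstream for zeros).
#' @param fw_sel,fw_unsel wild-type frequencies, likewise.
#' @param base logarithm base (default 2).
#' @return Numeric score (vectorized).
#' @export
phenotype_score <- function(fm_sel, fm_unsel, fw_sel, fw_unsel, base = 2) {
  if (any(c(fm_sel, fm_unsel, fw_sel, fw_unsel) < 0))
    stop("frequencies must be non-negative")
  if (any(c(fm_unsel, fw_sel, fw_unsel) == 0))
    stop("zero frequency: apply a pseudocount before scoring")
  log(fm_sel / fm_unsel, base) - log(fw_sel / fw_unsel, base)
}

#' Apply read-count filters to a screen's counts
#'
#' A variant is dropped from a replicate when it has fewer than
#' `min_pool_reads` reads in that replicate's transformed-pool sample; a
#' variant-condition-replicate cell is masked when its read count is below
#' `min_condition_reads` in both (or, under `rule = "either"`, in at least
#' one of) the selected and unselected samples of the comparison.
#'
#' @param counts long count data.frame with `condition`, `replicate`,
#'   `role`, `variant_id`, `count`.
#' @param cfg a [filter_config()].
#' @return data.frame (`variant_id`, `condition`, `replicate`, `pool_pass`,
#'   `cell_pass`, `keep`) with one row per scoreable cell.
#' @export
apply_filters <- function(counts, cfg = filter_config()) {
  pool <- counts[counts$role == "unselected" &
                   counts$condition == cfg$pool_condition_name, ]
  if (nrow(pool) == 0L) stop("pool condition '", cfg$pool_condition_name,
                             "' not present in counts")
  sel <- counts[counts$role == "selected", ]
  key <- function(v, r) paste(v, r, sep = "\r")
  pool_count <- stats::setNames(pool$count, key(pool$variant_id, pool$replicate))
  pc <- pool_count[key(sel$variant_id, sel$replicate)]
  pc[is.na(pc)] <- 0L
  pool_pass <- pc >= cfg$min_pool_reads
  low_sel <- sel$count < cfg$min_condition_reads
  low_unsel <- pc < cfg$min_condition_reads
  cell_pass <- if (cfg$rule == "both") !(low_sel & low_unsel)
               else !(low_sel | low_unsel)
  data.frame(variant_id = sel$variant_id, condition = sel$condition,
             replicate = sel$replicate, pool_pass = pool_pass,
             cell_pass = cell_pass, keep = pool_pass & cell_pass)
}

#' Score a screen: per-replicate log-ratio scores with filters
#'
#' For every variant, condition and replicate, computes the phenotypic score
#' of the selected sample against the same replicate's transformed-pool
#' sample, after adding `pseudocount` to every count (mutant and wild type,
#' selected and unselected alike) so that depleted variants stay finite.
#' Filtered cells are recorded with `keep = FALSE` and excluded from
#' aggregation.
#'
#' @param counts long count data.frame from [simulate_selection()] or
#'   [call_fastq()] tallies (must contain `"WT"` rows).
#' @param cfg a [filter_config()].
#' @param pseudocount added to counts before ratio computation (default 0.5).
#' @param log_base logarithm base (default 2).
#' @return data.frame (`variant_id`, `condition`, `replicate`, `score`,
#'   `keep`) of class `replicate_scores`.
#' @export
score_screen <- function(counts, cfg = filter_config(), pseudocount = 0.5,
                         log_base = 2) {
  counts <- counts[order(counts$condition, counts$replicate, counts$variant_id), ]
  pool <- counts[counts$role == "unselected" &
                   counts$condition == cfg$pool_condition_name, ]
  if (nrow(pool) == 0L) stop("pool condition '", cfg$pool_condition_name,
                             "' not present in counts")
  sel <- counts[counts$role == "selected", ]
  key <- function(v, r) paste(v, r, sep = "\r")
  pool_tot <- tapply(pool$count, pool$replicate, sum)
  pool_count <- stats::setNames(pool$count, key(pool$variant_id, pool$replicate))
  sel_tot <- tapply(sel$count, sel$sample, sum)

  wt_sel <- sel[sel$variant_id == "WT", ]
  wt_sel_count <- stats::setNames(wt_sel$count,
                                  paste(wt_sel$condition, wt_sel$replicate, sep = "\r"))
  wt_pool_count <- pool_count[key("WT", names(pool_tot))]
  names(wt_pool_count) <- names(pool_tot)

  mut <- sel[sel$variant_id != "WT", ]
  cm_sel <- mut$count + pseudocount
  tot_sel <- as.vector(sel_tot[mut$sample])
  cm_un <- pool_count[key(mut$variant_id, mut$replicate)]
  cm_un[is.na(cm_un)] <- 0
  cm_un <- cm_un + pseudocount
  tot_un <- as.vector(pool_tot[as.character(mut$replicate)])
  cw_sel <- wt_sel_count[paste(mut$condition, mut$replicate, sep = "\r")] + pseudocount
  cw_un <- as.vector(wt_pool_count[as.character(mut$replicate)]) + pseudocount

  score <- phenotype_score(cm_sel / tot_sel, cm_un / tot_un,
                           cw_sel / tot_sel, cw_un / tot_un, base = log_base)
  flt <- apply_filters(counts, cfg)
  fkey <- paste(flt$variant_id, flt$condition, flt$replicate, sep = "\r")
  keep <- stats::setNames(flt$keep, fkey)
  out <- data.frame(variant_id = mut$variant_id, condition = mut$condition,
                    replicate = mut$replicate, score = unname(score))
  out$keep <- unname(keep[paste(out$variant_id, out$condition, out$replicate,
                                sep = "\r")])
  out$keep[is.na(out$keep)] <- FALSE
  class(out) <- c("replicate_scores", class(out))
  out
}

#' Aggregate replicate scores into a score matrix
#'
#' Each cell is the median of its unmasked replicate scores; cells with no
#' unmasked replicate are `NA` with mask `"absent"`.
#'
#' @param rep_scores data.frame from [score_screen()] (columns `variant_id`,
#'   `condition`, `replicate`, `score`, `keep`).
#' @return A list of class `score_matrix` with `scores` (variant x condition
#'   numeric matrix), `mask` (character matrix, `measured`/`absent`), `n_rep`
#'   (replicates used per cell) and `replicate_scores` (the input).
#' @export
aggregate_replicates <- function(rep_scores) {
  kept <- rep_scores[rep_scores$keep, , drop = FALSE]
  vars <- sort(unique(rep_scores$variant_id))
  conds <- unique(rep_scores$condition)
  scores <- matrix(NA_real_, length(vars), length(conds),
                   dimnames = list(vars, conds))
  nrep <- matrix(0L, length(vars), length(conds), dimnames = list(vars, conds))
  if (nrow(kept)) {
    med <- tapply(kept$score, list(kept$variant_id, kept$condition),
                  stats::median)
    n <- tapply(kept$score, list(kept$variant_id, kept$condition), length)
    scores[rownames(med), colnames(med)] <- med
    nn <- n; nn[is.na(nn)] <- 0L
    nrep[rownames(n), colnames(n)] <- nn
  }
  mask <- ifelse(is.na(scores), "absent", "measured")
  structure(list(scores = scores, mask = mask, n_rep = nrep,
                 replicate_scores = rep_scores),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d variants x %d conditions (%.1f%% measured)\n",
              nrow(x$scores), ncol(x$scores),
              100 * mean(x$mask == "measured")))
  invisible(x)
}

#' Write a score matrix as TSV (masked cells as NA)
#' @param sm a `score_matrix`.
#' @param path output TSV.
#' @export
write_score_matrix <- function(sm, path) {
  df <- data.frame(variant_id = rownames(sm$scores), sm$scores,
                   check.names = FALSE)
  write_tsv_plain(df, path)
  invisible(path)
}

#' Calibrate the lethality cutoff on known viable / lethal variants
#'
#' Scans candidate cutpoints (midpoints between adjacent distinct calibration
#' scores) on the fitness-score axis and picks the threshold minimizing the
#' balanced misclassification error — the mean of the viable-below-threshold
#' rate and the lethal-at-or-above-threshold rate, which is robust to the
#' strong class imbalance of typical calibration sets. Ties resolve to the
#' midpoint of the optimal interval.
#'
#' @param fitness_scores named numeric vector of fitness scores.
#' @param viable_ids,lethal_ids character vectors of calibration variant ids
#'   (must be scored).
#' @return A list of class `lethality_model` with `threshold`,
#'   `balanced_error` and the calibration scores.
#' @export
calibrate_lethality <- function(fitness_scores, viable_ids, lethal_ids) {
  if (length(viable_ids) == 0L || length(lethal_ids) == 0L)
    stop("both calibration lists must be non-empty")
  v <- fitness_scores[viable_ids]
  l <- fitness_scores[lethal_ids]
  if (anyNA(v) || anyNA(l)) stop("all calibration variants must be scored")
  s <- sort(unique(c(v, l)))
  cand <- if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2 else s
  err <- vapply(cand, function(t) (mean(v < t) + mean(l >= t)) / 2, 0)
  best <- which(err == min(err))
  # contiguous run of optimal cutpoints -> midpoint of the interval
  run_end <- best[c(diff(best) != 1L, TRUE)][1L]
  run_start <- best[1L]
  threshold <- (cand[run_start] + cand[run_end]) / 2
  structure(list(threshold = threshold, balanced_error = min(err),
                 viable_scores = v, lethal_scores = l),
            class = "lethality_model")
}

#' Classify variants as viable or predicted lethal
#'
#' Variants whose fitness score is strictly below the calibrated threshold
#' are predicted lethal; a score exactly at the threshold is viable.
#'
#' @param fitness_scores named numeric vector (typically the 5FOA fitness
#'   column of a score matrix).
#' @param model a `lethality_model` from [calibrate_lethality()].
#' @return Named character vector, `"viable"` or `"predicted_lethal"`
#'   (`NA` scores give `NA`).
#' @export
classify_fitness <- function(fitness_scores, model) {
  out <- ifelse(fitness_scores < model$threshold, "predicted_lethal", "viable")
  stats::setNames(out, names(fitness_scores))
}
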