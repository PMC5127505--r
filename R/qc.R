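# Quality control: spike-in template-switching estimation and replicate
# reproducibility.

#' Estimate PCR template switching from spike-in doubles
#'
#' For every pair of spike-in single variants at distinct residues, the
#' template-switching ratio is
#' `R = Freq(double) / (Freq(single1) * Freq(single2))`, all frequencies
#' taken from the same sample. Doubles are two-substitution calls whose
#' parts are both spike-ins; pairs sharing a residue are excluded because
#' their double cannot exist on one molecule.
#'
#' @param freq data.frame for one sample with columns `variant_id`, `freq`
#'   (e.g. one sample's rows from [allele_frequencies()]).
#' @param spike_ins spike-in table from an [expected_variant_set()]
#'   (`variant_id`, `residue` columns used).
#' @return A list of class `template_switch_report` with `per_pair`
#'   (data.frame `single1`, `single2`, `double_id`, `f1`, `f2`, `f_double`,
#'   `ratio`) and `mean_ratio`.
#' @export
template_switch_ratio <- function(freq, spike_ins) {
  f <- stats::setNames(freq$freq, freq$variant_id)
  ids <- spike_ins$variant_id
  res <- spike_ins$residue
  pairs <- utils::combn(seq_along(ids), 2)
  keep <- res[pairs[1, ]] != res[pairs[2, ]]
  pairs <- pairs[, keep, drop = FALSE]
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dbl <- canonical_multi_id(c(ids[i], ids[j]))
    f1 <- unname(f[ids[i]]); f2 <- unname(f[ids[j]])
    fd <- unname(f[dbl]); if (is.na(fd)) fd <- 0
    if (is.na(f1) || is.na(f2) || f1 == 0 || f2 == 0) {
      warning("spike-in ", ids[i], " or ", ids[j],
              " has zero frequency; pair skipped")
      ratio <- NA_real_
    } else ratio <- fd / (f1 * f2)
    data.frame(single1 = ids[i], single2 = ids[j], double_id = dbl,
               f1 = f1, f2 = f2, f_double = fd, ratio = ratio)
  })
  per_pair <- do.call(rbind, rows)
  structure(list(per_pair = per_pair,
                 mean_ratio = mean(per_pair$ratio, na.rm = TRUE)),
            class = "template_switch_report")
}

#' Fold suppression of template switching between PCR modes
#'
#' Linear ratio of the mean per-pair switching ratios,
#' `mean_ratio(regular) / mean_ratio(emulsion)`.
#'
#' @param report_regular,report_emulsion `template_switch_report`s over the
#'   same spike-in pairs.
#' @return A list with `fold_suppression` and `infinite` flag (`TRUE` when
#'   the emulsion mean is zero while the regular mean is not).
#' @export
compare_pcr_modes <- function(report_regular, report_emulsion) {
  mr <- report_regular$mean_ratio
  me <- report_emulsion$mean_ratio
  if (!identical(report_regular$per_pair$double_id,
                 report_emulsion$per_pair$double_id))
    stop("reports must cover the same spike-in pairs")
  if (mr == 0) return(list(fold_suppression = 0, infinite = FALSE))
  if (me == 0) return(list(fold_suppression = Inf, infinite = TRUE))
  list(fold_suppression = mr / me, infinite = FALSE)
}

#' Pairwise Pearson correlation of per-variant frequencies across libraries
#'
#' @param freq_matrix numeric matrix, variants x samples (shared variant
#'   universe; e.g. built from [allele_frequencies()] output).
#' @return Symmetric correlation matrix with unit diagonal; pairs involving
#'   a constant frequency vector are `NA`.
#' @export
replicate_correlation <- function(freq_matrix) {
  stopifnot(is.matrix(freq_matrix), ncol(freq_matrix) >= 2L)
  suppressWarnings(r <- stats::cor(freq_matrix, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}
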