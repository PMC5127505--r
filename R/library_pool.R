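# Library composition: the fraction of the unselected pool carried by each
# programmed variant, each spike-in, and the residual wild type.

#' Compose the variant pool
#'
#' Distributes the non-wild-type, non-spike-in mass of the pool across the
#' programmed variants, either perfectly evenly (`uniform`) or with
#' Dirichlet-distributed unevenness (`dirichlet`) emulating synthesis and
#' transformation noise around an even design.
#'
#' @param ref an [amplicon_reference()] (unused beyond validation; kept for a
#'   stable signature).
#' @param evs an [expected_variant_set()].
#' @param mode `"uniform"` or `"dirichlet"`.
#' @param wt_fraction fraction of the pool that is unmutagenized wild type
#'   (default 0.1). Not stated by the screen design; exposed as a parameter.
#' @param concentration Dirichlet concentration per variant (default 50;
#'   larger is more even).
#' @param seed integer seed used in `dirichlet` mode.
#' @return Named numeric vector of pool fractions over programmed variants
#'   and spike-ins. Fractions sum to `1 - wt_fraction`; wild type holds the
#'   remainder and has no entry.
#' @export
make_library <- function(ref, evs, mode = c("uniform", "dirichlet"),
                         wt_fraction = 0.1, concentration = 50, seed = 1L) {
  mode <- match.arg(mode)
  if (wt_fraction <= 0 || wt_fraction >= 1)
    stop("wt_fraction must lie in (0, 1)")
  spike <- evs$spike_ins
  s_tot <- if (nrow(spike)) sum(spike$fraction) else 0
  if (wt_fraction + s_tot >= 1)
    stop("wt_fraction plus spike-in fractions must be < 1")
  ids <- evs$programmed$variant_id
  mass <- 1 - wt_fraction - s_tot
  if (mode == "uniform") {
    fr <- rep(mass / length(ids), length(ids))
  } else {
    set.seed(seed)
    g <- stats::rgamma(length(ids), shape = concentration, rate = 1)
    fr <- mass * g / sum(g)
  }
  names(fr) <- ids
  if (nrow(spike)) {
    sf <- spike$fraction
    names(sf) <- spike$variant_id
    fr <- c(fr, sf)
  }
  fr
}
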