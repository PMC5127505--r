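# Mutant-class discovery: hierarchical clustering of variant phenotype
# profiles under centered-correlation distance, silhouette-based choice of
# the class count, anchor-based class naming, and downstream class-level
# and residue-level analyses.

#' Centered-correlation distance between two condition profiles
#'
#' `1 - Pearson r`, computed over the conditions measured in both profiles
#' (pairwise-complete). `NA` when fewer than two conditions are shared or
#' either profile has zero variance over the shared conditions.
#'
#' @param x,y numeric score vectors over conditions (NAs allowed).
#' @return Distance in `[0, 2]`, or `NA`.
#' @export
centered_correlation_distance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  1 - stats::cor(x[ok], y[ok])
}

#' Centered-correlation distance matrix for a score matrix
#'
#' Variants whose distance to any other variant is undefined (fewer than two
#' shared measured conditions, or zero variance) are dropped with a warning.
#'
#' @param scores numeric matrix, variants x conditions (NAs for masked
#'   cells); a `score_matrix` is also accepted.
#' @return A `dist` object over the retained variants, ordered by variant id.
#' @export
score_distance <- function(scores) {
  if (inherits(scores, "score_matrix")) scores <- scores$scores
  scores <- scores[order(rownames(scores)), , drop = FALSE]
  suppressWarnings(r <- stats::cor(t(scores), use = "pairwise.complete.obs"))
  # drop the fewest variants needed to clear undefined pairwise correlations
  dropped <- 0L
  while (anyNA(r) && nrow(r) > 1L) {
    worst <- which.max(rowSums(is.na(r)))
    r <- r[-worst, -worst, drop = FALSE]
    dropped <- dropped + 1L
  }
  if (dropped > 0L)
    warning(dropped, " variant(s) with undefined profile correlations ",
            "excluded from clustering")
  stats::as.dist(1 - r)
}

#' Hierarchically cluster variant phenotype profiles
#'
#' Agglomerative clustering (default average linkage) on centered-correlation
#' distance. Variants are sorted by id before clustering so that the tree is
#' invariant to input order.
#'
#' Before clustering, a row-variation filter (in the style of the classic
#' expression-clustering tools this emulates) removes variants with no
#' reproducible phenotype: a variant is clustered only if at least
#' `min_signal_count` of its measured scores have absolute value at or above
#' `min_signal`. Correlation distance is meaningless on flat, noise-only
#' profiles, which otherwise scatter as spurious singleton clusters; the
#' default asks for one condition with at least a two-fold phenotype
#' (`min_signal = 1` log2 unit). Set `min_signal = 0` to cluster everything.
#'
#' @param scores a `score_matrix` or a variants x conditions numeric matrix.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param min_signal minimum absolute score a profile must reach (default 1).
#' @param min_signal_count in at least this many conditions (default 1).
#' @return An `hclust` object; the distance matrix used is attached as
#'   attribute `"distance"`, the ids of filtered-out variants as attribute
#'   `"unclustered"`.
#' @export
hier_cluster <- function(scores, linkage = c("average", "complete", "single"),
                         min_signal = 1, min_signal_count = 1L) {
  linkage <- match.arg(linkage)
  if (inherits(scores, "score_matrix")) scores <- scores$scores
  keep <- apply(abs(scores), 1L, function(x)
    sum(x >= min_signal, na.rm = TRUE) >= min_signal_count)
  unclustered <- rownames(scores)[!keep]
  d <- score_distance(scores[keep, , drop = FALSE])
  if (attr(d, "Size") < 3L) stop("need at least 3 clusterable variants")
  hc <- stats::hclust(d, method = linkage)
  attr(hc, "distance") <- d
  attr(hc, "unclustered") <- unclustered
  hc
}

#' Export a dendrogram as Newick with merge heights as branch lengths
#'
#' @param hc an `hclust` from [hier_cluster()].
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Cut the dendrogram into named mutant classes
#'
#' The number of classes is chosen to maximize the mean silhouette width
#' over `k_range`. Clusters are then named: the cluster holding the
#' majority of loss-of-function anchors becomes Class 1 and the one holding
#' the gain-of-function anchors becomes Class 3 (anchors only name clusters,
#' they never move variants); remaining clusters are named by decreasing
#' size. Consistency of the anchors (each anchor set co-clustered, and the
#' two sets in different clusters) is recorded.
#'
#' @param hc an `hclust` from [hier_cluster()] (with its `"distance"`
#'   attribute).
#' @param k_range candidate class counts (default `2:8`).
#' @param anchors named character vector mapping anchor variant ids to
#'   expected class names; default: loss-of-function spike-ins to
#'   `"Class1"`, gain-of-function spike-ins to `"Class3"`.
#' @param min_class_size clusters with fewer members than this are not
#'   reported as classes; their variants are labeled `unassigned` (default
#'   3). `k` counts the major classes only.
#' @return A list of class `class_assignment` with `k` (number of major
#'   classes), `labels` (named character vector variant -> class name or
#'   `unassigned`), `silhouette` (mean width per candidate k),
#'   `anchor_consistent` (logical) and `dendrogram`.
#' @export
assign_classes <- function(hc, k_range = 2:8, anchors = spike_in_classes(),
                           min_class_size = 3L) {
  d <- attr(hc, "distance")
  if (is.null(d)) stop("dendrogram lacks its distance attribute; use hier_cluster()")
  n <- attr(d, "Size")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0L) stop("no admissible k in k_range")
  # degenerate case: every pair of profiles correlates above 0.8 - there is
  # essentially one profile, and silhouette (being scale-invariant) could
  # otherwise manufacture structure out of noise
  if (max(d) < 0.2) {
    labels <- stats::setNames(rep("Class1", n), hc$labels)
    un <- attr(hc, "unclustered")
    if (length(un))
      labels <- c(labels, stats::setNames(rep("unassigned", length(un)), un))
    return(structure(list(k = 1L, labels = labels,
                          silhouette = stats::setNames(rep(NA_real_,
                                                           length(k_range)),
                                                       k_range),
                          anchor_consistent = NA, dendrogram = hc,
                          degenerate = TRUE),
                     class = "class_assignment"))
  }
  sil <- vapply(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, 0)
  names(sil) <- k_range
  # degenerate case: no candidate split shows real structure (essentially
  # identical profiles) -> one class
  if (max(sil) < 0.1) {
    cl <- stats::setNames(rep(1L, n), hc$labels)
    labels <- stats::setNames(rep("Class1", n), hc$labels)
    un <- attr(hc, "unclustered")
    if (length(un))
      labels <- c(labels, stats::setNames(rep("unassigned", length(un)), un))
    return(structure(list(k = 1L, labels = labels, silhouette = sil,
                          anchor_consistent = NA, dendrogram = hc,
                          degenerate = TRUE),
                     class = "class_assignment"))
  }
  k_cut <- k_range[which.max(sil)]
  cl <- stats::cutree(hc, k = k_cut)

  # clusters below the minimum size are not classes: their members are
  # reported unassigned, and k counts the major classes only
  sizes <- table(cl)
  minor <- as.integer(names(sizes)[sizes < min_class_size])
  major <- as.integer(names(sizes)[sizes >= min_class_size])
  k <- length(major)

  # name major clusters from anchors, then by size
  nm <- rep(NA_character_, k_cut)
  present <- intersect(names(anchors), names(cl))
  present <- present[cl[present] %in% major]
  for (cls in unique(anchors)) {
    a <- present[anchors[present] == cls]
    if (length(a) == 0L) next
    target <- as.integer(names(which.max(table(cl[a]))))
    if (is.na(nm[target])) nm[target] <- cls
  }
  free_nums <- setdiff(seq_len(max(k, 3L)),
                       as.integer(sub("Class", "", stats::na.omit(nm))))
  unnamed <- major[order(-as.integer(sizes[as.character(major)]))]
  unnamed <- unnamed[is.na(nm[unnamed])]
  nm[unnamed] <- paste0("Class", free_nums[seq_along(unnamed)])
  nm[minor] <- "unassigned"
  labels <- stats::setNames(nm[cl], names(cl))
  un <- attr(hc, "unclustered")
  if (length(un))
    labels <- c(labels, stats::setNames(rep("unassigned", length(un)), un))

  anchor_consistent <- TRUE
  for (cls in unique(anchors)) {
    a <- present[anchors[present] == cls]
    if (length(a) && length(unique(cl[a])) != 1L) anchor_consistent <- FALSE
  }
  if (length(present)) {
    sets <- split(present, anchors[present])
    if (length(sets) > 1L) {
      reps <- vapply(sets, function(a) cl[a[1]], 0L)
      if (anyDuplicated(reps)) anchor_consistent <- FALSE
    }
  }
  structure(list(k = k, labels = labels, silhouette = sil,
                 anchor_consistent = anchor_consistent, dendrogram = hc),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf("class_assignment: k = %d (mean silhouette %.3f)\n",
              x$k, max(x$silhouette)))
  print(table(x$labels))
  invisible(x)
}

#' Classical two-sample t-test between classes in one condition
#'
#' Two-tailed unpaired t-test with pooled variance, comparing the measured
#' scores of two classes in one condition.
#'
#' @param scores a `score_matrix` or variants x conditions matrix.
#' @param labels named character vector variant -> class.
#' @param condition condition name.
#' @param class_a,class_b class names to compare.
#' @return A list with `t`, `p`, `df`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
class_condition_test <- function(scores, labels, condition, class_a, class_b) {
  if (inherits(scores, "score_matrix")) scores <- scores$scores
  pick <- function(cls) {
    v <- intersect(names(labels)[labels == cls], rownames(scores))
    x <- scores[v, condition]
    x[!is.na(x)]
  }
  a <- pick(class_a); b <- pick(class_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both classes need >= 2 measured scores in ", condition)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b))
}

#' Change in transcription start site usage relative to wild type
#'
#' Start-site signal is binned into six ordered bins (upstream to
#' downstream) normalized to fractions; the change is the per-bin difference
#' between a mutant profile and the wild-type profile.
#'
#' @param mutant,wt numeric vectors of 6 non-negative bin fractions each
#'   (sums to 1 within tolerance).
#' @return Numeric vector of 6 per-bin deltas (sums to 0).
#' @export
tss_fraction_change <- function(mutant, wt) {
  if (length(mutant) != length(wt))
    stop("bin count mismatch")
  for (p in list(mutant, wt)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("bin profiles must be non-negative fractions summing to 1")
  }
  mutant - wt
}

#' Regression of phenotypic score on helical-propensity change
#'
#' For substitutions in the trigger-loop tip region, relates the change in
#' helical propensity (mutant minus wild-type amino acid, on a
#' user-supplied free-energy scale) to the phenotypic score under the MPA
#' condition, via least squares. The propensity scale is external
#' literature data and must be supplied by the caller.
#'
#' @param scores named numeric vector of phenotypic scores per single
#'   variant id (e.g. the MPA column of a score matrix).
#' @param propensity named numeric vector, amino acid -> helical propensity
#'   (free energy); must cover all amino acids appearing in the variants.
#' @param region residue numbers defining the tip region (default
#'   `1090:1096`).
#' @param exclude optional integer vector of residue numbers to drop (e.g.
#'   `1094` to remove V1094 variants).
#' @return A list with `r` (Pearson correlation, `NA` if either side is
#'   constant), `slope`, `intercept`, `n`, and the fitted data.
#' @export
helical_propensity_regression <- function(scores, propensity,
                                          region = 1090:1096,
                                          exclude = NULL) {
  p <- parse_variant_id(names(scores))
  multi <- names(which(table(p$id) > 1L))
  p <- p[!(p$id %in% multi), , drop = FALSE]
  p <- p[p$residue %in% setdiff(region, exclude), , drop = FALSE]
  p$y <- unname(scores[p$id])
  p <- p[!is.na(p$y), , drop = FALSE]
  if (nrow(p) < 3L) stop("fewer than 3 scored variants in the region")
  need <- unique(c(p$wt_aa, p$mut_aa))
  if (!all(need %in% names(propensity)))
    stop("propensity scale missing amino acids: ",
         paste(setdiff(need, names(propensity)), collapse = ", "))
  p$x <- unname(propensity[p$mut_aa] - propensity[p$wt_aa])
  fit <- stats::lm(y ~ x, data = p)
  r <- if (stats::sd(p$y) == 0 || stats::sd(p$x) == 0) NA_real_
       else stats::cor(p$x, p$y)
  slope <- unname(stats::coef(fit)[2]); if (is.na(slope)) slope <- 0
  list(r = r, slope = slope, intercept = unname(stats::coef(fit)[1]),
       n = nrow(p), data = p[, c("id", "residue", "x", "y")])
}
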