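---
title: "Methods: codon-aware analysis of saturation mutagenesis screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-aware analysis of saturation mutagenesis screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscan)
```

# The screen and its generative model

`codonscan` analyzes pooled saturation-mutagenesis screens of a short coding
region — the motivating system is the RNA polymerase II trigger loop (Rpb1
residues 1076–1106), a 31-codon mobile domain whose variants shift the
enzyme between loss-of-function (LOF) and gain-of-function (GOF) catalytic
regimes. A programmed library places one mutant codon per molecule; pooled
yeast transformants are replica-plated onto a panel of selective media, the
amplicon is deep-sequenced before and after selection, and each variant's
phenotype is summarized by the change of its allele frequency relative to
wild type.

The package implements both the analysis and a synthetic generator that
emulates the screen end-to-end, so every stage is testable without external
data. The generator assumes:

* **Library composition.** Each programmed variant receives an even (or
  Dirichlet-perturbed) share of the non-wild-type pool. The unmutagenized
  wild-type fraction of the pool is not publicly documented for this screen
  design; it is a parameter (`wt_fraction`, default 0.1). Five
  deliberately excluded substitutions (H1085Y, H1085Q, F1086S, G1097D,
  E1103G) are spiked back in as internal controls at `spike_in_fraction`
  (default 0.01 each).
* **Selection.** A variant with true effect $e$ (log2 units) changes its
  expected frequency by the factor $2^{e}$, with the wild-type effect fixed
  at 0; sampled counts are multinomial at the configured depth. This
  multiplicative model is exactly the quantity the phenotypic score
  estimates.
* **Class structure.** True effects follow three phenotype classes plus a
  neutral remainder (`class_profile_config()`). Signs encode the reported
  class signatures — Class 1 (LOF): strong galactose resistance, slight MPA
  resistance, formamide hypersensitivity; Class 2: weak galactose
  resistance, slight formamide resistance; Class 3 (GOF): galactose
  resistance, Spt^- reporter growth, MPA/Mn/caffeine/cycloheximide
  sensitivity. Only signs are anchored; magnitudes default to 2 log2 units
  for strong phenotypes, and per-variant-per-condition Gaussian noise has
  `noise_sd = 0.3`. Default class proportions are 0.35/0.30/0.25 plus 0.10
  neutral, reflecting that most clustered variants in this kind of screen
  carry a class signature. The 14-condition panel uses the seven named
  phenotyping conditions plus seven generic stress conditions with no class
  effect.
* **Sequencing.** Each molecule yields an innie read pair spanning both
  flanks and the whole coding region, with independent per-nucleotide
  substitution errors in each mate (default 0.001) and constant base
  qualities. Indel sequencing errors are not generated (they are handled
  only as alignment events).
* **Template switching.** With probability `template_switch_rate` a read is
  a single-crossover recombinant of two independently drawn pool molecules.
  When both parents are single-codon variants at distinct positions the
  chimera is visible as a false double mutant (the crossover falls between
  the two mutated codons); any other pairing is indistinguishable from its
  first parent. Emulsion PCR divides the switch rate by
  `switch_suppression` (default 2.5). Under this model the expected
  frequency of a spike-in double is $p \cdot 2 f_1 f_2$, so the estimator
  below rises linearly in the true rate.

What the generator deliberately does **not** emulate: PCR-cycle-level
amplification bias, indel sequencing errors, quality-score structure,
colony-growth competition, and epistasis between substitutions beyond the
chimeric spike-in doubles. Passing tests therefore demonstrate correctness
of the estimators under the stated sampling model, not robustness to every
artifact of real libraries.

# Variant calling

Calling is codon-aware because the library is: the programmed set contains
exactly one mutant codon per amino-acid substitution per position, chosen at
Hamming distance ≥ 2 from the wild-type codon whenever a synonym allows it.
A single sequencing error on a wild-type read can then never reach a
whitelisted codon, which is what lets the caller separate real variants from
errors.

1. **Merging.** Mate 2 is reverse-complemented; both mates must contain the
   15-nt flank anchors as exact matches, and the cores extracted from the
   two mates must agree at every position. Any flank mismatch rejects the
   pair (`flank_mismatch`); disagreeing mates are rejected
   (`overlap_disagreement`) rather than quality-arbitrated — conservative,
   and no arbitration rule is defined for this assay.
2. **Alignment.** The dynamic program indexes the reference in codons and
   the read in nucleotides. Moves: one codon against three read nucleotides
   (+1 exact match, −1 otherwise) or an insertion/deletion of 1–3
   nucleotides at a constant −2. The defaults make one codon substitution
   outscore any indel pair explaining the same core, keeping substitution
   calls canonical; all three scores are configurable. Traceback ties
   prefer substitution over indels, deletions over insertions, and longer
   indels over shorter, so the reported optimum is deterministic. Cores
   whose length differs from the reference by more than `band` (default 9
   nt) are unalignable. For the dominant case — a core of exactly the
   reference length whose substitution-only score provably beats the best
   conceivable indel-bearing alignment — a vectorized fast path skips the
   DP; the bound is $(C-1)\,m + 2g$ because any indel-bearing alignment of
   an equal-length core spends at least two gap penalties and at least one
   diagonal step.
3. **Identification.** Zero mismatched codons → wild type; all mismatched
   codons in the expected set → `single`/`multiple`; anything else →
   rejected (`unexpected_codon`, `indel`, `unalignable`). Indel-bearing
   reads are rejected for counting because the programmed library contains
   substitutions only; rejection reasons are tallied per sample.

# Scoring

Frequencies are counts over mapped (accepted) reads per sample. The
phenotypic score of a variant in a condition is

$$ f \;=\; \log_2\!\frac{f_{mut,sel}}{f_{mut,unsel}} \;-\;
   \log_2\!\frac{f_{wt,sel}}{f_{wt,unsel}} $$

with the transformed pool as the unselected baseline. The log base is not
dictated by the assay; base 2 (fold-change convention) is the default and is
configurable. A pseudocount of 0.5 is added to all four counts before
forming ratios, keeping depleted variants finite; this breaks exact depth
invariance by $O(1/\text{count})$, which is negligible past the read-count
filters.

Filters follow the screen's published rules: a variant needs ≥ 200 reads in
the transformed pool of a replicate to be scored in that replicate (each
replicate is an independent transformation with its own pool), and a
variant–condition cell is masked when it has fewer than 50 reads in *both*
the selected and unselected samples — the literal reading of the rule; the
stricter either-side version is available via `filter_config(rule =
"either")`. Reported scores are medians over unmasked replicates.

The lethality cutoff is calibrated on known viable and lethal variants by
minimizing the balanced misclassification error over 1-D cutpoints on the
fitness axis (ties resolve to the midpoint of the optimal interval);
balanced error is used because calibration sets of this kind are heavily
imbalanced (on the order of 163 viable to 16 lethal). Classification is
strictly-below-threshold.

# Quality control

Template switching is estimated as
$R = \mathrm{Freq}^{double} / (\mathrm{Freq}^{single_1} \cdot
\mathrm{Freq}^{single_2})$ over all spike-in pairs at distinct residues
(five spike-ins at four residues give exactly nine valid pairs), with all
frequencies from the same library — by default the unselected transformed
pool. Mode comparison is the linear ratio of mean ratios, matching the
"fold on average" convention. Replicate reproducibility is pairwise Pearson
correlation of per-variant frequencies.

# Clustering and class assignment

Profiles are compared by centered-correlation distance ($1 - r$,
pairwise-complete over jointly measured conditions), clustered
agglomeratively with average linkage (the metric is named by the original
workflow, the linkage is not; average is that tool's common choice and
complete/single are available). Variants are sorted by id first so the tree
is input-order invariant.

Two pre-clustering guards reflect how correlation distance behaves on this
kind of matrix:

* a **row-variation filter** (default: at least one measured score with
  |score| ≥ 1 log2 unit, i.e. a two-fold phenotype in at least one
  condition) keeps noise-only profiles out of the tree. Correlation between
  two flat noisy profiles is itself noise, so such variants otherwise
  scatter as spurious singleton clusters and dominate cluster-number
  selection; the classic expression-clustering workflow this emulates
  applies exactly this kind of filter before clustering. Filtered variants
  are reported as `unassigned`, not dropped. `min_signal = 0` disables the
  filter.
* variants still producing undefined correlations (too few shared measured
  conditions) are removed greedily, fewest removals first.

The class count is chosen by maximizing mean silhouette width over k = 2–8,
making the number of classes an output rather than an assumption. Two
safeguards keep the count meaningful: if every pair of profiles correlates
above 0.8 the matrix is declared degenerate (essentially one profile) and
collapses to a single class — this is judged on the absolute distance
scale, because silhouette is scale-invariant and would happily manufacture
structure out of pure noise around a single profile; and clusters smaller
than `min_class_size` (default 3) are not reported as classes — silhouette
occasionally prefers splitting off a single outlier variant, and a
one-member cluster is not a mutant *class* — their members join the
`unassigned` set. Clusters are then *named* by the spike-in anchors — the cluster holding the
LOF spike-ins becomes Class 1, the one holding the GOF spike-ins Class 3 —
and remaining clusters by size. Anchors never move variants, and anchor
consistency (each anchor set co-clustered, the two sets separated) is
recorded. Note the original report's figure legend and results text
disagree on which class number is GOF; this package follows the results
text (Class 1 = LOF, Class 3 = GOF), and the naming is cosmetic either way.

Downstream analyses: classical pooled-variance two-tailed t-tests between
classes per condition; transcription-start-site shifts as per-bin deltas of
six-bin fraction profiles against wild type; and an optional regression of
tip-region scores on helical-propensity change. The propensity scale is
external literature data and must be supplied by the caller — the package
ships no values as ground truth.

# Numerical and reproducibility choices

* All randomness flows from a single integer seed; pipeline stages derive
  per-stage seeds by hashing the stage name, so any stage is individually
  reproducible and identical configurations give byte-identical outputs
  (FASTQ included) and stable manifest checksums.
* The chimera bookkeeping conserves read totals exactly, clamping at
  exhausted parent pools (relevant only at extreme switch rates).
* `calibrate_lethality` scans midpoints of adjacent distinct calibration
  scores — the balanced error is piecewise constant, so this grid is
  exhaustive.
* Degenerate inputs are encoded, not raised: merge failures and call
  rejections carry reasons; zero spike-in frequencies skip the pair with a
  warning; constant profiles yield `NA` correlations.

# Problem sizes used by the tests

The test suite exercises the study-scale configuration — 412 pooled
variants × 14 conditions × 3 replicates at 1e5 reads per sample — at the
count level, where pooled selection, scoring, filtering, clustering and
class assignment run in seconds. The read-level path (FASTQ rendering plus
the full caller) is verified on smaller screens (tens of variants, depths
of a few thousand), including exact reconstruction of molecule counts from
error-free reads and byte-identical reruns; count-level and read-level
entries differ only by sequencing error, which the perfect-flank,
whitelist-checking caller rejects by construction. Template-switching
recovery uses six replicate libraries of 1e6 molecules per PCR mode. The
aligner is checked against a plain exhaustive path enumeration on 2-codon
references and an independently coded memoized suffix recursion on 3–6
codon references (all single-edit cores, plus fixed-seed samples of
double-edit cores; full two-edit enumeration over the nucleotide alphabet
is combinatorially out of reach).

# Known limitations

* The default reference is a synthetic stand-in: it back-translates the
  wild-type amino acids at the positions characterized in the literature
  and uses fixed placeholder residues elsewhere, with one representative
  codon per residue. Positional semantics (residue numbering, class
  anchors) are preserved; the nucleotide sequence is not the genomic one.
  Any real reference can be supplied as FASTA + offset.
* Multiply-substituted variants beyond spike-in doubles are tallied but not
  modeled; the frequency denominator counts all mapped reads.
* Silhouette-based cluster counting is a reproducible surrogate for the
  manual class annotation of the original heatmap; recovery of the class
  count is demonstrated on simulation, not claimed to replicate the
  original figure exactly.
* No variance shrinkage across conditions or replicates; scores are plain
  medians of log-ratios.
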