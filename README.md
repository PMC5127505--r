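# codonscan

Codon-aware analysis of pooled saturation-mutagenesis amplicon screens.

## The problem

Deep mutational scanning of a short coding region — the motivating system
is the RNA polymerase II trigger loop, Rpb1 residues 1076–1106, a 31-codon
mobile domain that couples NTP selection to catalysis — phenotypes hundreds
of variants at once: a programmed library carrying one mutant codon per
molecule is transformed into yeast, pooled transformants are replica-plated
onto a panel of selective media, and the amplicon is deep-sequenced before
and after selection. Turning those reads into a phenotypic landscape
requires a chain of steps that generic RNA-seq or variant-calling tools do
not provide:

* **Codon-aware variant calling.** Reads are merged with a perfect-match
  requirement on both flanks, aligned to the reference *in codon units* by
  dynamic programming (match/mismatch per codon, constant penalty for
  1–3-nt indels), and accepted only when every mismatched codon belongs to
  the expected set programmed into the library — which is what separates
  real variants from sequencing errors.
* **Log-ratio scoring.** The phenotypic score of a variant under condition
  *c* is

  ```
  f = log2(f_mut,sel / f_mut,unsel) − log2(f_wt,sel / f_wt,unsel)
  ```

  the change of allele frequency under selection normalized to wild type,
  with read-count filters (≥ 200 reads in the transformed pool; ≥ 50 reads
  in at least one side of each comparison) and replicate medians.
* **Spike-in quality control.** Five deliberately excluded substitutions
  spiked into the pool measure PCR template switching via
  `R = Freq(double) / (Freq(single1) × Freq(single2))` over the nine
  distinct-position spike-in pairs, and quantify how much emulsion PCR
  suppresses it.
* **Lethality calibration.** A fitness cutoff minimizing balanced
  misclassification error on known viable / lethal variants.
* **Class discovery.** Hierarchical clustering of variant × condition
  profiles under centered-correlation distance with average linkage,
  silhouette-selected class count, and cluster naming anchored by the
  spike-ins (loss-of-function anchors → Class 1, gain-of-function anchors
  → Class 3).

A synthetic-data module generates every input the pipeline needs —
reference, programmed library, pooled selection under class-structured
effects, FASTQ reads with sequencing error and template switching at
regular- vs emulsion-PCR rates — so the whole chain is testable without any
external download. See `vignettes/codonscan-methods.Rmd` for the model,
parameter choices, and limitations.

## Worked example

Simulate the screen at study scale — 412 pooled single variants
(spike-ins included) × 14 conditions × 3 replicates at 100,000 reads per
sample — then score and cluster it:

```r
library(codonscan)

ls <- simulate_landscape_screen(n_variants = 412, depth = 1e5, seed = 1)
sm <- aggregate_replicates(score_screen(ls$counts))
sm
#> score_matrix: 412 variants x 14 conditions (97.6% measured)

round(sm$scores["E1103G", c("Gal", "MPA", "Spt", "Mn")], 2)
#>   Gal   MPA   Spt    Mn
#>  1.60 -1.86  2.66 -2.43

ca <- assign_classes(hier_cluster(sm))
ca
#> class_assignment: k = 3 (mean silhouette 0.751)
#>
#>     Class1     Class2     Class3 unassigned
#>        133         76        115         88

tt <- class_condition_test(sm, ca$labels, "Mn", "Class3", "Class1")
sprintf("Mn, Class3 vs Class1: t = %.1f, p = %.3g", tt$t, tt$p)
#> "Mn, Class3 vs Class1: t = -46.1, p = 4.11e-123"
```

The spike-in E1103G — a known gain-of-function control — shows the Class 3
signature: enriched on galactose and the Spt reporter (positive scores,
i.e. Gal^R and Spt^-), depleted on mycophenolic acid and Mn²⁺ (negative
scores, i.e. MPA^S and Mn^S). Silhouette selection over k = 2–8 recovers
the three planted mutant classes; variants with no reproducible two-fold
phenotype in any condition are reported `unassigned`. The pooled-variance
t-test confirms Class 3 (gain of function) is far more Mn-sensitive than
Class 1.

The read-level pipeline — FASTQ simulation, paired-end merging, codon
alignment, whitelist calling, scoring, QC, clustering, with a provenance
manifest — runs end-to-end from a YAML config:

```r
run_pipeline(list(outdir = "demo_run", seed = 1,
                  simulate = list(n_variants = 25, depth = 10000)))
```

or from the shell via `inst/scripts/codonscan.R`
(`Rscript codonscan.R run --config cfg.yaml`).

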