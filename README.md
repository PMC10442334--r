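# replilicense

Integrative genomic analysis of replication origin licensing by a
chromatin-organizing transcription factor.

## The problem

Eukaryotic DNA replication begins at origins that are *licensed* in G1 —
ORC binds, then CDC6/CDT1 load the MCM2-7 helicase to form the
pre-replication complex — and *fire* in S phase. In metazoans no sequence
motif predicts origins; licensing is governed by chromatin. A line of
evidence in osteosarcoma cells implicates the transcription factor NFIB:
it co-binds chromatin with ORC1, its depletion diminishes ORC1 binding and
chromatin accessibility at a shared set of sites, shifts nascent-strand
(NS-seq) origin activity, weakens A-compartment structure around those
sites, and — when overexpressed — provokes recurrent copy-number
amplifications that co-occur with NFIB amplification in breast-cancer
cohorts.

`replilicense` packages every quantitative step of that integrative
argument as reusable, tested functions, plus a synthetic-data generator
with a known truth ledger so the whole chain can be validated end to end
without any sequencing data:

| stage | functions |
|---|---|
| peak colocalization + permutation null | `overlap_venn()`, `venn_percentages()`, `permutation_overlap_null()` |
| knockdown differentials, N1 peaks, ATAC groups | `classify_fold_change()`, `derive_n1()`, `classify_accessibility()` |
| NS-seq RNase filter and S1/S2/S3 classes | `fisher_rnase_test()`, `bh_adjust()`, `filter_true_ns()`, `classify_s123()` |
| Repli-seq timing | `assign_timing()`, `timing_distribution()` |
| A/B compartment changes + N1 enrichment | `orient_pc1()`, `classify_bins()`, `n1_enrichment()` |
| EM nucleosome occupancy, CNA co-occurrence | `r_value()`, `subtract_control_gains()`, `recurrent_amplifications()`, `cooccurrence_with_nfib()` |
| synthetic study | `simulation_config()`, `simulate_study()` |
| orchestration | `analyze_study()`, `run_pipeline()` |

## The statistics at the core

* **Overlap counting.** Two peak sets on 0-based half-open BED coordinates
  are intersected as connected components of the ≥ 1 bp pairwise-overlap
  graph, so one component count serves against both set sizes
  (e.g. 14,400 components against 27,579 and 22,915 peaks give 52% and
  62% after integer truncation). The null expectation comes from drawing
  the reference set's length multiset uniformly over the genome and
  recording the median overlap percentage across draws.
* **Fold-change rule.** With pseudocount *c*, a peak is *decreased* iff
  (control + *c*)/(kd + *c*) > 1.2, *increased* for the reciprocal, else
  *unchanged*. N1 peaks are overlapped ORC1 peaks where both the ORC1
  signal and the overlapping NFIB partner's signal decrease.
* **RNase filter.** Per NS-seq peak, a one-sided Fisher exact test on
  `[(n_untreated, lib − n), (n_RNase, lib − n)]` with Benjamini-Hochberg
  FDR; a peak is a true nascent-strand peak iff q ≤ 0.05 **and**
  log2(untreated/treated) ≥ log2(1.2). Surviving peaks split into S1
  (decreased on knockdown), S2 (increased), S3 (unaltered).
* **Compartments.** Per 250-kb bin, replicate PC1 eigenvectors (sign
  oriented so gene-dense = A = positive) are compared between conditions
  by a pooled-variance t-test (p < 0.05); significant bins are classified
  A/B-weakened/strengthened or A-to-B / B-to-A, and N1-peak counts per
  bin are compared across categories by Mann-Whitney U.
* **R-value.** Nucleosome occupancy from electron microscopy: summed
  nucleosome-bubble contour length divided by the total contour length of
  the DNA stretch.

## Worked example

```r
library(replilicense)
out <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                package = "replilicense"))
print(out)
#> replilicense run (seed 11)
#>   colocalization: 73 components; 48% of set A, 48% of set B; null median 5.00%
#>   N1 peaks: 68 (consistency 95.8%)
#>   origins: 167 true NS peaks (S1 81 / S2 61 / S3 25)
#>   compartments: 8 A-weakened bins
#>   aux: 6 recurrent amplification regions; validation fraction 1.00
```

Reading the output: 73 of the 150 simulated NFIB peaks co-bind ORC1 (48%
of either set), against a 5% median overlap for random length-matched
regions. 68 co-bound ORC1 peaks lose both signals on knockdown (N1);
95.8% of diminished co-bound ORC1 peaks coincide with diminished NFIB.
Of the RNase-validated nascent-strand peaks, S1 (decreased) dominates at
planted NFIB-dependent origins; the planted 8 weakened-A compartment
bins are recovered and carry a significant excess of N1 peaks; the six
planted co-amplified CNA regions are recovered and all validate against
the significant co-occurring loci of the simulated patient cohorts.

Every stage is equally usable on its own tables, e.g.

```r
study <- simulate_study(simulation_config(seed = 7))
venn  <- overlap_venn(study$nfib_peaks, study$orc1_peaks, study$layout)
venn_percentages(venn)
autoplot(permutation_overlap_null(study$nfib_peaks, study$orc1_peaks,
                                  study$layout, seed = 7))
```

A command-line wrapper is installed with the package
(`inst/scripts/replilicense`):

```sh
Rscript inst/scripts/replilicense run -c inst/extdata/demo_config.yaml --outdir run1
```

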