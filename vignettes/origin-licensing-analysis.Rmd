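---
title: "Integrative analysis of replication origin licensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative analysis of replication origin licensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replilicense)
```

## Scope and design

`replilicense` implements, as a chain of data-frame-first functions, the
integrative genomics used to argue that a chromatin-organizing
transcription factor (NFIB) licenses replication origins: if NFIB opens
chromatin for pre-RC assembly, then (i) NFIB and ORC1 peaks should
colocalize far above a random-placement null, (ii) NFIB knockdown should
diminish ORC1 binding specifically at co-bound sites (N1 peaks),
(iii) nascent-strand signal should fall at N1-linked origins (S1.N1) and
these should sit in early-replicating, A-compartment chromatin whose PC1
weakens upon knockdown, and (iv) chronic over-licensing should leave
recurrent copy-number amplifications that co-occur with NFIB
amplification in patient cohorts. Each link in that chain is a small,
testable statistical operation; this vignette records the model behind
each one, the defaults, and the choices that were genuinely open.

All interval logic uses 0-based half-open (BED) coordinates, converts to
`IRanges`/`GenomicRanges` internally, ignores strand (none of the assays
involved is strand-resolved at the peak level), and counts any overlap of
at least 1 bp.

## Colocalization and its null

`peak_intersect()` returns the connected components of the graph joining
any two intervals (from either set) that share ≥ 1 bp. A component must
contain members of both sets to count. We report the *component count* as
"the number of overlapping peaks" against both set sizes: with multiway
overlaps neither per-set matched count is canonical, while the component
count is symmetric and single-valued. Per-set matched counts are returned
alongside. Displayed percentages are *truncated*, not rounded, at the
requested precision (`venn_percentages()`), and full-precision values are
always retained; this is the convention under which 14,400 components
against 22,915 peaks prints as 62%.

The permutation null (`permutation_overlap_null()`) redraws, per draw,
as many regions as the reference set holds, reusing the reference length
multiset exactly and placing each region uniformly over all valid
genomic positions — chromosome choice is proportional to the number of
valid placements, so placement is uniform over the genome rather than
per chromosome. Whether a length-matched or fixed-width null is meant is
not fixed by the assays themselves; length-matched is the stronger and
therefore our choice. The summary is the empirical median over draws
(default 10). For unit-length probes the per-draw expectation equals the
merged target's coverage fraction, which the tests exploit as an
analytic oracle.

## Knockdown differentials and N1 peaks

`classify_fold_change()` applies the symmetric rule: *decreased* iff
(control + c)/(kd + c) > 1.2, *increased* for the reciprocal, else
*unchanged*, with pseudocount c = 0.5 so empty peaks never produce
infinite ratios. The three labels provably partition any table, and
raising the cutoff can only move peaks toward *unchanged*. Signal per
peak is the length-weighted mean of track bins over the peak interval —
whether a peak-caller score or mean signal was the original quantity is
open; mean signal is reproducible from tracks alone.

`derive_n1()` expresses N1 membership on ORC1 intervals (the licensing
substrate): an overlapped ORC1 peak is N1 iff it is *decreased* and at
least one NFIB partner in its overlap component is *decreased*. The
consistency percentage — N1 over all overlapped decreased ORC1 peaks —
is the headline "diminished ORC1 coincides with diminished NFIB" figure.

`classify_accessibility()` is a deliberately simple stand-in for a
negative-binomial GLM framework: library-size-normalized counts, a
two-sided pooled-variance t-test on log2(normalized + 0.5) across
replicates, and the joint rule |log2FC| > log2(1.2) with p < 0.01.
"Open" denotes peaks whose accessibility *falls* upon depletion (the
factor was needed to keep them open). With two replicates per condition
the t-test has 2 degrees of freedom and is conservative; at the
simulator's default dispersion most truly shifted peaks do not reach
p < 0.01, which mirrors the weak power of naive per-peak tests and is a
documented limitation, not a defect — no dispersion sharing or shrinkage
is attempted.

## Nascent-strand filtering and origin classes

RNase-treated libraries carry only non-nascent background, so a true
origin peak is enriched in the untreated library. `fisher_rnase_test()`
computes the one-sided Fisher exact p (upper hypergeometric tail) on the
2×2 table of peak counts versus library remainders; one-sided because
the filter's purpose is retaining RNase-sensitive signal. The FDR
procedure behind "FDR ≤ 0.05" is taken to be Benjamini-Hochberg
(`bh_adjust()` wraps `stats::p.adjust`). The keep rule is a conjunction:
q ≤ 0.05 **and** library-normalized, pseudocounted
log2(untreated/treated) ≥ log2(1.2).

Surviving peaks are classified S1/S2/S3 by the same fold-change rule
engine applied to knockdown versus control signal. Replication timing
(`assign_timing()`) is the argmax of the three unit-mean-normalized
early/mid/late Repli-seq signals over the peak, with ties resolved
toward the earlier class and all-zero peaks reported as *unassigned*;
how timing classes were originally assigned is unstated, and argmax of
the fraction signals is the minimal defensible rule.
`timing_distribution()` reports per-category fractions over assigned
peaks (summing to 1), with unassigned counts carried separately, and
obeys the set identity |S1| = |S1.N1| + |S1.non-N1|.

## Compartment dynamics

PC1 signs are arbitrary per chromosome; `orient_pc1()` flips whole
chromosomes so the mean PC1 correlates non-negatively with gene density
(A = gene-dense = positive). `classify_bins()` compares replicate PC1
values per 250-kb bin between conditions with a two-sided t-test
(pooled variance by default — with n = 2 per group Student's pooled
test with df = 2 is the only stable choice; Welch is available via
`var_equal = FALSE`). Significant bins (p < 0.05) fall into a seven-way
scheme reconstructed from the sign/magnitude cases: A/B-weakened,
A/B-strengthened, A-to-B, B-to-A; degenerate bins with zero variance in
both groups are unchanged when means agree and flagged significant when
they differ. `n1_enrichment()` counts N1 peaks per bin — a
boundary-spanning peak counts in every bin it overlaps (midpoint
assignment, which conserves the total, is available) — and compares
each category's per-bin distribution to *unchanged* bins with a
two-sided Mann-Whitney U test, the natural nonparametric choice for a
violin-plot comparison.

## EM occupancy and copy-number co-occurrence

The EM R-value is the combined contour length of nucleosome bubbles over
the total contour length of the stretch (`r_value()`), scale-invariant
by construction. Copy-number calls use diploid thresholds gain > 2.3 /
loss < 1.7 (configuration, not biology — no numeric calling thresholds
are standard). `subtract_control_gains()` removes spontaneous control
gains at base-pair resolution; `recurrent_amplifications()` keeps
maximal regions gained in ≥ 2 clones (recurrence is otherwise
undefined). Cohort co-occurrence (`cooccurrence_with_nfib()`) is a
one-sided Fisher exact test per locus (alternative: co-amplification)
with BH adjustment across loci — the upstream portal statistic is not
specified beyond "FDR", and the one-sided test matches the enumeration
arithmetic of a perfectly concordant toy cohort (p = 1/20 for 3 + 3
patients). `cohort_validation_fraction()` is the fraction of sample
regions overlapping a significant locus in the union of cohorts.

## The synthetic study

`simulate_study()` is first-class, tested code, not a fixture. Its
defaults define the study conditions:

* **Genome**: three 10-Mb chromosomes, 1-kb signal bins, 250-kb
  compartment bins (40 per chromosome) — large enough for hundreds of
  sites and 120 compartment bins, small enough that every stage runs in
  about a second.
* **Sites**: 300 NFIB sites and 300 ORC1 sites of width 4 kb placed on a
  non-overlapping slot grid; each ORC1 site is independently
  NFIB-dependent with probability 0.5 (dependent sites share the NFIB
  interval; independent ones never touch NFIB sites, so false N1 entry
  is structural, not statistical). Site width spans four signal bins on
  purpose: per-peak fold-change estimates average over bin-level
  dispersion, and a power calculation at dispersion 0.1 and fold change
  2 puts each per-assay "decreased" call near 97–98%, hence joint
  S1.N1 recovery above 90% — the regime the recovery tests check.
* **Noise**: every count readout is negative-binomial per bin with
  dispersion 0.1 (variance mu + phi mu²); dispersion 0 is defined as the
  exact zero-noise limit so the zero-noise study recovers 100% of
  planted labels. Backgrounds (RNase libraries, track baseline) are
  Poisson — Fisher filtering of Poisson-equal-rate nulls is then valid
  and conservative, which the 50-seed calibration test verifies.
* **Knockdown**: fold change 2 at dependent sites (NFIB everywhere,
  ORC1/NS only where dependent); compensatory origins gain the same
  factor; dormant origins (10%) are silent in control and fire upon
  knockdown, so they surface in the knockdown NS library and classify as
  increased.
* **Nascent strands**: per-peak counts sum the site's bins; origin
  activity defaults to 50 per bin against a background of 2 per bin,
  libraries 10^6 each. The 0.5–2.0-kb size-selection window is carried
  in the config and sets the widths of decoy NS peaks; true origin NS
  peaks use the site footprint (a simplification — fragment-level
  pileup shapes are not modelled).
* **Timing and compartments**: each chromosome splits into
  early/mid/late thirds (fraction signal 20 inside its domain, 1
  outside). PC1 alternates A/B blocks of ±0.8 in five-bin runs;
  replicate noise is Gaussian sd 0.05 (eigenvector replicates are
  far less noisy than counts); 8 weakened-A bins (0.8 → 0.3 upon
  knockdown, so the df = 2 t-test detects them with high probability)
  are drawn from A bins inside early domains, and 60% of dependent
  sites are planted inside them — one planting that simultaneously
  produces the weakened-A N1 enrichment and the early-timing preference
  of S1.N1 origins.
* **CNA/cohorts**: four clones plus a control; six co-amplified regions
  shared by ≥ 2 clones, three spontaneous gains inherited from the
  control (removed by subtraction), private gains/losses per clone;
  event widths scale with the genome so every event gets a distinct
  slot. Four cohorts of 120 patients; co-amplified loci are amplified
  with probability 0.5 given NFIB amplification versus 0.05 otherwise,
  null loci at 0.08 throughout.
* **Determinism**: one master seed; every output draws from a derived
  substream, so adding an output never perturbs earlier ones, and the
  same seed reproduces every emitted file byte for byte.

What the simulator does *not* emulate — read-level data, sequence
content, fragment-length pileups, mappability, copy-number noise,
cohort population structure — bounds what passing tests show: they
validate the statistical machinery and its calibration under the stated
noise model, not performance on real sequencing artifacts.

## Numerical conventions

Pseudocount 0.5 before every ratio; truncation (toward zero) for
displayed percentages; BH for all FDR control; pooled-variance t-tests
wherever replicate counts are 2; ties in timing argmax break toward the
earlier class; empty categories report missing values (never zero);
degenerate inputs (zero-variance PC1, all-zero gene density, degenerate
cohort margins, libraries smaller than counts) raise errors naming the
offending quantity.

## A complete run

```{r, eval = FALSE}
study <- simulate_study(simulation_config(seed = 7))
res <- analyze_study(study)
glance(res$differential$n1)
res$origins$timing
glance(res$compartments$enrichment)
autoplot(res$compartments$change)
```

`run_pipeline()` wraps the same chain behind a YAML configuration with
stage toggles (a disabled prerequisite fails loudly), writes per-stage
TSV/BED artifacts whose numbers re-derive the JSON report exactly, and
is byte-deterministic for a fixed seed. The problem sizes used by the
test-suite recovery checks are the generator defaults above with 20
seeds, and 50 seeds of 300 background peaks for the filter calibration.
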