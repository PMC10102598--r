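---
title: "Methods: fitness estimation and essentiality calling for barcoded transposon libraries"
author: "rbtnseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitness estimation and essentiality calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbtnseq)
```

# The experiment being modeled

A randomly barcoded transposon (RB-TnSeq) library places a Tn5-like
transposon, tagged with a unique 20-nt DNA barcode, at a random genomic
position in each of tens of thousands of mutant strains. Tn-seq links
each barcode to its insertion position once; afterwards, cheap BarSeq
(barcode amplicon sequencing) measures the relative abundance of every
strain in a pooled sample. A fitness assay grows the pooled library for
4–6 population doublings under a selective condition and compares
abundances after selection ("condition" sample) to an aliquot taken
before selection ("Time0" sample).

Two analyses come out of such a library. Insertion statistics identify
*essential* genes — genes that tolerate no disruptions in their central
portion. Barcode counting across many conditions yields a gene ×
experiment *fitness matrix*, from which significant phenotypes, specific
phenotypes and cofitness networks are derived.

Throughout, an insertion is considered disruptive only when it falls in
the central 10–90% of a gene's length: insertions in the outer 10% ends
frequently leave a functional protein. The fraction is positional,
`(pos − begin + 1)/(end − begin + 1)` on the + coordinate direction,
regardless of the gene's strand — the rule is about where the insertion
sits in the gene body, not about orientation.

# Essentiality calling

For every gene with at least 100 non-repetitive nucleotides (insertions
inside repeated sequence cannot be mapped unambiguously; genes below the
floor are reported `not_analyzable`), two statistics are computed from
the mapped pool:

* `dens` — the number of distinct central insertion positions
  (deduplicated ignoring strand) divided by the gene's non-repetitive
  length, then scaled so that the median over analyzable genes is 1.
* `normreads` — total Tn-seq reads at central positions per
  non-repetitive kilobase, corrected for GC content and scaled so that
  the median is 1. GC correction divides each gene's raw reads/kb by the
  median of its GC bin (bins of width 0.05 in GC fraction; bins with
  fewer than 10 analyzable genes fall back to the global median). This
  binned-median correction is assumption-light and exactly reproducible;
  transposon insertion and PCR efficiency both drift with GC, and a
  median ratio absorbs that trend without fitting a curve.

A gene is called **essential** when both metrics are below 0.2 *and* its
mutants were too scarce at Time0 to yield fitness values (`has_fitness =
FALSE` — a gene whose mutants demonstrably grow in the pool is not
essential however sparse its insertion statistics look). If exactly one
metric is below 0.2, or both are but the gene has fitness data, the call
is **nearly essential**; remaining analyzable genes are **dispensable**.
The 0.2 thresholds are strict inequalities.

Independently, `dispensableFromPositions()` implements the direct
evidence rule used with conventional (non-barcoded) Tn-seq: a gene with
≥ 10 distinct central insertion positions and ≥ 100 total reads at those
positions is dispensable for viability; positions supported by a single
read are ignored as likely mapping noise.

Degenerate libraries — a median raw insertion density of zero over
analyzable genes — raise an error rather than returning silent zeros:
every downstream number would be meaningless.

Denominator choice: insertion density uses the gene's total
non-repetitive length, not the central-region length. Both conventions
cancel out of the median scaling for genes of typical proportions; the
total-length convention is recorded here as the package's fixed choice.
Tn-seq insertion positions are deduplicated ignoring strand; a
same-position insertion on the opposite strand is almost always the same
junction read in both orientations.

# Fitness estimation

## Strain fitness

All Time0 samples of a group are summed into a single reference vector
before any ratio is formed; summing maximizes the effective sequencing
depth of the denominator. For strain *s* in a condition sample:

$$ r_s = \log_2\frac{n_{cond,s} + \psi}{D_{cond}} -
         \log_2\frac{n_{t0,s} + \psi}{D_{t0}} $$

with pseudocount $\psi = 1$ on both counts and $D$ the sample depth plus
one pseudocount per strain. The pseudocount keeps zero counts finite and
is symmetric between numerator and denominator, so a strain observed
equally on both sides always has $r_s = 0$; the cost is a compression of
extreme ratios when counts are small, which is one reason gene fitness
requires minimum Time0 abundance (below). Each strain carries an
inverse-variance weight from the Poisson-level uncertainty of its two
counts:

$$ w_s = \left[\frac{1/(n_{cond,s}+\psi) + 1/(n_{t0,s}+\psi)}
          {\ln(2)^2}\right]^{-1} $$

A strain is *usable* when it lies in the central 10–90% of a gene and
has at least 3 reads in the Time0 reference.

## Gene fitness and positional normalization

Gene fitness is the weighted average $f_g = \sum w_s r_s / \sum w_s$
over the gene's usable strains, computed only when those strains carry
at least 30 summed Time0 reads; genes below the floor are `NA` (and that
`NA`, surfaced by `fitnessAvailability()`, is exactly the
`has_fitness = FALSE` input of the essentiality caller).

Raw gene fitness drifts with chromosomal position: in growing cells,
genes near the replication origin are present at higher copy number than
genes near the terminus, biasing abundance ratios along the chromosome.
Two normalization steps remove this and fix the scale:

1. On each replicon with ≥ 100 scored genes, a centered running median
   over genes ordered by position (window 251 genes, truncated at the
   replicon ends) is subtracted. Replicons with fewer scored genes — a
   small plasmid — have their plain median subtracted instead; a running
   window is meaningless at that size.
2. The mode of the main-chromosome values is subtracted from *all*
   genes (including plasmid genes, so both replicons stay on one scale).
   The mode, not the median, defines "no phenotype": in a strongly
   selective condition many genes have real negative fitness and the
   median is dragged down, while the modal gene is still neutral. The
   mode is estimated by a Gaussian kernel density with Silverman's
   rule-of-thumb bandwidth, evaluated on a grid of step 0.01 spanning
   [min − 0.5, max + 0.5]; ties in the density argmax resolve to the
   grid point nearest zero.

The window of 251 genes (~260 kb at typical gene density) is wide
enough that an operon or even a large prophage cannot move its own
window's median, yet narrow relative to the origin–terminus copy-number
gradient it must track. It must be odd (validated); the acceptance-scale
tests on a 400-gene genome use window 51 to keep the same
window-to-replicon proportion.

## The t-like statistic

$$ t_g = \frac{f_g}{\sqrt{\sigma_0^2 + \max(V_{count}, V_{spread})}} $$

* $V_{count} = 1/\sum w_s$ — the count-limited variance of the weighted
  mean.
* $V_{spread}$ — the weighted sample variance of the gene's strain
  ratios about the unnormalized gene fitness
  ($\frac{n}{n-1}\sum w_s (r_s - f_g^{raw})^2 / \sum w_s$), divided by
  the number of strains. When strains within one gene disagree more than
  their counts explain (polar effects, secondary mutations), this term
  dominates and deflates $t$.
* $\sigma_0 = 0.1$ — a standard-deviation floor that prevents genes with
  enormous counts from reaching arbitrarily large $|t|$ on biologically
  negligible fitness differences.

Single-strain genes have no spread estimate and use $V_{count}$ alone.
This variance model is the package's explicit contract; it is stated in
full above precisely so that the brute-force oracle in the test suite
can recompute it independently.

## Quality control

Per experiment: `gmed`, the median summed Time0 reads over genes with
fitness (≥ 50 to pass); `cor12` and `mad12`, the correlation and median
absolute difference between fitness recomputed from first-half
(fraction 0.10–0.49) versus second-half (0.50–0.90) insertions (pass at
cor12 ≥ 0.5, mad12 ≤ 0.5). Two half-gene estimates measure the same
biology with independent strains, so their agreement is a direct
internal replicate. Note that an experiment with *no* biological signal
fails cor12 by construction — both halves are pure noise — which is the
desired behavior for flagging uninformative assays. Failing experiments
are flagged, never silently dropped.

# Phenotype analytics

**Significant phenotypes**: $|f| > 0.5$ and $|t| > 4$. The two
thresholds play different roles — the fitness bound excludes
statistically solid but biologically trivial effects, the t bound
excludes large but noisy ones.

**Empirical FDR**: each Time0 sample is compared against the sum of the
remaining Time0 samples of its group (leave-one-out). No biology
separates the two sides, so genes crossing the significance thresholds
in these comparisons are false positives. Scaling to the condition-
experiment count:

$$ \widehat{FP} = \mathrm{round}\!\left(n_{fp,t0} \cdot
   \frac{N_{cond}}{N_{t0}}\right), \qquad
   FDR = \widehat{FP} / N_{sig\,genes} $$

Rounding is to the nearest integer. With 4 significant genes in 83 Time0
comparisons scaled to 757 experiments against 1,137 significant genes,
this yields 36 expected false positives and an FDR of 3.2% — the
arithmetic `estimateFdr()` reproduces.

**Specific phenotypes**: $|f| > 1$ and $|t| > 5$ in the experiment;
$|f| < 1$ in at least 95% of the gene's non-`NA` experiments; and
$|f|$ exceeding the gene's 95th percentile of $|f|$ by more than 0.5.
The percentile uses linear interpolation between order statistics
(`quantile` type 7) — the rule needs *a* fixed convention and this one
is continuous and standard. Fractions are taken over non-`NA`
experiments only, and genes with fewer than 20 scored experiments are
skipped: a 95% rule over a handful of values is vacuous.

**Cofitness**: Pearson correlation of two genes' fitness profiles over
their shared non-`NA` experiments (pairwise-complete, rather than
dropping every experiment any gene misses — complete-case would discard
most of the matrix once a few genes are patchy). Pairs with fewer than
50 shared experiments (or fewer than the matrix width, when smaller) are
suppressed instead of reported with unstable r; zero-variance profiles
are excluded and logged. r ≥ 0.8 flags high cofitness.

# The synthetic-data generator

The generator exists so that every downstream stage can be tested
against known truth. Its defaults emulate the study system this package
models:

| quantity | default | rationale |
|---|---|---|
| genome | main chromosome + plasmid, ~6% of genes on the plasmid | two-replicon layout; exercises the per-replicon normalization paths |
| gene length | gamma, mean 780 nt, sd 300 nt; gaps exponential, mean 270 nt | ~1.05 kb spacing: a 3,400-gene genome spans ~3.6 Mb |
| GC per gene | AR(1) around 0.63, sd 0.05, lag correlation 0.8 | GC tracks along real chromosomes; exercises the GC-binned correction |
| essential genes | 12% of genes, planted | typical bacterial essential fraction |
| pool size | ~80,000 strains at the 3,400-gene scale | gives the median gene ~15 usable (central) insertion strains |
| strain abundances | log-normal, σ = 1, normalized | pooled libraries are strongly uneven; the heavy tail stresses the inverse-variance weighting |
| Tn-seq reads | negative binomial (mean 20, size 1) + 1 | overdispersed, as real junction-read counts are |
| sequencing | multinomial per sample at the requested depth | simplest model whose variance the t statistic must dominate; optional Dirichlet overdispersion parameter |
| doublings | 5 (midpoint of the 4–6 range) | true fitness is defined as the *final* expected log2 ratio, so doublings only scales the optional positional drift term |

Essential genes reject central insertions (redrawn elsewhere;
configurable leakage probability for edge realism, default 0). True
fitness effects are planted with `plantEffects()`: direct
(gene, condition) values, co-regulated modules sharing a per-condition
base effect up to gene-level noise (default base sd 1.2, noise sd 0.3 —
chosen so module-mates correlate near r ≈ 0.93 at 30+ conditions,
comfortably on either side of the 0.8 floor), and condition-specific
effects (default −2) for otherwise-neutral genes. Effects are clipped to
|f| ≤ 3. Every stochastic operation takes an explicit integer seed and
restores the caller's RNG state: identical arguments and seed give
byte-identical output.

What the generator does **not** emulate: raw reads (FASTQ), barcode
sequencing errors and chimeras, the Tn-seq mapping step itself,
insertion-site sequence bias, polar effects within operons, and
condition-dependent Time0 composition drift. Passing recovery tests on
synthetic data therefore demonstrates that the estimators are correct
and well calibrated under the stated noise model — not that real
libraries are free of the artifacts above; the QC metrics exist
precisely because real experiments violate the clean model.

# Numerical and design notes

* Coordinates are 1-based inclusive everywhere, and converted nowhere.
* `NA` (never 0) encodes "gene had insufficient Time0 abundance"; the
  literal string `NA` in TSV matrices.
* Medians over even counts are the standard mean of the two central
  order statistics.
* The initial strain-abundance distribution of real libraries is not
  well characterized; log-normal σ = 1 is a configurable stand-in.
* Whether plasmid genes should share the chromosome's mode shift is a
  genuine open choice; the package subtracts the chromosomal mode from
  all genes so both replicons share one zero point.
* Test problem sizes: the null-calibration and essentiality-recovery
  suites run at full library scale (3,400 genes, ~79,700 strains, 21
  Time0 samples, depth 10⁶); fitness / specific-phenotype / cofitness
  recovery run on a 400-gene genome with ~9,400 strains — the same
  per-gene strain coverage and per-strain read depth, so estimator
  behavior is preserved while the whole suite stays fast.
* The Time0-null calibration check counts genes significant in at least
  one leave-one-out comparison over genes with any fitness value; with
  21 comparisons at depth 10⁶ this fraction is far below the 1% bound
  (typically zero).

# Limitations

* Repeat masking is an input (`nonrepetitive_nt`), not computed here.
* The caller does not reconcile essentiality across two libraries in
  different strain backgrounds beyond re-running on each pool.
* Multi-library count merging, barcode demultiplexing and chimera
  correction are out of scope; counts enter as a finished barcode ×
  sample table.
* The t statistic is a calibration-tested heuristic, not an exact
  sampling distribution; its thresholds (4 and 5) are meaningful
  because the Time0-null machinery measures their empirical FDR.
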