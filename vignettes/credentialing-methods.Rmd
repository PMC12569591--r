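---
title: "Methods: credentialing mouse tumor models from targeted amplicon panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: credentialing mouse tumor models from targeted amplicon panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousecgp)
```

# Scope and model

Genetically engineered mouse models (GEMMs) of cancer are usually profiled
with targeted multiplex-PCR panels rather than whole-genome sequencing: the
lesions are minute, often formalin-fixed, and a few hundred kilobases of
amplicons are enough to read out the alteration classes that matter for
credentialing — engineered flox-site excisions, somatic mutations at
conserved hotspots, gene-level copy-number alterations, chromosome-arm
aneuploidy, strain admixture, and summary genomic-instability metrics.
`mousecgp` implements that analysis stack end to end, together with
synthetic-data generators that emulate every input with known ground truth,
so the whole pipeline is testable without external cohorts.

## Copy-number model

Read counts for amplicon $i$ in sample $s$ are modeled as negative binomial
around $\mu_{is} = d \cdot e_i \cdot b(\mathrm{gc}_i) \cdot r_{is}$, where
$d$ is the target depth, $e_i$ a per-amplicon efficiency (log-normal across
the panel, shared between tumors and normals — amplicon behavior is a
property of the assay, not the sample), $b(\cdot)$ a smooth multiplicative
GC bias, and $r_{is}$ the expected linear copy-number ratio. For a tumor of
purity $p$ and ploidy $\psi$ with local tumor copy number $C$,

$$ r = \frac{pC + 2(1-p)}{p\psi + 2(1-p)}. $$

Normalization inverts the nuisance terms in stages: a bottom-5th-percentile
amplicon filter on pooled-normal mean counts, per-sample total-count
scaling, a per-amplicon ratio against the weighted pooled normal, log2, a
robust loess fit of log2CNR on GC fraction (span 0.5, two robustifying
iterations — wide enough that focal CNAs are not absorbed), and median
re-centering. The pooled normal is the per-amplicon mean of the
total-normalized normal profiles; "weighted" is read as optional per-normal
weights, equal by default, which is the simplest consistent interpretation.
`scale_cnr()` inverts the purity/ploidy mixture above to an estimated tumor
copy number, optionally rounded; at zero noise this recovers planted
integer copy numbers exactly, which the tests assert.

Gene-level calls summarize each target's amplicons (mean by default; a
median mode reproduces bin-median gene calling for sparse subsampled
designs), form a Z-score against the pool of normals' per-gene summaries,
convert to two-tailed normal p values, and correct with Benjamini-Hochberg
within the sample. States are $\mathrm{sign}(\log_2 \mathrm{CNR})$ unless
the noise-zeroing rule fires. The rule is stated in the source material as
a conjunction — "q > 0.05 and $-0.2 < \log_2\mathrm{CNR} < 0.2$" — and is
implemented literally as an AND by default, with an OR mode exposed because
the conjunction leaves oddities (a significant q with a negligible effect
size survives the AND rule). Calibration of the Z-scores depends on the
normal-pool size: with very few normals the empirical SD makes the
statistic t-distributed with heavy tails, so the package's calibration
tests use pools of ten normals, and we recommend at least eight in
practice.

Segmentation is circular-binary-segmentation-style: single-marker outliers
are winsorized toward a running median, then each chromosome is split
recursively at the changepoint maximizing
$|\bar{x}_L - \bar{x}_R|\sqrt{n_L n_R / n}$ — the least-squares two-segment
fit, which the tests verify against an exhaustive-search oracle — with a
split accepted when a permutation test on that statistic gives p < 0.01 and
segments never dropping below 3 markers. Segments inherit the same
Z/q/state machinery as genes, computed from their constituent amplicons.

Per-sample QC uses MAPD (median absolute pairwise difference of adjacent
log2CNR, genomic order, after amplicon filtering) with a 0.50 failure
threshold, plus a 30% tumor-content floor where a flox target with expected
biallelic loss is available: that target's linear CNR is $1-p$, so tumor
content is $1 - \mathrm{CNR}$, clipped to $[0,1]$.

## Arm-level aneuploidy and the $R_c$ metric

A targeted panel does not see whole arms. For breadth of coverage $c$, the
coverage window of an arm is the centered interval of width
$\mathrm{round}(c \cdot L)$ (floor for the start), and $R_c$ is the
fraction of that window covered by the union of same-direction non-zero
segments. Gains and losses are evaluated separately; a direction is called
when $R_c$ meets the threshold (default $R_{0.6} \ge 0.8$) and the
directionality filter passes: at least a stated fraction of the genes on
the qualifying segments (all of them, for sparse gene-level panels; 0.3 to
0.5 for dense designs) altered in the call's direction, with unaltered
genes counting against the fraction. When both directions qualify the
larger $R_c$ wins; exact ties are refused with a warning — ties did not
arise in any cohort we simulated, and refusing is the conservative choice.
Reference calls for near-genome-wide assays use $R_{1.0} \ge 0.8$
(inclusive) with no directionality filter. Mouse autosomes are telocentric,
so a mouse layout carries one whole-chromosome arm per autosome and only
the 19 autosomes are considered.

Concordance against a reference call set reports PPA (direction-matched
recall over reference-altered cells), NPA, the full 3x3 confusion matrix,
and the 3-class macro-averaged recall. The last deserves a note: for any
fixed data, direction-matched PPA is mathematically non-increasing in the
$R_c$ threshold (raising the threshold can only shrink the qualified set,
and the larger-$R_c$ winner can never flip toward the correct direction),
so the well-known observation that stricter thresholds track better
agreement is a statement about the class-averaged metric, where suppressed
false positives raise the no-change class's recall. `run_coverage_simulation()`
therefore reports both `ppa` and `macro_ppa`, and the package's
threshold-correlation property is asserted on `macro_ppa`.

The marker-density harness (`subsample_markers()`,
`simulate_segmented_cohort()`) works at the marker level — the view an arm
caller sees after normalization — rather than re-simulating counts, which
keeps grid evaluations over coverage, thresholds and directionality
fractions fast. Planted whole-arm events use amplitude 0.8 in log2 units
with marker noise SD 0.1–0.25 depending on the scenario; null cohorts for
the false-positive checks use one marker per 10 Mb, the sparsest design
evaluated.

## Strain admixture

Inbred founder strains are homozygous, so each reference strain contributes
a 0/1 allele per SNP. Non-informative SNPs (zero entropy across the strains
of interest) are dropped; the remainder are ranked by multiple
correspondence analysis of the strain-by-allele indicator matrix (SVD of
the standardized residuals). A SNP's contribution is the sum over its two
indicator columns and the leading dimensions of the squared loading
weighted by the dimension's inertia share; with $k$ strains at most $k-1$
dimensions are informative, and on five synthetic strains four dimensions
separate all of them, which the tests assert. On the real panel this count
is an empirical observation that depends on the strains' divergence
structure, so it is only asserted on synthetic panels.

Admixture is estimated in supervised mode only (reference strains fixed):
the genotype likelihood is binomial with per-SNP alternate-allele
probability $f_j(Q) = \sum_s Q_s f_{js}$, maximized by EM on the simplex
from the barycenter — deterministic, with relative log-likelihood tolerance
1e-8 and a 2,000-iteration cap. Reference frequencies are clamped to
$[10^{-3}, 1-10^{-3}]$ so a single genotyping error against an inbred
reference cannot zero the likelihood. Samples below an 80% call rate are
QC-failed rather than estimated. SNPs lost to platform artifacts (e.g.
homopolymer-adjacent positions on semiconductor sequencers) are handled as
an input mask, not detected from sequence. Simulated crosses draw each
allele independently per SNP — no linkage, matching the sparse (~1.5 Mb)
marker spacing the panel design assumes.

## Cross-species hotspot mapping

Amino-acid positions map to genomic codons through CDS models (0-based
half-open exon intervals ordered 5'→3'; reverse-strand transcripts walk
descending coordinates; a codon may span an exon junction; stop-gain
positions map via index peptide length + 1). The forward and inverse maps
are verified to be mutually inverse on random models of both strands.

A hotspot is shared between species when (i) the focal residues are
identical and (ii) the mean local alignment score of the ±14-residue
windows is positive. Windows are pre-anchored, so the alignment is global;
the mean local score is the total alignment score, gap penalties included,
divided by the number of aligned columns (a no-gap-column denominator is
available behind a flag, since the exact denominator convention is not
pinned down by the original description). The default scoring matrix is
PAM30 with gap open 10 / extend 1: a standard published high-identity
matrix appropriate for the ~90% identity expected of cancer-gene orthologs,
and the matrix is fully configurable for users who prefer another
high-identity family. Under this scorer, identical windows always score
positive and randomly shuffled window pairs score non-positive >95% of the
time, which is the property that makes rule (ii) a usable chance filter.
The flank width (14) is exposed as a parameter.

The bundled SMAD4/PIK3CA fixture sequences are synthetic orthologous
stand-ins (labelled `synthetic` in the file names): random peptides
constructed so the focal arginine/glutamate, their conserved flanking
windows, and a one-residue upstream deletion in the mouse SMAD4 stand-in
reproduce the 361→360 and 545→545 index mapping. They exercise the mapping
rules, not the real Ensembl sequences, which are deliberately out of scope.

## Credentialing statistics

- **FGA** — genes with $|\log_2\mathrm{CNR}| > 0.2$ (strict) divided by
  genes measured, flox targets excluded; order-free by construction.
- **Copy-state score** — per arm, maximal runs of an identical state
  spanning ≥ 2 adjacent genes, summed over arms; a quiet genome scores one
  per arm, so the baseline equals the number of ≥2-gene arms. "Number of
  states" is read as the run count because that reading reproduces this
  baseline; a distinct-state mode is provided for the other reading.
- **Flox ratio** — Trp53-flox over Apc-flox log2CNR. The direction is fixed
  by the genotype expectations: with biallelic Apc loss in every tumor, the
  AK genotype (Trp53 flox intact) must give exactly 0, which only this
  orientation produces; homozygous Trp53 excision gives exactly 1 at any
  purity, and heterozygous excision gives $\log_2(1-p/2)/\log_2(1-p) \to
  1/2$ as purity $\to 0$.
- **Fisher tests** — exact hypergeometric p and the conditional-MLE odds
  ratio (not the sample cross-product), cross-checked in the tests against
  an exhaustive enumeration oracle.
- **Recurrent aneuploidy** — within-sample label permutation (each sample's
  arm labels shuffled without replacement, preserving per-sample burden);
  statistic per arm/direction is the two-proportion z of that arm versus
  the 18 others pooled (the tested arm's own events excluded from the
  pool); empirical p uses the +1 correction, so it is never exactly 0 — a
  reported 0 from enough permutations is best read as p < 1/n_perm. The
  +1-corrected p is conservative when the discrete statistic ties, so
  calibration should be judged on cohorts large enough that the statistic
  is effectively continuous; the direction of the bias is always
  conservative, never anticonservative.
- **Synteny scenarios** — for a recurrently gained human arm mapping to a
  set $S$ of mouse chromosomes, three scenarios are scored in the mouse
  cohort: all of $S$ gained, a proper nonempty subset gained ("singular"
  reads as ≥1-but-not-all by default, exactly-one behind a flag), or none.
  Because the human and mouse cohorts are unpaired, the joint statistic is
  the sum of the Haldane-corrected log odds of the human gain and of the
  mouse scenario event; scenarios 2 and 3 are compared to scenario 1 on the
  difference of these statistics against the permutation null, and
  scenario 1 against its own null. This is this package's concrete
  definition of the scenario log OR — the original description does not pin
  one down, and the underlying cohort matrices are not published — and it
  passes a three-way calibration: concordant data favor scenario 1,
  planted-subset data scenario 2, independent data none, and
  non-conserved events (normal instability elsewhere, $S$ never gained)
  scenario 3.

# Synthetic data: what it does and does not emulate

The generators cover tumors with known integer CN profiles, purity, ploidy,
GC bias and overdispersed counts; inbred reference panels and admixed
offspring (F1 crosses and arbitrary simplex mixtures, no linkage); ortholog
pairs with controlled per-position conservation; and sample-by-arm
aneuploidy matrices with planted recurrences. They do not emulate
FFPE-specific artifact spectra, platform error profiles (homopolymer
indels, strand bias — the variant filters implement the standard empirical
rules but the noise itself is not simulated), subclonal heterogeneity, or
linkage disequilibrium. Passing tests therefore demonstrate correctness of
the algorithms under the stated generative model, not robustness to every
artifact of real FFPE amplicon data.

# Numerical choices and problem sizes

All randomness flows from explicit seeds; identical seeds reproduce
identical outputs exactly. Counts at dispersion 0 are deterministic rounded
means, which the identity tests exploit. Default problem sizes in the test
suite — cohorts of 10–60 samples, panels of 50–1,000 amplicons, 200–1,000
permutations, 100 admixture replicates — were chosen as the smallest sizes
at which the asserted statistical properties are stable, and the full suite
runs in a few minutes on one core.

# Known limitations

Allele-specific copy number, ploidy inference from allele frequencies,
tumor mutational burden, HRD scar scores and read-level simulation are out
of scope. The directionality filter assumes gene-level calls exist on the
arm being called; arms with no genes under the qualifying segments fall
back to a zero fraction and are never called when the filter is active.
The conditional-MLE odds ratio is undefined for tables with a zero margin
and reported as NA with p = 1.
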