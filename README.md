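# mousecgp

Genomic credentialing of mouse tumor models from targeted amplicon panels.

Genetically engineered mouse models (GEMMs) of cancer are mostly profiled
with small multiplex-PCR panels — a few hundred kilobases of amplicons —
because the lesions are minute and often formalin-fixed. Whether such a
panel can faithfully report the genomic features that matter for
credentialing a model against its human counterpart (engineered flox-site
excisions, conserved hotspot mutations, gene-level copy number,
chromosome-arm aneuploidy, strain admixture, genomic-instability burden)
is a quantitative question. `mousecgp` implements the full analysis stack
and the simulations needed to answer it:

- **Copy number** — pooled-normal amplicon normalization with GC loess,
  per-gene Z/p/q calls with a noise-zeroing rule, CBS-style segmentation,
  MAPD QC, tumor content from flox-site CNR (TC = 1 − CNR), and
  purity/ploidy scaling to integer copy number,
  CN̂ = (2^log2CNR · (pψ + 2(1−p)) − 2(1−p)) / p.
- **Aneuploidy under partial coverage** — the R_c metric: the fraction of
  an arm's coverage window (breadth c, centered at the arm midpoint)
  covered by same-direction CNA segments, called at R_0.6 ≥ 0.8 by default
  with a gene directionality filter; reference calls at R_1.0 ≥ 0.8;
  PPA/NPA concordance; marker-subsampling and coverage-grid harnesses.
- **Strain admixture** — entropy filtering and multiple-correspondence-
  analysis ranking of genotyping SNPs; supervised maximum-likelihood
  admixture on the simplex (binomial genotype model, EM from the
  barycenter); SNP-set-size error benchmarks.
- **Cross-species hotspots** — amino acid ↔ genomic codon maps through CDS
  models, windowed (±14 residue) high-identity protein alignment, and the
  shared-hotspot rule: focal residues identical AND mean local alignment
  score > 0.
- **Credentialing statistics** — fraction of genes altered (|log2CNR| >
  0.2), per-arm copy-state scores, flox-site signal ratios with genotype
  regression, exact Fisher tests (conditional-MLE odds ratios),
  within-sample permutation tests for recurrent aneuploidy, and
  synteny-aware cross-species scenario tests.
- **Synthetic data** — generators for every input (tumor truth profiles,
  overdispersed amplicon counts, inbred strain panels and crosses,
  ortholog pairs, aneuploidy matrices) with known ground truth and full
  seed reproducibility.

See `vignettes/credentialing-methods.Rmd` for the models, parameter
choices and limitations.

## Worked example

Simulate a colorectal-style AKP tumor — homozygous excision of both the
Apc and Trp53 flox targets, a whole-chromosome 15 gain to CN 3, purity
0.6 — on a 104-amplicon panel, then run the pipeline:

```r
library(mousecgp)
layout <- mouse_layout()
set.seed(1)
mk <- function(gene, chrom, mb, n = 8, class = "cn-tiling") {
  data.frame(id = paste0(gene, "_", seq_len(n), "_", class), chrom = chrom,
             start = mb * 1e6 + (seq_len(n) - 1) * 1000,
             end = mb * 1e6 + (seq_len(n) - 1) * 1000 + 100,
             gene = gene, class = class, gc = runif(n, 0.35, 0.6), pool = "p1")
}
panel <- amplicon_panel(rbind(
  mk("Apc", "chr18", 34), mk("Smad4", "chr18", 61),
  mk("Trp53", "chr11", 69), mk("Brca1", "chr11", 101),
  mk("Kras", "chr6", 145), mk("Pten", "chr19", 32),
  mk("Myc", "chr15", 61), mk("Ctnnb1", "chr15", 25),
  mk("Fgfr2", "chr15", 45), mk("Trp53bp1", "chr15", 78),
  mk("Ntrk3", "chr15", 95), mk("Nf1", "chr11", 79),
  mk("Apc", "chr18", 34.5, 4, "flox"), mk("Trp53", "chr11", 69.5, 4, "flox")),
  layout)

truth <- simulate_cn_profile(layout,
  events = data.frame(chrom = "chr15", start = 0, end = 104e6, cn = 3),
  flox = data.frame(target = c("Apc_flox", "Trp53_flox"), cn = 0),
  purity = 0.6)
counts <- simulate_read_counts(
  list(tumor = truth, N1 = NULL, N2 = NULL, N3 = NULL),
  panel, depth = 2500, dispersion = 0.002, gc_bias = NULL, seed = 7)

cnr   <- normalize_counts(counts, panel, c("N1", "N2", "N3"),
                          gc_correct = FALSE)   # no GC bias simulated here
calls <- call_genes(cnr, "tumor")
calls[, c("target", "chrom", "log2cnr", "q", "state")]
```

```
       target chrom log2cnr        q state
1       Trp53 chr11 -0.0338  6.7e-08    -1
2  Trp53_flox chr11 -1.4468  0.0e+00    -1
3         Nf1 chr11 -0.0833  4.5e-11    -1
4       Brca1 chr11 -0.0071  4.4e-01     0
5      Ctnnb1 chr15  0.3348  3.5e-15     1
6       Fgfr2 chr15  0.3494 4.8e-254     1
7         Myc chr15  0.2732  1.4e-59     1
8    Trp53bp1 chr15  0.2816 9.2e-204     1
9       Ntrk3 chr15  0.2976 6.5e-154     1
10        Apc chr18 -0.0588  2.1e-12    -1
11   Apc_flox chr18 -1.3973  0.0e+00    -1
12      Smad4 chr18 -0.0597  1.9e-02    -1
13       Pten chr19 -0.0759  4.1e-02    -1
14       Kras  chr6 -0.0506  1.4e-01     0
```

Both flox targets sit near log2(0.4) ≈ −1.32, the expected signal for a
biallelically excised region at purity 0.6; the chr15 genes sit near
log2(1.3) ≈ +0.38 less a small compositional deflation (a 5-of-12-gene
gain is a large mass fraction on a demo panel this size — on a
hundred-gene panel the effect is negligible, which is itself one reason
larger panels credential better).

```r
flox_ratio(calls)$ratio                                  # Trp53:Apc flox signal
estimate_tumor_content(calls, "Trp53_flox")$tumor_content
```

```
flox ratio (Trp53:Apc) = 1.04 | tumor content = 0.63
```

The ratio ≈ 1 is the signature of the AKP^fl/fl genotype (both targets
biallelically lost; AK tumors give exactly 0, heterozygous AKP^fl tumors
approach 0.5), and 1 − CNR at the Trp53 flox site recovers the simulated
purity 0.6.

```r
segs <- segment_profile(cnr, "tumor", seed = 7)
arm  <- call_arm_aneuploidy(segs, calls, layout, c = 0.6, rc_threshold = 0.8)
arm[arm$direction != 0, ]
fga  <- fraction_genes_altered(calls)
```

```
   arm direction   rc_gain rc_loss   c gene_fraction
 chr15         1 0.9326763       0 0.6             1
FGA = 0.42 (5 of 12 genes altered)
```

The chr15 gain covers 93% of the coverage-restricted window (R_0.6 =
0.93 ≥ 0.8) with every chr15 gene altered in the same direction, so the
arm is called as a gain; no other arm qualifies.

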