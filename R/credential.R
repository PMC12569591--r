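#' Fraction of genes altered (FGA)
#'
#' A gene is altered when |log2CNR| exceeds `threshold` (strictly); the FGA
#' is the altered count divided by the genes measured. Flox targets are
#' excluded (they report engineered recombination, not somatic CNAs).
#'
#' @param gene_calls gene-call table ([call_genes()] output).
#' @param threshold |log2CNR| alteration threshold (default 0.2, strict >).
#' @param genes optional character vector restricting the evaluated gene
#'   set (e.g. autosomal genes with > 3 amplicons).
#' @return list of class `fga_result`: `sample`, `fga`, `n_altered`,
#'   `n_genes`, `threshold`.
#' @export
fraction_genes_altered <- function(gene_calls, threshold = 0.2,
                                   genes = NULL) {
  g <- gene_calls
  if ("flox" %in% names(g)) g <- g[!g$flox, , drop = FALSE]
  if (!is.null(genes)) g <- g[g$target %in% genes, , drop = FALSE]
  if (!nrow(g)) stop("empty gene set")
  altered <- abs(g$log2cnr) > threshold
  structure(list(sample = attr(gene_calls, "sample"),
                 fga = sum(altered) / nrow(g),
                 n_altered = sum(altered), n_genes = nrow(g),
                 threshold = threshold),
            class = "fga_result")
}

#' Copy-state score (genomic-instability surrogate)
#'
#' Per chromosome arm, counts the maximal runs of an identical copy state
#' (gain, loss or no change) spanning at least two adjacent genes, then
#' sums over arms. An unaltered genome scores one run per arm, so the
#' baseline equals the number of arms with >= 2 genes. The
#' `"distinct"` mode instead counts the distinct states among qualifying
#' runs per arm.
#'
#' @param gene_calls gene-call table in genome order (flox targets
#'   excluded automatically).
#' @param layout a `genome_layout` used to assign genes to arms.
#' @param min_run minimum adjacent genes for a state to count (default 2).
#' @param mode `"runs"` (count of qualifying runs) or `"distinct"`.
#' @return list of class `copy_state_score`: `per_arm` (named counts),
#'   `total`, `skipped_arms` (arms with < 2 genes).
#' @export
copy_state_score <- function(gene_calls, layout, min_run = 2,
                             mode = c("runs", "distinct")) {
  mode <- match.arg(mode)
  g <- gene_calls
  if ("flox" %in% names(g)) g <- g[!g$flox, , drop = FALSE]
  arms <- layout$arms
  per_arm <- stats::setNames(integer(nrow(arms)), arms$arm)
  skipped <- character(0)
  for (a in seq_len(nrow(arms))) {
    on_arm <- g$chrom == arms$chrom[a] &
      g$start < arms$end[a] & g$end > arms$start[a]
    ga <- g[on_arm, , drop = FALSE]
    ga <- ga[order(ga$start), , drop = FALSE]
    if (nrow(ga) < min_run) {
      skipped <- c(skipped, arms$arm[a])
      next
    }
    r <- rle(ga$state)
    qual <- r$lengths >= min_run
    per_arm[a] <- if (mode == "runs") sum(qual) else
      length(unique(r$values[qual]))
  }
  structure(list(per_arm = per_arm, total = sum(per_arm),
                 skipped_arms = skipped),
            class = "copy_state_score")
}

#' Flox-site log2CNR signal ratio
#'
#' Ratio of the numerator flox target's log2CNR to the denominator's
#' (Trp53 flox over Apc flox for the colorectal models, where every tumor
#' carries a biallelic Apc flox loss). Under biallelic loss of both
#' targets the expected ratio is exactly 1 at any purity; with the
#' numerator intact it is exactly 0; with a heterozygous numerator
#' deletion it is log2(1 - p/2)/log2(1 - p), which tends to 1/2 in the
#' low-purity limit.
#'
#' @param gene_calls gene-call table containing both flox targets.
#' @param numerator,denominator flox target labels.
#' @return list of class `flox_ratio`: `sample`, `numerator`,
#'   `denominator`, `num_log2cnr`, `den_log2cnr`, `ratio` (NA when the
#'   denominator log2CNR is 0).
#' @export
flox_ratio <- function(gene_calls, numerator = "Trp53_flox",
                       denominator = "Apc_flox") {
  i <- match(numerator, gene_calls$target)
  j <- match(denominator, gene_calls$target)
  if (is.na(i) || is.na(j))
    stop("flox target(s) missing from gene calls")
  num <- gene_calls$log2cnr[i]
  den <- gene_calls$log2cnr[j]
  structure(list(sample = attr(gene_calls, "sample"),
                 numerator = numerator, denominator = denominator,
                 num_log2cnr = num, den_log2cnr = den,
                 ratio = if (den == 0) NA_real_ else num / den),
            class = "flox_ratio")
}

#' Regression of flox ratios on genotype
#'
#' Linear model of the flox-site signal ratio on the genotype category
#' (no intercept, so coefficients are per-genotype means), used to verify
#' engineered-deletion expectations (e.g. 1, 0.5 and 0 for homozygous,
#' heterozygous and absent numerator deletions).
#'
#' @param data data.frame with columns `ratio` and `genotype`.
#' @param min_tumor_content optional filter applied when a
#'   `tumor_content` column is present (default 0.3).
#' @return list: `coefficients` (per-genotype mean, se, p), `fit` (the lm),
#'   `n_excluded` (undefined ratios and low-tumor-content samples).
#' @export
genotype_ratio_regression <- function(data, min_tumor_content = 0.3) {
  stopifnot(all(c("ratio", "genotype") %in% names(data)))
  n0 <- nrow(data)
  if ("tumor_content" %in% names(data))
    data <- data[data$tumor_content >= min_tumor_content, , drop = FALSE]
  data <- data[is.finite(data$ratio), , drop = FALSE]
  fit <- stats::lm(ratio ~ 0 + genotype, data = data)
  co <- summary(fit)$coefficients
  tab <- data.frame(genotype = sub("^genotype", "", rownames(co)),
                    mean = co[, "Estimate"], se = co[, "Std. Error"],
                    p = co[, "Pr(>|t|)"], row.names = NULL)
  list(coefficients = tab, fit = fit, n_excluded = n0 - nrow(data))
}

#' Fisher exact test on a 2x2 table
#'
#' Exact p from the (non)central hypergeometric distribution (two-sided:
#' total probability of tables no more likely than the observed) and the
#' conditional maximum-likelihood odds ratio. A zero margin makes the odds
#' ratio undefined (NA) with p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list: `odds_ratio` (conditional MLE), `p_value`, `alternative`.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2),
            all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1,
                alternative = alternative))
  ft <- stats::fisher.test(table, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       alternative = alternative)
}

#' Map a genomic interval through a synteny block table
#'
#' Intersects the interval with the human side of every block and reports,
#' per mouse chromosome, the percent synteny: total intersected block
#' length divided by the interval length. Optionally intersects the
#' interval with supplied peak intervals.
#'
#' @param chrom,start,end the human query interval (0-based half-open).
#' @param synteny block table (see [read_synteny()]).
#' @param peaks optional data.frame of intervals (`chrom`, `start`, `end`)
#'   to intersect with the query.
#' @return list: `blocks` (intersected block rows with `overlap_bp`),
#'   `percent_synteny` (named by mouse chromosome), `peak_overlaps`.
#' @export
map_syntenic <- function(chrom, start, end, synteny, peaks = NULL) {
  stopifnot(end > start)
  b <- synteny[synteny$hchrom == chrom &
                 synteny$hstart < end & synteny$hend > start, , drop = FALSE]
  if (!nrow(b)) {
    warning("no syntenic blocks overlap the interval")
    return(list(blocks = b, percent_synteny = numeric(0),
                peak_overlaps = NULL))
  }
  b$overlap_bp <- pmin(b$hend, end) - pmax(b$hstart, start)
  pct <- c(tapply(b$overlap_bp, b$mchrom, sum)) / (end - start)
  peak_overlaps <- NULL
  if (!is.null(peaks)) {
    p <- peaks[peaks$chrom == chrom &
                 peaks$start < end & peaks$end > start, , drop = FALSE]
    if (nrow(p)) {
      p$overlap_start <- pmax(p$start, start)
      p$overlap_end <- pmin(p$end, end)
    }
    peak_overlaps <- p
  }
  list(blocks = b,
       percent_synteny = sort(pct[pct > 0], decreasing = TRUE),
       peak_overlaps = peak_overlaps)
}
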