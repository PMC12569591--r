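#' Per-sample sequencing / profile QC
#'
#' MAPD (median absolute pairwise difference) is the median of
#' |log2CNR[i+1] - log2CNR[i]| over amplicons adjacent in genomic order
#' (after amplicon filtering); profiles with MAPD > 0.50 are unreliable.
#' Uniformity is the fraction of amplicons with at least 20% of the mean
#' depth. When a tumor-content estimate is supplied the 30% floor is also
#' checked.
#'
#' @param counts integer vector of the sample's amplicon counts (panel order).
#' @param cnrset a `cnr_set` (for the retained panel and log2CNR).
#' @param sample sample id.
#' @param mapd_max MAPD pass threshold.
#' @param tumor_content optional tumor-content estimate in [0, 1].
#' @param min_tumor_content tumor-content pass threshold.
#' @return list of class `qc_report`: `mean_depth`, `on_target_fraction`,
#'   `uniformity`, `mapd`, `tumor_content`, `pass_mapd`, `pass_tumor_content`,
#'   `pass`.
#' @export
qc_sample <- function(counts, cnrset, sample, mapd_max = 0.5,
                      tumor_content = NULL, min_tumor_content = 0.3) {
  stopifnot(inherits(cnrset, "cnr_set"))
  p <- cnrset$panel
  v <- cnrset$log2cnr[, sample]
  ord <- order(p$chrom, p$start)
  d <- diff(v[ord])
  same_chrom <- p$chrom[ord][-1] == p$chrom[ord][-length(ord)]
  mapd <- stats::median(abs(d[same_chrom]))
  mean_depth <- mean(counts)
  uniformity <- mean(counts >= 0.2 * mean_depth)
  pass_mapd <- mapd <= mapd_max
  pass_tc <- if (is.null(tumor_content)) NA else
    tumor_content >= min_tumor_content
  structure(list(mean_depth = mean_depth, on_target_fraction = 1,
                 uniformity = uniformity, mapd = mapd,
                 tumor_content = tumor_content,
                 pass_mapd = pass_mapd, pass_tumor_content = pass_tc,
                 pass = pass_mapd && !isFALSE(pass_tc)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> depth %.0f | uniformity %.2f | MAPD %.3f | %s\n",
              x$mean_depth, x$uniformity, x$mapd,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Tumor content from a biallelically lost flox target
#'
#' With both flox alleles excised in tumor cells, the flox region's linear
#' CNR equals 1 - p, so tumor content is 1 - CNR (clipped to [0, 1]).
#'
#' @param gene_calls gene-call table from [call_genes()].
#' @param flox_target flox target label (e.g. `"Trp53_flox"`).
#' @return list: `flox_target`, `cnr` (linear), `tumor_content`.
#' @export
estimate_tumor_content <- function(gene_calls, flox_target) {
  i <- match(flox_target, gene_calls$target)
  if (is.na(i)) stop("flox target not in gene calls: ", flox_target)
  cnr <- 2^gene_calls$log2cnr[i]
  list(flox_target = flox_target, cnr = cnr,
       tumor_content = min(1, max(0, 1 - cnr)))
}

#' Scale log2CNR to estimated tumor copy number
#'
#' Inverts the purity/ploidy mixture: CN = (2^log2CNR * (p*psi + 2(1-p)) -
#' 2(1-p)) / p, optionally rounded to the nearest non-negative integer.
#' Non-physical negative estimates are clipped to 0 with a warning.
#'
#' @param log2cnr numeric vector of log2 copy-number ratios.
#' @param purity tumor purity in (0, 1].
#' @param ploidy tumor ploidy (> 0).
#' @param round round to the nearest integer?
#' @return estimated tumor copy numbers.
#' @export
scale_cnr <- function(log2cnr, purity, ploidy = 2, round = FALSE) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (ploidy <= 0) stop("ploidy must be > 0")
  cn <- (2^log2cnr * (purity * ploidy + 2 * (1 - purity)) -
           2 * (1 - purity)) / purity
  if (any(cn < 0, na.rm = TRUE)) {
    warning("negative copy-number estimates clipped to 0")
    cn[cn < 0] <- 0
  }
  if (round) cn <- round(cn)
  cn
}
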