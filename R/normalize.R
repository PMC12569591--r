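#' Normalize amplicon read counts to log2 copy-number ratios
#'
#' Stages, in order: (1) drop amplicons whose pooled-normal mean raw count
#' falls in the bottom 5th percentile; (2) total-count normalize each
#' sample; (3) per-amplicon ratio against the weighted pooled normal (mean
#' of the total-normalized normals, optional per-normal weights); (4) log2;
#' (5) per-sample loess correction of log2CNR on amplicon GC fraction
#' (robust fit, span 0.5); profiles are then median-centered so a diploid
#' background sits at log2CNR ~ 0.
#'
#' @param counts integer matrix amplicons x samples (rownames = amplicon ids).
#' @param panel the `amplicon_panel` describing the rows.
#' @param normal_ids character vector (>= 2) of normal sample columns.
#' @param weights optional per-normal weights (default equal).
#' @param drop_quantile quantile of pooled-normal mean counts below which
#'   amplicons are dropped (default 0.05).
#' @param pseudocount added to all counts before ratio formation.
#' @param include_snps keep genotyping-SNP amplicons in the profile?
#' @param gc_correct apply the loess GC correction? (skipped automatically
#'   when the panel's GC spread is negligible or too few amplicons remain).
#' @param span loess span for the GC fit.
#' @return object of class `cnr_set`: list with `log2cnr` (matrix retained
#'   amplicons x samples), `panel` (retained rows), `normal_ids`.
#' @export
normalize_counts <- function(counts, panel, normal_ids, weights = NULL,
                             drop_quantile = 0.05, pseudocount = 0.5,
                             include_snps = TRUE, gc_correct = TRUE,
                             span = 0.5) {
  stopifnot(inherits(panel, "amplicon_panel"),
            is.matrix(counts), nrow(counts) == nrow(panel))
  if (!all(rownames(counts) == panel$id))
    stop("count rows must match the panel's amplicon ids in order")
  if (length(normal_ids) < 2) stop("at least 2 normal samples are required")
  if (!all(normal_ids %in% colnames(counts)))
    stop("normal ids not present in counts")
  totals0 <- colSums(counts)
  if (any(totals0 == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[totals0 == 0], collapse = ", "))
  keep <- rep(TRUE, nrow(panel))
  if (!include_snps) keep <- panel$class != "genotyping-snp"
  # (1) low-coverage amplicon filter on pooled-normal mean raw counts
  nm <- rowMeans(counts[, normal_ids, drop = FALSE])
  cut <- stats::quantile(nm[keep], drop_quantile)
  keep <- keep & nm >= cut
  counts <- counts[keep, , drop = FALSE]
  p <- panel[keep, , drop = FALSE]
  # (2) total-count normalization (pseudocount guards zero counts)
  x <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  # (3) weighted pooled normal
  if (is.null(weights)) weights <- rep(1, length(normal_ids))
  weights <- weights / sum(weights)
  pool <- as.vector(x[, normal_ids, drop = FALSE] %*% weights)
  # (4) log2 ratio
  l <- log2(sweep(x, 1, pool, "/"))
  # (5) GC loess per sample, then median centering
  gc <- p$gc
  do_gc <- gc_correct && nrow(p) >= 10 && stats::sd(gc) > 1e-3
  for (s in seq_len(ncol(l))) {
    v <- l[, s]
    if (do_gc) {
      # near-constant response (e.g. noise-free data) makes the local fits
      # singular; loess falls back to a pseudoinverse and warns, harmlessly
      suppressWarnings({
        fit <- stats::loess(v ~ gc, span = span, family = "symmetric",
                            degree = 2,
                            control = stats::loess.control(iterations = 2,
                                                           surface = "direct"))
        v <- v - stats::predict(fit, gc)
      })
    }
    l[, s] <- v - stats::median(v)
  }
  structure(list(log2cnr = l, panel = p, normal_ids = normal_ids),
            class = "cnr_set")
}

#' @export
print.cnr_set <- function(x, ...) {
  cat("<cnr_set>", nrow(x$log2cnr), "amplicons x", ncol(x$log2cnr),
      "samples (", length(x$normal_ids), "normals )\n")
  invisible(x)
}
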