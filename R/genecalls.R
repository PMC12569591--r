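#' Gene-level copy-number calls for one sample
#'
#' Summarizes each calling target's amplicon log2CNR (mean by default;
#' median reproduces bin-median calling for sparse designs), computes a
#' Z-score against the pool of normals' per-gene summaries, converts to
#' two-tailed normal p values, applies Benjamini-Hochberg correction across
#' genes within the sample, and assigns a copy state: sign of the log2CNR
#' unless the noise-zeroing rule fires. With `zero_rule = "and"` (the
#' literal reading) a gene is zeroed when q > q_max AND |log2CNR| <
#' cnr_floor; `"or"` zeroes when either holds.
#'
#' Genotyping-SNP amplicons never form genes; flox targets are separate
#' genes (split from their parent before calling).
#'
#' @param cnrset a `cnr_set` from [normalize_counts()].
#' @param sample sample id to call.
#' @param q_max FDR threshold for the zeroing rule.
#' @param cnr_floor log2CNR magnitude floor for the zeroing rule.
#' @param summary amplicon summary statistic per gene.
#' @param zero_rule conjunction used by the noise-zeroing rule.
#' @return data.frame with `target`, `chrom`, `start`, `end`,
#'   `n_amplicons`, `flox`, `log2cnr`, `z`, `p`, `q`, `state`. Genes whose
#'   normal-pool SD is zero are flagged (`sd_zero`), get NA z/p/q and state
#'   0, with a warning.
#' @export
call_genes <- function(cnrset, sample, q_max = 0.05, cnr_floor = 0.2,
                       summary = c("mean", "median"),
                       zero_rule = c("and", "or")) {
  summary <- match.arg(summary)
  zero_rule <- match.arg(zero_rule)
  stopifnot(inherits(cnrset, "cnr_set"))
  if (!sample %in% colnames(cnrset$log2cnr)) stop("unknown sample: ", sample)
  p <- cnrset$panel
  genic <- p$class != "genotyping-snp"
  sp <- split(which(genic), p$target[genic])
  fun <- if (summary == "mean") mean else stats::median
  gi <- gene_intervals(p)
  summarize <- function(col) vapply(sp, function(i) fun(col[i]), numeric(1))
  v <- summarize(cnrset$log2cnr[, sample])
  norm <- vapply(cnrset$normal_ids,
                 function(n) summarize(cnrset$log2cnr[, n]),
                 numeric(length(sp)))
  mu <- rowMeans(norm)
  sd <- apply(norm, 1, stats::sd)
  z <- (v - mu) / sd
  z[sd == 0] <- NA
  pval <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(pval, "BH")
  state <- sign(v)
  zero <- if (zero_rule == "and") {
    (is.na(q) | q > q_max) & abs(v) < cnr_floor
  } else {
    (is.na(q) | q > q_max) | abs(v) < cnr_floor
  }
  state[zero] <- 0
  sd_zero <- sd == 0
  state[sd_zero] <- 0
  if (any(sd_zero))
    warning(sum(sd_zero), " gene(s) with zero normal-pool SD; state forced 0")
  out <- data.frame(target = names(sp), log2cnr = v, z = z, p = pval, q = q,
                    state = as.integer(state), sd_zero = sd_zero,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- merge(gi, out, by = "target", sort = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample") <- sample
  out
}
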