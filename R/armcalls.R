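#' R_c: coverage-restricted proportion of a chromosome arm altered
#'
#' R_c is the fraction of the arm's coverage window (breadth c, centered at
#' the arm midpoint) covered by the union of same-direction CNA segments.
#'
#' @param segments data.frame with `start`, `end` (0-based half-open) for
#'   one direction on the window's chromosome; non-overlapping.
#' @param window one row of [build_arm_windows()] (or any list with
#'   `start`, `end`).
#' @return R_c in [0, 1].
#' @export
compute_rc <- function(segments, window) {
  w <- window$end - window$start
  if (w <= 0) stop("zero-length window")
  if (is.null(segments) || nrow(segments) == 0) return(0)
  interval_overlap(segments$start, segments$end,
                   window$start, window$end) / w
}

#' Arm-level aneuploidy calls with the gene directionality filter
#'
#' Gains and losses are evaluated independently per arm: the union of
#' same-direction non-zero segments is overlapped with the arm's coverage
#' window. A direction is called when its R_c meets `rc_threshold` AND at
#' least `min_direction_fraction` of the relevant genes are altered in that
#' direction (genes with state 0 count against the fraction). When both
#' directions qualify the larger R_c wins; an exact tie is called `none`
#' with a warning.
#'
#' @param segments segment table for one sample ([segment_profile()] output
#'   or equivalent with `chrom`, `start`, `end`, `state`).
#' @param gene_calls gene-call table for the sample (`chrom`, `start`,
#'   `end`, `state`); flox targets are ignored when a `flox` column is
#'   present.
#' @param layout a `genome_layout`.
#' @param c breadth of coverage for the windows.
#' @param rc_threshold minimum R_c to call a direction.
#' @param min_direction_fraction minimum fraction of genes altered in the
#'   call's direction (1.0 for sparse gene-level panels; 0.3-0.5 for dense
#'   designs). Use 0 to disable the directionality filter.
#' @param genes_on `"segments"` counts genes overlapping the qualifying
#'   segments; `"arm"` counts all genes on the arm.
#' @return data.frame, one row per arm: `arm`, `direction` (-1/0/+1),
#'   `rc_gain`, `rc_loss`, `c`, `gene_fraction` (directional fraction for
#'   the called direction, NA when no call).
#' @export
call_arm_aneuploidy <- function(segments, gene_calls, layout, c = 0.6,
                                rc_threshold = 0.8,
                                min_direction_fraction = 1.0,
                                genes_on = c("segments", "arm")) {
  genes_on <- match.arg(genes_on)
  if (min_direction_fraction > 1)
    stop("min_direction_fraction must be <= 1")
  windows <- build_arm_windows(layout, c)
  if (!is.null(gene_calls) && "flox" %in% names(gene_calls))
    gene_calls <- gene_calls[!gene_calls$flox, , drop = FALSE]
  out <- lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    segs <- segments[segments$chrom == w$chrom, , drop = FALSE]
    eval_dir <- function(d) {
      s <- segs[segs$state == d, , drop = FALSE]
      rc <- compute_rc(s, w)
      frac <- NA_real_
      if (!is.null(gene_calls)) {
        g <- gene_calls[gene_calls$chrom == w$chrom, , drop = FALSE]
        if (genes_on == "segments" && nrow(s)) {
          hit <- rep(FALSE, nrow(g))
          for (j in seq_len(nrow(s)))
            hit <- hit | (g$start < s$end[j] & g$end > s$start[j])
          g <- g[hit, , drop = FALSE]
        }
        frac <- if (nrow(g)) mean(g$state == d) else 0
      }
      qual <- rc >= rc_threshold &&
        (min_direction_fraction == 0 || is.null(gene_calls) ||
           (!is.na(frac) && frac >= min_direction_fraction))
      list(rc = rc, frac = frac, qual = qual)
    }
    gain <- eval_dir(1L); loss <- eval_dir(-1L)
    dir <- 0L; frac <- NA_real_
    if (gain$qual && loss$qual) {
      if (gain$rc == loss$rc) {
        warning("gain/loss R_c tie on arm ", w$arm, "; no call")
      } else if (gain$rc > loss$rc) {
        dir <- 1L; frac <- gain$frac
      } else {
        dir <- -1L; frac <- loss$frac
      }
    } else if (gain$qual) {
      dir <- 1L; frac <- gain$frac
    } else if (loss$qual) {
      dir <- -1L; frac <- loss$frac
    }
    data.frame(arm = w$arm, direction = dir, rc_gain = gain$rc,
               rc_loss = loss$rc, c = c, gene_fraction = frac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reference arm calls at full coverage
#'
#' Reference aneuploidy definition for near genome-wide assays: a direction
#' is called when its R_1.0 (whole-arm overlap) is >= `rc_threshold`; no
#' directionality filter.
#'
#' @param segments_by_sample named list of per-sample segment tables.
#' @param layout a `genome_layout`.
#' @param rc_threshold reference threshold (default 0.8, inclusive).
#' @return aneuploidy matrix (samples x arms, entries -1/0/+1).
#' @export
reference_arm_calls <- function(segments_by_sample, layout,
                                rc_threshold = 0.8) {
  arms <- layout$arms$arm
  m <- matrix(0L, length(segments_by_sample), length(arms),
              dimnames = list(names(segments_by_sample), arms))
  for (s in names(segments_by_sample)) {
    calls <- call_arm_aneuploidy(segments_by_sample[[s]], gene_calls = NULL,
                                 layout = layout, c = 1.0,
                                 rc_threshold = rc_threshold,
                                 min_direction_fraction = 0)
    m[s, calls$arm] <- calls$direction
  }
  m
}

#' Concordance between two aneuploidy matrices
#'
#' PPA (positive percent agreement) is the direction-matched fraction of
#' reference-altered cells; NPA is the fraction of reference-unaltered
#' cells called unaltered. The full 3x3 confusion matrix and the per-class
#' recalls (macro-averaged as `macro_ppa`) are also returned.
#'
#' @param calls,reference aneuploidy matrices (same samples x arms).
#' @return list: `ppa`, `npa`, `macro_ppa`, `confusion` (3x3, reference in
#'   rows).
#' @export
evaluate_concordance <- function(calls, reference) {
  if (!identical(dim(calls), dim(reference)))
    stop("calls and reference must have identical dimensions")
  lev <- c(-1, 0, 1)
  confusion <- table(factor(reference, lev), factor(calls, lev),
                     dnn = c("reference", "call"))
  altered <- reference != 0
  ppa <- if (any(altered)) mean(calls[altered] == reference[altered]) else NA
  npa <- if (any(!altered)) mean(calls[!altered] == 0) else NA
  recalls <- diag(confusion) / rowSums(confusion)
  macro_ppa <- mean(recalls, na.rm = TRUE)
  list(ppa = ppa, npa = npa, macro_ppa = macro_ppa, confusion = confusion)
}
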