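#' Simulate a tumor copy-number truth profile
#'
#' Builds a piecewise-constant integer copy-number profile over the genome,
#' with optional engineered flox deletions that are independent of the
#' parent gene's copy number. The expected copy-number ratio at any locus
#' under an admixed tumor of purity p and tumor ploidy psi is
#' (p * CN + 2 (1 - p)) / (p * psi + 2 (1 - p)).
#'
#' @param layout a `genome_layout`.
#' @param events data.frame with columns `chrom`, `start`, `end`, `cn`
#'   (integer tumor copy number over the interval); may be empty/NULL.
#'   Overlapping events with conflicting CN are rejected.
#' @param flox data.frame with columns `target` (flox target label, e.g.
#'   `"Trp53_flox"`), `cn` (copy number of the flox region in tumor cells);
#'   may be NULL.
#' @param purity tumor purity p in [0, 1].
#' @param ploidy tumor ploidy psi (> 0); the background copy number outside
#'   events is 2 (diploid) and psi is the normalization reference.
#' @return object of class `truth_profile`.
#' @export
simulate_cn_profile <- function(layout, events = NULL, flox = NULL,
                                purity = 1, ploidy = 2) {
  stopifnot(inherits(layout, "genome_layout"))
  if (purity < 0 || purity > 1) stop("purity must be in [0, 1]")
  if (ploidy <= 0) stop("ploidy must be > 0")
  if (is.null(events)) events <- data.frame(chrom = character(), start = numeric(),
                                            end = numeric(), cn = numeric())
  stopifnot(all(c("chrom", "start", "end", "cn") %in% names(events)))
  if (any(events$cn < 0)) stop("copy numbers must be >= 0")
  m <- match(events$chrom, layout$chroms$chrom)
  if (anyNA(m)) stop("event chromosome not in layout")
  if (any(events$start < 0 | events$end > layout$chroms$length[m]))
    stop("event outside layout")
  # conflicting overlaps
  if (nrow(events) > 1) {
    for (ch in unique(events$chrom)) {
      e <- events[events$chrom == ch, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1) {
        ov <- e$start[-1] < e$end[-nrow(e)]
        conf <- ov & (e$cn[-1] != e$cn[-nrow(e)])
        if (any(conf)) stop("overlapping events with conflicting CN on ", ch)
      }
    }
  }
  if (!is.null(flox)) {
    stopifnot(all(c("target", "cn") %in% names(flox)))
    if (any(flox$cn < 0)) stop("flox copy numbers must be >= 0")
  }
  structure(list(layout = layout, events = events, flox = flox,
                 purity = purity, ploidy = ploidy),
            class = "truth_profile")
}

#' @export
print.truth_profile <- function(x, ...) {
  cat("<truth_profile> purity", x$purity, "ploidy", x$ploidy, "|",
      nrow(x$events), "events,",
      if (is.null(x$flox)) 0 else nrow(x$flox), "flox deletions\n")
  invisible(x)
}

#' Tumor copy number of a truth profile at given loci
#'
#' @param truth a `truth_profile`.
#' @param chrom,pos vectors of loci (pos in bp).
#' @param target optional target labels; flox targets override positional CN.
#' @return integer tumor copy number per locus (background 2).
#' @export
truth_cn <- function(truth, chrom, pos, target = NULL) {
  cn <- rep(2, length(chrom))
  e <- truth$events
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      hit <- chrom == e$chrom[i] & pos >= e$start[i] & pos < e$end[i]
      cn[hit] <- e$cn[i]
    }
  }
  if (!is.null(target) && !is.null(truth$flox)) {
    m <- match(target, truth$flox$target)
    cn[!is.na(m)] <- truth$flox$cn[m[!is.na(m)]]
  }
  cn
}

#' Expected copy-number ratio under the purity/ploidy mixture
#'
#' @param truth a `truth_profile`.
#' @param chrom,pos,target loci as in [truth_cn()].
#' @return expected linear CNR per locus:
#'   (p*CN + 2(1-p)) / (p*psi + 2(1-p)).
#' @export
expected_cnr <- function(truth, chrom, pos, target = NULL) {
  cn <- truth_cn(truth, chrom, pos, target)
  p <- truth$purity
  (p * cn + 2 * (1 - p)) / (p * truth$ploidy + 2 * (1 - p))
}

#' Default gentle GC-bias curve
#'
#' Multiplicative efficiency as a smooth function of GC fraction:
#' exp(-2 (gc - 0.5)^2), a mild quadratic dip away from 50% GC that the
#' loess GC corrector is expected to remove.
#'
#' @param gc vector of GC fractions.
#' @return multiplicative bias per amplicon.
#' @export
gc_bias_default <- function(gc) exp(-2 * (gc - 0.5)^2)

#' Simulate amplicon read counts for a set of samples
#'
#' Per-amplicon efficiencies are drawn once per call (log-normal across the
#' panel) and shared by every sample so tumor and normal profiles see the
#' same amplicon behavior. Counts are negative-binomial around
#' depth * efficiency * gc_bias(gc) * expected CNR (CNR = 1 for normals).
#' With `dispersion = 0` counts are the rounded means (noise-free).
#'
#' @param truths named list, one element per sample: a `truth_profile`, or
#'   NULL for a normal (diploid, CNR 1) sample.
#' @param panel an `amplicon_panel`.
#' @param depth mean per-amplicon depth (> 0).
#' @param dispersion negative-binomial dispersion (variance = mu + disp*mu^2);
#'   0 gives deterministic counts.
#' @param gc_bias function of GC fraction giving a multiplicative bias, or
#'   NULL for a flat profile.
#' @param efficiency_sdlog sd of log amplicon efficiency (log-normal).
#' @param seed RNG seed; the same seed reproduces the matrix exactly.
#' @return integer matrix amplicons x samples, rownames = amplicon ids.
#' @export
simulate_read_counts <- function(truths, panel, depth = 500, dispersion = 0.02,
                                 gc_bias = gc_bias_default,
                                 efficiency_sdlog = 0.3, seed = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"), depth > 0, dispersion >= 0)
  if (is.null(names(truths)) || any(!nzchar(names(truths))))
    stop("truths must be a named list (sample ids)")
  with_seed(seed, {
    n_amp <- nrow(panel)
    eff <- exp(stats::rnorm(n_amp, 0, efficiency_sdlog))
    bias <- if (is.null(gc_bias)) rep(1, n_amp) else gc_bias(panel$gc)
    mid <- (panel$start + panel$end) / 2
    out <- matrix(0L, n_amp, length(truths),
                  dimnames = list(panel$id, names(truths)))
    for (s in seq_along(truths)) {
      tr <- truths[[s]]
      cnr <- if (is.null(tr)) rep(1, n_amp) else
        expected_cnr(tr, panel$chrom, mid, panel$target)
      mu <- depth * eff * bias * cnr
      out[, s] <- if (dispersion == 0) as.integer(round(mu)) else
        as.integer(stats::rnbinom(n_amp, mu = mu, size = 1 / dispersion))
    }
    out
  })
}
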