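#' Segment a log2CNR profile (CBS-style)
#'
#' Per chromosome, markers (amplicons in genomic order) are outlier-smoothed
#' and then recursively split by the best mean-shift changepoint: the split
#' maximizing |mean difference| * sqrt(n1 n2 / n), i.e. the least-squares
#' two-segment fit. A split is accepted when a permutation test on that
#' statistic gives p < `alpha`; segments never drop below `min_width`
#' markers. Each accepted segment is then annotated with a Z-score against
#' the pool of normals (mean over its constituent amplicons), two-tailed p,
#' Benjamini-Hochberg q across the sample's segments, and a copy state
#' under the same q/log2CNR noise-zeroing rule as gene calls.
#'
#' @param cnrset a `cnr_set` from [normalize_counts()].
#' @param sample sample id to segment.
#' @param min_width minimum markers per segment.
#' @param alpha permutation acceptance level for a split.
#' @param n_perm permutations per candidate split.
#' @param smooth apply single-marker outlier smoothing first?
#' @param q_max,cnr_floor,zero_rule state-assignment rule (see
#'   [call_genes()]).
#' @param seed RNG seed for the permutation tests.
#' @return data.frame of segments: `sample`, `chrom`, `start`, `end`
#'   (0-based half-open, spanning first to last marker), `num_mark`,
#'   `seg_mean`, `z`, `p`, `q`, `state`.
#' @export
segment_profile <- function(cnrset, sample, min_width = 3, alpha = 0.01,
                            n_perm = 200, smooth = TRUE, q_max = 0.05,
                            cnr_floor = 0.2, zero_rule = c("and", "or"),
                            seed = NULL) {
  zero_rule <- match.arg(zero_rule)
  stopifnot(inherits(cnrset, "cnr_set"))
  if (!sample %in% colnames(cnrset$log2cnr)) stop("unknown sample: ", sample)
  p <- cnrset$panel
  v <- cnrset$log2cnr[, sample]
  with_seed(seed, {
    segs <- list()
    for (ch in unique(p$chrom)) {
      i <- which(p$chrom == ch)
      i <- i[order(p$start[i])]
      x <- v[i]
      if (smooth) x <- smooth_outliers(x)
      bounds <- recursive_split(x, min_width, alpha, n_perm)
      for (k in seq_len(nrow(bounds))) {
        idx <- i[bounds$from[k]:bounds$to[k]]
        segs[[length(segs) + 1L]] <- data.frame(
          sample = sample, chrom = ch,
          start = min(p$start[idx]), end = max(p$end[idx]),
          num_mark = length(idx),
          seg_mean = mean(v[idx]),
          marker_ids = I(list(p$id[idx])),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, segs)
    # significance vs the pool of normals over the same amplicons
    norm_means <- vapply(seq_len(nrow(out)), function(k) {
      idx <- match(out$marker_ids[[k]], p$id)
      colMeans(cnrset$log2cnr[idx, cnrset$normal_ids, drop = FALSE])
    }, numeric(length(cnrset$normal_ids)))
    mu <- colMeans(norm_means)
    sd <- apply(norm_means, 2, stats::sd)
    z <- (out$seg_mean - mu) / sd
    z[sd == 0] <- NA
    pv <- 2 * stats::pnorm(-abs(z))
    q <- stats::p.adjust(pv, "BH")
    state <- sign(out$seg_mean)
    zero <- if (zero_rule == "and") {
      (is.na(q) | q > q_max) & abs(out$seg_mean) < cnr_floor
    } else {
      (is.na(q) | q > q_max) | abs(out$seg_mean) < cnr_floor
    }
    state[zero | is.na(z)] <- 0
    out$z <- z; out$p <- pv; out$q <- q; out$state <- as.integer(state)
    out$marker_ids <- NULL
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# pull single-marker outliers toward their neighborhood median
smooth_outliers <- function(x, width = 5, nmad = 3) {
  n <- length(x)
  if (n < 3) return(x)
  med <- stats::runmed(x, k = min(width, n - (1 - n %% 2)))
  dev <- x - med
  s <- stats::mad(diff(x)) / sqrt(2)
  if (s == 0) return(x)
  out <- abs(dev) > nmad * s
  x[out] <- med[out] + sign(dev[out]) * nmad * s
  x
}

# best mean-shift split statistic and location on x
best_split <- function(x, min_width) {
  n <- length(x)
  if (n < 2 * min_width) return(NULL)
  cs <- cumsum(x)
  k <- min_width:(n - min_width)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  stat <- abs(m1 - m2) * sqrt(k * (n - k) / n)
  i <- which.max(stat)
  list(k = k[i], stat = stat[i])
}

# recursive binary segmentation with permutation acceptance
recursive_split <- function(x, min_width, alpha, n_perm) {
  n <- length(x)
  split_rec <- function(from, to) {
    seg <- x[from:to]
    bs <- best_split(seg, min_width)
    if (is.null(bs) || bs$stat == 0)
      return(data.frame(from = from, to = to))
    perm <- vapply(seq_len(n_perm), function(b) {
      best_split(sample(seg), min_width)$stat
    }, numeric(1))
    pval <- (1 + sum(perm >= bs$stat)) / (1 + n_perm)
    if (pval >= alpha) return(data.frame(from = from, to = to))
    rbind(split_rec(from, from + bs$k - 1L),
          split_rec(from + bs$k, to))
  }
  split_rec(1L, n)
}
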