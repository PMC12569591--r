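# shared fixture builders (everything generated in code)

# single-chromosome toy layout
toy_layout <- function(len = 1e8, chrom = "chr1") {
  genome_layout(data.frame(chrom = chrom, arm = chrom, start = 0, end = len))
}

# small multi-gene panel on the mouse layout, with flox targets for
# Apc / Trp53 and a handful of genotyping SNPs
toy_panel <- function(layout = mouse_layout(), amps_per_gene = 10,
                      genes = c(Apc = "chr18", Trp53 = "chr11",
                                Myc = "chr15", Pten = "chr19",
                                Kras = "chr6", Smad4 = "chr18"),
                      flox = c(Apc = "chr18", Trp53 = "chr11"),
                      n_snps = 20, seed = 42) {
  set.seed(seed)
  rows <- list()
  base <- 5e6
  for (g in names(genes)) {
    rows[[g]] <- data.frame(
      id = paste0(g, "_", seq_len(amps_per_gene)),
      chrom = genes[[g]],
      start = base + (seq_len(amps_per_gene) - 1) * 1000,
      end = base + (seq_len(amps_per_gene) - 1) * 1000 + 100,
      gene = g, class = "cn-tiling",
      gc = runif(amps_per_gene, 0.35, 0.6), pool = "p1")
    base <- base + 2e6
  }
  for (g in names(flox)) {
    rows[[paste0(g, "fl")]] <- data.frame(
      id = paste0(g, "_fl_", 1:2), chrom = flox[[g]],
      start = 3e7 + (1:2) * 500, end = 3e7 + (1:2) * 500 + 100,
      gene = g, class = "flox",
      gc = runif(2, 0.4, 0.55), pool = "p1")
  }
  if (n_snps > 0) {
    rows$snps <- data.frame(
      id = paste0("rs", seq_len(n_snps)),
      chrom = sample(layout$chroms$chrom, n_snps, replace = TRUE),
      start = round(runif(n_snps, 1e6, 5e7)), end = NA,
      gene = paste0("rs", seq_len(n_snps)), class = "genotyping-snp",
      gc = runif(n_snps, 0.3, 0.6), pool = "p2")
    rows$snps$end <- rows$snps$start + 100
  }
  amplicon_panel(do.call(rbind, rows), layout)
}

# wrap a log2CNR matrix as a cnr_set (for tests that bypass normalization)
as_cnrset <- function(log2cnr, panel, normal_ids) {
  stopifnot(nrow(log2cnr) == nrow(panel))
  rownames(log2cnr) <- panel$id
  structure(list(log2cnr = log2cnr, panel = panel, normal_ids = normal_ids),
            class = "cnr_set")
}

# gene-call-shaped table from explicit values (for credential tests)
fake_gene_calls <- function(targets, log2cnr, state = NULL, chrom = "chr1",
                            start = NULL, flox = NULL, sample = "s1") {
  n <- length(targets)
  if (is.null(start)) start <- seq_len(n) * 1e6
  if (is.null(state)) state <- ifelse(abs(log2cnr) > 0.2, sign(log2cnr), 0)
  if (is.null(flox)) flox <- grepl("_flox$", targets)
  out <- data.frame(target = targets, chrom = chrom, start = start,
                    end = start + 1e5, n_amplicons = 10, flox = flox,
                    log2cnr = log2cnr, z = NA, p = NA, q = NA,
                    state = as.integer(state), stringsAsFactors = FALSE)
  attr(out, "sample") <- sample
  out
}

# brute-force base-by-base overlap counter (independent R_c oracle)
rc_bruteforce <- function(segments, window) {
  w <- seq(window$start, window$end - 1)
  altered <- rep(FALSE, length(w))
  for (i in seq_len(nrow(segments))) {
    altered <- altered |
      (w >= segments$start[i] & w < segments$end[i])
  }
  mean(altered)
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exhaustive least-squares two-segment split (segmentation oracle)
best_split_bruteforce <- function(x, min_width = 3) {
  n <- length(x)
  rss <- vapply(min_width:(n - min_width), function(k) {
    sum((x[1:k] - mean(x[1:k]))^2) +
      sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
  }, numeric(1))
  (min_width:(n - min_width))[which.min(rss)]
}
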