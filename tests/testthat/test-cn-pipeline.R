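test_that("a sample identical to the pooled normal normalizes to zero", {
  pan <- toy_panel()
  base <- rpois(nrow(pan), 400) + 50
  cts <- cbind(T1 = base, N1 = base, N2 = base, N3 = base)
  rownames(cts) <- pan$id
  storage.mode(cts) <- "integer"
  cn <- normalize_counts(cts, pan, c("N1", "N2", "N3"), gc_correct = FALSE)
  expect_lt(max(abs(cn$log2cnr)), 1e-9)
})

test_that("a doubled small gene lands at log2CNR 1 (compositional oracle)", {
  pan <- toy_panel(n_snps = 60)           # dilute the doubled gene's mass
  set.seed(13)
  base <- rpois(nrow(pan), 400) + 50
  tum <- base
  myc <- pan$target == "Myc"
  tum[myc] <- 2 * tum[myc]
  cts <- cbind(T1 = tum, N1 = base, N2 = base, N3 = base)
  rownames(cts) <- pan$id; storage.mode(cts) <- "integer"
  cn <- normalize_counts(cts, pan, c("N1", "N2", "N3"), gc_correct = FALSE,
                         pseudocount = 0)
  # independent oracle: work the stages by hand on the raw counts
  keep <- rownames(cn$log2cnr)
  ratio <- (tum[match(keep, pan$id)] / sum(tum)) /
    (base[match(keep, pan$id)] / sum(base))
  oracle <- log2(ratio) - median(log2(ratio))
  expect_equal(unname(cn$log2cnr[, "T1"]), unname(oracle), tolerance = 1e-12)
  got <- mean(cn$log2cnr[cn$panel$target == "Myc", "T1"])
  expect_equal(got, 1, tolerance = 0.05)
})

test_that("the loess stage removes a synthetic linear GC trend", {
  pan <- toy_panel(n_snps = 100)
  set.seed(17)
  base <- rpois(nrow(pan), 500) + 100
  # multiplicative linear GC trend on the tumor only
  trend <- 2^(2 * (pan$gc - mean(pan$gc)))
  tum <- round(base * trend)
  cts <- cbind(T1 = as.integer(tum), N1 = base, N2 = base, N3 = base)
  rownames(cts) <- pan$id; storage.mode(cts) <- "integer"
  cn <- normalize_counts(cts, pan, c("N1", "N2", "N3"), gc_correct = TRUE)
  slope <- unname(coef(lm(cn$log2cnr[, "T1"] ~ cn$panel$gc))[2])
  # residual trend under 0.02 per 10% GC
  expect_lt(abs(slope) * 0.1, 0.02)
})

test_that("gene Z-scores, BH q and the zeroing rule follow the stated rules", {
  pan <- toy_panel(n_snps = 0)
  set.seed(23)
  n <- nrow(pan)
  l <- matrix(rnorm(n * 4, 0, 0.05), n, 4,
              dimnames = list(pan$id, c("T1", "N1", "N2", "N3")))
  l[pan$target == "Myc", "T1"] <- 1.0
  cn <- as_cnrset(l, pan, c("N1", "N2", "N3"))
  calls <- call_genes(cn, "T1")
  myc <- calls[calls$target == "Myc", ]
  # arithmetic oracle for z
  norm_means <- sapply(c("N1", "N2", "N3"),
                       function(s) mean(l[pan$target == "Myc", s]))
  z_expect <- (1 - mean(norm_means)) / sd(norm_means)
  expect_equal(myc$z, z_expect)
  expect_lt(myc$q, 1e-6)
  expect_equal(myc$state, 1L)
  # BH monotonicity: q non-decreasing in p order
  ord <- order(calls$p)
  expect_true(all(diff(calls$q[ord]) >= -1e-12))
  # zeroing rule: small CNR with non-significant q is zeroed in "and" mode
  l2 <- l
  l2[pan$target == "Kras", "T1"] <- 0.15
  l2[pan$target == "Kras", "N1"] <- 0.35   # spread the normals so q is large
  l2[pan$target == "Kras", "N2"] <- -0.35
  cn2 <- as_cnrset(l2, pan, c("N1", "N2", "N3"))
  calls2 <- call_genes(cn2, "T1")
  kras <- calls2[calls2$target == "Kras", ]
  expect_gt(kras$q, 0.05)
  expect_equal(kras$state, 0L)
  # "or" mode zeroes any |log2CNR| below the floor
  calls3 <- call_genes(cn2, "T1", zero_rule = "or")
  expect_equal(calls3$state[calls3$target == "Kras"], 0L)
})

test_that("degenerate normals and missing normals are handled explicitly", {
  pan <- toy_panel(n_snps = 0)
  l <- matrix(0, nrow(pan), 4,
              dimnames = list(pan$id, c("T1", "N1", "N2", "N3")))
  l[pan$target == "Myc", "T1"] <- 1
  cn <- as_cnrset(l, pan, c("N1", "N2", "N3"))
  expect_warning(calls <- call_genes(cn, "T1"), "zero normal-pool SD")
  expect_true(all(calls$state == 0L))
  cts <- matrix(100L, nrow(pan), 2, dimnames = list(pan$id, c("T1", "N1")))
  expect_error(normalize_counts(cts, pan, "N1"), "at least 2 normal")
})

test_that("null gene calls stay calibrated (type-I under 1.5x nominal)", {
  lay <- toy_layout(2e8)
  n_genes <- 100
  pan <- amplicon_panel(data.frame(
    id = paste0("a", 1:(n_genes * 10)), chrom = "chr1",
    start = (0:(n_genes * 10 - 1)) * 1e4,
    end = (0:(n_genes * 10 - 1)) * 1e4 + 100,
    gene = rep(paste0("g", 1:n_genes), each = 10),
    class = "cn-tiling", gc = 0.5, pool = "p"), lay)
  set.seed(31)
  called <- 0L
  normals <- paste0("N", 1:10)             # a realistically sized pool
  for (r in 1:10) {                        # 10 x 100 = 1,000 null genes
    l <- matrix(rnorm(n_genes * 10 * 11, 0, 0.15), n_genes * 10, 11,
                dimnames = list(pan$id, c("T1", normals)))
    cn <- as_cnrset(l, pan, normals)
    calls <- call_genes(cn, "T1")
    called <- called + sum(calls$state != 0)
  }
  expect_lte(called / 1000, 1.5 * 0.05)
})

test_that("segmentation recovers changepoints and matches the exhaustive fit", {
  lay <- toy_layout(2.2e6)
  pan <- amplicon_panel(data.frame(
    id = paste0("a", 1:200), chrom = "chr1", start = (0:199) * 1e4,
    end = (0:199) * 1e4 + 100, gene = rep(paste0("g", 1:20), each = 10),
    class = "cn-tiling", gc = 0.5, pool = "p"), lay)
  set.seed(41)
  l <- matrix(rnorm(200 * 4, 0, 0.1), 200, 4,
              dimnames = list(pan$id, c("T1", "N1", "N2", "N3")))
  l[101:200, "T1"] <- l[101:200, "T1"] + 1
  cn <- as_cnrset(l, pan, c("N1", "N2", "N3"))
  segs <- segment_profile(cn, "T1", seed = 6)
  expect_equal(nrow(segs), 2)
  # breakpoint within +/- 2 markers of marker 100 (position 1e6)
  expect_lte(abs(segs$start[2] - 1e6), 2 * 1e4)
  # segment mean equals the mean of its markers
  idx <- pan$start >= segs$start[2]
  expect_equal(segs$seg_mean[2], mean(l[idx, "T1"]))
  # constant profile: a single segment
  flat <- as_cnrset(matrix(rnorm(200 * 4, 0, 0.05), 200, 4,
                           dimnames = dimnames(l)), pan,
                    c("N1", "N2", "N3"))
  expect_equal(nrow(segment_profile(flat, "T1", seed = 7)), 1)
  # the chosen split equals the exhaustive least-squares two-segment fit
  set.seed(43)
  for (r in 1:5) {
    x <- c(rnorm(9, 0, 0.2), rnorm(9, 1.2, 0.2))
    bf <- best_split_bruteforce(x)
    bs <- mousecgp:::best_split(x, 3)
    expect_equal(bs$k, bf)
  }
})

test_that("MAPD matches hand computations and drives the QC verdict", {
  lay <- toy_layout(1e7)
  pan <- amplicon_panel(data.frame(
    id = paste0("a", 1:100), chrom = "chr1", start = (0:99) * 1e4,
    end = (0:99) * 1e4 + 100, gene = "g1", class = "cn-tiling",
    gc = 0.5, pool = "p"), lay)
  mk <- function(v) as_cnrset(cbind(T1 = v, N1 = 0, N2 = 0), pan,
                              c("N1", "N2"))
  counts <- rep(500L, 100)
  q1 <- qc_sample(counts, mk(rep(c(0, 0.1), 50)), "T1")
  expect_equal(q1$mapd, 0.1)
  expect_true(q1$pass)
  q2 <- qc_sample(counts, mk(rep(c(0, 0.6), 50)), "T1")
  expect_equal(q2$mapd, 0.6)
  expect_false(q2$pass)
  q3 <- qc_sample(counts, mk(rep(0.3, 100)), "T1")
  expect_equal(q3$mapd, 0)
  # tumor-content floor
  q4 <- qc_sample(counts, mk(rep(0, 100)), "T1", tumor_content = 0.2)
  expect_false(q4$pass)
})

test_that("purity/ploidy scaling inverts the simulator's mixture exactly", {
  expect_equal(scale_cnr(0, purity = 1, ploidy = 2), 2)
  expect_equal(scale_cnr(log2(1.25), purity = 0.5, ploidy = 2), 3)
  expect_equal(scale_cnr(log2(2.4 / 2), purity = 1, round = TRUE), 2)
  expect_warning(scale_cnr(-8, purity = 0.5), "clipped")
  # round trip with the simulator's expected CNR at zero noise
  lay <- mouse_layout()
  for (case in list(c(cn = 4, p = 0.6, psi = 2), c(cn = 1, p = 0.8, psi = 2),
                    c(cn = 3, p = 0.5, psi = 2.5))) {
    truth <- simulate_cn_profile(lay, events = data.frame(
      chrom = "chr2", start = 0, end = 1e8, cn = case["cn"]),
      purity = case["p"], ploidy = case["psi"])
    cnr <- expected_cnr(truth, "chr2", 5e7)
    expect_equal(unname(scale_cnr(log2(cnr), case["p"], case["psi"])),
                 unname(case["cn"]), tolerance = 1e-9)
  }
})

test_that("tumor content from flox CNR follows 1 - CNR with clipping", {
  calls <- fake_gene_calls(c("Apc", "Trp53_flox"), c(0, log2(0.6)))
  expect_equal(estimate_tumor_content(calls, "Trp53_flox")$tumor_content,
               0.4, tolerance = 1e-9)
  calls2 <- fake_gene_calls(c("Trp53_flox"), 0)
  expect_equal(estimate_tumor_content(calls2, "Trp53_flox")$tumor_content, 0)
  expect_error(estimate_tumor_content(calls, "Pten_flox"), "not in gene calls")
})

test_that("variant filters apply the five empirical rules with reasons", {
  recs <- data.frame(
    depth = c(150, 90, 150, 150, 150, 150),
    alt_fwd = c(10, 10, 12, 10, 10, 6),
    alt_rev = c(10, 10, 1, 10, 10, 6),
    homopolymer = c(2, 2, 2, 5, 2, 2),
    allele_fraction = c(0.2, 0.2, 0.2, 0.2, 0.05, 0.08))
  out <- filter_variants(recs)
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$fail_reasons[2], "depth")
  expect_equal(out$fail_reasons[3], "strand")
  expect_equal(out$fail_reasons[4], "homopolymer")
  expect_equal(out$fail_reasons[5], "allele_fraction")
  # reverse = 0 gives an infinite (failing) strand ratio
  inf <- filter_variants(data.frame(depth = 200, alt_fwd = 20, alt_rev = 0,
                                    homopolymer = 1, allele_fraction = 0.3))
  expect_false(inf$pass)
  expect_match(inf$fail_reasons, "strand")
})
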