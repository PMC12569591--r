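test_that("FGA is the exact altered fraction with a strict threshold", {
  calls <- fake_gene_calls(paste0("g", 1:10), rep(0, 10))
  expect_equal(fraction_genes_altered(calls)$fga, 0)
  # 48 of 119 beyond threshold
  v <- c(rep(0.5, 48), rep(0, 71))
  calls2 <- fake_gene_calls(paste0("g", 1:119), v)
  r <- fraction_genes_altered(calls2)
  expect_equal(r$fga, 48 / 119)
  expect_equal(round(r$fga, 4), 0.4034)
  # exactly 0.2 is not altered (strict >)
  calls3 <- fake_gene_calls(c("g1", "g2"), c(0.2, 0.21))
  expect_equal(fraction_genes_altered(calls3)$fga, 0.5)
  # flox targets never count; order never matters
  calls4 <- fake_gene_calls(c("g1", "Apc_flox", "g2"), c(0.5, 3, 0))
  expect_equal(fraction_genes_altered(calls4)$n_genes, 2)
  shuf <- calls4[c(3, 1, 2), ]
  attr(shuf, "sample") <- "s1"
  expect_equal(fraction_genes_altered(shuf)$fga,
               fraction_genes_altered(calls4)$fga)
  expect_error(fraction_genes_altered(calls4, genes = "nope"), "empty")
})

test_that("copy-state score counts qualifying runs per arm", {
  lay <- genome_layout(data.frame(chrom = c("chr1", "chr2"),
                                  arm = c("chr1", "chr2"),
                                  start = 0, end = c(1e8, 1e8)))
  mk <- function(states1, states2 = integer(0)) {
    n1 <- length(states1); n2 <- length(states2)
    fake_gene_calls(paste0("g", 1:(n1 + n2)),
                    log2cnr = c(states1, states2) * 0.5,
                    state = c(states1, states2),
                    chrom = rep(c("chr1", "chr2"), c(n1, n2)),
                    start = c(seq_len(n1), seq_len(n2)) * 1e6)
  }
  # quiet arm: one run
  expect_equal(copy_state_score(mk(c(0, 0, 0)), lay)$total, 1)
  # [+1,+1,-1,-1,0,0] -> 3 runs
  expect_equal(copy_state_score(mk(c(1, 1, -1, -1, 0, 0)), lay)$total, 3)
  # [+1,0,+1] -> no run reaches length 2
  expect_equal(copy_state_score(mk(c(1, 0, 1)), lay)$total, 0)
  # arms with < 2 genes are skipped and flagged
  r <- copy_state_score(mk(c(0, 0), c(0)), lay)
  expect_equal(r$total, 1)
  expect_equal(r$skipped_arms, "chr2")
  # unaltered genome scores one per (>= 2 gene) arm
  r2 <- copy_state_score(mk(c(0, 0, 0), c(0, 0)), lay)
  expect_equal(r2$total, 2)
  # distinct-state reading collapses repeated states
  expect_equal(copy_state_score(mk(c(1, 1, 0, 0, 1, 1)), lay,
                                mode = "distinct")$total, 2)
})

test_that("flox ratios reproduce the engineered-genotype expectations", {
  mk <- function(num, den) fake_gene_calls(
    c("Trp53_flox", "Apc_flox"), c(num, den))
  # homozygous loss of both targets: CNR (1-p) each, ratio exactly 1
  for (p in c(0.2, 0.5, 0.9))
    expect_equal(flox_ratio(mk(log2(1 - p), log2(1 - p)))$ratio, 1)
  # numerator intact: ratio exactly 0
  expect_equal(flox_ratio(mk(0, log2(0.5)))$ratio, 0)
  # heterozygous numerator: log2(1-p/2)/log2(1-p) -> 0.5 as p -> 0
  p <- 0.01
  r <- flox_ratio(mk(log2(1 - p / 2), log2(1 - p)))$ratio
  expect_equal(r, 0.5, tolerance = 0.01)
  # denominator zero: undefined
  expect_true(is.na(flox_ratio(mk(1, 0))$ratio))
  expect_error(flox_ratio(fake_gene_calls("g1", 0)), "missing")
})

test_that("genotype regression recovers per-genotype ratio means", {
  set.seed(83)
  d <- data.frame(
    genotype = rep(c("AK", "AKPfl", "AKPflfl"), each = 12),
    ratio = c(rnorm(12, 0, 0.05), rnorm(12, 0.5, 0.05),
              rnorm(12, 1, 0.05)),
    tumor_content = 0.6)
  fit <- genotype_ratio_regression(d)
  co <- fit$coefficients
  expect_equal(co$mean[co$genotype == "AK"], 0, tolerance = 0.08)
  expect_equal(co$mean[co$genotype == "AKPfl"], 0.5, tolerance = 0.08)
  expect_equal(co$mean[co$genotype == "AKPflfl"], 1, tolerance = 0.08)
  # low-tumor-content samples are excluded
  d$tumor_content[1:6] <- 0.1
  expect_equal(genotype_ratio_regression(d)$n_excluded, 6)
})

test_that("Fisher p values match hypergeometric enumeration on small tables", {
  set.seed(85)
  for (r in 1:100) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_enum_p(tab),
                 tolerance = 1e-7)
  }
  # symmetry and degeneracy
  sym <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(sym$p_value, 1)
  zero <- fisher_exact_2x2(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))
  expect_true(is.na(zero$odds_ratio))
  expect_equal(zero$p_value, 1)
})

test_that("within-sample permutation preserves burden and flags planted arms", {
  m <- simulate_aneuploidy_matrix(15, paste0("chr", 1:19), 0.2, seed = 87)
  pm <- mousecgp:::permute_rows(m)
  expect_equal(rowSums(pm == 1), rowSums(m == 1))
  expect_equal(rowSums(pm == -1), rowSums(m == -1))
  # all-zero matrix: p = 1 everywhere
  z <- recurrent_aneuploidy_permutation(
    matrix(0L, 5, 19, dimnames = list(NULL, paste0("chr", 1:19))), 100)
  expect_true(all(z$gain_p == 1) && all(z$loss_p == 1))
  # planted recurrent gain reaches q < 0.05
  planted <- simulate_aneuploidy_matrix(
    20, paste0("chr", 1:19), background_rate = 0.05,
    planted = data.frame(arm = "chr1", rate = 0.6, direction = 1),
    seed = 89)
  r <- recurrent_aneuploidy_permutation(planted, n_perm = 1000, seed = 91)
  expect_lt(r$gain_q[r$arm == "chr1"], 0.05)
})

test_that("arm-specificity testing flags target-enriched arms", {
  arms <- paste0("chr", 1:10)
  target <- simulate_aneuploidy_matrix(
    200, arms, 0.05,
    planted = data.frame(arm = "chr3", rate = 0.6, direction = 1),
    seed = 93)
  comps <- list(c1 = simulate_aneuploidy_matrix(200, arms, 0.05, seed = 94),
                c2 = simulate_aneuploidy_matrix(200, arms, 0.05, seed = 95))
  r <- arm_specificity_test(target, comps)
  expect_true("chr3" %in% r$flagged)
  expect_lt(max(r$tests$q[r$tests$arm == "chr3"]), 0.05)
  # identical cohorts: no flags, odds ratios near 1
  same <- arm_specificity_test(comps$c1, list(only = comps$c1))
  expect_length(same$flagged, 0)
  expect_error(arm_specificity_test(target, list()), "at least one")
})

test_that("synteny interval mapping computes percent synteny and peak overlap", {
  syn <- data.frame(hchrom = "chr13", hstart = c(0, 5e7), hend = c(5e7, 1e8),
                    mchrom = c("chr14", "chr5"), mstart = 0,
                    mend = c(5e7, 5e7), orientation = "+")
  # identity-style map: 100% to one chromosome
  r1 <- map_syntenic("chr13", 0, 5e7, syn)
  expect_equal(unname(r1$percent_synteny["chr14"]), 1)
  # an interval split evenly across two mouse chromosomes
  r2 <- map_syntenic("chr13", 2.5e7, 7.5e7, syn)
  expect_equal(unname(r2$percent_synteny[c("chr14", "chr5")]), c(0.5, 0.5))
  expect_warning(r3 <- map_syntenic("chr2", 0, 1e6, syn), "no syntenic")
  expect_equal(nrow(r3$blocks), 0)
  peaks <- data.frame(chrom = "chr13", start = 4e7, end = 4.5e7)
  r4 <- map_syntenic("chr13", 0, 5e7, syn, peaks = peaks)
  expect_equal(r4$peak_overlaps$overlap_start, 4e7)
})

test_that("the scenario test distinguishes concordant, subset and independent data", {
  arm_table <- data.frame(arm = "h13q", chrom = "chr13", start = 0, end = 9e7)
  # three syntenic mouse chromosomes
  syn <- data.frame(hchrom = "chr13", hstart = c(0, 3e7, 6e7),
                    hend = c(3e7, 6e7, 9e7),
                    mchrom = c("chr14", "chr5", "chr8"),
                    mstart = 0, mend = 3e7, orientation = "+")
  arms_m <- paste0("chr", 1:19)
  n <- 40
  # concordant: human arm and all three mouse chrs gained in the same 70%
  set.seed(97)
  hm <- matrix(0L, n, 3, dimnames = list(NULL, c("h13q", "hX", "hY")))
  gained <- runif(n) < 0.7
  hm[gained, "h13q"] <- 1L
  mm <- matrix(0L, n, 19, dimnames = list(NULL, arms_m))
  mm[gained, c("chr14", "chr5", "chr8")] <- 1L
  r1 <- synteny_scenario_test(hm, "h13q", mm, syn, arm_table,
                              n_perm = 500, seed = 99)
  expect_gt(r1$logor_s1, 0)
  expect_equal(r1$favored, "1")
  # subset: only chr5 co-gained
  mm2 <- matrix(0L, n, 19, dimnames = list(NULL, arms_m))
  mm2[gained, "chr5"] <- 1L
  r2 <- synteny_scenario_test(hm, "h13q", mm2, syn, arm_table,
                              n_perm = 500, seed = 101)
  expect_equal(r2$favored, "2")
  # independent matrices: nothing favored
  hm3 <- simulate_aneuploidy_matrix(n, c("h13q", "hX", "hY"), 0.15,
                                    seed = 103)
  mm3 <- simulate_aneuploidy_matrix(n, arms_m, 0.15, seed = 104)
  r3 <- synteny_scenario_test(hm3, "h13q", mm3, syn, arm_table,
                              n_perm = 500, seed = 105)
  expect_equal(r3$favored, "none")
  # the event is not conserved: normal instability elsewhere, S never gained
  mm4 <- simulate_aneuploidy_matrix(n, arms_m, 0.2, seed = 106)
  mm4[, c("chr14", "chr5", "chr8")] <- 0L
  r4 <- synteny_scenario_test(hm, "h13q", mm4, syn, arm_table,
                              n_perm = 500, seed = 107)
  expect_equal(r4$favored, "3")
  # an arm with no syntenic chromosomes is skipped with a warning
  at2 <- rbind(arm_table, data.frame(arm = "hX", chrom = "chrX",
                                     start = 0, end = 1e7))
  expect_warning(synteny_scenario_test(hm, c("h13q", "hX"), mm, syn, at2,
                                       n_perm = 50, seed = 109),
                 "skipped")
})
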