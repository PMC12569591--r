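test_that("R_c matches interval arithmetic and the brute-force counter", {
  lay <- toy_layout(100)
  w <- build_arm_windows(lay, 0.6)[1, ]       # window [20, 80)
  expect_equal(compute_rc(data.frame(start = numeric(0), end = numeric(0)),
                          w), 0)
  expect_equal(compute_rc(data.frame(start = 0, end = 100), w), 1)
  expect_equal(compute_rc(data.frame(start = 50, end = 100), w), 0.5)
  expect_error(compute_rc(data.frame(start = 0, end = 10),
                          list(start = 5, end = 5)), "zero-length")
  # brute-force base-by-base oracle on random toy arms (<= 1 Mb)
  set.seed(19)
  for (r in 1:20) {
    len <- sample(1e4:1e5, 1)
    lay2 <- toy_layout(len)
    cc <- runif(1, 0.2, 1)
    w2 <- build_arm_windows(lay2, cc)[1, ]
    k <- sample(1:4, 1)
    s <- sort(sample(0:(len - 1), 2 * k))
    segs <- data.frame(start = s[seq(1, 2 * k, 2)],
                       end = s[seq(2, 2 * k, 2)] + 1)
    expect_equal(compute_rc(segs, w2), rc_bruteforce(segs, w2))
  }
})

test_that("arm calls require both the R_c threshold and gene directionality", {
  lay <- toy_layout(1e8)
  whole_gain <- data.frame(chrom = "chr1", start = 0, end = 1e8,
                           state = 1L)
  genes3 <- function(states) data.frame(chrom = "chr1",
                                        start = c(1e6, 4e7, 9e7),
                                        end = c(2e6, 5e7, 9.5e7),
                                        state = as.integer(states))
  # whole-arm gain, all genes concordant
  calls <- call_arm_aneuploidy(whole_gain, genes3(c(1, 1, 1)), lay)
  expect_equal(calls$direction, 1L)
  # R_c = 1 but one gene at state 0: blocked at fraction 1.0, called at 0.5
  strict <- call_arm_aneuploidy(whole_gain, genes3(c(1, 1, 0)), lay,
                                min_direction_fraction = 1.0)
  expect_equal(strict$direction, 0L)
  relaxed <- call_arm_aneuploidy(whole_gain, genes3(c(1, 1, 0)), lay,
                                 min_direction_fraction = 0.5)
  expect_equal(relaxed$direction, 1L)
  # R_c below threshold is never called, whatever the genes say
  part <- data.frame(chrom = "chr1", start = 2e7, end = 6.2e7, state = 1L)
  low <- call_arm_aneuploidy(part, genes3(c(1, 1, 1)), lay,
                             c = 0.6, rc_threshold = 0.8)
  expect_equal(low$rc_gain, 0.7)
  expect_equal(low$direction, 0L)
  # an exact gain/loss tie gives no call with a warning
  tie <- data.frame(chrom = "chr1", start = c(2e7, 5e7),
                    end = c(5e7, 8e7), state = c(1L, -1L))
  expect_warning(
    res <- call_arm_aneuploidy(tie, NULL, lay, c = 0.6, rc_threshold = 0.5,
                               min_direction_fraction = 0),
    "tie")
  expect_equal(res$direction, 0L)
})

test_that("reference calls use an inclusive R_1.0 >= 0.8 rule", {
  lay <- toy_layout(1e8)
  mk <- function(frac, state = 1L)
    data.frame(chrom = "chr1", start = 0, end = frac * 1e8, state = state)
  ref <- reference_arm_calls(list(full = mk(1), at80 = mk(0.8),
                                  at79 = mk(0.79)), lay)
  expect_equal(unname(ref[, "chr1"]), c(1L, 1L, 0L))
})

test_that("concordance metrics count direction-matched agreement", {
  ref <- matrix(c(1L, -1L, 0L, 1L), 1, 4,
                dimnames = list("s1", paste0("a", 1:4)))
  calls <- matrix(c(1L, 0L, 0L, 1L), 1, 4,
                  dimnames = dimnames(ref))
  r <- evaluate_concordance(calls, ref)
  expect_equal(r$ppa, 2 / 3)
  expect_equal(r$npa, 1)
  ident <- evaluate_concordance(ref, ref)
  expect_equal(ident$ppa, 1)
  expect_equal(ident$npa, 1)
  none <- evaluate_concordance(ref * 0L, ref)
  expect_equal(none$ppa, 0)
  expect_error(evaluate_concordance(ref[, 1:3], ref), "dimensions")
})

test_that("marker subsampling keeps one pick per window and is seeded", {
  lay <- toy_layout(1e8)
  targets <- data.frame(id = paste0("t", 1:100), chrom = "chr1",
                        start = (0:99) * 1e6, end = (0:99) * 1e6 + 100,
                        gene = rep(c(NA, "gA", NA, "gB", NA), 20))
  # window of a whole chromosome: at most one marker survives
  one <- subsample_markers(targets, lay, 1e9, "single-marker",
                           n_repeats = 1, seed = 1)
  expect_equal(length(one[[1]]), 1)
  # 10 windows, each populated: exactly 10 picks
  ten <- subsample_markers(targets, lay, 1e7, "single-marker",
                           n_repeats = 1, seed = 2)
  expect_equal(length(ten[[1]]), 10)
  expect_identical(
    subsample_markers(targets, lay, 1e7, "whole-gene", n_repeats = 3,
                      seed = 3),
    subsample_markers(targets, lay, 1e7, "whole-gene", n_repeats = 3,
                      seed = 3))
  # whole-gene mode prefers genes and keeps all their window markers
  wg <- subsample_markers(targets, lay, 1e8, "whole-gene",
                          n_repeats = 1, seed = 4)[[1]]
  genes_kept <- unique(targets$gene[targets$id %in% wg])
  expect_length(genes_kept, 1)
  expect_true(genes_kept %in% c("gA", "gB"))
  expect_setequal(wg, targets$id[!is.na(targets$gene) &
                                   targets$gene == genes_kept])
})

test_that("calling at c = 1 with the reference threshold reproduces reference calls", {
  cohort <- simulate_segmented_cohort(mouse_layout(), n_samples = 12,
                                      arm_event_rate = 0.2,
                                      marker_spacing = 5e6,
                                      noise_sd = 0.05, seed = 29)
  ref2 <- reference_arm_calls(lapply(cohort$samples, `[[`, "segments"),
                              cohort$layout)
  calls <- ref2 * 0L
  for (s in names(cohort$samples)) {
    cc <- call_arm_aneuploidy(cohort$samples[[s]]$segments, NULL,
                              cohort$layout, c = 1.0, rc_threshold = 0.8,
                              min_direction_fraction = 0)
    calls[s, cc$arm] <- cc$direction
  }
  r <- evaluate_concordance(calls, ref2)
  expect_equal(r$ppa, 1)
  expect_equal(r$npa, 1)
})

test_that("the coverage-grid table tracks the expected trends", {
  cohort <- simulate_segmented_cohort(mouse_layout(), n_samples = 10,
                                      arm_event_rate = 0.2,
                                      partial_event_rate = 0.3,
                                      marker_spacing = 5e6,
                                      noise_sd = 0.1, seed = 37)
  tab <- run_coverage_simulation(cohort, c_grid = 1.0,
                                 rc_grid = c(0.2, 0.5, 0.8),
                                 direction_fractions = 0)
  # planted 30-70% partial events are not reference events: a permissive
  # threshold calls them (false positives), a strict one does not
  expect_true(tab$fpr[tab$rc_threshold == 0.2] >
                tab$fpr[tab$rc_threshold == 0.8])
  # directional recall over reference-altered cells stays high throughout
  expect_true(all(tab$ppa >= 0.8))
})
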