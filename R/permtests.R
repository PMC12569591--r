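# two-proportion z statistic for one arm vs all other arms pooled
# m: samples x arms matrix in {-1,0,1}; d: +1 or -1; returns one z per arm
arm_vs_rest_z <- function(m, d) {
  hits <- m == d
  n <- nrow(m); A <- ncol(m)
  x1 <- colSums(hits)
  x2 <- sum(hits) - x1
  n1 <- n; n2 <- n * (A - 1)
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  z[!is.finite(z)] <- 0
  z
}

# permute each row's arm labels independently (without replacement)
permute_rows <- function(m) {
  out <- t(apply(m, 1, function(r) sample(unname(r))))
  dimnames(out) <- dimnames(m)
  out
}

#' Permutation test for recurrently aneuploid arms
#'
#' The null is generated by shuffling each sample's arm labels within the
#' sample (resampling without replacement), preserving every sample's
#' event burden. The statistic per arm and direction is the two-proportion
#' z comparing the arm's event rate against all other arms pooled; the
#' empirical p is (1 + #\{permuted z >= observed z\}) / (1 + n_perm) and
#' Benjamini-Hochberg q values are computed across arms and directions.
#'
#' @param matrix aneuploidy matrix (samples x arms, entries -1/0/+1).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return data.frame per arm: `arm`, `gain_rate`, `loss_rate`, `gain_p`,
#'   `loss_p`, `gain_q`, `loss_q`.
#' @export
recurrent_aneuploidy_permutation <- function(matrix, n_perm = 10000,
                                             seed = NULL) {
  stopifnot(all(matrix %in% c(-1, 0, 1)))
  arms <- colnames(matrix) %||% paste0("arm", seq_len(ncol(matrix)))
  if (all(matrix == 0)) {
    return(data.frame(arm = arms, gain_rate = 0, loss_rate = 0,
                      gain_p = 1, loss_p = 1, gain_q = 1, loss_q = 1))
  }
  with_seed(seed, {
    obs_g <- arm_vs_rest_z(matrix, 1L)
    obs_l <- arm_vs_rest_z(matrix, -1L)
    cnt_g <- rep(0L, ncol(matrix)); cnt_l <- rep(0L, ncol(matrix))
    for (b in seq_len(n_perm)) {
      pm <- permute_rows(matrix)
      cnt_g <- cnt_g + (arm_vs_rest_z(pm, 1L) >= obs_g)
      cnt_l <- cnt_l + (arm_vs_rest_z(pm, -1L) >= obs_l)
    }
    gain_p <- (1 + cnt_g) / (1 + n_perm)
    loss_p <- (1 + cnt_l) / (1 + n_perm)
    q <- stats::p.adjust(c(gain_p, loss_p), "BH")
    data.frame(arm = arms,
               gain_rate = colMeans(matrix == 1),
               loss_rate = colMeans(matrix == -1),
               gain_p = gain_p, loss_p = loss_p,
               gain_q = q[seq_along(arms)],
               loss_q = q[-seq_along(arms)],
               row.names = NULL)
  })
}

#' Arm-specificity Fisher tests across cohorts
#'
#' For each arm, a Fisher exact test compares the target cohort's
#' altered/unaltered counts (in the requested direction) against each
#' comparison cohort, with Benjamini-Hochberg correction across all tests.
#' Arms altered significantly more frequently in the target than in at
#' least half of the comparison cohorts are flagged, and pairwise
#' co-occurrence among flagged arms is tested the same way.
#'
#' @param target aneuploidy matrix of the target cohort.
#' @param comparisons named list of comparison aneuploidy matrices.
#' @param direction +1 (gains) or -1 (losses).
#' @param q_max significance level on the BH q values.
#' @return list: `tests` (arm x cohort table of OR, p, q, target/cohort
#'   rates), `flagged` (arm ids), `cooccurrence` (pairwise tests among
#'   flagged arms, NULL when < 2 flagged).
#' @export
arm_specificity_test <- function(target, comparisons, direction = 1,
                                 q_max = 0.05) {
  if (!length(comparisons)) stop("at least one comparison cohort required")
  if (any(vapply(comparisons, nrow, 1L) == 0) || nrow(target) == 0)
    stop("empty cohort")
  arms <- colnames(target)
  rows <- list()
  for (a in arms) {
    x1 <- sum(target[, a] == direction); n1 <- nrow(target)
    for (cn in names(comparisons)) {
      cm <- comparisons[[cn]]
      x2 <- sum(cm[, a] == direction); n2 <- nrow(cm)
      ft <- fisher_exact_2x2(matrix(c(x1, n1 - x1, x2, n2 - x2), 2,
                                    byrow = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        arm = a, cohort = cn, target_rate = x1 / n1, cohort_rate = x2 / n2,
        odds_ratio = ft$odds_ratio, p = ft$p_value)
    }
  }
  tests <- do.call(rbind, rows)
  tests$q <- stats::p.adjust(tests$p, "BH")
  sig <- tests$q < q_max & tests$target_rate > tests$cohort_rate
  frac_sig <- tapply(sig, tests$arm, mean)
  flagged <- names(frac_sig)[frac_sig >= 0.5]
  cooc <- NULL
  if (length(flagged) >= 2) {
    prs <- utils::combn(flagged, 2, simplify = FALSE)
    comp_all <- do.call(rbind, comparisons)
    cooc <- do.call(rbind, lapply(prs, function(pr) {
      both_t <- sum(target[, pr[1]] == direction &
                      target[, pr[2]] == direction)
      both_c <- sum(comp_all[, pr[1]] == direction &
                      comp_all[, pr[2]] == direction)
      ft <- fisher_exact_2x2(matrix(c(both_t, nrow(target) - both_t,
                                      both_c, nrow(comp_all) - both_c),
                                    2, byrow = TRUE))
      data.frame(arm1 = pr[1], arm2 = pr[2], odds_ratio = ft$odds_ratio,
                 p = ft$p_value)
    }))
    cooc$q <- stats::p.adjust(cooc$p, "BH")
  }
  list(tests = tests, flagged = flagged, cooccurrence = cooc)
}

# log odds with Haldane correction
log_odds <- function(x, n) log((x + 0.5) / (n - x + 0.5))

# per-sample indicator of each synteny scenario for a mouse gain matrix
scenario_counts <- function(mouse, S, subset_rule) {
  gains <- mouse[, S, drop = FALSE] == 1
  n_g <- rowSums(gains)
  k <- length(S)
  c(s1 = sum(n_g == k),
    s2 = if (subset_rule == "any") sum(n_g > 0 & n_g < k) else
      sum(n_g == 1 & k > 1),
    s3 = sum(n_g == 0))
}

#' Synteny scenario test for cross-species aneuploidy gains
#'
#' For a recurrently gained human arm whose synteny map links it to a set
#' S of mouse chromosomes, three scenarios are scored in the mouse cohort:
#' all of S gained (scenario 1), a proper nonempty subset gained
#' (scenario 2; `subset_rule = "one"` restricts to exactly one), or none
#' gained (scenario 3). The scenario statistic is the joint log odds
#' log odds(human arm gained) + log odds(mouse scenario event), with
#' Haldane correction. Scenarios 2 and 3 are compared against scenario 1
#' on the difference of log ORs, with the null from within-sample
#' permutations of both matrices; scenario 1 itself is tested against its
#' own permutation null. A scenario is favored when its observed statistic
#' exceeds the reference's with empirical p below `alpha`.
#'
#' @param human aneuploidy matrix of the human cohort.
#' @param human_arms human arms of interest (columns of `human`).
#' @param mouse aneuploidy matrix of the mouse cohort.
#' @param synteny synteny block table; mouse chromosomes linked to a human
#'   arm by any block (>= `min_fraction` of the arm) form S.
#' @param arm_table data.frame `arm`, `chrom`, `start`, `end` giving the
#'   human arm intervals used to query the synteny map.
#' @param n_perm permutations.
#' @param subset_rule scenario-2 subset definition.
#' @param min_fraction minimum fraction of the human arm a mouse
#'   chromosome must cover to enter S.
#' @param alpha favoring threshold on empirical p.
#' @param seed RNG seed.
#' @return data.frame per human arm: `human_arm`, `mouse_chroms`,
#'   `logor_s1`, `logor_s2`, `logor_s3`, `p_s1`, `p_s2_vs_s1`,
#'   `p_s3_vs_s1`, `favored` ("1", "2", "3" or "none"). Arms without
#'   syntenic mouse chromosomes are skipped with a warning.
#' @export
synteny_scenario_test <- function(human, human_arms, mouse, synteny,
                                  arm_table, n_perm = 10000,
                                  subset_rule = c("any", "one"),
                                  min_fraction = 0.01, alpha = 0.05,
                                  seed = NULL) {
  subset_rule <- match.arg(subset_rule)
  with_seed(seed, {
    out <- list()
    for (arm in human_arms) {
      at <- arm_table[arm_table$arm == arm, , drop = FALSE]
      if (!nrow(at)) stop("arm not in arm_table: ", arm)
      ms <- suppressWarnings(
        map_syntenic(at$chrom, at$start, at$end, synteny))
      S <- names(ms$percent_synteny)[ms$percent_synteny >= min_fraction]
      S <- intersect(S, colnames(mouse))
      if (!length(S)) {
        warning("no syntenic mouse chromosomes for ", arm, "; skipped")
        next
      }
      n_h <- nrow(human); n_m <- nrow(mouse)
      stat <- function(hm, mm) {
        a <- sum(hm[, arm] == 1)
        sc <- scenario_counts(mm, S, subset_rule)
        log_odds(a, n_h) + vapply(sc, log_odds, numeric(1), n = n_m)
      }
      obs <- stat(human, mouse)
      d2 <- obs["s2"] - obs["s1"]; d3 <- obs["s3"] - obs["s1"]
      c1 <- c2 <- c3 <- 0L
      for (b in seq_len(n_perm)) {
        st <- stat(permute_rows(human), permute_rows(mouse))
        c1 <- c1 + (st["s1"] >= obs["s1"])
        c2 <- c2 + ((st["s2"] - st["s1"]) >= d2)
        c3 <- c3 + ((st["s3"] - st["s1"]) >= d3)
      }
      p1 <- (1 + c1) / (1 + n_perm)
      p2 <- (1 + c2) / (1 + n_perm)
      p3 <- (1 + c3) / (1 + n_perm)
      fav <- "none"
      if (d2 > 0 && p2 < alpha && (!(d3 > 0 && p3 < alpha) || d2 >= d3)) {
        fav <- "2"
      } else if (d3 > 0 && p3 < alpha) {
        fav <- "3"
      } else if (p1 < alpha) {
        fav <- "1"
      }
      out[[arm]] <- data.frame(
        human_arm = arm, mouse_chroms = paste(S, collapse = ","),
        logor_s1 = unname(obs["s1"]), logor_s2 = unname(obs["s2"]),
        logor_s3 = unname(obs["s3"]),
        p_s1 = unname(p1), p_s2_vs_s1 = unname(p2),
        p_s3_vs_s1 = unname(p3), favored = fav,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
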