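#' Drop non-informative SNPs from a strain panel
#'
#' Keeps SNPs whose allele distribution across the selected strains has
#' non-zero entropy, i.e. the strains are not all identical at the SNP.
#'
#' @param panel a `strain_panel`.
#' @param strains strain ids to consider (default all; >= 2 required).
#' @return a `strain_panel` restricted to the informative SNPs (and the
#'   selected strains). An empty result triggers a warning.
#' @export
filter_informative_snps <- function(panel, strains = colnames(panel$geno)) {
  stopifnot(inherits(panel, "strain_panel"))
  if (length(strains) < 2) stop("need at least 2 strains")
  g <- panel$geno[, strains, drop = FALSE]
  keep <- apply(g, 1, function(r) length(unique(r)) > 1)
  if (!any(keep)) warning("all SNPs are monomorphic in the selected strains")
  strain_panel(panel$snps[keep, , drop = FALSE], g[keep, , drop = FALSE])
}

#' Rank SNPs by multiple correspondence analysis
#'
#' MCA on the strain x SNP-allele indicator matrix via the SVD of the
#' standardized residual matrix (classic correspondence analysis of the
#' indicator table). The contribution of a SNP is the sum, over its two
#' allele-indicator columns and the leading `n_dimensions` dimensions, of
#' the squared column loading weighted by the dimension's share of total
#' inertia. The top `n_target` SNPs by contribution are returned together
#' with the strain factor scores.
#'
#' @param panel a `strain_panel` (filter non-informative SNPs first).
#' @param n_target number of SNPs to keep (<= panel size).
#' @param n_dimensions dimensions used for the ranking (default: all
#'   non-null dimensions, at most n_strains - 1).
#' @return list: `panel` (reduced `strain_panel`), `ranking` (data.frame
#'   `id`, `contribution`, ordered), `scores` (strain x dimension factor
#'   scores), `inertia` (per-dimension inertia shares).
#' @export
reduce_snps_mca <- function(panel, n_target, n_dimensions = NULL) {
  stopifnot(inherits(panel, "strain_panel"))
  J <- nrow(panel$snps)
  if (n_target > J) stop("n_target exceeds panel size")
  g <- t(panel$geno)                      # strains x SNPs
  S <- nrow(g)
  # indicator matrix: two columns per SNP (allele 0, allele 1)
  Z <- cbind(1 - g, g)
  snp_of_col <- rep(panel$snps$id, 2)
  nonzero <- colSums(Z) > 0            # monomorphic SNPs have an empty column
  Z <- Z[, nonzero, drop = FALSE]
  snp_of_col <- snp_of_col[nonzero]
  tot <- sum(Z)
  P <- Z / tot
  r <- rowSums(P); cc <- colSums(P)
  Sres <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  if (any(!is.finite(Sres))) stop("degenerate indicator matrix")
  sv <- svd(Sres)
  lambda <- sv$d^2
  nz <- which(lambda > 1e-12)
  if (!length(nz)) stop("degenerate indicator matrix: no variation")
  if (is.null(n_dimensions)) n_dimensions <- length(nz)
  k <- nz[seq_len(min(n_dimensions, length(nz)))]
  inertia_share <- lambda / sum(lambda)
  # column contribution to dim k is v_jk^2 (sums to 1 per dimension)
  contrib_col <- sweep(sv$v[, k, drop = FALSE]^2, 2, inertia_share[k], "*")
  contrib_snp <- rowsum(rowSums(contrib_col), snp_of_col)
  ranking <- data.frame(id = rownames(contrib_snp),
                        contribution = contrib_snp[, 1],
                        row.names = NULL, stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$contribution), , drop = FALSE]
  keep <- panel$snps$id %in% ranking$id[seq_len(n_target)]
  scores <- diag(1 / sqrt(r)) %*% sv$u[, nz, drop = FALSE] %*%
    diag(sv$d[nz], length(nz))
  rownames(scores) <- rownames(g)
  colnames(scores) <- paste0("dim", seq_along(nz))
  list(panel = strain_panel(panel$snps[keep, , drop = FALSE],
                            panel$geno[keep, , drop = FALSE]),
       ranking = ranking, scores = scores,
       inertia = inertia_share[nz])
}

#' Supervised strain-admixture estimation
#'
#' Maximum-likelihood admixture proportions Q on the simplex under the
#' binomial genotype model: each of a sample's two allele copies at SNP j
#' is the alternate allele with probability f_j(Q) = sum_s Q_s f_js, where
#' f_js are the (fixed, supervised) reference strain allele frequencies.
#' Solved by EM from the barycenter, so the result is deterministic.
#' Reference frequencies are clamped away from 0/1 by `freq_clamp` to
#' absorb genotyping error against inbred references.
#'
#' @param genotype a `sample_genotype` (0/1/2 alt copies, NA missing) or
#'   plain numeric vector aligned with `panel`'s SNPs.
#' @param panel a `strain_panel` of reference strains.
#' @param min_call_rate QC floor on the fraction of non-missing genotypes.
#' @param freq_clamp clamp for reference frequencies.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return list of class `admixture_estimate`: `proportions` (named, on the
#'   simplex), `loglik`, `n_snps`, `call_rate`, `qc_pass`, `n_iter`.
#'   Samples below `min_call_rate` return `qc_pass = FALSE` with NA
#'   proportions.
#' @export
estimate_admixture <- function(genotype, panel, min_call_rate = 0.8,
                               freq_clamp = 1e-3, tol = 1e-8,
                               max_iter = 2000) {
  stopifnot(inherits(panel, "strain_panel"))
  g <- as.numeric(genotype)
  if (length(g) != nrow(panel$snps))
    stop("genotype length does not match panel")
  call_rate <- mean(!is.na(g))
  strains <- colnames(panel$geno)
  if (call_rate < min_call_rate) {
    return(structure(list(proportions = stats::setNames(
      rep(NA_real_, length(strains)), strains),
      loglik = NA_real_, n_snps = sum(!is.na(g)),
      call_rate = call_rate, qc_pass = FALSE, n_iter = 0L),
      class = "admixture_estimate"))
  }
  use <- !is.na(g)
  f <- pmin(pmax(panel$geno[use, , drop = FALSE], freq_clamp), 1 - freq_clamp)
  g <- g[use]
  S <- length(strains)
  Q <- rep(1 / S, S)
  ll_of <- function(Q) {
    fq <- as.vector(f %*% Q)
    sum(g * log(fq) + (2 - g) * log(1 - fq))
  }
  ll <- ll_of(Q)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fq <- as.vector(f %*% Q)
    # expected ancestry counts per strain (alt and ref copies separately)
    alt <- colSums((g / fq) * sweep(f, 2, Q, "*"))
    ref <- colSums(((2 - g) / (1 - fq)) * sweep(1 - f, 2, Q, "*"))
    Q_new <- (alt + ref) / (2 * length(g))
    Q_new <- Q_new / sum(Q_new)
    ll_new <- ll_of(Q_new)
    done <- iter >= max_iter ||
      abs(ll_new - ll) < tol * (abs(ll) + 1e-12)
    Q <- Q_new; ll <- ll_new
    if (done) break
  }
  structure(list(proportions = stats::setNames(Q, strains), loglik = ll,
                 n_snps = length(g), call_rate = call_rate,
                 qc_pass = TRUE, n_iter = iter),
            class = "admixture_estimate")
}

#' @export
print.admixture_estimate <- function(x, ...) {
  if (!x$qc_pass) {
    cat("<admixture_estimate> QC FAIL (call rate",
        sprintf("%.2f", x$call_rate), ")\n")
  } else {
    cat("<admixture_estimate>",
        paste(sprintf("%s=%.3f", names(x$proportions), x$proportions),
              collapse = " "),
        sprintf("| loglik %.1f | %d SNPs\n", x$loglik, x$n_snps))
  }
  invisible(x)
}

#' Admixture error as a function of SNP-set size
#'
#' For each requested set size, takes the top SNPs by MCA contribution,
#' simulates pairwise F1 crosses of the panel strains, re-estimates their
#' admixture and reports the root-mean-square error of the estimated
#' versus true proportions, averaged over replicates.
#'
#' @param panel a `strain_panel` (informative SNPs).
#' @param sizes SNP-set sizes to evaluate.
#' @param n_replicates simulated F1s per size.
#' @param missing_rate genotype missingness in the simulated samples.
#' @param seed RNG seed.
#' @return data.frame `size`, `rmse`.
#' @export
benchmark_snp_sets <- function(panel, sizes, n_replicates = 100,
                               missing_rate = 0, seed = NULL) {
  stopifnot(inherits(panel, "strain_panel"))
  strains <- colnames(panel$geno)
  pairs <- utils::combn(strains, 2, simplify = FALSE)
  with_seed(seed, {
    res <- lapply(sizes, function(sz) {
      sub <- if (sz >= nrow(panel$snps)) panel else
        reduce_snps_mca(panel, n_target = sz)$panel
      errs <- vapply(seq_len(n_replicates), function(r) {
        pr <- pairs[[(r - 1L) %% length(pairs) + 1L]]
        gt <- simulate_cross(sub, stats::setNames(c(.5, .5), pr),
                             missing_rate = missing_rate, f1 = TRUE)
        est <- estimate_admixture(gt, sub)
        truth <- attr(gt, "truth")[names(est$proportions)]
        sqrt(mean((est$proportions - truth)^2))
      }, numeric(1))
      data.frame(size = sz, rmse = mean(errs))
    })
    do.call(rbind, res)
  })
}
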