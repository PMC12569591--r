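#' Simulate an inbred strain reference panel
#'
#' Each SNP carries an ancestral allele; every strain keeps the ancestral
#' allele with probability `1 - divergence` and otherwise draws a fresh
#' random allele, independently per SNP (inbred strains are homozygous, so
#' one 0/1 allele per strain per SNP). `divergence = 1` gives fully
#' independent random alleles, the most divergent design.
#'
#' @param n_strains number of strains (named S1..Sn).
#' @param n_snps number of SNPs.
#' @param divergence probability in [0, 1] that a strain's allele is drawn
#'   anew rather than copied from the ancestral allele.
#' @param seed RNG seed.
#' @return a `strain_panel`.
#' @export
simulate_strain_panel <- function(n_strains, n_snps, divergence = 0.5,
                                  seed = NULL) {
  stopifnot(n_strains >= 1, n_snps >= 1,
            divergence >= 0, divergence <= 1)
  with_seed(seed, {
    anc <- stats::rbinom(n_snps, 1, 0.5)
    g <- matrix(0, n_snps, n_strains,
                dimnames = list(NULL, paste0("S", seq_len(n_strains))))
    for (s in seq_len(n_strains)) {
      redraw <- stats::runif(n_snps) < divergence
      g[, s] <- ifelse(redraw, stats::rbinom(n_snps, 1, 0.5), anc)
    }
    snps <- data.frame(chrom = "chr1",
                       pos = seq_len(n_snps) * 1000L,
                       id = sprintf("snp%05d", seq_len(n_snps)),
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
    strain_panel(snps, g)
  })
}

#' Simulate an admixed sample genotype from a strain panel
#'
#' Each of the two gametes at every SNP draws a founder strain according to
#' `proportions` and inherits that strain's allele; SNPs are independent
#' (no linkage). An F1 of strains A and B is `proportions = c(A = .5, B = .5)`
#' with `f1 = TRUE`, which forces exactly one gamete from each parent.
#'
#' @param panel a `strain_panel`.
#' @param proportions named numeric vector on the simplex (names must be
#'   strain ids of the panel).
#' @param missing_rate probability a genotype is missing.
#' @param f1 logical; when TRUE `proportions` must name exactly two strains
#'   at 0.5 each and each SNP takes one allele from each parent.
#' @param seed RNG seed.
#' @return object of class `sample_genotype`: integer vector (0/1/2 alt
#'   copies, NA = missing) named by SNP id, with attributes `call_rate` and
#'   `truth` (the admixture proportions used).
#' @export
simulate_cross <- function(panel, proportions, missing_rate = 0, f1 = FALSE,
                           seed = NULL) {
  stopifnot(inherits(panel, "strain_panel"))
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  if (any(proportions < 0)) stop("proportions must be >= 0")
  if (is.null(names(proportions)) ||
      !all(names(proportions) %in% colnames(panel$geno)))
    stop("proportions must be named by panel strains")
  n <- nrow(panel$geno)
  with_seed(seed, {
    if (f1) {
      if (length(proportions) != 2 || any(abs(proportions - 0.5) > 1e-8))
        stop("f1 = TRUE requires two strains at 0.5 each")
      a <- panel$geno[, names(proportions)[1]]
      b <- panel$geno[, names(proportions)[2]]
      g <- a + b
    } else {
      pick <- function() {
        s <- sample(names(proportions), n, replace = TRUE,
                    prob = proportions)
        panel$geno[cbind(seq_len(n), match(s, colnames(panel$geno)))]
      }
      g <- pick() + pick()
    }
    if (missing_rate > 0) g[stats::runif(n) < missing_rate] <- NA
    g <- as.integer(g)
    names(g) <- panel$snps$id
    full <- rep(0, ncol(panel$geno))
    names(full) <- colnames(panel$geno)
    full[names(proportions)] <- proportions
    structure(g, class = "sample_genotype",
              call_rate = mean(!is.na(g)), truth = full)
  })
}
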