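#' Simulate an orthologous protein pair with known conservation
#'
#' Generates a random "human" peptide, derives a "mouse" ortholog by
#' substituting a controlled fraction of positions (each substituted
#' position gets a different residue), and builds single-exon CDS models
#' consistent with both peptides. The truth map records, per position,
#' whether the residue is conserved.
#'
#' @param length peptide length (>= 29, so a +/-14 window fits somewhere).
#' @param conserved_fraction fraction of positions left identical.
#' @param substituted optional integer positions forced to be substituted
#'   (overrides the random draw at those positions).
#' @param seed RNG seed.
#' @return list with `human` and `mouse` (each a list `peptide`,
#'   `cds` = [cds_model()]) and `truth` (data.frame `pos`, `conserved`).
#' @export
simulate_ortholog_pair <- function(length, conserved_fraction = 1,
                                   substituted = NULL, seed = NULL) {
  stopifnot(length >= 29, conserved_fraction >= 0, conserved_fraction <= 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    hum <- sample(aa, length, replace = TRUE)
    n_sub <- round((1 - conserved_fraction) * length)
    subs <- sample.int(length, n_sub)
    if (!is.null(substituted)) subs <- union(subs, as.integer(substituted))
    mou <- hum
    for (i in subs) mou[i] <- sample(setdiff(aa, hum[i]), 1)
    hum_pep <- paste(hum, collapse = "")
    mou_pep <- paste(mou, collapse = "")
    mk <- function(pep, offset) {
      cds_model(transcript = paste0("tx_", offset), strand = "+",
                exons = data.frame(start = offset,
                                   end = offset + 3 * nchar(pep)),
                peptide = pep, stop_included = FALSE)
    }
    list(human = list(peptide = hum_pep, cds = mk(hum_pep, 1000)),
         mouse = list(peptide = mou_pep, cds = mk(mou_pep, 5000)),
         truth = data.frame(pos = seq_len(length),
                            conserved = !(seq_len(length) %in% subs)))
  })
}

#' Simulate a sample-by-arm aneuploidy matrix with planted recurrences
#'
#' Each cell independently carries an event with the background rate (sign
#' chosen uniformly), except planted arms which use their own rate and
#' fixed direction.
#'
#' @param n_samples number of samples (rows).
#' @param arms character vector of arm ids (columns).
#' @param background_rate per-cell probability of a background event.
#' @param planted optional data.frame with columns `arm`, `rate`,
#'   `direction` (+1/-1).
#' @param seed RNG seed.
#' @return integer matrix in {-1, 0, +1} with a `truth` attribute naming
#'   planted arms.
#' @export
simulate_aneuploidy_matrix <- function(n_samples, arms, background_rate = 0.05,
                                       planted = NULL, seed = NULL) {
  stopifnot(background_rate >= 0, background_rate <= 1)
  with_seed(seed, {
    m <- matrix(0L, n_samples, length(arms),
                dimnames = list(paste0("sample", seq_len(n_samples)), arms))
    ev <- matrix(stats::runif(length(m)) < background_rate, n_samples)
    sgn <- matrix(sample(c(-1L, 1L), length(m), replace = TRUE), n_samples)
    m[ev] <- sgn[ev]
    if (!is.null(planted)) {
      stopifnot(all(c("arm", "rate", "direction") %in% names(planted)),
                all(planted$rate >= 0 & planted$rate <= 1),
                all(planted$arm %in% arms))
      for (i in seq_len(nrow(planted))) {
        hit <- stats::runif(n_samples) < planted$rate[i]
        m[, planted$arm[i]] <- ifelse(hit, as.integer(planted$direction[i]), 0L)
      }
    }
    attr(m, "truth") <- planted
    m
  })
}
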