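#' Empirical variant filters for semiconductor amplicon sequencing
#'
#' A variant passes when all five rules hold: flow-corrected alt-allele
#' strand ratio (forward/reverse) within [0.2, 5.0] (reverse = 0 gives
#' ratio +Inf), flow-corrected depth > 100, flow-corrected alt reads > 10,
#' homopolymer run length < 4, and allele fraction > 0.1. Each failed rule
#' is recorded.
#'
#' @param records data.frame with columns `depth`, `alt_fwd`, `alt_rev`,
#'   `homopolymer`, `allele_fraction`.
#' @return the input with added `strand_ratio`, `pass` (logical) and
#'   `fail_reasons` (semicolon-joined) columns.
#' @export
filter_variants <- function(records) {
  req <- c("depth", "alt_fwd", "alt_rev", "homopolymer", "allele_fraction")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  alt <- records$alt_fwd + records$alt_rev
  if (any(alt > records$depth)) stop("alt reads exceed depth")
  if (any(records$allele_fraction < 0 | records$allele_fraction > 1))
    stop("allele fraction must be in [0, 1]")
  ratio <- ifelse(records$alt_rev == 0, Inf,
                  records$alt_fwd / records$alt_rev)
  checks <- list(
    strand = ratio >= 0.2 & ratio <= 5.0,
    depth = records$depth > 100,
    alt_reads = alt > 10,
    homopolymer = records$homopolymer < 4,
    allele_fraction = records$allele_fraction > 0.1)
  fails <- vapply(seq_len(nrow(records)), function(i) {
    paste(names(checks)[!vapply(checks, `[`, logical(1), i)], collapse = ";")
  }, character(1))
  records$strand_ratio <- ratio
  records$pass <- !nzchar(fails)
  records$fail_reasons <- fails
  records
}
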