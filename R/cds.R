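#' CDS model for a transcript
#'
#' Exon CDS intervals are 0-based half-open genomic coordinates, ordered
#' 5'-to-3' along the transcript: ascending genomic order on the + strand,
#' descending on the - strand. The total CDS length must equal
#' 3 * peptide length, plus 3 for the stop codon when `stop_included`.
#'
#' @param transcript transcript id.
#' @param strand "+" or "-".
#' @param exons data.frame with columns `start`, `end`, one row per CDS
#'   exon, ordered 5'->3' of the transcript.
#' @param peptide peptide string (stop codon excluded).
#' @param stop_included does the CDS include the stop codon?
#' @return object of class `cds_model`.
#' @export
cds_model <- function(transcript, strand, exons, peptide,
                      stop_included = TRUE) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            all(exons$end > exons$start))
  widths <- exons$end - exons$start
  expected <- 3 * nchar(peptide) + if (stop_included) 3 else 0
  if (sum(widths) != expected)
    stop("CDS length ", sum(widths), " != ", expected,
         " (3 * peptide length", if (stop_included) " + stop", ")")
  # exons must be disjoint and ordered 5'->3'
  gstart <- exons$start
  if (strand == "+" && is.unsorted(gstart, strictly = TRUE) && nrow(exons) > 1)
    stop("+ strand exons must ascend in genomic order")
  if (strand == "-" && nrow(exons) > 1 && is.unsorted(rev(gstart), strictly = TRUE))
    stop("- strand exons must descend in genomic order")
  structure(list(transcript = transcript, strand = strand,
                 exons = exons, peptide = peptide,
                 stop_included = stop_included),
            class = "cds_model")
}

# genomic position of each CDS offset (0-based), in transcript order
cds_offset_positions <- function(model) {
  ex <- model$exons
  if (model$strand == "+") {
    unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:(ex$end[i] - 1L)))
  } else {
    unlist(lapply(seq_len(nrow(ex)), function(i) (ex$end[i] - 1L):ex$start[i]))
  }
}

#' Map an amino-acid index to genomic codon positions (and back)
#'
#' Forward: amino acid `aa` occupies CDS offsets [3(aa-1), 3aa), walked
#' through the exons in transcript order (descending genomic coordinates on
#' the - strand); a codon may span an exon junction. The stop codon, when
#' included in the CDS, maps via index `peptide length + 1`.
#'
#' @param model a `cds_model`.
#' @param aa 1-based amino-acid index.
#' @return `aa_to_genomic`: integer vector of 3 genomic positions (0-based)
#'   in transcript order.
#' @export
aa_to_genomic <- function(model, aa) {
  npep <- nchar(model$peptide)
  nmax <- npep + if (model$stop_included) 1L else 0L
  if (aa < 1 || aa > nmax)
    stop("aa index out of range 1..", nmax)
  pos <- cds_offset_positions(model)
  pos[(3L * (aa - 1L) + 1L):(3L * aa)]
}

#' @rdname aa_to_genomic
#' @param gpos 0-based genomic position.
#' @return `genomic_to_aa`: the 1-based amino-acid index containing `gpos`,
#'   or NA when the position is outside the CDS (not an error).
#' @export
genomic_to_aa <- function(model, gpos) {
  pos <- cds_offset_positions(model)
  i <- match(gpos, pos)
  if (is.na(i)) return(NA_integer_)
  as.integer((i - 1L) %/% 3L + 1L)
}
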