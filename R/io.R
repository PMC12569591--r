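#' Read / write a read-count matrix
#'
#' TSV with amplicon ids in the first column (`amplicon`) and one integer
#' column per sample.
#'
#' @param path file path.
#' @param panel optional `amplicon_panel`; when given, rows are checked and
#'   reordered against the panel's amplicon ids.
#' @return `read_counts_tsv` returns an integer matrix (amplicons x samples)
#'   with amplicon ids as rownames.
#' @export
read_counts_tsv <- function(path, panel = NULL) {
  d <- read_tsv_checked(path, "amplicon")
  num <- vapply(d[-1], is.numeric, logical(1))
  if (!all(num))
    stop("counts parse error: non-numeric sample column ",
         names(num)[!num][1])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("counts must be non-negative")
  rownames(m) <- d$amplicon
  if (!is.null(panel)) {
    if (!setequal(rownames(m), panel$id))
      stop("count rows do not match panel amplicon ids")
    m <- m[panel$id, , drop = FALSE]
  }
  m
}

#' @rdname read_counts_tsv
#' @param counts integer matrix (amplicons x samples).
#' @export
write_counts_tsv <- function(counts, path) {
  d <- data.frame(amplicon = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write segment tables (SEG)
#'
#' On disk the SEG format is 1-based with inclusive ends (sample, chrom,
#' start, end, num.mark, seg.mean, and optional z, q, state columns);
#' internally segments are 0-based half-open. Out-of-order segments are
#' sorted on read with a warning.
#'
#' @param path file path.
#' @return `read_seg` returns a data.frame with columns `sample`, `chrom`,
#'   `start`, `end`, `num_mark`, `seg_mean` and, when present, `z`, `q`,
#'   `state`.
#' @export
read_seg <- function(path) {
  d <- read_tsv_checked(path, c("sample", "chrom", "start", "end",
                                "num.mark", "seg.mean"))
  for (col in c("start", "end", "num.mark", "seg.mean")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v))
      stop("SEG parse error at line ", which(is.na(v))[1] + 1L,
           ": non-numeric ", col)
    d[[col]] <- v
  }
  out <- data.frame(sample = d$sample, chrom = d$chrom,
                    start = d$start - 1, end = d$end,
                    num_mark = as.integer(d$num.mark),
                    seg_mean = d$seg.mean, stringsAsFactors = FALSE)
  for (col in c("z", "q", "state")) if (col %in% names(d)) out[[col]] <- d[[col]]
  if (any(out$num_mark < 1)) stop("SEG: num.mark must be >= 1")
  ord <- order(out$sample, out$chrom, out$start)
  if (!identical(ord, seq_len(nrow(out)))) {
    warning("SEG segments out of order; normalized to sorted order")
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' @rdname read_seg
#' @param segs internal segment data.frame (0-based half-open).
#' @export
write_seg <- function(segs, path) {
  d <- data.frame(sample = segs$sample, chrom = segs$chrom,
                  start = format(segs$start + 1, scientific = FALSE, trim = TRUE),
                  end = format(segs$end, scientific = FALSE, trim = TRUE),
                  num.mark = segs$num_mark, seg.mean = segs$seg_mean,
                  check.names = FALSE)
  for (col in c("z", "q", "state")) if (col %in% names(segs)) d[[col]] <- segs[[col]]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Strain reference panel
#'
#' Reference genotypes for inbred founder strains at a set of biallelic
#' SNPs. Inbred strains are homozygous, so each strain carries a single
#' 0/1 allele per SNP (1 = alternate).
#'
#' @param snps data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param geno 0/1 matrix, SNPs x strains, with strain ids as colnames.
#' @return object of class `strain_panel` (list with `snps`, `geno`).
#' @export
strain_panel <- function(snps, geno) {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(snps)),
            is.matrix(geno), nrow(geno) == nrow(snps),
            !is.null(colnames(geno)))
  if (anyDuplicated(paste(snps$chrom, snps$pos))) stop("SNP positions must be unique")
  if (!all(geno %in% c(0, 1))) stop("inbred strain alleles must be 0/1")
  rownames(geno) <- snps$id
  structure(list(snps = snps, geno = geno), class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat("<strain_panel>", nrow(x$snps), "SNPs x", ncol(x$geno), "strains\n")
  invisible(x)
}

#' Read / write a strain panel as a VCF-like TSV
#'
#' Columns: chrom, pos, id, ref, alt, then one 0/1 column per strain.
#'
#' @param path file path.
#' @return `read_strain_panel` returns a `strain_panel`.
#' @export
read_strain_panel <- function(path) {
  d <- read_tsv_checked(path, c("chrom", "pos", "id", "ref", "alt"))
  strains <- setdiff(names(d), c("chrom", "pos", "id", "ref", "alt"))
  if (!length(strains)) stop("strain panel has no strain columns")
  g <- as.matrix(d[, strains, drop = FALSE])
  storage.mode(g) <- "numeric"
  if (anyNA(g))
    stop("strain panel parse error at line ",
         which(apply(is.na(g), 1, any))[1] + 1L, ": non-numeric genotype")
  strain_panel(d[, c("chrom", "pos", "id", "ref", "alt")], g)
}

#' @rdname read_strain_panel
#' @param panel a `strain_panel` to write.
#' @export
write_strain_panel <- function(panel, path) {
  d <- cbind(panel$snps, as.data.frame(panel$geno))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a synteny block table
#'
#' TSV with columns hchrom, hstart, hend, mchrom, mstart, mend, orientation
#' (`+`/`-`); coordinates 0-based half-open in both genomes.
#'
#' @param path file path.
#' @return `read_synteny` returns a data.frame of blocks.
#' @export
read_synteny <- function(path) {
  d <- read_tsv_checked(path, c("hchrom", "hstart", "hend",
                                "mchrom", "mstart", "mend", "orientation"))
  for (col in c("hstart", "hend", "mstart", "mend")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v))
      stop("synteny parse error at line ", which(is.na(v))[1] + 1L,
           ": non-numeric ", col)
    d[[col]] <- v
  }
  if (any(d$hend <= d$hstart) || any(d$mend <= d$mstart))
    stop("synteny blocks must have positive length")
  d
}

#' @rdname read_synteny
#' @param blocks synteny block data.frame to write.
#' @export
write_synteny <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
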