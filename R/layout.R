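#' Genome layout: chromosomes and chromosome arms
#'
#' A genome layout records chromosome lengths and arm intervals for one
#' species. All coordinates are 0-based half-open. Mouse autosomes are
#' telocentric, so a mouse layout carries exactly one arm per autosome
#' spanning the whole chromosome; human-style layouts carry p/q arms taken
#' from a cytoband-derived arm table.
#'
#' @param arms data.frame with columns `chrom`, `arm`, `start`, `end`
#'   (0-based half-open bp). Arm ids must be unique.
#' @param species species tag, e.g. `"mouse"` or `"human"`.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the maximum arm end per chromosome.
#' @return An object of class `genome_layout` with elements `species`,
#'   `chroms` (data.frame `chrom`, `length`) and `arms`.
#' @export
genome_layout <- function(arms, species = "mouse", chrom_lengths = NULL) {
  stopifnot(is.data.frame(arms),
            all(c("chrom", "arm", "start", "end") %in% names(arms)))
  arms <- arms[, c("chrom", "arm", "start", "end")]
  arms$chrom <- as.character(arms$chrom)
  arms$arm <- as.character(arms$arm)
  if (anyDuplicated(arms$arm)) stop("arm ids must be unique")
  if (any(arms$end <= arms$start)) stop("arms must be non-empty (end > start)")
  if (any(arms$start < 0)) stop("arm start must be >= 0")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(arms$end, arms$chrom, max)
  }
  chroms <- data.frame(chrom = names(chrom_lengths),
                       length = as.numeric(chrom_lengths),
                       stringsAsFactors = FALSE)
  if (any(arms$end > chroms$length[match(arms$chrom, chroms$chrom)]))
    stop("arm extends beyond chromosome length")
  # arms on the same chromosome must not overlap
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)]))
      stop("arms overlap on chromosome ", ch)
  }
  structure(list(species = species, chroms = chroms, arms = arms),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> species:", x$species, "|",
      nrow(x$chroms), "chromosomes,", nrow(x$arms), "arms\n")
  invisible(x)
}

#' Default mouse autosome layout
#'
#' Telocentric convention: one arm per autosome spanning the whole
#' chromosome (mice have no short arms; only the 19 autosomes are carried).
#' Lengths approximate the GRCm38 autosomes, in bp.
#'
#' @return A `genome_layout` for the 19 mouse autosomes.
#' @export
mouse_layout <- function() {
  len <- c(195.5, 182.1, 160.0, 156.5, 151.8, 149.7, 145.4, 129.4, 124.6,
           130.7, 122.1, 120.1, 120.4, 124.9, 104.0, 98.2, 94.9, 90.7, 61.4) * 1e6
  chrom <- paste0("chr", 1:19)
  genome_layout(data.frame(chrom = chrom, arm = chrom,
                           start = 0, end = len),
                species = "mouse")
}

#' Coverage-restricted arm windows
#'
#' For each arm, builds the interval of breadth `c` centered at the arm
#' midpoint: width = round(c * arm length), start = floor(midpoint - width/2),
#' clipped to the arm bounds. These windows are the denominator of the R_c
#' aneuploidy metric.
#'
#' @param layout a `genome_layout`.
#' @param c breadth of coverage, a fraction in (0, 1].
#' @return data.frame with columns `arm`, `chrom`, `start`, `end`, `c`.
#' @export
build_arm_windows <- function(layout, c) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0 || c > 1)
    stop("c must be a single number in (0, 1]")
  a <- layout$arms
  len <- a$end - a$start
  w <- round(c * len)
  mid <- (a$start + a$end) / 2
  start <- pmax(a$start, floor(mid - c * len / 2))
  end <- pmin(a$end, start + w)
  data.frame(arm = a$arm, chrom = a$chrom, start = start, end = end, c = c,
             stringsAsFactors = FALSE)
}

#' Read / write arm layout tables
#'
#' TSV with columns species, chrom, arm, start, end (0-based half-open).
#'
#' @param path file path.
#' @return `read_arm_layout` returns a `genome_layout`.
#' @export
read_arm_layout <- function(path) {
  d <- read_tsv_checked(path, c("species", "chrom", "arm", "start", "end"))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("arm layout parse error at line ", bad[1] + 1L,
           ": non-numeric ", col)
    d[[col]] <- v
  }
  genome_layout(d[, c("chrom", "arm", "start", "end")],
                species = d$species[1])
}

#' @rdname read_arm_layout
#' @param layout a `genome_layout` to write.
#' @export
write_arm_layout <- function(layout, path) {
  d <- layout$arms
  d <- cbind(species = layout$species, d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
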