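#' Amplicon panel
#'
#' The panel describes every amplicon target: coordinates (0-based
#' half-open), the gene symbol or SNP id it measures, a target class, its GC
#' fraction and primer pool. Flox amplicons (engineered Cre-recombinase
#' excision targets) carry both a parent gene and a distinct flox target
#' label (`<gene>_flox`) so that flox signal is called separately from the
#' rest of the gene.
#'
#' @param df data.frame with columns `id`, `chrom`, `start`, `end`, `gene`,
#'   `class` (one of hotspot, tsg-cds, cn-tiling, genotyping-snp, flox),
#'   `gc`, `pool`. For `class == "flox"` rows, `gene` is the parent gene;
#'   the constructor derives `target` = `<gene>_flox` for them and `target`
#'   = `gene` otherwise.
#' @param layout optional `genome_layout` used to validate coordinates.
#' @return data.frame of class `amplicon_panel` with an added `target`
#'   column (the label used for gene-level calling) and `parent_gene`.
#' @export
amplicon_panel <- function(df, layout = NULL) {
  req <- c("id", "chrom", "start", "end", "gene", "class", "gc", "pool")
  stopifnot(is.data.frame(df), all(req %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("amplicon ids must be unique")
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1]
    stop("invalid amplicon interval (end <= start) for id ", df$id[bad])
  }
  if (any(df$gc < 0 | df$gc > 1)) stop("gc must be in [0, 1]")
  cls <- c("hotspot", "tsg-cds", "cn-tiling", "genotyping-snp", "flox")
  if (!all(df$class %in% cls))
    stop("unknown target class: ",
         paste(setdiff(unique(df$class), cls), collapse = ", "))
  if (!is.null(layout)) {
    m <- match(df$chrom, layout$chroms$chrom)
    if (anyNA(m)) stop("amplicon chromosome not in layout: ",
                       df$chrom[which(is.na(m))[1]])
    if (any(df$end > layout$chroms$length[m]))
      stop("amplicon beyond chromosome end: ",
           df$id[which(df$end > layout$chroms$length[m])[1]])
  }
  df$parent_gene <- ifelse(df$class == "flox", df$gene, NA_character_)
  df$target <- ifelse(df$class == "flox", paste0(df$gene, "_flox"), df$gene)
  class(df) <- c("amplicon_panel", "data.frame")
  df
}

#' Read / write an amplicon panel as BED6+
#'
#' BED columns: chrom, start, end, name (gene or SNP id), score (unused, 0),
#' strand (unused, "."), then class, gc, pool, floxFlag.
#'
#' @param path file path.
#' @param layout optional `genome_layout` for coordinate validation.
#' @return `read_panel_bed` returns an `amplicon_panel`; amplicon ids are
#'   taken from the name column suffixed with the row index when duplicated.
#' @export
read_panel_bed <- function(path, layout = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 10))
    stop("panel BED parse error at line ", which(n < 10)[1],
         ": expected 10 tab-separated columns")
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(start) || anyNA(end))
    stop("panel BED parse error at line ",
         which(is.na(start) | is.na(end))[1], ": non-numeric coordinate")
  if (any(end <= start))
    stop("panel BED parse error at line ", which(end <= start)[1],
         ": end <= start")
  flox <- m[, 10] %in% c("1", "TRUE", "true")
  df <- data.frame(id = paste0(m[, 4], "_", seq_along(lines)),
                   chrom = m[, 1], start = start, end = end,
                   gene = m[, 4], class = m[, 7],
                   gc = as.numeric(m[, 8]), pool = m[, 9],
                   stringsAsFactors = FALSE)
  df$class[flox] <- "flox"
  amplicon_panel(df, layout)
}

#' @rdname read_panel_bed
#' @param panel an `amplicon_panel` to write.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "amplicon_panel"))
  out <- data.frame(panel$chrom, format(panel$start, scientific = FALSE, trim = TRUE),
                    format(panel$end, scientific = FALSE, trim = TRUE),
                    panel$gene, 0L, ".",
                    ifelse(panel$class == "flox", "flox", panel$class),
                    panel$gc, panel$pool,
                    as.integer(panel$class == "flox"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene intervals spanned by a panel's amplicons
#'
#' One row per calling target (`target` column): the enclosing interval of
#' its amplicons. Genotyping SNPs are excluded.
#'
#' @param panel an `amplicon_panel`.
#' @return data.frame with `target`, `chrom`, `start`, `end`, `n_amplicons`,
#'   `flox` (logical).
#' @export
gene_intervals <- function(panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  p <- panel[panel$class != "genotyping-snp", , drop = FALSE]
  sp <- split(seq_len(nrow(p)), p$target)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    i <- sp[[g]]
    data.frame(target = g, chrom = p$chrom[i[1]],
               start = min(p$start[i]), end = max(p$end[i]),
               n_amplicons = length(i), flox = p$class[i[1]] == "flox",
               stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}
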