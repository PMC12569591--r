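#' Windowed protein alignment score around a focal residue
#'
#' Aligns the two peptide windows (the focal residue plus `flank` residues
#' on each side, clipped at sequence ends) globally under a high-identity
#' substitution matrix, and reports the mean local alignment score: total
#' alignment score divided by the aligned length. Gap columns are penalized
#' inside the total; `mean_mode = "no_gap_columns"` divides by the number of
#' substitution columns instead.
#'
#' @param seq_a,seq_b peptide strings.
#' @param pos_a,pos_b 1-based focal residue positions.
#' @param flank residues kept on each side of the focal position.
#' @param matrix substitution matrix name from Biostrings (default
#'   `"PAM30"`, suitable for ~90%-identity orthologs) or a numeric matrix.
#' @param gap_open,gap_ext gap penalties (matrix units).
#' @param mean_mode denominator for the mean score: all aligned columns
#'   (default) or substitution columns only.
#' @return list with `score` (total), `mean_score`, `aligned_length`,
#'   `focal_aligned` (do the focal positions share a column?),
#'   `residue_match` (are the focal residues identical?).
#' @export
window_alignment_score <- function(seq_a, pos_a, seq_b, pos_b, flank = 14,
                                   matrix = "PAM30", gap_open = 10,
                                   gap_ext = 1,
                                   mean_mode = c("all_columns",
                                                 "no_gap_columns")) {
  mean_mode <- match.arg(mean_mode)
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (la == 0 || lb == 0) stop("empty sequence")
  if (pos_a < 1 || pos_a > la || pos_b < 1 || pos_b > lb)
    stop("focal position outside sequence")
  mat <- if (is.character(matrix)) get_sub_matrix(matrix) else matrix
  a0 <- max(1, pos_a - flank); a1 <- min(la, pos_a + flank)
  b0 <- max(1, pos_b - flank); b1 <- min(lb, pos_b + flank)
  wa <- substr(seq_a, a0, a1)
  wb <- substr(seq_b, b0, b1)
  pa <- Biostrings::pairwiseAlignment(wa, wb, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_ext)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncols <- length(ap)
  ia <- cumsum(ap != "-")          # window-relative index of a at each column
  ib <- cumsum(as != "-")
  fa <- pos_a - a0 + 1L; fb <- pos_b - b0 + 1L
  col_a <- which(ap != "-" & ia == fa)[1]
  col_b <- which(as != "-" & ib == fb)[1]
  focal_aligned <- !is.na(col_a) && !is.na(col_b) && col_a == col_b
  resid_a <- substr(seq_a, pos_a, pos_a)
  resid_b <- substr(seq_b, pos_b, pos_b)
  denom <- if (mean_mode == "all_columns") ncols else
    sum(ap != "-" & as != "-")
  list(score = Biostrings::score(pa),
       mean_score = Biostrings::score(pa) / max(denom, 1L),
       aligned_length = ncols,
       focal_aligned = focal_aligned,
       residue_match = resid_a == resid_b,
       residue_a = resid_a, residue_b = resid_b)
}

# cached Biostrings scoring matrices by name
get_sub_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!exists(name, envir = cache)) {
      e <- new.env()
      utils::data(list = name, package = "Biostrings", envir = e)
      assign(name, get(name, envir = e), envir = cache)
    }
    get(name, envir = cache)
  }
})

#' Classify a cross-species shared hotspot
#'
#' A human hotspot position is shared with the mouse ortholog when (i) the
#' focal residues are identical and (ii) the mean local alignment score of
#' the flanking windows is greater than 0 (which rejects residues matching
#' by chance in otherwise diverged context).
#'
#' @param human_peptide,mouse_peptide peptide strings.
#' @param human_pos 1-based hotspot position in the human peptide.
#' @param mouse_pos candidate mouse position (e.g. from a coordinate-map
#'   table); when NULL the mouse position is located by a global-local
#'   alignment of the human window against the whole mouse peptide.
#' @param ... passed to [window_alignment_score()].
#' @return data.frame (one row) with `human_pos`, `mouse_pos`,
#'   `residue_match`, `mean_score`, `shared`.
#' @export
classify_shared_hotspot <- function(human_peptide, mouse_peptide, human_pos,
                                    mouse_pos = NULL, ...) {
  if (is.null(mouse_pos))
    mouse_pos <- locate_ortholog_position(human_peptide, mouse_peptide,
                                          human_pos, ...)
  if (is.na(mouse_pos))
    return(data.frame(human_pos = human_pos, mouse_pos = NA_integer_,
                      residue_match = FALSE, mean_score = NA_real_,
                      shared = FALSE))
  w <- window_alignment_score(human_peptide, human_pos,
                              mouse_peptide, mouse_pos, ...)
  data.frame(human_pos = human_pos, mouse_pos = mouse_pos,
             residue_match = w$residue_match, mean_score = w$mean_score,
             shared = w$residue_match && w$mean_score > 0)
}

# find the mouse residue aligned to the human focal position by aligning
# the human window against the full mouse peptide (global-local)
locate_ortholog_position <- function(human_peptide, mouse_peptide, human_pos,
                                     flank = 14, matrix = "PAM30",
                                     gap_open = 10, gap_ext = 1, ...) {
  la <- nchar(human_peptide)
  a0 <- max(1, human_pos - flank); a1 <- min(la, human_pos + flank)
  w <- substr(human_peptide, a0, a1)
  mat <- if (is.character(matrix)) get_sub_matrix(matrix) else matrix
  pa <- Biostrings::pairwiseAlignment(w, mouse_peptide,
                                      type = "global-local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_ext)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- cumsum(ap != "-")
  fa <- human_pos - a0 + 1L
  col <- which(ap != "-" & ia == fa)[1]
  if (is.na(col) || as[col] == "-") return(NA_integer_)
  sub_start <- pa@subject@range@start
  sub_start + sum(as[seq_len(col)] != "-") - 1L
}

#' Choose a mouse transcript for cross-species mapping
#'
#' Candidates are ranked by their number of conserved positions (mapped to
#' the human reference transcript), ties broken by the principal-isoform
#' rank (smaller = more principal).
#'
#' @param candidates data.frame with columns `transcript`,
#'   `conserved_count`, `principal_rank`.
#' @return the selected transcript id.
#' @export
choose_mouse_transcript <- function(candidates) {
  stopifnot(nrow(candidates) >= 1,
            all(c("transcript", "conserved_count", "principal_rank") %in%
                  names(candidates)))
  ord <- order(-candidates$conserved_count, candidates$principal_rank)
  candidates$transcript[ord[1]]
}

#' Logistic regression on determinants of hotspot conservation
#'
#' Fits shared ~ predictors by logistic regression. For the standardized
#' model, continuous predictors are centered at their median and scaled by
#' two standard deviations so that continuous and binary effect sizes are
#' comparable; raw and standardized odds ratios are reported with Wald
#' confidence intervals. Complete separation is flagged and CIs suppressed.
#'
#' @param data data.frame containing the outcome and predictors.
#' @param outcome name of the logical/0-1 outcome column.
#' @param predictors character vector of predictor columns.
#' @param conf_level confidence level for Wald intervals.
#' @return list with `raw` and `standardized` coefficient tables (term,
#'   estimate, or, ci_lo, ci_hi, p) and `separation` flag.
#' @export
conservation_factor_regression <- function(data, outcome, predictors,
                                           conf_level = 0.95) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y[!is.na(y)])) < 2) {
    return(list(raw = NULL, standardized = NULL, separation = TRUE))
  }
  fit_one <- function(d) {
    f <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
    d$.y <- y
    fit <- suppressWarnings(stats::glm(f, data = d, family = stats::binomial()))
    co <- summary(fit)$coefficients
    sep <- !fit$converged || any(abs(co[, "Estimate"]) > 15)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    tab <- data.frame(term = rownames(co),
                      estimate = co[, "Estimate"],
                      or = exp(co[, "Estimate"]),
                      ci_lo = if (sep) NA else exp(co[, "Estimate"] - z * co[, "Std. Error"]),
                      ci_hi = if (sep) NA else exp(co[, "Estimate"] + z * co[, "Std. Error"]),
                      p = co[, "Pr(>|z|)"], row.names = NULL)
    list(tab = tab, sep = sep)
  }
  raw <- fit_one(data)
  std_data <- data
  for (p in predictors) {
    v <- std_data[[p]]
    if (is.numeric(v) && length(unique(v)) > 2)
      std_data[[p]] <- (v - stats::median(v, na.rm = TRUE)) /
        (2 * stats::sd(v, na.rm = TRUE))
  }
  std <- fit_one(std_data)
  list(raw = raw$tab, standardized = std$tab,
       separation = raw$sep || std$sep)
}
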