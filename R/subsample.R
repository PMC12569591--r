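#' Subsample panel targets by genomic windows
#'
#' Chromosomes are split into non-overlapping windows of `window_size` bp.
#' In `"single-marker"` mode one random target is kept per window; in
#' `"whole-gene"` mode a random gene with targets in the window is chosen
#' and all of its targets in the window kept (a gene is preferred whenever
#' one is present; windows without a gene fall back to a single marker).
#' Empty windows contribute nothing.
#'
#' @param targets data.frame with `id`, `chrom`, `start`, `end` and
#'   optionally `gene` (NA for non-genic markers).
#' @param layout a `genome_layout`.
#' @param window_size window size in bp (e.g. 1e5, 2.5e5, 5e5, 1e6, 5e6, 1e7).
#' @param mode `"single-marker"` or `"whole-gene"`.
#' @param n_repeats number of independent subsamples.
#' @param seed RNG seed; repeats are reproducible given the seed.
#' @return list of length `n_repeats`; each element a character vector of
#'   retained target ids.
#' @export
subsample_markers <- function(targets, layout, window_size,
                              mode = c("single-marker", "whole-gene"),
                              n_repeats = 10, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(window_size > 0)
  targets <- targets[order(targets$chrom, targets$start), , drop = FALSE]
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      keep <- character(0)
      for (ch in layout$chroms$chrom) {
        len <- layout$chroms$length[layout$chroms$chrom == ch]
        t <- targets[targets$chrom == ch, , drop = FALSE]
        if (!nrow(t)) next
        win <- floor(t$start / window_size)
        for (w in unique(win)) {
          tw <- t[win == w, , drop = FALSE]
          genes <- if ("gene" %in% names(tw))
            unique(tw$gene[!is.na(tw$gene)]) else character(0)
          if (mode == "whole-gene" && length(genes)) {
            g <- if (length(genes) == 1) genes else sample(genes, 1)
            keep <- c(keep, tw$id[!is.na(tw$gene) & tw$gene == g])
          } else {
            keep <- c(keep, tw$id[sample.int(nrow(tw), 1)])
          }
        }
      }
      keep
    })
  })
}

#' Simulate a segmented cohort for arm-calling evaluation
#'
#' Generates, per sample, a marker-level profile over the layout (markers
#' every `marker_spacing` bp), plants whole-arm events (rate
#' `arm_event_rate`, amplitude +/- `amplitude`) and optionally partial-arm
#' events (covering a random fraction of the arm in
#' `partial_frac`), adds Gaussian noise, segments each chromosome with the
#' CBS-style splitter, and derives simplified gene calls (one gene per
#' marker; state = sign when |value| exceeds `state_floor`). Reference
#' calls are taken from the noise-free truth at c = 1.0, threshold 0.8, so
#' whole-arm events are reference-altered and partial events are not.
#'
#' This harness trades the full count-level pipeline for speed: it is the
#' marker-level view an arm caller sees after normalization.
#'
#' @param layout a `genome_layout`.
#' @param n_samples cohort size.
#' @param arm_event_rate per-arm probability of a whole-arm event.
#' @param partial_event_rate per-arm probability of a partial-arm event
#'   (only on arms without a whole-arm event).
#' @param partial_frac range of the arm fraction covered by partial events.
#' @param marker_spacing marker spacing in bp.
#' @param noise_sd marker noise SD.
#' @param amplitude |log2CNR| of planted events.
#' @param state_floor |value| floor for marker/gene/segment states.
#' @param seed RNG seed.
#' @return list with `samples` (per sample: `segments`, `genes`),
#'   `reference` (aneuploidy matrix from the truth), `layout`.
#' @export
simulate_segmented_cohort <- function(layout, n_samples = 20,
                                      arm_event_rate = 0.15,
                                      partial_event_rate = 0,
                                      partial_frac = c(0.3, 0.7),
                                      marker_spacing = 2e6,
                                      noise_sd = 0.1, amplitude = 0.8,
                                      state_floor = 0.2, seed = NULL) {
  with_seed(seed, {
    arms <- layout$arms
    ref <- matrix(0L, n_samples, nrow(arms),
                  dimnames = list(paste0("s", seq_len(n_samples)), arms$arm))
    samples <- list()
    for (s in seq_len(n_samples)) {
      seg_list <- list(); gene_list <- list()
      for (a in seq_len(nrow(arms))) {
        astart <- arms$start[a]; aend <- arms$end[a]
        pos <- seq(astart, aend - 1, by = marker_spacing)
        truth <- rep(0, length(pos))
        if (stats::runif(1) < arm_event_rate) {
          dir <- sample(c(-1, 1), 1)
          truth[] <- dir * amplitude
          ref[s, a] <- as.integer(dir)
        } else if (stats::runif(1) < partial_event_rate) {
          dir <- sample(c(-1, 1), 1)
          frac <- stats::runif(1, partial_frac[1], partial_frac[2])
          len <- frac * (aend - astart)
          estart <- stats::runif(1, astart, aend - len)
          truth[pos >= estart & pos < estart + len] <- dir * amplitude
        }
        x <- truth + stats::rnorm(length(pos), 0, noise_sd)
        bounds <- recursive_split(x, min_width = 3, alpha = 0.01,
                                  n_perm = 100)
        segs <- do.call(rbind, lapply(seq_len(nrow(bounds)), function(k) {
          i <- bounds$from[k]:bounds$to[k]
          m <- mean(x[i])
          data.frame(chrom = arms$chrom[a],
                     start = pos[bounds$from[k]],
                     end = min(aend, pos[bounds$to[k]] + marker_spacing),
                     num_mark = length(i), seg_mean = m,
                     state = if (abs(m) > state_floor) as.integer(sign(m)) else 0L,
                     stringsAsFactors = FALSE)
        }))
        genes <- data.frame(chrom = arms$chrom[a], start = pos,
                            end = pmin(aend, pos + marker_spacing),
                            state = ifelse(abs(x) > state_floor,
                                           as.integer(sign(x)), 0L),
                            stringsAsFactors = FALSE)
        seg_list[[a]] <- segs; gene_list[[a]] <- genes
      }
      samples[[s]] <- list(segments = do.call(rbind, seg_list),
                           genes = do.call(rbind, gene_list))
    }
    names(samples) <- rownames(ref)
    list(samples = samples, reference = ref, layout = layout)
  })
}

#' Grid evaluation of arm-calling performance
#'
#' Runs [call_arm_aneuploidy()] over a grid of coverage breadths, R_c
#' thresholds and directionality fractions on a simulated cohort and
#' tabulates agreement with the cohort's reference calls.
#'
#' @param cohort output of [simulate_segmented_cohort()] (or a list with the
#'   same shape).
#' @param c_grid,rc_grid,direction_fractions grid values.
#' @return data.frame with one row per grid cell: `c`, `rc_threshold`,
#'   `direction_fraction`, `ppa` (directional recall over reference-altered
#'   cells), `npa`, `macro_ppa` (3-class averaged recall), `fpr`
#'   (1 - NPA), `n_calls`, `n_false_calls`.
#' @export
run_coverage_simulation <- function(cohort,
                                    c_grid = c(0.4, 0.6, 0.8, 1.0),
                                    rc_grid = c(0.2, 0.5, 0.8),
                                    direction_fractions = 1.0) {
  layout <- cohort$layout
  grid <- expand.grid(c = c_grid, rc_threshold = rc_grid,
                      direction_fraction = direction_fractions)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    calls <- cohort$reference * 0L
    for (s in names(cohort$samples)) {
      cc <- call_arm_aneuploidy(cohort$samples[[s]]$segments,
                                cohort$samples[[s]]$genes, layout,
                                c = grid$c[g],
                                rc_threshold = grid$rc_threshold[g],
                                min_direction_fraction =
                                  grid$direction_fraction[g])
      calls[s, cc$arm] <- cc$direction
    }
    conc <- evaluate_concordance(calls, cohort$reference)
    false_calls <- sum(calls != 0 & cohort$reference == 0)
    cbind(grid[g, , drop = FALSE],
          data.frame(ppa = conc$ppa, npa = conc$npa,
                     macro_ppa = conc$macro_ppa, fpr = 1 - conc$npa,
                     n_calls = sum(calls != 0),
                     n_false_calls = false_calls))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
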