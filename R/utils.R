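# internal helpers

# read a TSV with a header and required columns; errors name the offending
# data line (1-based, counting the header as line 1)
read_tsv_checked <- function(path, required) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  d
}

# set the RNG state for a call; seed = NULL leaves it untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L)
      stop("seed must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
  }
  force(expr)
}

# 0-based half-open intervals -> IRanges
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# total overlap (bp) between the union of [start,end) intervals and a window
interval_overlap <- function(start, end, wstart, wend) {
  if (length(start) == 0L) return(0)
  ir <- IRanges::reduce(as_iranges0(start, end))
  w <- as_iranges0(wstart, wend)
  sum(IRanges::width(IRanges::intersect(ir, w)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
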