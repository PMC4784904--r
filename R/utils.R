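# Internal helpers shared across modules.

# Stable ordering that does not depend on the session locale.
order_c <- function(...) order(..., method = "radix")

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Total length of the union of [start, end) intervals (0-based half-open).
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::IRanges(start = start + 1L, end = end)  # to 1-based closed
  sum(IRanges::width(IRanges::reduce(ir)))
}

# Clip intervals to a [lo, hi) region, drop empties.
clip_intervals <- function(start, end, lo, hi) {
  s <- pmax(start, lo)
  e <- pmin(end, hi)
  keep <- s < e
  list(start = s[keep], end = e[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
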