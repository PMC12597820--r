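#' @importFrom stats median quantile rbinom rpois runif setNames p.adjust
#'   pnorm wilcox.test cor
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper around
#' [Biostrings::reverseComplement()]. `N` is preserved.
#'
#' @param x single DNA string (A/C/G/T/N, uppercase).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA string
#'
#' Uniform i.i.d. bases; uses the current RNG state (callers seed).
#'
#' @param n length in bp.
#' @return character scalar of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Substitute a fraction of positions with a different base (never the same
## base, so `rate` is the realized per-base difference rate in expectation).
mutate_seq <- function(x, rate) {
  if (rate <= 0 || nchar(x) == 0L) return(x)
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(v)) < rate & v %in% DNA_BASES)
  if (length(idx)) {
    v[idx] <- vapply(v[idx], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  }
  paste(v, collapse = "")
}

## Tandem array of `monomer` truncated/extended to exactly `len` bp.
tandem_array <- function(monomer, len) {
  reps <- ceiling(len / nchar(monomer))
  substr(strrep(monomer, reps), 1L, len)
}

count_n <- function(x) {
  if (nchar(x) == 0L) return(0L)
  lengths(regmatches(x, gregexpr("N", x, fixed = TRUE)))[[1]]
}

## ---- interval helpers -------------------------------------------------------
## All intervals are 0-based half-open [start, end). Data frames carry columns
## `start` and `end` (and usually `chrom`). IRanges (1-based closed) is used
## for the set arithmetic; the +1 shift happens only inside these helpers.

as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

## Merge possibly-overlapping intervals; gap <= merge_gap bridges blocks.
## Returns data.frame(start, end) sorted, 0-based half-open.
merge_intervals0 <- function(start, end, merge_gap = 0L) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  r <- IRanges::reduce(as_iranges0(start, end), min.gapwidth = merge_gap + 1L)
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

## Total bp of [s,e) covered by the merged interval set (same chrom assumed).
overlap_bp0 <- function(s, e, set_start, set_end) {
  if (length(set_start) == 0L || e <= s) return(0L)
  r <- IRanges::reduce(as_iranges0(set_start, set_end))
  q <- as_iranges0(s, e)
  sum(IRanges::width(IRanges::intersect(r, q)))
}

## Fast repeated-window overlap against one fixed merged interval set:
## returns a function f(starts, ends) -> total covered bp per window.
## Prefix-sum formulation over sorted disjoint intervals.
make_coverage_fn <- function(set_start, set_end) {
  if (length(set_start) == 0L) {
    return(function(s, e) rep(0, length(s)))
  }
  m <- merge_intervals0(set_start, set_end)
  S <- m$start
  E <- m$end
  cw <- cumsum(E - S)
  cov_at <- function(x) {
    j <- findInterval(x, S)
    out <- numeric(length(x))
    nz <- j > 0L
    out[nz] <- cw[j[nz]] - pmax(0, E[j[nz]] - x[nz])
    out
  }
  function(s, e) cov_at(e) - cov_at(s)
}

## coverage fraction of each window [s,e) by the set
coverage_fraction0 <- function(s, e, set_start, set_end) {
  f <- make_coverage_fn(set_start, set_end)
  w <- e - s
  ifelse(w > 0, f(s, e) / w, 0)
}
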