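## Terminal canonical telomere detection and centromeric satellite region
## delineation for telocentric assemblies.

## default satellite annotation names recognized as the pericentromeric
## (major, 234-bp monomer) and centromere-core (minor, 120-bp monomer) arrays
MAJOR_SAT_NAMES <- c("GSAT_MM", "MajSat")
MINOR_SAT_NAMES <- c("SYNREP_MM", "MinSat")

## all (possibly overlapping) 0-based start positions of `motif` in `seq`
motif_starts0 <- function(seq, motif) {
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  IRanges::start(m) - 1L
}

## right-end detection core; left ends are handled by reverse-complement
## symmetry in detect_telomere()
detect_right <- function(seq, motif, min_length, min_purity,
                         max_interruption, end_slack) {
  L <- nchar(seq)
  if (L < min_length) return(NULL)
  k <- nchar(motif)
  starts <- motif_starts0(seq, motif)
  if (!length(starts)) return(NULL)
  ends <- starts + k
  ## outermost occurrence: maximal end, must touch the terminus within slack
  if (max(ends) < L - end_slack) return(NULL)
  ord <- order(starts, decreasing = TRUE)
  starts <- starts[ord]
  ends <- ends[ord]
  keep <- rep(FALSE, length(starts))
  i_out <- which.max(ends)
  keep[i_out] <- TRUE
  inner <- starts[i_out]
  for (i in seq_along(starts)) {
    if (starts[i] >= inner) next
    if (inner - ends[i] <= max_interruption) {
      keep[i] <- TRUE
      inner <- starts[i]
    } else if (ends[i] < inner) {
      break   # occurrences are start-sorted descending; chain is broken
    }
  }
  cs <- starts[keep]
  ce <- ends[keep]
  repeat {
    lo <- min(cs)
    hi <- max(ce)
    cov <- sum(merge_intervals0(cs, ce)$end - merge_intervals0(cs, ce)$start)
    purity <- cov / (hi - lo)
    if (purity >= min_purity || length(cs) <= 1L) break
    drop <- which.min(cs)   # trim the innermost occurrence
    cs <- cs[-drop]
    ce <- ce[-drop]
  }
  len <- max(ce) - min(cs)
  if (len < min_length || purity < min_purity) return(NULL)
  list(start = min(cs), end = max(ce), length = len, purity = purity)
}

#' Detect a terminal canonical telomere array
#'
#' Scans one end of a sequence for the canonical telomere motif (`TTAGGG` at
#' the right end, its reverse complement `CCCTAA` at the left end, so the
#' G-rich strand points outward) and returns the maximal terminal segment in
#' which consecutive motif occurrences are separated by at most
#' `max_interruption` bp and overall motif coverage is at least `min_purity`.
#'
#' @param seq sequence (character scalar).
#' @param which_end `"left"` or `"right"`.
#' @param min_length minimal reported array length, bp.
#' @param min_purity minimal fraction of the reported segment covered by
#'   motif occurrences.
#' @param max_interruption maximal motif-free stretch inside the array, bp.
#' @param end_slack maximal distance between the array and the sequence
#'   terminus, bp.
#' @param either_orientation also try the opposite-strand motif at this end
#'   and keep the longer call.
#' @param chrom label stored in the returned row.
#' @return one-row data.frame (`chrom, which_end, start, end, length, purity,
#'   motif`) or `NULL` when no array qualifies.
#' @export
detect_telomere <- function(seq, which_end = c("right", "left"),
                            min_length = 300, min_purity = 0.9,
                            max_interruption = 60, end_slack = 1000,
                            either_orientation = FALSE, chrom = "seq") {
  which_end <- match.arg(which_end)
  stopifnot(min_length >= 6, min_purity > 0, min_purity <= 1)
  run <- function(motif, label) {
    if (which_end == "right") {
      r <- detect_right(seq, motif, min_length, min_purity,
                        max_interruption, end_slack)
      if (is.null(r)) return(NULL)
      data.frame(chrom = chrom, which_end = "right",
                 start = r$start, end = r$end, length = r$length,
                 purity = r$purity, motif = label, stringsAsFactors = FALSE)
    } else {
      L <- nchar(seq)
      r <- detect_right(revcomp(seq), revcomp(motif), min_length, min_purity,
                        max_interruption, end_slack)
      if (is.null(r)) return(NULL)
      data.frame(chrom = chrom, which_end = "left",
                 start = L - r$end, end = L - r$start, length = r$length,
                 purity = r$purity, motif = label, stringsAsFactors = FALSE)
    }
  }
  primary <- if (which_end == "right") "TTAGGG" else "CCCTAA"
  out <- run(if (which_end == "right") "TTAGGG" else "CCCTAA", primary)
  if (either_orientation) {
    alt_label <- if (which_end == "right") "CCCTAA" else "TTAGGG"
    alt <- run(alt_label, alt_label)
    if (!is.null(alt) && (is.null(out) || alt$length > out$length)) out <- alt
  }
  out
}

#' Detect telomeres at both ends of every sequence
#'
#' @param seqs named character vector of sequences.
#' @param ... passed to [detect_telomere()].
#' @return data.frame of calls (possibly empty).
#' @export
detect_telomeres <- function(seqs, ...) {
  rows <- list()
  for (nm in names(seqs)) {
    for (we in c("left", "right")) {
      r <- detect_telomere(seqs[[nm]], which_end = we, chrom = nm, ...)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), which_end = character(),
               start = integer(), end = integer(), length = integer(),
               purity = numeric(), motif = character(),
               stringsAsFactors = FALSE)
}

#' Count called telomeres and telomere pairs
#'
#' @param calls data.frame from [detect_telomeres()].
#' @param chromosomes chromosome names considered.
#' @return list with `per_end` (chromosome x end table), `n_telomeres` and
#'   `n_pairs` (chromosomes called at both ends).
#' @export
count_telomere_pairs <- function(calls, chromosomes) {
  per_end <- data.frame(
    chrom = chromosomes,
    left = vapply(chromosomes, function(ch)
      any(calls$chrom == ch & calls$which_end == "left"), TRUE),
    right = vapply(chromosomes, function(ch)
      any(calls$chrom == ch & calls$which_end == "right"), TRUE),
    stringsAsFactors = FALSE
  )
  list(per_end = per_end,
       n_telomeres = sum(per_end$left) + sum(per_end$right),
       n_pairs = sum(per_end$left & per_end$right))
}

#' Delineate the centromeric satellite region of one chromosome
#'
#' Merges major/minor satellite annotations whose gaps do not exceed
#' `merge_gap` into blocks and returns the block nearest the telocentric end
#' (the end bearing the supplied telomere call), with total major- and
#' minor-satellite bp inside.
#'
#' @param annotations repeat annotations for one chromosome.
#' @param telomere one-row telomere call for that chromosome.
#' @param merge_gap maximal gap bridged when merging satellite blocks, bp.
#' @param major_names,minor_names annotation `repeat_name` values recognized
#'   as major/minor satellite.
#' @return one-row data.frame (`chrom, start, end, size, major_bp,
#'   minor_bp`) or `NULL` when the chromosome carries no satellite
#'   annotation.
#' @export
delineate_centromere <- function(annotations, telomere, merge_gap = 1e5,
                                 major_names = MAJOR_SAT_NAMES,
                                 minor_names = MINOR_SAT_NAMES) {
  stopifnot(nrow(telomere) == 1L, merge_gap >= 0)
  if (!any(annotations$chrom == telomere$chrom)) {
    stop("no annotations for chromosome ", telomere$chrom)
  }
  ann <- annotations[annotations$chrom == telomere$chrom, ]
  sat <- ann[ann$repeat_name %in% c(major_names, minor_names), ]
  if (!nrow(sat)) return(NULL)
  blocks <- merge_intervals0(sat$start, sat$end, merge_gap = merge_gap)
  ## block nearest the telocentric end
  anchor <- if (telomere$which_end == "left") telomere$end else telomere$start
  d <- pmax(0, pmax(blocks$start - anchor, anchor - blocks$end))
  b <- blocks[which.min(d), ]
  major <- sat[sat$repeat_name %in% major_names, ]
  minor <- sat[sat$repeat_name %in% minor_names, ]
  data.frame(
    chrom = telomere$chrom, start = b$start, end = b$end,
    size = b$end - b$start,
    major_bp = overlap_bp0(b$start, b$end, major$start, major$end),
    minor_bp = overlap_bp0(b$start, b$end, minor$start, minor$end),
    stringsAsFactors = FALSE
  )
}

#' Summary statistics of centromeric regions
#'
#' @param regions data.frame of [delineate_centromere()] rows.
#' @return list with `median_size`, `iqr_size`, `min_size`, `max_size`,
#'   `total_major_bp`, `total_minor_bp`, `n`.
#' @export
summarize_censat <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L) {
    stop("no centromeric regions to summarize")
  }
  q <- quantile(regions$size, c(0.25, 0.75), names = FALSE)
  list(median_size = median(regions$size),
       iqr_size = q[2] - q[1],
       min_size = min(regions$size), max_size = max(regions$size),
       total_major_bp = sum(regions$major_bp),
       total_minor_bp = sum(regions$minor_bp),
       n = nrow(regions))
}

#' Flag excess-coverage intervals inside centromeric regions
#'
#' Reports the maximal intervals inside the supplied regions where per-base
#' depth exceeds `factor` times the global mean (the collapsed-duplication
#' screen: with a 35x global mean and factor 2 the threshold is 70x).
#'
#' @param depth named list of per-base integer depth vectors (one per
#'   chromosome; position i holds the depth of base i-1 in 0-based
#'   coordinates).
#' @param regions data.frame of regions (`chrom, start, end`).
#' @param factor multiple of the global mean used as threshold.
#' @param global_mean genome-wide mean sequencing depth.
#' @param chrom_lengths optional named lengths used to validate the depth
#'   vectors.
#' @return data.frame `chrom, start, end, mean_depth_inside, threshold`.
#' @export
flag_coverage_anomalies <- function(depth, regions, factor = 2,
                                    global_mean, chrom_lengths = NULL) {
  stopifnot(factor > 0)
  if (!is.null(chrom_lengths)) {
    for (ch in names(depth)) {
      if (!is.null(chrom_lengths[[ch]]) &&
          length(depth[[ch]]) != chrom_lengths[[ch]]) {
        stop("depth track length does not match length of ", ch)
      }
    }
  }
  thr <- factor * global_mean
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    d <- depth[[r$chrom]]
    if (is.null(d)) stop("no depth track for ", r$chrom)
    idx <- (r$start + 1L):r$end
    hot <- d[idx] > thr
    rl <- rle(hot)
    ends_rel <- cumsum(rl$lengths)
    starts_rel <- ends_rel - rl$lengths
    for (j in which(rl$values)) {
      s <- r$start + starts_rel[j]
      e <- r$start + ends_rel[j]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = r$chrom, start = s, end = e,
        mean_depth_inside = mean(d[(s + 1L):e]),
        threshold = thr, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               mean_depth_inside = numeric(), threshold = numeric(),
               stringsAsFactors = FALSE)
}
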