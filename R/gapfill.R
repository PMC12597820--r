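## Reference-gap fill classification: select real (non-model) gaps from an
## AGP, extract gap flanks, anchor them on the complete assembly, infer the
## fill between the anchors and classify it; plus the novel-gene filter
## applied to de novo vs lifted-over annotation pairs.

MODEL_GAP_TYPES <- c("centromere", "telomere", "short_arm")

#' Select real (non-model) gaps from an AGP
#'
#' Drops gap components whose `gap_type` belongs to the excluded model-gap
#' set (centromere, telomere, short-arm placeholders by default).
#'
#' @param agp data.frame from [read_agp()].
#' @param excluded_gap_types model gap types to exclude.
#' @param autosomes_only restrict to objects matching `autosome_pattern`.
#' @param autosome_pattern regular expression for autosome names.
#' @return list with `gaps` (AGP gap rows) and `total_gap_bp` (sum of
#'   estimated gap lengths).
#' @export
select_real_gaps <- function(agp, excluded_gap_types = MODEL_GAP_TYPES,
                             autosomes_only = FALSE,
                             autosome_pattern = "^chr[0-9]+$") {
  g <- agp[agp$kind == "gap" & !(agp$gap_type %in% excluded_gap_types), ,
           drop = FALSE]
  if (autosomes_only) {
    g <- g[grepl(autosome_pattern, g$object), , drop = FALSE]
  }
  rownames(g) <- NULL
  list(gaps = g, total_gap_bp = sum(g$gap_length))
}

#' Extract the flanking sequences of a reference gap
#'
#' Left flank `[gap_start - flank_length, gap_start)`, right flank
#' `[gap_end, gap_end + flank_length)`, truncated at the chromosome bounds
#' (truncation recorded); flanks with more than half `N` are flagged as
#' low-information.
#'
#' @param genome named character vector of reference sequences.
#' @param gap one AGP gap row (`object, start, end`).
#' @param flank_length requested flank length, bp.
#' @return list with `left`, `right` (each `seq, start, end, truncated,
#'   mostly_n`).
#' @export
extract_flanks <- function(genome, gap, flank_length) {
  stopifnot(flank_length > 0)
  chrom <- gap$object
  g <- genome[[chrom]]
  if (is.null(g)) stop("gap chromosome absent from genome: ", chrom)
  L <- nchar(g)
  ls <- max(0L, gap$start - flank_length)
  le <- gap$start
  rs <- gap$end
  re <- min(L, gap$end + flank_length)
  if (le <= ls || re <= rs) {
    stop("zero-length flank after truncation for gap at ", chrom, ":",
         gap$start, "-", gap$end)
  }
  mk <- function(s, e, truncated) {
    seq <- substr(g, s + 1L, e)
    list(seq = seq, start = s, end = e, truncated = truncated,
         mostly_n = count_n(seq) > 0.5 * nchar(seq))
  }
  list(left = mk(ls, le, ls > gap$start - flank_length),
       right = mk(rs, re, re < gap$end + flank_length))
}

#' Locate a flank on an assembly by exact substring search
#'
#' Produces PAF-style alignment rows for every exact occurrence of the flank
#' (or its reverse complement) in the target sequences. Valid only for
#' error-free inputs (synthetic assemblies); real data should supply
#' aligner-produced PAF instead.
#'
#' @param flank flank sequence (character scalar).
#' @param targets named character vector of target sequences.
#' @param query_id label stored in the `query` column.
#' @return PAF-style data.frame (possibly zero rows).
#' @export
align_flank_exact <- function(flank, targets, query_id = "flank") {
  n <- nchar(flank)
  rows <- list()
  if (count_n(flank) == n) return(empty_paf())
  for (tn in names(targets)) {
    tg <- targets[[tn]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") flank else revcomp(flank)
      hits <- gregexpr(pat, tg, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (h in as.integer(hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = query_id, query_len = n, qstart = 0L, qend = n,
          strand = strand, target = tn, target_len = nchar(tg),
          tstart = h - 1L, tend = h - 1L + n,
          matches = n, block_len = n, mapq = 60L, secondary = FALSE,
          identity = 1, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_paf()
}

flank_anchor <- function(alns, unique_fraction) {
  if (is.null(alns) || nrow(alns) == 0L) return(NULL)
  prim <- alns[!alns$secondary, , drop = FALSE]
  if (nrow(prim) != 1L) return(NULL)   # ambiguous or absent
  covered <- (prim$qend - prim$qstart) / prim$query_len
  if (covered < unique_fraction) return(NULL)
  prim
}

#' Infer the fill status of one reference gap
#'
#' A flank is anchored when it has exactly one primary alignment covering at
#' least `unique_fraction` of its length. With both flanks anchored on the
#' same chromosome and strand and ordered consistently with the reference,
#' the inserted sequence is the target interval between the anchors
#' (orientation-normalized). Classification: `completely_filled` (non-N
#' sequence added, no N remaining), `partially_filled` (non-N sequence added,
#' N remaining) or `not_filled` (fewer than two anchors, or no non-N base
#' added). Anchor overlaps up to `overlap_tolerance` bp count as completely
#' filled with zero inserted length.
#'
#' @param gap one AGP gap row.
#' @param left_alns,right_alns alignments of the left/right flank to the
#'   complete assembly.
#' @param t2t named character vector of complete-assembly sequences.
#' @param unique_fraction minimal flank coverage of the single primary
#'   alignment.
#' @param overlap_tolerance maximal tolerated anchor overlap, bp.
#' @param flank_length_used recorded in the result.
#' @return one-row data.frame (`chrom, gap_start, gap_end, gap_length_est,
#'   status, reason, target, inserted_start, inserted_end, inserted_length,
#'   remaining_N, size_delta, flank_length_used`) plus attribute
#'   `inserted_seq` (reference-orientation inserted sequence).
#' @export
infer_fill <- function(gap, left_alns, right_alns, t2t,
                       unique_fraction = 0.8, overlap_tolerance = 1000,
                       flank_length_used = NA_integer_) {
  res <- function(status, reason = NA_character_, target = NA_character_,
                  is_ = NA_integer_, ie = NA_integer_, ilen = 0L,
                  remn = NA_integer_, iseq = NA_character_) {
    out <- data.frame(
      chrom = gap$object, gap_start = gap$start, gap_end = gap$end,
      gap_length_est = gap$gap_length, status = status, reason = reason,
      target = target, inserted_start = is_, inserted_end = ie,
      inserted_length = ilen,
      remaining_N = remn,
      size_delta = ilen - gap$gap_length,
      flank_length_used = flank_length_used, stringsAsFactors = FALSE)
    attr(out, "inserted_seq") <- iseq
    out
  }
  la <- flank_anchor(left_alns, unique_fraction)
  ra <- flank_anchor(right_alns, unique_fraction)
  if (is.null(la) || is.null(ra)) {
    return(res("not_filled", reason = "unanchored_flank"))
  }
  if (la$target != ra$target) {
    return(res("not_filled", reason = "anchors_on_different_chromosomes"))
  }
  if (la$strand != ra$strand) {
    return(res("not_filled", reason = "anchor_strand_mismatch"))
  }
  ## orientation normalization: on the minus strand the reference-left flank
  ## lies to the right on the target
  if (la$strand == "+") {
    is_ <- la$tend
    ie <- ra$tstart
  } else {
    is_ <- ra$tend
    ie <- la$tstart
  }
  width <- ie - is_
  if (width < 0) {
    if (-width <= overlap_tolerance) {
      return(res("completely_filled", target = la$target,
                 is_ = is_, ie = is_, ilen = 0L, remn = 0L, iseq = ""))
    }
    return(res("not_filled", reason = "flank_overlap", target = la$target))
  }
  seq <- substr(t2t[[la$target]], is_ + 1L, ie)
  if (la$strand == "-") seq <- revcomp(seq)
  remn <- count_n(seq)
  non_n <- width - remn
  status <- if (non_n == 0L) "not_filled"
            else if (remn == 0L) "completely_filled" else "partially_filled"
  reason <- if (status == "not_filled") "no_non_N_bases_added" else NA_character_
  res(status, reason = reason, target = la$target, is_ = is_, ie = ie,
      ilen = width, remn = remn, iseq = seq)
}

#' Infer fill status with an escalating flank-length schedule
#'
#' Runs [extract_flanks()] / [infer_fill()] at each schedule length until
#' both flanks anchor; reports the first anchored result, or the last
#' attempt when none anchors.
#'
#' @param reference,t2t named character vectors of sequences.
#' @param gap one AGP gap row.
#' @param schedule increasing flank lengths, bp (50/100/200 kb default).
#' @param ... passed to [infer_fill()].
#' @return [infer_fill()] result with `flank_length_used` set.
#' @export
escalate_flanks <- function(reference, t2t, gap,
                            schedule = c(50e3, 100e3, 200e3), ...) {
  stopifnot(length(schedule) >= 1L, !is.unsorted(schedule))
  last <- NULL
  for (fl in schedule) {
    fk <- extract_flanks(reference, gap, fl)
    la <- align_flank_exact(fk$left$seq, t2t, query_id = "left")
    ra <- align_flank_exact(fk$right$seq, t2t, query_id = "right")
    last <- infer_fill(gap, la, ra, t2t, flank_length_used = as.integer(fl),
                       ...)
    if (!identical(last$reason, "unanchored_flank")) return(last)
  }
  last
}

#' Filter candidate novel genes
#'
#' Keeps de novo genes with no base-pair overlap with any lifted-over gene,
#' at least `min_exons` exons and strictly more than `min_cds` bp of coding
#' sequence.
#'
#' @param denovo,liftover gene tables from [read_gff3_genes()] (columns
#'   `gene_id, chrom, start, end, n_exons, cds_length`).
#' @param min_exons minimal exon count.
#' @param min_cds CDS length that must be strictly exceeded, bp.
#' @return the retained de novo gene rows.
#' @export
filter_novel_genes <- function(denovo, liftover, min_exons = 3L,
                               min_cds = 200L) {
  keep <- logical(nrow(denovo))
  for (i in seq_len(nrow(denovo))) {
    g <- denovo[i, ]
    if (g$n_exons < min_exons || g$cds_length <= min_cds) next
    lo <- liftover[liftover$chrom == g$chrom, , drop = FALSE]
    ov <- overlap_bp0(g$start, g$end, lo$start, lo$end)
    keep[i] <- ov == 0L
  }
  out <- denovo[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
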