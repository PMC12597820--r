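## Chromosome assignment of unplaced telomere/satellite contigs: cumulative
## alignment similarity as primary evidence, Hi-C mate links as confirmation,
## model-gap joining of assigned contigs.

#' Score a contig's chromosome assignment
#'
#' Alignments below `min_identity` (and secondary alignments) are discarded;
#' the remaining target-interval lengths are summed per chromosome and the
#' argmax compared with the chromosome holding the most Hi-C mate links.
#' Assignment requires a unique alignment argmax; Hi-C support alone never
#' assigns unless `allow_hic_only`.
#'
#' @param alignments PAF-style data.frame for one query contig.
#' @param min_identity minimal `matches/block_len` retained (the 95%
#'   similarity cutoff of satellite-array placement).
#' @param links Hi-C link rows for this contig (`contig, chrom, pair_count`),
#'   may be empty.
#' @param min_aligned_bp,min_links minimal evidence below which assignment is
#'   refused.
#' @param allow_hic_only assign from Hi-C argmax when no alignment survives.
#' @return list (`contig, aligned_bp, hic_pairs, best_by_alignment,
#'   best_by_hic, assigned, status, orientation`).
#' @export
score_contig <- function(alignments, min_identity = 0.95, links = NULL,
                         min_aligned_bp = 0, min_links = 0,
                         allow_hic_only = FALSE) {
  stopifnot(min_identity > 0, min_identity <= 1)
  contig <- if (nrow(alignments)) unique(alignments$query) else
    if (!is.null(links) && nrow(links)) unique(links$contig) else NA_character_
  if (length(contig) != 1L) stop("alignments must share one query contig")
  aln <- alignments[alignments$identity >= min_identity &
                      !alignments$secondary, , drop = FALSE]
  aligned_bp <- if (nrow(aln))
    tapply(aln$tend - aln$tstart, aln$target, sum) else
    setNames(numeric(), character())
  hic_pairs <- if (!is.null(links) && nrow(links))
    setNames(links$pair_count, links$chrom) else setNames(numeric(), character())

  argmax_unique <- function(v, floor_value) {
    v <- v[v > 0 & v >= floor_value]
    if (!length(v)) return(NA_character_)
    m <- max(v)
    w <- names(v)[v == m]
    if (length(w) != 1L) return(NA_character_)   # tie: refuse
    w
  }
  best_aln <- argmax_unique(aligned_bp, min_aligned_bp)
  best_hic <- argmax_unique(hic_pairs, min_links)

  status <- if (!is.na(best_aln) && !is.na(best_hic)) {
    if (best_aln == best_hic) "concordant" else "discordant"
  } else if (!is.na(best_aln)) {
    "alignment_only"
  } else if (!is.na(best_hic)) {
    "hic_only"
  } else "unassigned"
  ## an alignment tie (argmax not unique despite surviving alignments)
  if (is.na(best_aln) && length(aligned_bp) && max(aligned_bp) > 0 &&
      sum(aligned_bp == max(aligned_bp)) > 1L) {
    status <- "unassigned"
  }
  assigned <- if (status %in% c("concordant", "alignment_only")) {
    best_aln
  } else if (status == "hic_only" && allow_hic_only) {
    best_hic
  } else NA_character_

  orientation <- NA_character_
  if (nrow(aln)) {
    by_strand <- tapply(aln$tend - aln$tstart, aln$strand, sum)
    orientation <- names(by_strand)[which.max(by_strand)]
  }
  list(contig = contig,
       aligned_bp = as.list(aligned_bp), hic_pairs = as.list(hic_pairs),
       best_by_alignment = best_aln, best_by_hic = best_hic,
       assigned = assigned, status = status, orientation = orientation)
}

#' Join an assigned contig to a scaffold across a model gap
#'
#' The contig (reverse-complemented when `orientation == "-"`) is
#' concatenated at the stated scaffold end with `gap_length` `N`s between,
#' and the scaffold AGP gains one `contig_join` gap component plus one
#' sequence component.
#'
#' @param scaffold,contig sequences (character scalars; names used as AGP
#'   ids when present).
#' @param end `"left"` or `"right"` scaffold end receiving the contig.
#' @param orientation `"+"` or `"-"` contig orientation.
#' @param gap_length model gap length, bp (100 by default).
#' @param agp optional AGP data.frame for the scaffold, updated and
#'   returned.
#' @return list (`seq`, `agp`).
#' @export
join_with_model_gap <- function(scaffold, contig, end = c("left", "right"),
                                orientation = "+", gap_length = 100L,
                                agp = NULL) {
  end <- match.arg(end)
  stopifnot(gap_length > 0)
  scaffold_id <- if (!is.null(names(scaffold))) names(scaffold) else "scaffold"
  contig_id <- if (!is.null(names(contig))) names(contig) else "contig"
  s <- unname(scaffold)
  c0 <- unname(contig)
  if (orientation == "-") c0 <- revcomp(c0)
  gap <- strrep("N", gap_length)
  joined <- if (end == "right") paste0(s, gap, c0) else paste0(c0, gap, s)
  ns <- nchar(s)
  nc <- nchar(c0)
  if (is.null(agp)) {
    agp <- data.frame(object = scaffold_id, start = 0L, end = ns, part = 1L,
                      kind = "sequence", component_id = scaffold_id,
                      comp_start = 0L, comp_end = ns, orientation = "+",
                      gap_length = NA_integer_, gap_type = NA_character_,
                      linkage = NA_character_, stringsAsFactors = FALSE)
  }
  if (contig_id %in% agp$component_id) stop("contig already placed: ", contig_id)
  if (end == "right") {
    off <- 0L
    gap_start <- ns
  } else {
    off <- nc + gap_length
    gap_start <- nc
  }
  agp$start <- agp$start + off
  agp$end <- agp$end + off
  add <- data.frame(
    object = scaffold_id,
    start = c(gap_start, if (end == "right") gap_start + gap_length else 0L),
    end = c(gap_start + gap_length,
            if (end == "right") gap_start + gap_length + nc else nc),
    part = NA_integer_,
    kind = c("gap", "sequence"),
    component_id = c(NA_character_, contig_id),
    comp_start = c(NA_integer_, 0L), comp_end = c(NA_integer_, nc),
    orientation = c(NA_character_, orientation),
    gap_length = c(gap_length, NA_integer_),
    gap_type = c("contig_join", NA_character_),
    linkage = c("yes", NA_character_), stringsAsFactors = FALSE)
  agp <- rbind(agp, add)
  agp <- agp[order(agp$start), ]
  agp$part <- seq_len(nrow(agp))
  rownames(agp) <- NULL
  out_seq <- setNames(joined, scaffold_id)
  list(seq = out_seq, agp = agp)
}
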