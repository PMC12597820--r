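## File-format readers/writers. Every parser converts file coordinates to the
## internal convention (0-based half-open) at the boundary; writers convert
## back. No function beyond this file touches a 1-based coordinate.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and IUPAC ambiguity codes other than `N` are
#' replaced by `N` (the number of substitutions is reported via `message()`).
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences over `A,C,G,T,N`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("empty sequence record(s): ", paste(ids[empty], collapse = ", "))
  }
  n_before <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_before > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    message(n_before, " ambiguity-code base(s) converted to N")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read an AGP v2 file
#'
#' Coordinates are converted from the file's 1-based inclusive convention to
#' 0-based half-open. Gap (`N`/`U`) components carry `gap_length` and
#' `gap_type` (column 7) verbatim; sequence (`W`) components carry the
#' component id, component coordinates and orientation.
#'
#' @param path AGP file (tab- or whitespace-separated; `#` comments ignored).
#' @return data.frame with columns `object, start, end, part, kind,
#'   component_id, comp_start, comp_end, orientation, gap_length, gap_type,
#'   linkage`.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    stop("empty AGP file: ", path)
  }
  f <- strsplit(lines, "[\t ]+")
  n <- lengths(f)
  if (any(n < 8L)) stop("AGP line with <8 columns at line ", which(n < 8L)[1])
  get <- function(i) vapply(f, function(x) if (length(x) >= i) x[i] else NA_character_, "")
  kind_code <- get(5)
  is_gap <- kind_code %in% c("N", "U")
  nr <- length(f)
  component_id <- orientation <- gap_type <- linkage <-
    rep(NA_character_, nr)
  comp_start <- comp_end <- gap_length <- rep(NA_integer_, nr)
  component_id[!is_gap] <- get(6)[!is_gap]
  comp_start[!is_gap] <- as.integer(get(7)[!is_gap]) - 1L
  comp_end[!is_gap] <- as.integer(get(8)[!is_gap])
  orientation[!is_gap] <- get(9)[!is_gap]
  gap_length[is_gap] <- as.integer(get(6)[is_gap])
  gap_type[is_gap] <- get(7)[is_gap]
  linkage[is_gap] <- get(8)[is_gap]
  out <- data.frame(
    object = get(1),
    start = as.integer(get(2)) - 1L,
    end = as.integer(get(3)),
    part = as.integer(get(4)),
    kind = ifelse(is_gap, "gap", "sequence"),
    component_id = component_id,
    comp_start = comp_start,
    comp_end = comp_end,
    orientation = orientation,
    gap_length = gap_length,
    gap_type = gap_type,
    linkage = linkage,
    stringsAsFactors = FALSE
  )
  if (any(out$end <= out$start)) {
    stop("non-positive component length in AGP at line ",
         which(out$end <= out$start)[1])
  }
  ## components must tile each object without gap or overlap
  for (obj in unique(out$object)) {
    o <- out[out$object == obj, ]
    o <- o[order(o$start), ]
    if (o$start[1] != 0L ||
        (nrow(o) > 1L && any(o$start[-1] != o$end[-nrow(o)]))) {
      stop("AGP components do not tile object ", obj)
    }
  }
  out
}

#' Write an AGP v2 file
#'
#' Inverse of [read_agp()]; internal 0-based half-open coordinates are
#' converted back to 1-based inclusive.
#'
#' @param agp data.frame in [read_agp()] layout.
#' @param path output file.
#' @export
write_agp <- function(agp, path) {
  lines <- character(nrow(agp))
  for (i in seq_len(nrow(agp))) {
    a <- agp[i, ]
    lines[i] <- if (a$kind == "gap") {
      paste(a$object, a$start + 1L, a$end, a$part, "N", a$gap_length,
            a$gap_type, a$linkage, "na", sep = "\t")
    } else {
      paste(a$object, a$start + 1L, a$end, a$part, "W", a$component_id,
            a$comp_start + 1L, a$comp_end, a$orientation, sep = "\t")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

RM_CLASS_MAP <- c(
  "Simple_repeat" = "Simple",
  "Low_complexity" = "LowComplexity"
)
KNOWN_RM_CLASSES <- c("LINE", "SINE", "LTR", "DNA", "Satellite",
                      "Simple", "LowComplexity", "SD", "Other")

normalize_repeat_class <- function(cls) {
  top <- sub("/.*$", "", cls)
  fam <- ifelse(grepl("/", cls), sub("^[^/]*/", "", cls), "")
  top <- ifelse(top %in% names(RM_CLASS_MAP), RM_CLASS_MAP[top], top)
  top <- ifelse(top %in% KNOWN_RM_CLASSES, top, "Other")
  list(class = unname(top), family = unname(fam))
}

#' Read a RepeatMasker `.out` annotation table
#'
#' The standard 3 header lines are skipped; 1-based inclusive query
#' coordinates become 0-based half-open; `class/family` is split on `/`;
#' `Simple_repeat` maps to class `Simple` and `Low_complexity` to
#' `LowComplexity`; the `C` strand code becomes `-`.
#'
#' @param path RepeatMasker `.out` file.
#' @return data.frame `chrom, start, end, strand, repeat_name, repeat_class,
#'   family, divergence_pct`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character()
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), repeat_name = character(),
                      repeat_class = character(), family = character(),
                      divergence_pct = numeric(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(f) < 11L)
  if (length(bad)) {
    stop("malformed RepeatMasker row (need >=11 columns) at body line ", bad[1])
  }
  get <- function(i) vapply(f, `[[`, "", i)
  cf <- normalize_repeat_class(get(11))
  data.frame(
    chrom = get(5),
    start = as.integer(get(6)) - 1L,
    end = as.integer(get(7)),
    strand = ifelse(get(9) == "C", "-", "+"),
    repeat_name = get(10),
    repeat_class = cf$class,
    family = cf$family,
    divergence_pct = as.numeric(get(2)),
    stringsAsFactors = FALSE
  )
}

#' Write annotations as a RepeatMasker-style `.out` table
#'
#' Emits the 3-line header and one row per annotation, converting internal
#' coordinates back to 1-based inclusive. Only the columns [read_repeatmasker_out()]
#' interprets are populated meaningfully.
#'
#' @param ann annotation data.frame (see [read_repeatmasker_out()]).
#' @param path output file.
#' @export
write_repeatmasker_out <- function(ann, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat class/family begin end (left) ID",
    ""
  )
  cls <- ifelse(ann$family == "", ann$repeat_class,
                paste0(ann$repeat_class, "/", ann$family))
  rows <- sprintf("%5d %6.1f  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d",
                  1000L,
                  ifelse(is.na(ann$divergence_pct), 0, ann$divergence_pct),
                  ann$chrom, ann$start + 1L, ann$end,
                  ifelse(ann$strand == "-", "C", "+"),
                  ann$repeat_name, cls,
                  ann$end - ann$start, seq_len(nrow(ann)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a PAF alignment file
#'
#' The 12 mandatory columns are parsed (coordinates are already 0-based
#' half-open in PAF and are kept as-is). Optional tags are ignored except
#' `tp:A`, retained as the logical `secondary` column (`tp:A:S`).
#'
#' @param path PAF file (CRLF tolerated).
#' @return data.frame `query, query_len, qstart, qend, strand, target,
#'   target_len, tstart, tend, matches, block_len, mapq, secondary, identity`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(empty_paf())
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 12L)) {
    stop("PAF line with <12 columns at line ", which(lengths(f) < 12L)[1])
  }
  get <- function(i) vapply(f, `[[`, "", i)
  secondary <- vapply(f, function(x) any(x == "tp:A:S"), logical(1))
  out <- data.frame(
    query = get(1), query_len = as.integer(get(2)),
    qstart = as.integer(get(3)), qend = as.integer(get(4)),
    strand = get(5),
    target = get(6), target_len = as.integer(get(7)),
    tstart = as.integer(get(8)), tend = as.integer(get(9)),
    matches = as.numeric(get(10)), block_len = as.numeric(get(11)),
    mapq = as.integer(get(12)),
    secondary = secondary,
    stringsAsFactors = FALSE
  )
  if (any(out$qend <= out$qstart)) {
    stop("PAF query end <= start at line ", which(out$qend <= out$qstart)[1])
  }
  out$identity <- out$matches / out$block_len
  out
}

empty_paf <- function() {
  data.frame(query = character(), query_len = integer(), qstart = integer(),
             qend = integer(), strand = character(), target = character(),
             target_len = integer(), tstart = integer(), tend = integer(),
             matches = numeric(), block_len = numeric(), mapq = integer(),
             secondary = logical(), identity = numeric(),
             stringsAsFactors = FALSE)
}

#' Write alignments in PAF format
#'
#' @param paf data.frame in [read_paf()] layout.
#' @param path output file.
#' @export
write_paf <- function(paf, path) {
  tp <- ifelse(isTRUE(paf$secondary) | paf$secondary %in% TRUE, "tp:A:S", "tp:A:P")
  lines <- paste(paf$query, paf$query_len, paf$qstart, paf$qend, paf$strand,
                 paf$target, paf$target_len, paf$tstart, paf$tend,
                 paf$matches, paf$block_len, paf$mapq, tp, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/4/6 file
#'
#' BED is already 0-based half-open; coordinates pass through unchanged. A
#' 4th column becomes `name` (used for segmental-duplication pair ids), 5th
#' `score`, 6th `strand`.
#'
#' @param path BED file.
#' @return data.frame `chrom, start, end` plus `name`, `score`, `strand` when
#'   present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nc <- min(lengths(f))
  get <- function(i) vapply(f, `[[`, "", i)
  out <- data.frame(chrom = get(1), start = as.integer(get(2)),
                    end = as.integer(get(3)), stringsAsFactors = FALSE)
  if (nc >= 4L) out$name <- get(4)
  if (nc >= 5L) out$score <- suppressWarnings(as.numeric(get(5)))
  if (nc >= 6L) out$strand <- get(6)
  out
}

#' Write a BED file
#'
#' @param bed data.frame with `chrom, start, end` and optionally `name,
#'   score, strand`.
#' @param path output file.
#' @export
write_bed <- function(bed, path) {
  cols <- list(bed$chrom, bed$start, bed$end)
  for (cn in c("name", "score", "strand")) {
    if (!is.null(bed[[cn]])) cols <- c(cols, list(bed[[cn]])) else break
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a Hi-C mate-link table
#'
#' Three tab-separated columns: contig, chromosome, pair count (the number of
#' Hi-C read pairs with one mate on the contig and one on the chromosome).
#'
#' @param path TSV with a header line `contig chrom pair_count`.
#' @return data.frame `contig, chrom, pair_count`.
#' @export
read_links <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "chrom", "pair_count") %in% names(d)))
  if (any(d$pair_count < 0)) stop("negative Hi-C pair_count")
  if (anyDuplicated(d[c("contig", "chrom")])) {
    stop("duplicate (contig, chrom) pair in link table")
  }
  d
}

#' Write a Hi-C mate-link table
#'
#' @param links data.frame `contig, chrom, pair_count`.
#' @param path output file.
#' @export
write_links <- function(links, path) {
  utils::write.table(links[c("contig", "chrom", "pair_count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Interprets only `gene`, `mRNA`, `exon` and `CDS` features (via
#' [rtracklayer::import.gff3()]) and aggregates them into one row per gene
#' with its exon count and total CDS length. Coordinates are converted to
#' 0-based half-open.
#'
#' @param path GFF3 file.
#' @param source label stored in the `source` column (`"denovo"` or
#'   `"liftover"`).
#' @return data.frame `gene_id, chrom, start, end, strand, n_exons,
#'   cds_length, source, extra_copy_number`.
#' @export
read_gff3_genes <- function(path, source = "denovo") {
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  keep <- type %in% c("gene", "mRNA", "exon", "CDS")
  g <- g[keep]
  type <- type[keep]
  ids <- as.character(g$ID)
  parents <- vapply(g$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  ## map every feature to its gene ancestor (gene -> mRNA -> exon/CDS)
  parent_of <- setNames(parents, ids)
  to_gene <- function(id) {
    seen <- character()
    while (!is.na(id) && id %in% names(parent_of) && !is.na(parent_of[[id]])) {
      if (id %in% seen) break
      seen <- c(seen, id)
      id <- parent_of[[id]]
    }
    id
  }
  genes <- which(type == "gene")
  if (!length(genes)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_exons = integer(), cds_length = integer(),
                      source = character(), extra_copy_number = integer(),
                      stringsAsFactors = FALSE))
  }
  feat_gene <- vapply(seq_along(g), function(i) {
    if (type[i] == "gene") ids[i] else to_gene(parents[i])
  }, "")
  ecn <- if (!is.null(g$extra_copy_number)) {
    suppressWarnings(as.integer(as.character(g$extra_copy_number)))
  } else rep(NA_integer_, length(g))
  out <- data.frame(
    gene_id = ids[genes],
    chrom = as.character(GenomicRanges::seqnames(g[genes])),
    start = GenomicRanges::start(g[genes]) - 1L,
    end = GenomicRanges::end(g[genes]),
    strand = as.character(GenomicRanges::strand(g[genes])),
    stringsAsFactors = FALSE
  )
  out$n_exons <- vapply(out$gene_id, function(gi) {
    sum(type == "exon" & feat_gene == gi)
  }, integer(1))
  out$cds_length <- vapply(out$gene_id, function(gi) {
    sel <- type == "CDS" & feat_gene == gi
    as.integer(sum(GenomicRanges::width(g[sel])))
  }, integer(1))
  out$source <- source
  out$extra_copy_number <- ecn[genes]
  rownames(out) <- NULL
  out
}
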