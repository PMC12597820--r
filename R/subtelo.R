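## Subtelomeric repeat-organization profiling for telocentric chromosome
## ends: tokenize the annotation stream from the telomere inward, classify
## the TLC-array punctuation pattern, quantify TLC repeat content.

DEFAULT_TLC_NAMES <- c("TLC_Mm", "TLC")

## lexicographically minimal rotation, so (TATA)n and (ATAT)n compare equal
min_rotation <- function(unit) {
  n <- nchar(unit)
  if (n <= 1L) return(unit)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(unit, i, n), substr(unit, 1L, i - 1L)), "")
  sort(rots)[1L]
}

simple_unit <- function(repeat_name) {
  u <- sub("^\\((.*)\\)n$", "\\1", repeat_name)
  min_rotation(u)
}

#' Tokenize the subtelomeric annotation stream of one chromosome end
#'
#' Annotations within `window` bp of the telomere's inner boundary are sorted
#' by distance from the telomere, mapped to structural tokens (`TELOMERE`,
#' `L1_LINE`, `TLC_ARRAY`, `LTR`, `SIMPLE`, `MINOR_SAT`, `MAJOR_SAT`,
#' `OTHER`), sub-`min_feature` annotations dropped, and adjacent identical
#' tokens merged (TLC array bp summed).
#'
#' @param annotations repeat annotations for one chromosome.
#' @param telomere one-row telomere call for the profiled end.
#' @param window profiled distance from the telomere inward, bp.
#' @param min_feature minimal annotation width retained, bp.
#' @param tlc_names `repeat_name` values recognized as the TLC repeat.
#' @param major_names,minor_names satellite names (see
#'   [delineate_centromere()]).
#' @return data.frame `token, name, bp` ordered from the telomere inward,
#'   beginning with a `TELOMERE` token.
#' @export
tokenize_subtelomere <- function(annotations, telomere, window = 5e6,
                                 min_feature = 100,
                                 tlc_names = DEFAULT_TLC_NAMES,
                                 major_names = MAJOR_SAT_NAMES,
                                 minor_names = MINOR_SAT_NAMES) {
  if (is.null(telomere) || nrow(telomere) != 1L) {
    stop("subtelomere profile undefined without a telomere call")
  }
  stopifnot(window > 0)
  ann <- annotations[annotations$chrom == telomere$chrom, , drop = FALSE]
  if (telomere$which_end == "left") {
    lo <- telomere$end
    hi <- telomere$end + window
    ann <- ann[ann$end > lo & ann$start < hi, , drop = FALSE]
    ann <- ann[order(ann$start), , drop = FALSE]
  } else {
    hi <- telomere$start
    lo <- telomere$start - window
    ann <- ann[ann$end > lo & ann$start < hi, , drop = FALSE]
    ann <- ann[order(-ann$end), , drop = FALSE]
  }
  ann <- ann[(ann$end - ann$start) >= min_feature, , drop = FALSE]
  tok <- function(a) {
    if (a$repeat_name %in% tlc_names) {
      c("TLC_ARRAY", a$repeat_name)
    } else if (a$repeat_name %in% minor_names) {
      c("MINOR_SAT", a$repeat_name)
    } else if (a$repeat_name %in% major_names) {
      c("MAJOR_SAT", a$repeat_name)
    } else if (a$repeat_class == "LINE" && a$family == "L1") {
      c("L1_LINE", a$repeat_name)
    } else if (a$repeat_class == "LTR") {
      c("LTR", a$repeat_name)
    } else if (a$repeat_class == "Simple") {
      c("SIMPLE", simple_unit(a$repeat_name))
    } else {
      c("OTHER", a$repeat_class)
    }
  }
  rows <- data.frame(token = "TELOMERE", name = telomere$motif,
                     bp = telomere$length, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ann))) {
    t <- tok(ann[i, ])
    bp <- ann$end[i] - ann$start[i]
    last <- nrow(rows)
    if (rows$token[last] == t[1] && rows$name[last] == t[2]) {
      rows$bp[last] <- rows$bp[last] + bp   # merge same-token run
    } else {
      rows <- rbind(rows, data.frame(token = t[1], name = t[2], bp = bp,
                                     stringsAsFactors = FALSE))
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Classify the TLC punctuation pattern of a tokenized subtelomere
#'
#' `LTR_punctuated` when every stretch between consecutive TLC arrays
#' contains at least one LTR token; `single_simple` / `double_simple` when
#' every stretch is exactly one / exactly two simple-repeat tokens;
#' `nonstandard` otherwise (including profiles without separated TLC
#' arrays).
#'
#' @param tokens data.frame from [tokenize_subtelomere()].
#' @return list with `pattern`, `punctuators` (names of the separating
#'   elements), `has_l1_tlc_minorsat_motif` and `tlc_total_bp`.
#' @export
classify_pattern <- function(tokens) {
  idx <- which(tokens$token == "TLC_ARRAY")
  tlc_total <- sum(tokens$bp[idx])
  ## the canonical chromosome-end motif: an L1 LINE, then TLC repeat, then
  ## the minor satellite marking the centromere core
  t <- tokens$token
  has_motif <- FALSE
  for (i in which(t == "L1_LINE")) {
    j <- which(t == "TLC_ARRAY" & seq_along(t) > i)
    if (!length(j)) next
    k <- which(t == "MINOR_SAT" & seq_along(t) > min(j))
    if (length(k)) { has_motif <- TRUE; break }
  }
  pattern <- "nonstandard"
  punct <- character()
  if (length(idx) >= 2L) {
    seps <- lapply(seq_len(length(idx) - 1L), function(i) {
      if (idx[i + 1L] - idx[i] <= 1L) {
        tokens[0L, , drop = FALSE]
      } else {
        tokens[(idx[i] + 1L):(idx[i + 1L] - 1L), , drop = FALSE]
      }
    })
    sep_ok <- function(f) all(vapply(seps, f, TRUE))
    if (sep_ok(function(s) nrow(s) >= 1L && any(s$token == "LTR"))) {
      pattern <- "LTR_punctuated"
    } else if (sep_ok(function(s) nrow(s) == 1L && s$token == "SIMPLE")) {
      pattern <- "single_simple"
    } else if (sep_ok(function(s) nrow(s) == 2L &&
                      all(s$token == "SIMPLE"))) {
      pattern <- "double_simple"
    }
    punct <- unique(unlist(lapply(seps, function(s)
      s$name[s$token %in% c("LTR", "SIMPLE")])))
  }
  list(pattern = pattern, punctuators = punct,
       has_l1_tlc_minorsat_motif = has_motif, tlc_total_bp = tlc_total)
}

#' Per-chromosome TLC repeat content
#'
#' @param profiles named list of token data.frames (one per chromosome end),
#'   names used as chromosome labels.
#' @return list with `table` (chrom, tlc_total_bp) and `min`, `max`,
#'   `median`.
#' @export
tlc_content <- function(profiles) {
  if (!length(profiles)) stop("no subtelomere profiles supplied")
  tot <- vapply(profiles, function(p)
    sum(p$bp[p$token == "TLC_ARRAY"]), 0)
  tab <- data.frame(chrom = names(profiles), tlc_total_bp = unname(tot),
                    stringsAsFactors = FALSE)
  list(table = tab, min = min(tot), max = max(tot), median = median(tot))
}
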