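## Iterative seed-extension ("walking") targeted assembly: select reads
## matching the terminal seed, assemble them by greedy exact suffix-prefix
## overlap, pick the read-richest contig, merge it onto the growing sequence
## at the center of the shared anchor, reseed from the new terminus.

## k-mer index of `seq`: environment mapping k-mer string -> integer
## positions (1-based)
kmer_index <- function(seq, k) {
  n <- nchar(seq)
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (n < k) return(env)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  for (i in seq_along(kmers)) {
    key <- kmers[i]
    env[[key]] <- c(env[[key]], i)
  }
  env
}

## extend an anchor (a_pos in `a`, b_pos in `b`, both 1-based, length k)
## outward allowing at most `rate` mismatches per kb of final match length;
## returns c(a_start, b_start, len) of the maximal budgeted match
extend_anchor <- function(a_raw, b_raw, a_pos, b_pos, k, rate) {
  na <- length(a_raw)
  nb <- length(b_raw)
  budget_ok <- function(mm, len) mm <= rate * len / 1000
  ## rightward
  ra <- a_pos + k
  rb <- b_pos + k
  mm <- 0L
  right <- 0L
  best_right <- 0L
  while (ra + right <= na && rb + right <= nb) {
    if (a_raw[ra + right] != b_raw[rb + right]) {
      if (!budget_ok(mm + 1L, k + right + 1L)) break
      mm <- mm + 1L
    }
    right <- right + 1L
    if (a_raw[ra + right - 1L] == b_raw[rb + right - 1L] || rate > 0) {
      best_right <- right
    }
  }
  mm_right <- mm
  ## leftward
  la <- a_pos - 1L
  lb <- b_pos - 1L
  mm <- 0L
  left <- 0L
  best_left <- 0L
  while (la - left >= 1L && lb - left >= 1L) {
    if (a_raw[la - left] != b_raw[lb - left]) {
      if (!budget_ok(mm_right + mm + 1L, k + best_right + left + 1L)) break
      mm <- mm + 1L
    }
    left <- left + 1L
    if (a_raw[la - left + 1L] == b_raw[lb - left + 1L] || rate > 0) {
      best_left <- left
    }
  }
  c(a_start = a_pos - best_left, b_start = b_pos - best_left,
    len = k + best_left + best_right)
}

## longest budgeted match between `a` and `b` found via k-mer anchoring of
## `b` (index) against k-mers of `a` sampled every `stride` bases (stride=k
## guarantees any exact match >= 2k-1 is found; mismatch-tolerant matches
## are found through their exact sub-stretches)
longest_match <- function(a, b, k = 24L, rate = 0, stride = k, idx = NULL) {
  na <- nchar(a)
  nb <- nchar(b)
  if (na < k || nb < k) return(NULL)
  if (is.null(idx)) idx <- kmer_index(b, k)
  a_raw <- charToRaw(a)
  b_raw <- charToRaw(b)
  best <- NULL
  starts <- unique(c(seq(1L, na - k + 1L, by = stride), na - k + 1L))
  kmers <- substring(a, starts, starts + k - 1L)
  seen <- character()
  for (i in seq_along(starts)) {
    hits <- idx[[kmers[i]]]
    if (is.null(hits)) next
    for (h in hits) {
      key <- paste0(starts[i] - h)   # diagonal; one extension per diagonal
      if (key %in% seen) next
      m <- extend_anchor(a_raw, b_raw, starts[i], h, k, rate)
      seen <- c(seen, key)
      if (is.null(best) || m["len"] > best["len"]) best <- m
    }
  }
  best   # c(a_start, b_start, len), 1-based, or NULL
}

#' Select reads matching a seed sequence
#'
#' A read is selected when it shares a contiguous match of at least
#' `min_match` bp with the seed, allowing at most `max_mismatch_per_kb`
#' mismatches per kb (0 = identical; no indels are tolerated). Matching is
#' k-mer anchoring plus budgeted exact extension.
#'
#' @param seed seed sequence (character scalar).
#' @param reads named character vector of reads.
#' @param min_match minimal shared-match length, bp.
#' @param max_mismatch_per_kb mismatch allowance per kb of match.
#' @param k anchor k-mer size.
#' @return data.frame `read_id, match_len, read_start, seed_start` (0-based
#'   match starts), one row per selected read.
#' @export
select_reads <- function(seed, reads, min_match = 4000,
                         max_mismatch_per_kb = 0, k = 24L) {
  stopifnot(min_match <= nchar(seed))
  idx <- kmer_index(seed, k)
  rows <- list()
  for (rn in names(reads)) {
    rd <- reads[[rn]]
    m <- longest_match(rd, seed, k = k, rate = max_mismatch_per_kb,
                       idx = idx)
    if (is.null(m) || m["len"] < min_match) next
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = rn, match_len = unname(m["len"]),
      read_start = unname(m["a_start"]) - 1L,
      seed_start = unname(m["b_start"]) - 1L, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), match_len = integer(),
               read_start = integer(), seed_start = integer(),
               stringsAsFactors = FALSE)
}

## longest exact suffix(a)/prefix(b) overlap >= min_overlap, or 0
suffix_prefix_overlap <- function(a, b, min_overlap) {
  na <- nchar(a)
  nb <- nchar(b)
  max_l <- min(na, nb)
  if (max_l < min_overlap) return(0L)
  probe <- substr(b, 1L, min_overlap)
  hits <- gregexpr(probe, a, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(0L)
  best <- 0L
  for (h in as.integer(hits)) {
    l <- na - h + 1L
    if (l < min_overlap || l > nb) next
    if (substr(a, h, na) == substr(b, 1L, l)) best <- max(best, l)
  }
  best
}

#' Assemble reads by greedy exact-overlap layout
#'
#' Reads contained in other reads are absorbed first; remaining reads are
#' merged greedily by maximal exact suffix-prefix overlap of at least
#' `min_overlap` bp. With exact overlaps every layout column is unanimous,
#' so the consensus is the concatenation itself. Contigs are returned sorted
#' by the number of constituent reads.
#'
#' @param reads named character vector (non-empty).
#' @param min_overlap minimal exact overlap merged, bp.
#' @return list of contigs, each a list (`id, seq, n_reads, reads`), sorted
#'   by decreasing `n_reads`.
#' @export
assemble_contigs <- function(reads, min_overlap = 2000) {
  stopifnot(length(reads) >= 1L)
  pieces <- lapply(seq_along(reads), function(i)
    list(seq = unname(reads[[i]]), n_reads = 1L, reads = names(reads)[i]))
  ## absorb contained pieces
  absorb <- function(pieces) {
    i <- 1L
    while (i <= length(pieces)) {
      j <- 1L
      absorbed <- FALSE
      while (j <= length(pieces)) {
        if (i != j && nchar(pieces[[j]]$seq) >= nchar(pieces[[i]]$seq) &&
            grepl(pieces[[i]]$seq, pieces[[j]]$seq, fixed = TRUE)) {
          pieces[[j]]$n_reads <- pieces[[j]]$n_reads + pieces[[i]]$n_reads
          pieces[[j]]$reads <- c(pieces[[j]]$reads, pieces[[i]]$reads)
          pieces[[i]] <- NULL
          absorbed <- TRUE
          break
        }
        j <- j + 1L
      }
      if (!absorbed) i <- i + 1L
    }
    pieces
  }
  pieces <- absorb(pieces)
  repeat {
    n <- length(pieces)
    if (n < 2L) break
    best <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      l <- suffix_prefix_overlap(pieces[[i]]$seq, pieces[[j]]$seq,
                                 min_overlap)
      if (l > 0L && (is.null(best) || l > best$l)) {
        best <- list(i = i, j = j, l = l)
      }
    }
    if (is.null(best)) break
    a <- pieces[[best$i]]
    b <- pieces[[best$j]]
    merged <- list(seq = paste0(a$seq, substr(b$seq, best$l + 1L,
                                              nchar(b$seq))),
                   n_reads = a$n_reads + b$n_reads,
                   reads = c(a$reads, b$reads))
    pieces[[max(best$i, best$j)]] <- NULL
    pieces[[min(best$i, best$j)]] <- merged
    pieces <- absorb(pieces)
  }
  ord <- order(-vapply(pieces, `[[`, 0L, "n_reads"),
               -vapply(pieces, function(p) nchar(p$seq), 0L))
  pieces <- pieces[ord]
  for (i in seq_along(pieces)) pieces[[i]]$id <- sprintf("contig_%03d", i)
  pieces
}

#' Choose the representative contig
#'
#' The contig built from the most reads; ties broken by length, then by
#' lexicographically smallest id.
#'
#' @param contigs list from [assemble_contigs()].
#' @return one contig (list).
#' @export
choose_representative <- function(contigs) {
  if (!length(contigs)) stop("no contigs to choose from")
  nr <- vapply(contigs, function(x) as.numeric(x$n_reads), 0)
  ln <- vapply(contigs, function(x) nchar(x$seq), 0L)
  id <- vapply(contigs, `[[`, "", "id")
  contigs[[order(-nr, -ln, id)[1L]]]
}

#' Merge a contig onto the growing sequence at the anchor center
#'
#' The contig must share an exact anchor of at least `min_anchor` bp with
#' the terminal `search_tail` bp of the current sequence; the junction is
#' placed at the midpoint of the anchor and the merged sequence keeps the
#' current sequence up to the junction.
#'
#' @param current growing sequence (character scalar).
#' @param contig representative contig sequence.
#' @param min_anchor minimal exact anchor, bp.
#' @param search_tail length of the terminal region searched for the
#'   anchor, bp.
#' @return list (`seq, extension`) or `NULL` when no sufficient anchor
#'   exists (a walk-terminating condition).
#' @export
merge_at_center <- function(current, contig, min_anchor = 500,
                            search_tail = 20000) {
  nc <- nchar(current)
  tail_start <- max(0L, nc - search_tail)   # 0-based offset of the tail
  tail_seq <- substr(current, tail_start + 1L, nc)
  m <- longest_match(contig, tail_seq)
  if (is.null(m) || m["len"] < min_anchor) return(NULL)
  mid <- as.integer(m["len"] %/% 2L)
  junction_cur <- tail_start + (m["b_start"] - 1L) + mid   # 0-based
  junction_ctg <- (m["a_start"] - 1L) + mid
  merged <- paste0(substr(current, 1L, junction_cur),
                   substr(contig, junction_ctg + 1L, nchar(contig)))
  extension <- nchar(merged) - nc
  if (extension < 0L) return(list(seq = current, extension = 0L))
  list(seq = merged, extension = extension)
}

#' Iterative seed-extension walk
#'
#' Repeats select-assemble-choose-merge, reseeding with the terminal
#' `seed_len` bases after each extension, until no reads are selected, no
#' progress is made, a previously used seed recurs (cycle guard for tandem
#' arrays longer than the reads) or `max_rounds` is reached.
#'
#' @param initial_seed starting seed sequence.
#' @param reads named character vector of reads.
#' @param seed_len reseed length, bp (10 kb default).
#' @param min_match minimal read-seed match, bp (4 kb default).
#' @param min_overlap minimal assembly overlap, bp.
#' @param max_rounds round cap.
#' @param max_mismatch_per_kb read-selection mismatch allowance.
#' @param min_anchor minimal merge anchor, bp.
#' @return list (`seq`, `rounds` data.frame with per-round read counts,
#'   contig sizes and extensions, `status` in `converged, no_reads,
#'   no_progress, cycle, max_rounds`).
#' @export
walk <- function(initial_seed, reads, seed_len = 10000, min_match = 4000,
                 min_overlap = 2000, max_rounds = 50,
                 max_mismatch_per_kb = 0, min_anchor = 500) {
  stopifnot(seed_len > 0, min_match > 0, max_rounds >= 1)
  current <- unname(initial_seed)
  seen_seeds <- character()
  rounds <- list()
  status <- "max_rounds"
  for (round in seq_len(max_rounds)) {
    seed <- substr(current, max(1L, nchar(current) - seed_len + 1L),
                   nchar(current))
    if (seed %in% seen_seeds) {
      status <- "cycle"
      break
    }
    seen_seeds <- c(seen_seeds, seed)
    sel <- select_reads(seed, reads, min_match = min_match,
                        max_mismatch_per_kb = max_mismatch_per_kb)
    if (nrow(sel) == 0L) {
      status <- "no_reads"
      break
    }
    contigs <- assemble_contigs(reads[sel$read_id], min_overlap = min_overlap)
    rep_ctg <- choose_representative(contigs)
    merged <- merge_at_center(current, rep_ctg$seq, min_anchor = min_anchor,
                              search_tail = max(2L * seed_len,
                                                nchar(rep_ctg$seq)))
    if (is.null(merged)) {
      status <- "no_progress"
      break
    }
    rounds[[round]] <- data.frame(
      round = round, n_reads_selected = nrow(sel),
      n_contigs = length(contigs),
      representative_size = nchar(rep_ctg$seq),
      representative_reads = rep_ctg$n_reads,
      extension = merged$extension, stringsAsFactors = FALSE)
    if (merged$extension == 0L) {
      status <- "converged"
      break
    }
    current <- merged$seq
  }
  list(seq = current,
       rounds = if (length(rounds)) do.call(rbind, rounds) else
         data.frame(round = integer(), n_reads_selected = integer(),
                    n_contigs = integer(), representative_size = integer(),
                    representative_reads = integer(), extension = integer(),
                    stringsAsFactors = FALSE),
       status = status)
}
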