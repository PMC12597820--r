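## End-to-end recovery pipelines over a simulated genome pair: each function
## runs one analysis stage on the emitted files/objects and scores the
## result against the TruthLedger. These are the drivers behind the
## `analysis/` scripts and the acceptance checks.

#' Telomere and centromeric-region recovery on a simulated pair
#'
#' Detects telomeres at both ends of every complete-assembly chromosome,
#' counts pairs, delineates the centromeric satellite region per chromosome
#' and scores both against the ledger.
#'
#' @param sim [simulate_genome_pair()] result.
#' @param ... passed to [detect_telomere()].
#' @return list with `calls`, `pairs`, `regions`, `summary` and recovery
#'   fractions (`telomere_recovery`, `censat_recovery`).
#' @export
pipeline_telomere_censat <- function(sim, ...) {
  calls <- detect_telomeres(sim$t2t, ...)
  chroms <- names(sim$t2t)
  pairs <- count_telomere_pairs(calls, chroms)
  truth <- sim$truth$chromosomes
  tel_ok <- 0L
  regions <- list()
  cen_ok <- 0L
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    left <- calls[calls$chrom == ch & calls$which_end == "left", ]
    right <- calls[calls$chrom == ch & calls$which_end == "right", ]
    t <- truth[truth$chrom == ch, ]
    if (nrow(left) == 1L && nrow(right) == 1L &&
        abs(left$length - t$tel_left) <= 60 &&
        abs(right$length - t$tel_right) <= 60) {
      tel_ok <- tel_ok + 1L
    }
    if (nrow(left) == 1L) {
      reg <- delineate_centromere(sim$t2t_repeats, left)
      if (!is.null(reg)) {
        regions[[length(regions) + 1L]] <- reg
        if (reg$start == t$censat_start && reg$end == t$censat_end &&
            reg$major_bp == t$major_bp && reg$minor_bp == t$minor_bp) {
          cen_ok <- cen_ok + 1L
        }
      }
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else NULL
  list(calls = calls, pairs = pairs, regions = regions,
       summary = if (!is.null(regions)) summarize_censat(regions) else NULL,
       telomere_recovery = tel_ok / length(chroms),
       censat_recovery = cen_ok / length(chroms))
}

#' Subtelomeric-pattern recovery on a simulated pair
#'
#' @param sim [simulate_genome_pair()] result.
#' @param calls telomere calls (computed when `NULL`).
#' @return list with `profiles`, `patterns`, `tlc`, `pattern_accuracy` and
#'   `tlc_accuracy` (fraction of chromosomes whose TLC bp equals the
#'   ledger).
#' @export
pipeline_subtelo <- function(sim, calls = NULL) {
  if (is.null(calls)) calls <- detect_telomeres(sim$t2t)
  truth <- sim$truth$chromosomes
  profiles <- list()
  pat <- character()
  ok <- 0L
  tlc_ok <- 0L
  for (ch in names(sim$t2t)) {
    left <- calls[calls$chrom == ch & calls$which_end == "left", ]
    if (nrow(left) != 1L) next
    tokens <- tokenize_subtelomere(sim$t2t_repeats, left)
    ## stop the profile at the centromeric satellite block
    cls <- classify_pattern(trim_to_censat(tokens))
    profiles[[ch]] <- tokens
    pat[ch] <- cls$pattern
    t <- truth[truth$chrom == ch, ]
    if (cls$pattern == t$subtelo_pattern) ok <- ok + 1L
    if (cls$tlc_total_bp == t$tlc_bp) tlc_ok <- tlc_ok + 1L
  }
  list(profiles = profiles, patterns = pat, tlc = tlc_content(profiles),
       pattern_accuracy = ok / nrow(truth),
       tlc_accuracy = tlc_ok / nrow(truth))
}

## tokens from the telomere up to (and including) the first centromeric
## satellite token; the satellite block itself is not part of the pattern
trim_to_censat <- function(tokens) {
  i <- which(tokens$token %in% c("MINOR_SAT", "MAJOR_SAT"))
  if (length(i)) tokens[seq_len(min(i)), , drop = FALSE] else tokens
}

#' Unplaced-contig placement recovery on a simulated pair
#'
#' Scores every unplaced contig (cumulative high-identity alignment bp plus
#' Hi-C support) against the curation-stage scaffolds and compares the
#' assignment with the ledger's true chromosome.
#'
#' @param sim [simulate_genome_pair()] result.
#' @param min_identity alignment identity cutoff.
#' @return list with `assignments` (one row per contig) and
#'   `placement_accuracy`.
#' @export
pipeline_placement <- function(sim, min_identity = 0.95) {
  truth <- sim$truth$contigs
  if (is.null(truth) || nrow(truth) == 0L) {
    return(list(assignments = NULL, placement_accuracy = NA_real_))
  }
  rows <- list()
  ok <- 0L
  for (i in seq_len(nrow(truth))) {
    ct <- truth$contig[i]
    res <- score_contig(sim$contig_paf[sim$contig_paf$query == ct, ,
                                       drop = FALSE],
                        min_identity = min_identity,
                        links = sim$hic_links[sim$hic_links$contig == ct, ,
                                              drop = FALSE])
    good <- identical(res$assigned, truth$true_chrom[i]) &&
      res$status == "concordant" &&
      identical(res$orientation, truth$orientation[i])
    if (good) ok <- ok + 1L
    rows[[i]] <- data.frame(contig = ct, assigned = res$assigned,
                            status = res$status,
                            orientation = res$orientation,
                            true_chrom = truth$true_chrom[i],
                            correct = good, stringsAsFactors = FALSE)
  }
  list(assignments = do.call(rbind, rows),
       placement_accuracy = ok / nrow(truth))
}

#' Gap-fill classification recovery on a simulated pair
#'
#' Selects the real (non-model) gaps from the reference AGP, anchors their
#' flanks on the complete assembly by exact search and classifies each fill,
#' scoring status, inserted interval and inserted sequence against the
#' ledger.
#'
#' @param sim [simulate_genome_pair()] result.
#' @param flank_schedule flank lengths tried, bp (scaled to the toy
#'   chromosomes).
#' @return list with `results`, `status_accuracy`, `sequence_accuracy` and
#'   `total_inserted_bp`.
#' @export
pipeline_gapfill <- function(sim, flank_schedule = c(2000)) {
  sel <- select_real_gaps(sim$reference$agp)
  gaps <- sel$gaps
  truth <- sim$truth$gaps
  rows <- list()
  status_ok <- 0L
  seq_ok <- 0L
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    r <- escalate_flanks(sim$reference$seq, sim$t2t, g,
                         schedule = flank_schedule)
    t <- truth[truth$chrom == g$object & truth$ref_start == g$start, ]
    stopifnot(nrow(t) == 1L)
    s_ok <- r$status == t$expected_status
    q_ok <- FALSE
    if (!is.na(r$inserted_start) && r$status != "not_filled") {
      q_ok <- r$inserted_start == t$t2t_start && r$inserted_end == t$t2t_end
    } else if (r$status == "not_filled" && t$expected_status == "not_filled") {
      q_ok <- TRUE
    }
    if (s_ok) status_ok <- status_ok + 1L
    if (q_ok) seq_ok <- seq_ok + 1L
    r$true_status <- t$expected_status
    rows[[i]] <- r
  }
  results <- do.call(rbind, rows)
  list(results = results,
       status_accuracy = status_ok / nrow(gaps),
       interval_accuracy = seq_ok / nrow(gaps),
       total_inserted_bp = sum(results$inserted_length[
         results$status != "not_filled"]))
}

#' Inversion-mechanism recovery on a simulated pair
#'
#' Filters the inversion calls (dropping twin-priming artifacts), builds
#' breakpoint windows, classifies the NAHR mechanism of each kept call and
#' scores the calls against the planted mechanisms.
#'
#' @param sim [simulate_genome_pair()] result.
#' @param w_nahr breakpoint half-window, bp.
#' @return list with `kept`, `dropped`, `calls`, `summary`,
#'   `mechanism_accuracy` (kept calls matching the planted mechanism),
#'   `twin_priming_filtered` (fraction of planted twin-priming calls
#'   dropped with that reason).
#' @export
pipeline_inversions <- function(sim, w_nahr = 500) {
  truth <- sim$truth$inversions
  filt <- filter_inversions(sim$inversions, sim$t2t_repeats)
  chrom_len <- setNames(nchar(sim$t2t), names(sim$t2t))
  calls <- list()
  ok <- 0L
  for (i in seq_len(nrow(filt$kept))) {
    v <- filt$kept[i, ]
    w <- make_windows(v, chrom_length = chrom_len[[v$chrom]],
                      w_nahr = w_nahr)
    call <- classify_nahr(v, w$nahr_windows, sim$t2t_repeats, sim$sd)
    t <- truth[truth$inv_id == v$name, ]
    call$true_mechanism <- t$mechanism
    if (call$mechanism == t$mechanism) ok <- ok + 1L
    calls[[i]] <- call
  }
  calls <- if (length(calls)) do.call(rbind, calls) else NULL
  tp <- truth[truth$mechanism == "twin_priming", ]
  tp_filtered <- if (nrow(tp)) {
    mean(tp$inv_id %in% filt$dropped$name[
      filt$dropped$reason == "twin_priming"])
  } else NA_real_
  list(kept = filt$kept, dropped = filt$dropped, calls = calls,
       summary = if (!is.null(calls)) mechanism_summary(calls) else NULL,
       mechanism_accuracy = if (nrow(filt$kept)) ok / nrow(filt$kept)
         else NA_real_,
       twin_priming_filtered = tp_filtered)
}

#' Breakpoint repeat enrichment on a simulated pair
#'
#' Runs the segment-randomization permutation test over the enrichment
#' flanks of all kept inversions, with the assembled (non-N) chromosome
#' intervals as workspace and the planted SD intervals added as class
#' `"SD"`.
#'
#' @param sim [simulate_genome_pair()] result.
#' @param kept kept inversion calls (computed when `NULL`).
#' @param n_perm,seed permutation parameters.
#' @param classes repeat classes tested.
#' @return [permutation_enrichment()] table.
#' @export
pipeline_enrichment <- function(sim, kept = NULL, n_perm = 1000, seed = 1L,
                                classes = c("SD", "LINE", "SINE", "LTR",
                                            "Satellite")) {
  if (is.null(kept)) kept <- filter_inversions(sim$inversions,
                                               sim$t2t_repeats)$kept
  wins <- list()
  chrom_len <- setNames(nchar(sim$t2t), names(sim$t2t))
  for (i in seq_len(nrow(kept))) {
    v <- kept[i, ]
    wins[[i]] <- make_windows(v, chrom_length = chrom_len[[v$chrom]]
                              )$enrichment_flanks
  }
  windows <- do.call(rbind, wins)
  workspace <- data.frame(chrom = names(sim$t2t), start = 0L,
                          end = unname(nchar(sim$t2t)),
                          stringsAsFactors = FALSE)
  ann <- rbind(
    sim$t2t_repeats[c("chrom", "start", "end", "repeat_class")],
    if (nrow(sim$sd)) data.frame(chrom = sim$sd$chrom, start = sim$sd$start,
                                 end = sim$sd$end, repeat_class = "SD",
                                 stringsAsFactors = FALSE))
  permutation_enrichment(windows, ann, workspace, classes = classes,
                         n_perm = n_perm, seed = seed)
}

#' Null calibration of the permutation enrichment test
#'
#' Simulates replicates in which windows and annotations are drawn
#' independently and uniformly over a workspace, runs the permutation test
#' and returns all per-class p-values; under the null the fraction below
#' 0.05 should not exceed 0.05 beyond Monte-Carlo error.
#'
#' @param n_replicates number of independent replicates.
#' @param n_perm permutations per replicate.
#' @param seed integer seed.
#' @param workspace_length workspace size, bp.
#' @param n_windows,window_bp window count and width.
#' @param n_ann,ann_bp annotations per class and their width.
#' @param classes class labels simulated.
#' @return numeric vector of p-values (`n_replicates * length(classes)`).
#' @export
calibrate_enrichment_null <- function(n_replicates = 200, n_perm = 200,
                                      seed = 1L, workspace_length = 2e5,
                                      n_windows = 20, window_bp = 1000,
                                      n_ann = 30, ann_bp = 500,
                                      classes = c("SD", "LINE", "SINE",
                                                  "LTR", "Satellite")) {
  set.seed(seed)
  workspace <- data.frame(chrom = "w", start = 0L, end = workspace_length,
                          stringsAsFactors = FALSE)
  ps <- numeric(0)
  for (b in seq_len(n_replicates)) {
    win_start <- sample.int(workspace_length - window_bp, n_windows,
                            replace = TRUE)
    windows <- data.frame(chrom = "w", start = win_start,
                          end = win_start + window_bp,
                          stringsAsFactors = FALSE)
    ann <- do.call(rbind, lapply(classes, function(cl) {
      s <- sample.int(workspace_length - ann_bp, n_ann, replace = TRUE)
      data.frame(chrom = "w", start = s, end = s + ann_bp,
                 repeat_class = cl, stringsAsFactors = FALSE)
    }))
    res <- permutation_enrichment(windows, ann, workspace,
                                  classes = classes, n_perm = n_perm,
                                  seed = sample.int(2^30, 1L))
    ps <- c(ps, res$p)
  }
  ps
}

#' Walking reconstruction of the ledger's target sequence
#'
#' Simulates error-free long reads over the ledger's walking target, seeds
#' the walk with the target's first `seed_len` bases and reports whether the
#' walk reconstructs the target exactly.
#'
#' @param target target sequence (e.g. `sim$truth$walk_target`).
#' @param read_length,depth read simulation parameters.
#' @param seed integer seed for read simulation.
#' @param seed_len,min_match walk parameters.
#' @return list with `walk` (the [walk()] result), `exact` (logical),
#'   `extensions` (per full round, bp).
#' @export
pipeline_walk <- function(target, read_length = 15000, depth = 10,
                          seed = 1L, seed_len = 10000, min_match = 4000) {
  reads <- simulate_reads(c(target = target), read_length = read_length,
                          depth = depth, error_rate = 0, seed = seed)
  w <- walk(substr(target, 1L, seed_len), reads, seed_len = seed_len,
            min_match = min_match)
  list(walk = w, exact = identical(w$seq, target),
       extensions = w$rounds$extension[w$rounds$extension > 0])
}
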