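## Synthetic telocentric genome-pair generator.
##
## Emits a "reference-with-gaps" assembly and a complete chromosome-end-to-
## chromosome-end assembly of the same underlying genome, together with
## repeat annotations, segmental-duplication and inversion intervals, a
## construction-derived alignment set, Hi-C mate-link counts, split-off
## unplaced satellite contigs and a TruthLedger recording every planted
## feature. All downstream modules are tested against the ledger.

## Fixed monomer units. 234-bp pericentromeric (major) and 120-bp centromeric
## (minor) satellite monomers mirror the mouse repeat unit lengths; the 76-bp
## unit stands in for the telocentric (TLC) subtelomeric repeat monomer.
MAJOR_MONOMER <- "TTAGTCTTCAAAATAACAAAAAGACCTTTAACCATTGGATAACATACGTTTGGATTTTTTTGTAAAGTGAAGTAATAGGTATGCCACACATTAAGGTTTTATGAAGTACTTGGGATTTTCATTTATGATTTTAATTTACTTCATCTTCATATTATAATTTCGGATCAAGATTGGACCTTAGTTTTATATCATTTTCCCTGAATATAGATTAGAAAAACGAGTCTTTCGAATTCA"
MINOR_MONOMER <- "TCTAGCCCTCCTTGCTGAAATTGTAACCGATGTACTATAAGTGTCCTTCCAGATGATTATTTTATTATGTAAAGACGAAATTCAGGAATATCACTTGACTCGAAGCCCTTAAAAATTTTT"
TLC_MONOMER <- "AGTAAGCAGTGTACAAATAGATAGATTAAGTTTCATATGGCAATGAAGCATCTCCGATCGCGCATGTTGTGTTACT"

TELOMERE_MOTIF <- "TTAGGG"

SUBTELO_PATTERNS <- c("LTR_punctuated", "single_simple", "double_simple",
                      "nonstandard")
INVERSION_MECHANISMS <- c("LINE", "LTR", "SINE", "SD", "none", "twin_priming")
GAP_FILL_STATUSES <- c("complete", "partial", "none")

#' Configuration for the synthetic genome-pair generator
#'
#' Defaults describe the toy study conditions: six telocentric 1-Mb
#' chromosomes, terminal canonical telomere arrays at both ends, a minor
#' (120-bp monomer) plus major (234-bp monomer) satellite block adjacent to
#' the left telomere, one of the four subtelomeric structural patterns per
#' chromosome, six reference gaps cycling through the three fill statuses,
#' six inversions cycling through the planted formation mechanisms, and two
#' chromosomes whose telomere/satellite end is split off as an unplaced
#' contig with concentrated Hi-C support.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length complete-assembly chromosome length, bp.
#' @param telomere_length_range min/max terminal telomere array length, bp.
#' @param tlc_array_length_range min/max length of each TLC repeat array, bp.
#' @param minor_length_range min/max minor-satellite array length, bp.
#' @param major_length_range min/max major-satellite array length, bp.
#' @param subtelo_patterns per-chromosome pattern labels (recycled); one of
#'   `LTR_punctuated, single_simple, double_simple, nonstandard`.
#' @param array_noise per-base substitution rate applied to each satellite
#'   array copy (array divergence).
#' @param private_divergence per-base substitution rate turning the shared
#'   satellite monomer into each chromosome's private consensus.
#' @param n_gaps number of reference gaps.
#' @param gap_statuses per-gap fill status (recycled): `complete, partial,
#'   none`.
#' @param gap_length_est_range min/max AGP-estimated gap length, bp.
#' @param fill_length_range min/max true fill length, bp.
#' @param n_inversions number of inversions.
#' @param inversion_mechanisms per-inversion planted mechanism (recycled):
#'   `LINE, LTR, SINE, SD, none, twin_priming`.
#' @param inversion_length_range min/max inversion length, bp.
#' @param flanking_repeat_length length of each planted breakpoint TE copy, bp.
#' @param sd_length length of each planted breakpoint SD copy, bp.
#' @param n_split_contigs number of chromosomes whose telomere/satellite end
#'   is emitted as an unplaced contig.
#' @param background_repeat_density either a single value or a named vector
#'   (names from `LINE, SINE, LTR, Satellite`) of per-class background
#'   annotation densities on the chromosome arms, fraction of bp in [0, 1).
#' @param min_spacer minimum plain-sequence spacer between arm features, bp.
#' @param centromere_gap_length length of the reference model gap standing in
#'   for the missing telomere/satellite end, bp.
#' @param telomere_gap_length length of the reference model gap at the distal
#'   telomere, bp.
#' @param walk_target_length length of the ledger's walking target, bp.
#' @param read_length,read_depth defaults used when simulating reads.
#' @param seed integer RNG seed; all emission is deterministic given the
#'   config.
#' @return a `sim_config` list, validated.
#' @export
simulation_config <- function(n_chromosomes = 6L,
                              chrom_length = 1e6,
                              telomere_length_range = c(2000, 5000),
                              tlc_array_length_range = c(3000, 6000),
                              minor_length_range = c(20e3, 40e3),
                              major_length_range = c(60e3, 120e3),
                              subtelo_patterns = NULL,
                              array_noise = 0.02,
                              private_divergence = 0.05,
                              n_gaps = 6L,
                              gap_statuses = NULL,
                              gap_length_est_range = c(3000, 8000),
                              fill_length_range = c(2000, 12000),
                              n_inversions = 6L,
                              inversion_mechanisms = NULL,
                              inversion_length_range = c(2000, 8000),
                              flanking_repeat_length = 300,
                              sd_length = 500,
                              n_split_contigs = 2L,
                              background_repeat_density = 0,
                              min_spacer = 2500,
                              centromere_gap_length = 10000,
                              telomere_gap_length = 1000,
                              walk_target_length = 1e5,
                              read_length = 15000,
                              read_depth = 10,
                              seed = 1L) {
  if (is.null(subtelo_patterns)) {
    subtelo_patterns <- c("LTR_punctuated", "LTR_punctuated", "single_simple",
                          "single_simple", "double_simple", "nonstandard")
  }
  if (is.null(gap_statuses)) {
    gap_statuses <- rep(GAP_FILL_STATUSES, length.out = max(n_gaps, 1L))
  }
  if (is.null(inversion_mechanisms)) {
    inversion_mechanisms <- INVERSION_MECHANISMS
  }
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    telomere_length_range = telomere_length_range,
    tlc_array_length_range = tlc_array_length_range,
    minor_length_range = minor_length_range,
    major_length_range = major_length_range,
    subtelo_patterns = rep(subtelo_patterns, length.out = n_chromosomes),
    array_noise = array_noise,
    private_divergence = private_divergence,
    n_gaps = as.integer(n_gaps),
    gap_statuses = if (n_gaps > 0) rep(gap_statuses, length.out = n_gaps) else character(),
    gap_length_est_range = gap_length_est_range,
    fill_length_range = fill_length_range,
    n_inversions = as.integer(n_inversions),
    inversion_mechanisms = if (n_inversions > 0)
      rep(inversion_mechanisms, length.out = n_inversions) else character(),
    inversion_length_range = inversion_length_range,
    flanking_repeat_length = as.integer(flanking_repeat_length),
    sd_length = as.integer(sd_length),
    n_split_contigs = as.integer(n_split_contigs),
    background_repeat_density = background_repeat_density,
    min_spacer = as.integer(min_spacer),
    centromere_gap_length = as.integer(centromere_gap_length),
    telomere_gap_length = as.integer(telomere_gap_length),
    walk_target_length = as.integer(walk_target_length),
    read_length = as.integer(read_length),
    read_depth = read_depth,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_chromosomes >= 1L, cfg$chrom_length > 0L,
    all(cfg$telomere_length_range > 0), all(cfg$minor_length_range > 0),
    all(cfg$major_length_range > 0),
    cfg$array_noise >= 0, cfg$array_noise < 1,
    cfg$private_divergence >= 0, cfg$private_divergence < 1,
    all(cfg$background_repeat_density >= 0),
    all(cfg$background_repeat_density < 1),
    cfg$n_gaps >= 0L, cfg$n_inversions >= 0L,
    cfg$n_split_contigs >= 0L, cfg$n_split_contigs <= cfg$n_chromosomes
  )
  if (!all(cfg$subtelo_patterns %in% SUBTELO_PATTERNS)) {
    stop("unknown subtelomere pattern label")
  }
  if (!all(cfg$inversion_mechanisms %in% INVERSION_MECHANISMS)) {
    stop("unknown inversion mechanism label")
  }
  if (!all(cfg$gap_statuses %in% GAP_FILL_STATUSES)) {
    stop("unknown gap fill status label")
  }
  class(cfg) <- "sim_config"
  cfg
}

runif_len <- function(range) {
  as.integer(round(runif(1, range[1], range[2])))
}

## satellite array with a private consensus: the shared monomer is first
## mutated at `private_divergence` (once per chromosome), then tandem-copied
## and mutated per base at `array_noise`
private_array <- function(monomer, len, private_consensus, noise) {
  mutate_seq(tandem_array(private_consensus, len), noise)
}

seg <- function(type, t2t_seq, ref_seq = t2t_seq, annotate = FALSE,
                name = NA_character_, class = NA_character_,
                family = "", strand = "+", gap_type = NA_character_,
                gap_length = NA_integer_) {
  list(type = type, t2t_seq = t2t_seq, ref_seq = ref_seq, annotate = annotate,
       name = name, class = class, family = family, strand = strand,
       gap_type = gap_type, gap_length = gap_length)
}

#' Simulate a reference/complete genome pair with ground truth
#'
#' Builds `n_chromosomes` telocentric chromosomes (left telomere, subtelomeric
#' pattern, minor then major satellite array, arm, right telomere), derives a
#' gapped reference from them (model gaps replace the telomere/satellite ends,
#' N-runs replace the planted fills, inversions appear in the opposite
#' orientation), and returns both genomes plus annotations, alignments, Hi-C
#' links, split-off unplaced contigs and the TruthLedger.
#'
#' @param config a [simulation_config()].
#' @return list with elements `t2t`, `reference` (`$seq`, `$agp`),
#'   `t2t_repeats`, `ref_repeats`, `sd` (BED-like with `name` pair ids),
#'   `inversions` (complete-assembly coordinates), `paf` (reference vs
#'   complete assembly, from construction bookkeeping), `scaffolds`,
#'   `unplaced`, `contig_paf`, `hic_links`, `truth`, `config`.
#' @export
simulate_genome_pair <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## shared element sequences (one copy each; planted copies are identical)
  elements <- list(
    L1MdA3 = random_dna(1500),
    RLTR17B_Mm = random_dna(500),
    B1_Mus1 = random_dna(150),
    IAPLTR1_Mm = random_dna(400),
    L1MdGf_II = random_dna(1200),
    IAPEz_int = random_dna(900),
    B1_Mm = random_dna(150)
  )

  ## assign arm features to chromosomes round-robin
  gap_chrom <- if (cfg$n_gaps > 0)
    rep(seq_len(cfg$n_chromosomes), length.out = cfg$n_gaps) else integer()
  inv_chrom <- if (cfg$n_inversions > 0)
    rep(seq_len(cfg$n_chromosomes), length.out = cfg$n_inversions) else integer()

  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  split_idx <- seq_len(cfg$n_split_contigs)

  all_segs <- vector("list", cfg$n_chromosomes)
  truth_chrom <- list()
  truth_gap <- list()
  truth_inv <- list()
  sd_rows <- list()
  gap_counter <- 0L
  inv_counter <- 0L

  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- chroms[ci]
    segs <- list()
    tel_left <- 6L * (runif_len(cfg$telomere_length_range) %/% 6L)
    tel_right <- 6L * (runif_len(cfg$telomere_length_range) %/% 6L)
    segs[[length(segs) + 1L]] <- seg("tel_left",
      tandem_array(revcomp(TELOMERE_MOTIF), tel_left), ref_seq = NA)

    ## subtelomere
    pattern <- cfg$subtelo_patterns[ci]
    tlc_bp <- 0L
    add_tlc <- function() {
      len <- runif_len(cfg$tlc_array_length_range)
      tlc_bp <<- tlc_bp + len
      seg("tlc", mutate_seq(tandem_array(TLC_MONOMER, len), cfg$array_noise),
          ref_seq = NA, annotate = TRUE, name = "TLC_Mm", class = "Satellite")
    }
    add_el <- function(name, class, family) {
      seg("element", elements[[gsub("-", "_", name)]], ref_seq = NA,
          annotate = TRUE, name = name, class = class, family = family)
    }
    add_simple <- function(unit, len) {
      seg("simple", tandem_array(unit, len), ref_seq = NA, annotate = TRUE,
          name = paste0("(", unit, ")n"), class = "Simple")
    }
    sub_segs <- switch(pattern,
      LTR_punctuated = list(
        add_el("L1MdA3", "LINE", "L1"), add_tlc(),
        add_el("RLTR17B_Mm", "LTR", "ERVK"), add_tlc()),
      single_simple = list(
        add_el("L1MdA3", "LINE", "L1"), add_tlc(),
        add_simple("CATACT", 300), add_tlc()),
      double_simple = list(
        add_el("L1MdA3", "LINE", "L1"), add_tlc(),
        add_simple("ACATAGTAT", 300), add_simple("TATATGAG", 240), add_tlc()),
      nonstandard = list(
        add_el("B1_Mus1", "SINE", "Alu"), add_el("IAPLTR1_Mm", "LTR", "ERVK"),
        add_el("B1_Mus1", "SINE", "Alu"))
    )
    segs <- c(segs, sub_segs)

    ## centromeric satellite block: minor (centromere core) then major
    ## (pericentromere), directly following the subtelomere
    minor_len <- runif_len(cfg$minor_length_range)
    major_len <- runif_len(cfg$major_length_range)
    minor_cons <- mutate_seq(MINOR_MONOMER, cfg$private_divergence)
    major_cons <- mutate_seq(MAJOR_MONOMER, cfg$private_divergence)
    segs[[length(segs) + 1L]] <- seg("minor_sat",
      private_array(MINOR_MONOMER, minor_len, minor_cons, cfg$array_noise),
      ref_seq = NA, annotate = TRUE, name = "SYNREP_MM", class = "Satellite")
    segs[[length(segs) + 1L]] <- seg("major_sat",
      private_array(MAJOR_MONOMER, major_len, major_cons, cfg$array_noise),
      ref_seq = NA, annotate = TRUE, name = "GSAT_MM", class = "Satellite")

    ## arm features for this chromosome
    my_gaps <- which(gap_chrom == ci)
    my_invs <- which(inv_chrom == ci)
    feat_segs <- list()   # list of lists of segments (one feature = >=1 seg)
    feat_meta <- list()
    for (g in my_gaps) {
      gap_counter_local <- g
      status <- cfg$gap_statuses[g]
      gest <- runif_len(cfg$gap_length_est_range)
      flen <- runif_len(cfg$fill_length_range)
      fill_seq <- switch(status,
        complete = random_dna(flen),
        partial = {
          nrun <- max(200L, flen %/% 5L)
          core <- flen - nrun
          paste0(random_dna(core %/% 2L), strrep("N", nrun),
                 random_dna(core - core %/% 2L))
        },
        none = strrep("N", flen)
      )
      feat_segs[[length(feat_segs) + 1L]] <- list(
        seg("gap_fill", fill_seq, ref_seq = strrep("N", gest),
            gap_type = "contig", gap_length = gest))
      feat_meta[[length(feat_meta) + 1L]] <-
        list(kind = "gap", id = g, status = status, gest = gest, flen = flen)
    }
    for (v in my_invs) {
      mech <- cfg$inversion_mechanisms[v]
      ilen <- runif_len(cfg$inversion_length_range)
      sd_len <- cfg$sd_length
      if (mech == "SD") {
        ## SD-flanked inversions sit in the upper part of the length range
        ## and their duplicated segments scale with inversion length,
        ## emulating the association between larger repeats and larger
        ## rearrangements
        ilen <- runif_len(c(mean(cfg$inversion_length_range),
                            cfg$inversion_length_range[2]))
        sd_len <- max(cfg$sd_length %/% 2L,
                      as.integer(round(ilen * runif(1, 0.08, 0.18))))
      }
      core <- random_dna(ilen)
      fs <- list()
      te <- switch(mech,
        LINE = list(name = "L1MdGf_II", class = "LINE", family = "L1"),
        LTR = list(name = "IAPEz-int", class = "LTR", family = "ERVK"),
        SINE = list(name = "B1_Mm", class = "SINE", family = "Alu"),
        NULL)
      if (!is.null(te)) {
        copy <- substr(elements[[gsub("-", "_", te$name)]], 1L,
                       cfg$flanking_repeat_length)
        copy <- tandem_array(copy, cfg$flanking_repeat_length)
        fs[[length(fs) + 1L]] <- seg("inv_flank", copy, annotate = TRUE,
          name = te$name, class = te$class, family = te$family, strand = "+")
      } else if (mech == "SD") {
        sd_seq <- random_dna(sd_len)
        fs[[length(fs) + 1L]] <- seg("sd_copy", sd_seq, strand = "+")
      }
      if (mech == "twin_priming") {
        fs[[length(fs) + 1L]] <- seg("inv_core", revcomp(core), ref_seq = core,
          annotate = TRUE, name = "L1MdTf_I", class = "LINE", family = "L1")
      } else {
        fs[[length(fs) + 1L]] <- seg("inv_core", revcomp(core), ref_seq = core)
      }
      if (!is.null(te)) {
        copy <- substr(elements[[gsub("-", "_", te$name)]], 1L,
                       cfg$flanking_repeat_length)
        copy <- tandem_array(copy, cfg$flanking_repeat_length)
        fs[[length(fs) + 1L]] <- seg("inv_flank", revcomp(copy),
          annotate = TRUE, name = te$name, class = te$class,
          family = te$family, strand = "-")
      } else if (mech == "SD") {
        fs[[length(fs) + 1L]] <- seg("sd_copy",
          revcomp(fs[[1L]]$t2t_seq), strand = "-")
      }
      feat_segs[[length(feat_segs) + 1L]] <- fs
      feat_meta[[length(feat_meta) + 1L]] <-
        list(kind = "inv", id = v, mech = mech, ilen = ilen)
    }

    ## arm packing: spacers around features fill the chromosome to
    ## chrom_length exactly (complete-assembly coordinates)
    fixed_len <- sum(vapply(segs, function(s) nchar(s$t2t_seq), 0)) + tel_right
    feat_len <- sum(vapply(feat_segs, function(fs)
      sum(vapply(fs, function(s) nchar(s$t2t_seq), 0)), 0))
    n_spacer <- length(feat_segs) + 1L
    rem <- cfg$chrom_length - fixed_len - feat_len
    if (rem < n_spacer * cfg$min_spacer) {
      stop("infeasible packing: planted features exceed chrom_length on ",
           chrom)
    }
    base <- rem %/% n_spacer
    spacer_len <- rep(base, n_spacer)
    spacer_len[1L] <- spacer_len[1L] + (rem - base * n_spacer)
    for (k in seq_along(feat_segs)) {
      segs[[length(segs) + 1L]] <- seg("spacer", random_dna(spacer_len[k]))
      for (s in feat_segs[[k]]) segs[[length(segs) + 1L]] <- s
    }
    segs[[length(segs) + 1L]] <- seg("spacer", random_dna(spacer_len[n_spacer]))
    segs[[length(segs) + 1L]] <- seg("tel_right",
      tandem_array(TELOMERE_MOTIF, tel_right), ref_seq = NA)

    ## reference-side replacements for the dropped chromosome ends
    ## (model gaps, as in a conventional reference assembly)
    segs <- c(
      list(seg("model_gap_cen", t2t_seq = "", ref_seq =
                 strrep("N", cfg$centromere_gap_length),
               gap_type = "centromere",
               gap_length = cfg$centromere_gap_length)),
      segs,
      list(seg("model_gap_tel", t2t_seq = "", ref_seq =
                 strrep("N", cfg$telomere_gap_length),
               gap_type = "telomere", gap_length = cfg$telomere_gap_length))
    )

    ## coordinates
    t2t_len_v <- vapply(segs, function(s) nchar(s$t2t_seq), 0L)
    ref_len_v <- vapply(segs, function(s)
      if (is.na(s$ref_seq[1])) 0L else nchar(s$ref_seq), 0L)
    t2t_start <- cumsum(c(0L, head(t2t_len_v, -1L)))
    ref_start <- cumsum(c(0L, head(ref_len_v, -1L)))
    for (k in seq_along(segs)) {
      segs[[k]]$t2t_start <- t2t_start[k]
      segs[[k]]$t2t_end <- t2t_start[k] + t2t_len_v[k]
      segs[[k]]$ref_start <- ref_start[k]
      segs[[k]]$ref_end <- ref_start[k] + ref_len_v[k]
      segs[[k]]$in_ref <- !is.na(segs[[k]]$ref_seq[1])
      segs[[k]]$chrom <- chrom
    }
    all_segs[[ci]] <- segs

    ## truth records
    types <- vapply(segs, `[[`, "", "type")
    minor_seg <- segs[[which(types == "minor_sat")]]
    major_seg <- segs[[which(types == "major_sat")]]
    truth_chrom[[ci]] <- data.frame(
      chrom = chrom, length = cfg$chrom_length,
      tel_left = tel_left, tel_right = tel_right,
      censat_start = minor_seg$t2t_start, censat_end = major_seg$t2t_end,
      minor_bp = minor_len, major_bp = major_len,
      subtelo_pattern = pattern, tlc_bp = tlc_bp,
      stringsAsFactors = FALSE
    )
    fi <- 0L
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      if (s$type == "gap_fill") {
        meta <- feat_meta[[which(vapply(feat_meta, function(m)
          m$kind == "gap", TRUE))[sum(types[seq_len(k)] == "gap_fill")]]]
        nn <- count_n(s$t2t_seq)
        truth_gap[[length(truth_gap) + 1L]] <- data.frame(
          gap_id = paste0("gap_", meta$id), chrom = chrom,
          ref_start = s$ref_start, ref_end = s$ref_end,
          gap_length_est = meta$gest,
          fill_status = meta$status,
          expected_status = switch(meta$status,
            complete = "completely_filled", partial = "partially_filled",
            none = "not_filled"),
          t2t_start = s$t2t_start, t2t_end = s$t2t_end,
          fill_length = meta$flen, remaining_N = nn,
          inserted_nonN = nchar(s$t2t_seq) - nn,
          stringsAsFactors = FALSE)
      }
      if (s$type == "inv_core") {
        meta <- feat_meta[[which(vapply(feat_meta, function(m)
          m$kind == "inv", TRUE))[sum(types[seq_len(k)] == "inv_core")]]]
        truth_inv[[length(truth_inv) + 1L]] <- data.frame(
          inv_id = paste0("inv_", meta$id), chrom = chrom,
          ref_start = s$ref_start, ref_end = s$ref_end,
          t2t_start = s$t2t_start, t2t_end = s$t2t_end,
          length = meta$ilen, mechanism = meta$mech,
          stringsAsFactors = FALSE)
      }
      if (s$type == "sd_copy") {
        sd_rows[[length(sd_rows) + 1L]] <- data.frame(
          chrom = chrom, t2t_start = s$t2t_start, t2t_end = s$t2t_end,
          ref_start = s$ref_start, ref_end = s$ref_end,
          name = paste0("sd_pair_", chrom), strand = s$strand,
          stringsAsFactors = FALSE)
      }
    }
  }

  ## assemble genomes, annotations, AGP, alignment bookkeeping
  t2t <- vapply(all_segs, function(segs)
    paste(vapply(segs, `[[`, "", "t2t_seq"), collapse = ""), "")
  names(t2t) <- chroms
  ref <- vapply(all_segs, function(segs)
    paste(vapply(segs, function(s)
      if (s$in_ref) s$ref_seq else "", ""), collapse = ""), "")
  names(ref) <- chroms

  ann_rows <- function(which_genome) {
    rows <- list()
    for (segs in all_segs) for (s in segs) {
      if (!isTRUE(s$annotate)) next
      if (which_genome == "ref" && !s$in_ref) next
      st <- if (which_genome == "ref") s$ref_start else s$t2t_start
      en <- if (which_genome == "ref") s$ref_end else s$t2t_end
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = s$chrom, start = st, end = en, strand = s$strand,
        repeat_name = s$name, repeat_class = s$class, family = s$family,
        divergence_pct = NA_real_, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), repeat_name = character(),
                 repeat_class = character(), family = character(),
                 divergence_pct = numeric(), stringsAsFactors = FALSE)
  }
  t2t_repeats <- ann_rows("t2t")
  ref_repeats <- ann_rows("ref")

  ## background annotations sprinkled over arm spacers (annotation only)
  bg <- cfg$background_repeat_density
  if (any(bg > 0)) {
    if (is.null(names(bg))) {
      bg <- setNames(rep(bg[1], 3L), c("LINE", "SINE", "LTR"))
    }
    bg_names <- list(LINE = c("L1Md_F", "L1"), SINE = c("B1_Mus2", "Alu"),
                     LTR = c("RLTR10", "ERVK"),
                     Satellite = c("GSAT_MM", ""))
    el_len <- 200L
    new_rows <- list()
    for (segs in all_segs) {
      spacers <- Filter(function(s) s$type == "spacer", segs)
      if (!length(spacers)) next
      sp_len <- vapply(spacers, function(s) s$t2t_end - s$t2t_start, 0)
      total <- sum(sp_len)
      for (cl in names(bg)) {
        if (bg[[cl]] <= 0) next
        n_el <- max(0L, as.integer(round(bg[[cl]] * total / el_len)))
        if (n_el == 0L) next
        pick <- sample(seq_along(spacers), n_el, replace = TRUE,
                       prob = sp_len)
        for (p in pick) {
          s <- spacers[[p]]
          w <- s$t2t_end - s$t2t_start
          if (w <= el_len) next
          off <- sample.int(w - el_len, 1L) - 1L
          nm <- bg_names[[cl]]
          new_rows[[length(new_rows) + 1L]] <- data.frame(
            chrom = s$chrom,
            t2t_start = s$t2t_start + off, t2t_end = s$t2t_start + off + el_len,
            ref_start = s$ref_start + off, ref_end = s$ref_start + off + el_len,
            strand = sample(c("+", "-"), 1L),
            repeat_name = nm[1], repeat_class = cl, family = nm[2],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(new_rows)) {
      nr <- do.call(rbind, new_rows)
      t2t_repeats <- rbind(t2t_repeats, data.frame(
        chrom = nr$chrom, start = nr$t2t_start, end = nr$t2t_end,
        strand = nr$strand, repeat_name = nr$repeat_name,
        repeat_class = nr$repeat_class, family = nr$family,
        divergence_pct = NA_real_, stringsAsFactors = FALSE))
      ref_repeats <- rbind(ref_repeats, data.frame(
        chrom = nr$chrom, start = nr$ref_start, end = nr$ref_end,
        strand = nr$strand, repeat_name = nr$repeat_name,
        repeat_class = nr$repeat_class, family = nr$family,
        divergence_pct = NA_real_, stringsAsFactors = FALSE))
    }
  }
  ord <- function(a) a[order(a$chrom, a$start), , drop = FALSE]
  t2t_repeats <- ord(t2t_repeats)
  ref_repeats <- ord(ref_repeats)
  rownames(t2t_repeats) <- rownames(ref_repeats) <- NULL

  ## reference AGP
  agp_rows <- list()
  for (segs in all_segs) {
    chrom <- segs[[1]]$chrom
    part <- 0L
    comp <- 0L
    run_start <- NULL
    flush_seq <- function(run_start, run_end) {
      part <<- part + 1L
      comp <<- comp + 1L
      agp_rows[[length(agp_rows) + 1L]] <<- data.frame(
        object = chrom, start = run_start, end = run_end, part = part,
        kind = "sequence",
        component_id = sprintf("%s_ctg%02d", chrom, comp),
        comp_start = 0L, comp_end = run_end - run_start, orientation = "+",
        gap_length = NA_integer_, gap_type = NA_character_,
        linkage = NA_character_, stringsAsFactors = FALSE)
    }
    pos <- 0L
    for (s in segs) {
      if (!s$in_ref) next
      w <- s$ref_end - s$ref_start
      if (w == 0L) next
      if (!is.na(s$gap_type)) {
        if (!is.null(run_start)) {
          flush_seq(run_start, s$ref_start)
          run_start <- NULL
        }
        part <- part + 1L
        agp_rows[[length(agp_rows) + 1L]] <- data.frame(
          object = chrom, start = s$ref_start, end = s$ref_end, part = part,
          kind = "gap", component_id = NA_character_,
          comp_start = NA_integer_, comp_end = NA_integer_,
          orientation = NA_character_,
          gap_length = s$gap_length, gap_type = s$gap_type, linkage = "yes",
          stringsAsFactors = FALSE)
      } else if (is.null(run_start)) {
        run_start <- s$ref_start
      }
      pos <- s$ref_end
    }
    if (!is.null(run_start)) flush_seq(run_start, pos)
  }
  agp <- do.call(rbind, agp_rows)
  rownames(agp) <- NULL

  ## ground-truth reference<->complete alignment from construction bookkeeping
  paf_rows <- list()
  for (segs in all_segs) {
    chrom <- segs[[1]]$chrom
    ref_len <- sum(vapply(segs, function(s)
      if (s$in_ref) s$ref_end - s$ref_start else 0L, 0))
    t2t_len <- segs[[length(segs)]]$t2t_end
    cur <- NULL
    flush <- function() {
      if (is.null(cur)) return()
      paf_rows[[length(paf_rows) + 1L]] <<- data.frame(
        query = chrom, query_len = ref_len,
        qstart = cur$qs, qend = cur$qe, strand = cur$strand,
        target = chrom, target_len = t2t_len,
        tstart = cur$ts, tend = cur$te,
        matches = cur$qe - cur$qs, block_len = cur$qe - cur$qs,
        mapq = 60L, secondary = FALSE,
        identity = 1, stringsAsFactors = FALSE)
    }
    for (s in segs) {
      alignable <- s$in_ref && is.na(s$gap_type) && s$type != "gap_fill"
      if (!alignable) {
        flush(); cur <- NULL
        next
      }
      strand <- if (s$type == "inv_core") "-" else "+"
      if (strand == "-") {
        flush()
        cur <- list(qs = s$ref_start, qe = s$ref_end, strand = "-",
                    ts = s$t2t_start, te = s$t2t_end)
        flush(); cur <- NULL
      } else if (!is.null(cur) && cur$strand == "+" &&
                 cur$qe == s$ref_start && cur$te == s$t2t_start) {
        cur$qe <- s$ref_end
        cur$te <- s$t2t_end
      } else {
        flush()
        cur <- list(qs = s$ref_start, qe = s$ref_end, strand = "+",
                    ts = s$t2t_start, te = s$t2t_end)
      }
    }
    flush()
  }
  paf <- do.call(rbind, paf_rows)
  rownames(paf) <- NULL

  ## split-off unplaced telomere/satellite contigs + curation-stage scaffolds
  scaffolds <- t2t
  unplaced <- character()
  contig_meta <- list()
  contig_paf_rows <- list()
  link_rows <- list()
  for (ci in split_idx) {
    chrom <- chroms[ci]
    segs <- all_segs[[ci]]
    types <- vapply(segs, `[[`, "", "type")
    major_seg <- segs[[which(types == "major_sat")]]
    major_len <- major_seg$t2t_end - major_seg$t2t_start
    split_point <- major_seg$t2t_start + as.integer(round(0.6 * major_len))
    contig_id <- paste0("ctg_tlc_", chrom)
    orientation <- if (ci %% 2L == 0L) "-" else "+"
    piece <- substr(t2t[[chrom]], 1L, split_point)
    contig_seq <- if (orientation == "-") revcomp(piece) else piece
    unplaced[contig_id] <- contig_seq
    scaffolds[[chrom]] <- substr(t2t[[chrom]], split_point + 1L,
                                 nchar(t2t[[chrom]]))
    contig_meta[[length(contig_meta) + 1L]] <- data.frame(
      contig = contig_id, true_chrom = chrom, split_point = split_point,
      orientation = orientation, has_telomere = TRUE,
      stringsAsFactors = FALSE)

    ## construction-derived alignments of the contig's major-satellite tail
    ## against every scaffold's array (same private consensus on the true
    ## chromosome; shared monomer only elsewhere)
    ctg_maj_len <- split_point - major_seg$t2t_start
    noise_id <- (1 - cfg$array_noise)^2
    cons_div <- 2 * cfg$private_divergence * (1 - cfg$private_divergence)
    for (cj in seq_len(cfg$n_chromosomes)) {
      segs_j <- all_segs[[cj]]
      types_j <- vapply(segs_j, `[[`, "", "type")
      major_j <- segs_j[[which(types_j == "major_sat")]]
      if (cj %in% split_idx) {
        sp_j <- major_j$t2t_start +
          as.integer(round(0.6 * (major_j$t2t_end - major_j$t2t_start)))
        tgt_major <- c(0L, major_j$t2t_end - sp_j)
        tgt_len <- nchar(t2t[[cj]]) - sp_j
      } else {
        tgt_major <- c(major_j$t2t_start, major_j$t2t_end)
        tgt_len <- nchar(t2t[[cj]])
      }
      same <- cj == ci
      block <- if (same) min(ctg_maj_len, tgt_major[2] - tgt_major[1])
               else as.integer(round(0.8 * min(ctg_maj_len,
                                               tgt_major[2] - tgt_major[1])))
      if (block < 1000L) next
      identity <- if (same) noise_id else noise_id * (1 - cons_div)
      q_int <- if (orientation == "+") {
        c(major_seg$t2t_start, major_seg$t2t_start + block)
      } else {
        c(0L, block)   # reverse-complemented contig: satellite tail leads
      }
      contig_paf_rows[[length(contig_paf_rows) + 1L]] <- data.frame(
        query = contig_id, query_len = nchar(contig_seq),
        qstart = q_int[1], qend = q_int[2],
        strand = orientation,
        target = chroms[cj], target_len = tgt_len,
        tstart = tgt_major[1], tend = tgt_major[1] + block,
        matches = as.integer(round(identity * block)), block_len = block,
        mapq = 60L, secondary = FALSE,
        identity = round(identity, 4), stringsAsFactors = FALSE)
    }
    for (cj in seq_len(cfg$n_chromosomes)) {
      lambda <- if (cj == ci) 50 else 2
      link_rows[[length(link_rows) + 1L]] <- data.frame(
        contig = contig_id, chrom = chroms[cj],
        pair_count = rpois(1L, lambda), stringsAsFactors = FALSE)
    }
  }
  contig_paf <- if (length(contig_paf_rows)) {
    d <- do.call(rbind, contig_paf_rows)
    d$identity <- d$matches / d$block_len
    d
  } else empty_paf()
  hic_links <- if (length(link_rows)) do.call(rbind, link_rows) else
    data.frame(contig = character(), chrom = character(),
               pair_count = integer(), stringsAsFactors = FALSE)
  rownames(contig_paf) <- rownames(hic_links) <- NULL

  truth <- list(
    chromosomes = do.call(rbind, truth_chrom),
    gaps = if (length(truth_gap)) do.call(rbind, truth_gap) else NULL,
    inversions = if (length(truth_inv)) do.call(rbind, truth_inv) else NULL,
    contigs = if (length(contig_meta)) do.call(rbind, contig_meta) else NULL,
    walk_target = random_dna(cfg$walk_target_length)
  )

  sd <- if (length(sd_rows)) {
    d <- do.call(rbind, sd_rows)
    data.frame(chrom = d$chrom, start = d$t2t_start, end = d$t2t_end,
               name = d$name, stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), start = integer(), end = integer(),
                    name = character(), stringsAsFactors = FALSE)

  inversions <- if (!is.null(truth$inversions)) {
    data.frame(chrom = truth$inversions$chrom,
               start = truth$inversions$t2t_start,
               end = truth$inversions$t2t_end,
               name = truth$inversions$inv_id, stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), start = integer(), end = integer(),
                    name = character(), stringsAsFactors = FALSE)

  list(t2t = t2t,
       reference = list(seq = ref, agp = agp),
       t2t_repeats = t2t_repeats, ref_repeats = ref_repeats,
       sd = sd, inversions = inversions, paf = paf,
       scaffolds = scaffolds, unplaced = unplaced,
       contig_paf = contig_paf, hic_links = hic_links,
       truth = truth, config = cfg)
}

#' Write a simulated genome pair to a directory
#'
#' Emits the full plain-text file set (FASTA, AGP, RepeatMasker-style `.out`,
#' BED, PAF, Hi-C link TSV, `truth.json`) so the format readers can be
#' exercised round-trip.
#'
#' @param sim result of [simulate_genome_pair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_pair <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$t2t, p("t2t.fa"))
  write_fasta(sim$reference$seq, p("reference.fa"))
  write_agp(sim$reference$agp, p("reference.agp"))
  write_repeatmasker_out(sim$t2t_repeats, p("t2t_repeats.out"))
  write_repeatmasker_out(sim$ref_repeats, p("ref_repeats.out"))
  write_bed(sim$sd, p("sd.bed"))
  write_bed(sim$inversions, p("inversions.bed"))
  write_paf(sim$paf, p("ref_vs_t2t.paf"))
  if (length(sim$unplaced)) {
    write_fasta(sim$unplaced, p("unplaced.fa"))
    write_fasta(sim$scaffolds, p("scaffolds.fa"))
    write_paf(sim$contig_paf, p("contig_vs_scaffold.paf"))
    write_links(sim$hic_links, p("hic_links.tsv"))
  }
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Simulate long reads from a genome sequence
#'
#' Uniform random start positions at the requested depth; each read id
#' encodes its true origin (`name:start-end`, 0-based half-open). With
#' `error_rate = 0` every read is an exact substring of the genome.
#'
#' @param genome single sequence (character scalar, optionally named) or a
#'   named vector of length 1.
#' @param read_length read length, bp; must be `< nchar(genome)`.
#' @param depth target mean coverage; must be positive.
#' @param error_rate per-base substitution rate.
#' @param seed optional integer seed.
#' @return named character vector of reads.
#' @export
simulate_reads <- function(genome, read_length, depth, error_rate = 0,
                           seed = NULL) {
  stopifnot(length(genome) == 1L)
  if (depth <= 0) stop("depth must be positive")
  gname <- if (!is.null(names(genome))) names(genome) else "seq"
  g <- unname(genome)
  L <- nchar(g)
  if (read_length >= L) {
    stop("read_length must be smaller than the genome length")
  }
  if (!is.null(seed)) set.seed(seed)
  n_reads <- max(2L, as.integer(ceiling(depth * L / read_length)))
  ## the template is a linear fragment: its two terminal reads are always
  ## present in the pool, interior starts are uniform
  starts <- c(0L, L - read_length,
              sample.int(L - read_length + 1L, n_reads - 2L,
                         replace = TRUE) - 1L)
  starts <- sort(starts)
  reads <- substring(g, starts + 1L, starts + read_length)
  if (error_rate > 0) {
    reads <- vapply(reads, mutate_seq, "", rate = error_rate,
                    USE.NAMES = FALSE)
  }
  names(reads) <- sprintf("read_%05d|%s:%d-%d", seq_len(n_reads), gname,
                          starts, starts + read_length)
  reads
}
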