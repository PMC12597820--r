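# Shared fixtures: a small simulated genome pair reused across test files
# (built lazily once per run) and a few construction helpers.

.fixture_env <- new.env()

small_config <- function(...) {
  defaults <- list(
    n_chromosomes = 3L, chrom_length = 200e3,
    telomere_length_range = c(1200, 2400),
    tlc_array_length_range = c(1500, 3000),
    minor_length_range = c(5e3, 8e3),
    major_length_range = c(15e3, 25e3),
    subtelo_patterns = c("LTR_punctuated", "double_simple", "nonstandard"),
    n_gaps = 3L, gap_length_est_range = c(1000, 3000),
    fill_length_range = c(800, 4000),
    n_inversions = 3L,
    inversion_mechanisms = c("LINE", "SD", "twin_priming"),
    inversion_length_range = c(1500, 4000),
    n_split_contigs = 1L, min_spacer = 1500,
    centromere_gap_length = 2000, telomere_gap_length = 500,
    walk_target_length = 30e3,
    seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_genome_pair(small_config())
  }
  .fixture_env$sim
}

# annotation row constructor
ann_row <- function(chrom, start, end, name, class, family = "",
                    strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             repeat_name = name, repeat_class = class, family = family,
             divergence_pct = NA_real_, stringsAsFactors = FALSE)
}

tel_call <- function(chrom, which_end, start, end, motif = "CCCTAA") {
  data.frame(chrom = chrom, which_end = which_end, start = start, end = end,
             length = end - start, purity = 1, motif = motif,
             stringsAsFactors = FALSE)
}
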