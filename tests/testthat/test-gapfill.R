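# Gap selection, flank extraction, fill inference and the novel-gene filter.

agp_gap <- function(object, start, end, gap_type = "contig",
                    gap_length = end - start) {
  data.frame(object = object, start = start, end = end, part = NA_integer_,
             kind = "gap", component_id = NA_character_,
             comp_start = NA_integer_, comp_end = NA_integer_,
             orientation = NA_character_, gap_length = gap_length,
             gap_type = gap_type, linkage = "yes", stringsAsFactors = FALSE)
}

# a reference/complete pair built by hand around one gap
make_pair <- function(fill, gap_est = 1000, flank = 200) {
  set.seed(33)
  left <- random_dna(2000)
  right <- random_dna(2000)
  ref <- c(chr1 = paste0(left, strrep("N", gap_est), right))
  t2t <- c(chr1 = paste0(left, fill, right))
  gap <- agp_gap("chr1", 2000, 2000 + gap_est)
  list(ref = ref, t2t = t2t, gap = gap, flank = flank)
}

run_infer <- function(p, t2t = p$t2t) {
  fk <- extract_flanks(p$ref, p$gap, p$flank)
  la <- align_flank_exact(fk$left$seq, t2t, "left")
  ra <- align_flank_exact(fk$right$seq, t2t, "right")
  infer_fill(p$gap, la, ra, t2t)
}

test_that("model gaps are excluded from the real-gap set", {
  agp <- rbind(agp_gap("chr1", 0, 3e6, "centromere"),
               agp_gap("chr1", 5e6, 5.01e6),
               agp_gap("chr2", 1e6, 1.02e6))
  sel <- select_real_gaps(agp)
  expect_identical(nrow(sel$gaps), 2L)
  expect_identical(sel$total_gap_bp, 30000)

  all_model <- agp_gap("chr1", 0, 100, "telomere")
  sel0 <- select_real_gaps(all_model)
  expect_identical(nrow(sel0$gaps), 0L)
  expect_identical(sel0$total_gap_bp, 0)

  sexed <- rbind(agp_gap("chr2", 0, 100), agp_gap("chrX", 0, 100))
  expect_identical(select_real_gaps(sexed, autosomes_only = TRUE)$gaps$object,
                   "chr2")
})

test_that("flanks are the adjacent reference intervals, truncated at bounds", {
  set.seed(21)
  g <- c(chr1 = random_dna(10e3))
  gap <- agp_gap("chr1", 1000, 1100)
  fk <- extract_flanks(g, gap, 500)
  expect_identical(c(fk$left$start, fk$left$end), c(500, 1000))
  expect_identical(c(fk$right$start, fk$right$end), c(1100, 1600))
  expect_identical(fk$left$seq, substr(g[[1]], 501, 1000))
  expect_false(fk$left$truncated)

  near_edge <- agp_gap("chr1", 100, 200)
  fk2 <- extract_flanks(g, near_edge, 500)
  expect_true(fk2$left$truncated)
  expect_identical(c(fk2$left$start, fk2$left$end), c(0, 100))

  at_edge <- agp_gap("chr1", 0, 200)
  expect_error(extract_flanks(g, at_edge, 500), "zero-length flank")
})

test_that("fill inference classifies complete, partial and absent fills", {
  set.seed(34)
  complete <- run_infer(make_pair(random_dna(5000)))
  expect_identical(complete$status, "completely_filled")
  expect_identical(complete$inserted_length, 5000L)
  expect_identical(complete$remaining_N, 0L)
  expect_identical(complete$size_delta, 4000)

  partial <- run_infer(make_pair(paste0(random_dna(2000), strrep("N", 1000),
                                        random_dna(2000))))
  expect_identical(partial$status, "partially_filled")
  expect_identical(partial$remaining_N, 1000L)

  none <- run_infer(make_pair(strrep("N", 800)))
  expect_identical(none$status, "not_filled")
  expect_identical(none$reason, "no_non_N_bases_added")

  # unanchored right flank: the complete assembly lacks it
  p <- make_pair(random_dna(5000))
  truncated_t2t <- c(chr1 = substr(p$t2t[[1]], 1, 7100))
  r <- run_infer(p, truncated_t2t)
  expect_identical(r$status, "not_filled")
  expect_identical(r$reason, "unanchored_flank")
})

test_that("anchor overlaps are tolerated up to the overlap tolerance", {
  # flanks abutting with nothing between: no non-N base added
  abut <- run_infer(make_pair(""))
  expect_identical(abut$status, "not_filled")
  expect_identical(abut$reason, "no_non_N_bases_added")

  # flanks sharing 100 bp: anchors overlap within tolerance, the gap is
  # closed with zero inserted length
  set.seed(35)
  A <- random_dna(2000)
  rest <- random_dna(1900)
  B <- paste0(substr(A, 1901, 2000), rest)
  ref <- c(chr1 = paste0(A, strrep("N", 1000), B))
  t2t <- c(chr1 = paste0(A, rest))
  gap <- agp_gap("chr1", 2000, 3000)
  fk <- extract_flanks(ref, gap, 200)
  r <- infer_fill(gap, align_flank_exact(fk$left$seq, t2t, "left"),
                  align_flank_exact(fk$right$seq, t2t, "right"), t2t)
  expect_identical(r$status, "completely_filled")
  expect_identical(r$inserted_length, 0L)

  # overlap beyond tolerance is refused
  B2 <- paste0(substr(A, 501, 2000), rest)
  ref2 <- c(chr1 = paste0(A, strrep("N", 1000), B2))
  fk2 <- extract_flanks(ref2, gap, 200)
  r2 <- infer_fill(gap, align_flank_exact(fk2$left$seq, t2t, "left"),
                   align_flank_exact(fk2$right$seq, t2t, "right"), t2t)
  expect_identical(r2$status, "not_filled")
  expect_identical(r2$reason, "flank_overlap")
})

test_that("fill inference is invariant to reverse-complementing the assembly", {
  set.seed(36)
  p <- make_pair(paste0(random_dna(1500), strrep("N", 300), random_dna(1200)))
  fwd <- run_infer(p)
  rc <- c(chr1 = revcomp(p$t2t[[1]]))
  rev <- run_infer(p, rc)
  expect_identical(rev$status, fwd$status)
  expect_identical(rev$inserted_length, fwd$inserted_length)
  expect_identical(rev$remaining_N, fwd$remaining_N)
  expect_identical(attr(rev, "inserted_seq"), attr(fwd, "inserted_seq"))
})

test_that("the flank schedule escalates past repetitive flanks", {
  set.seed(37)
  unit <- random_dna(150)
  unique_left <- random_dna(300)
  left <- paste0(unique_left, strrep(unit, 3))   # short flank is repetitive
  right <- random_dna(600)
  fill <- random_dna(1000)
  ref <- c(chr1 = paste0(left, strrep("N", 500), right))
  # a second copy of the repeat unit elsewhere makes the 150 bp flank
  # ambiguous; the 600 bp flank includes the unique prefix
  t2t <- c(chr1 = paste0(random_dna(400), unit, random_dna(200),
                         left, fill, right))
  gap <- agp_gap("chr1", nchar(left), nchar(left) + 500)
  r <- escalate_flanks(ref, t2t, gap, schedule = c(150, 600))
  expect_identical(r$flank_length_used, 600L)
  expect_identical(r$status, "completely_filled")
  expect_identical(r$inserted_length, 1000L)

  # anchors at the first length use it directly
  p <- make_pair(random_dna(800))
  r2 <- escalate_flanks(p$ref, p$t2t, p$gap, schedule = c(200, 400))
  expect_identical(r2$flank_length_used, 200L)

  # never anchored: not_filled after the full schedule
  r3 <- escalate_flanks(p$ref, c(chr1 = random_dna(5000)), p$gap,
                        schedule = c(200, 400))
  expect_identical(r3$status, "not_filled")
  expect_identical(r3$flank_length_used, 400L)
})

test_that("synthetic gap statuses and inserted intervals match the ledger", {
  sim <- small_sim()
  gf <- pipeline_gapfill(sim, flank_schedule = c(1200))
  expect_equal(gf$status_accuracy, 1)
  expect_equal(gf$interval_accuracy, 1)
  # conservation: inserted bp total equals the planted fill bp
  planted <- sim$truth$gaps
  expect_identical(gf$total_inserted_bp,
                   sum(planted$fill_length[planted$fill_status != "none"]))
})

gene_row <- function(id, chrom, start, end, n_exons, cds) {
  data.frame(gene_id = id, chrom = chrom, start = start, end = end,
             strand = "+", n_exons = n_exons, cds_length = cds,
             source = "denovo", extra_copy_number = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("novel-gene filter applies exon, CDS and overlap rules", {
  lift <- gene_row("lg", "chr1", 5000, 6000, 5, 900)
  denovo <- rbind(
    gene_row("two_exons", "chr1", 100, 400, 2, 500),
    gene_row("min_cds", "chr1", 700, 1200, 3, 201),
    gene_row("cds_at_threshold", "chr1", 1500, 2000, 3, 200),
    gene_row("one_bp_overlap", "chr1", 4500, 5001, 4, 800),
    gene_row("clean", "chr2", 100, 900, 3, 400))
  kept <- filter_novel_genes(denovo, lift)
  expect_identical(kept$gene_id, c("min_cds", "clean"))
})
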