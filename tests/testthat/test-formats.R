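# Format readers/writers: coordinate-convention conversion at the parse
# boundary, dialect robustness, round trips.

test_that("read_fasta normalizes case and ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACgt"), f)
  expect_identical(read_fasta(f), c(a = "ACGT"))

  writeLines(c(">a", "AC", ">b", "GT"), f)
  r <- read_fasta(f)
  expect_identical(unname(nchar(r)), c(2L, 2L))
  expect_identical(names(r), c("a", "b"))

  writeLines(c(">a", "ACRT"), f)
  expect_message(r <- read_fasta(f), "1 ambiguity")
  expect_identical(unname(r), "ACNT")

  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "", ">b", "ACGT"), f)
  expect_error(read_fasta(f), "empty sequence.*a")
})

test_that("FASTA round trip preserves sequences", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(chrA = strrep("ACGTN", 50), chrB = "TTAGGG")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

test_that("read_agp converts 1-based inclusive to half-open and validates tiling", {
  f <- withr::local_tempfile(fileext = ".agp")
  writeLines(c("chr1\t1\t100\t1\tW\tctg1\t1\t100\t+",
               "chr1\t101\t200\t2\tN\t100\tcontig\tyes\tpaired-ends"), f)
  a <- read_agp(f)
  expect_identical(a$start, c(0L, 100L))
  expect_identical(a$end, c(100L, 200L))
  expect_identical(a$kind, c("sequence", "gap"))
  expect_identical(a$gap_length[2], 100L)
  expect_identical(a$gap_type[2], "contig")
  # internal length equals the file's printed span
  expect_identical(a$end - a$start, c(100L, 100L))

  # non-tiling components rejected
  writeLines(c("chr1\t1\t100\t1\tW\tctg1\t1\t100\t+",
               "chr1\t150\t200\t2\tW\tctg2\t1\t51\t+"), f)
  expect_error(read_agp(f), "tile")
})

test_that("AGP round trip reproduces records", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".agp")
  write_agp(sim$reference$agp, f)
  back <- read_agp(f)
  expect_equal(back, sim$reference$agp)
})

test_that("read_repeatmasker_out splits class/family and maps simple classes", {
  f <- withr::local_tempfile(fileext = ".out")
  body <- c(
    " 1000 12.5  0.0  0.0  chr1 101 600 (0) + L1MdA3 LINE/L1 1 500 (0) 1",
    " 1000  1.0  0.0  0.0  chr1 700 900 (0) C GSAT_MM Satellite 1 200 (0) 2",
    " 1000  0.0  0.0  0.0  chr2 10 80 (0) + (TATA)n Simple_repeat 1 70 (0) 3",
    " 1000  0.0  0.0  0.0  chr2 90 120 (0) + AT_rich Low_complexity 1 30 (0) 4")
  writeLines(c("hdr", "hdr", "", body), f)
  r <- read_repeatmasker_out(f)
  expect_identical(r$repeat_class, c("LINE", "Satellite", "Simple",
                                     "LowComplexity"))
  expect_identical(r$family, c("L1", "", "", ""))
  expect_identical(r$start[1], 100L)   # 1-based inclusive -> 0-based
  expect_identical(r$end[1], 600L)
  expect_identical(r$strand, c("+", "-", "+", "+"))

  writeLines(c("hdr", "hdr", ""), f)
  expect_identical(nrow(read_repeatmasker_out(f)), 0L)

  writeLines(c("hdr", "hdr", "", "only five columns here x y"), f)
  expect_error(read_repeatmasker_out(f), "line 1")
})

test_that("RepeatMasker round trip preserves the interpreted columns", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(sim$t2t_repeats, f)
  back <- read_repeatmasker_out(f)
  for (col in c("chrom", "start", "end", "strand", "repeat_name",
                "repeat_class", "family")) {
    expect_identical(back[[col]], sim$t2t_repeats[[col]])
  }
})

test_that("read_paf parses mandatory columns, tp:A tag and CRLF dialect", {
  f <- withr::local_tempfile(fileext = ".paf")
  l1 <- "q1\t1000\t0\t800\t+\tt1\t5000\t100\t900\t760\t800\t60"
  l2 <- "q1\t1000\t0\t400\t-\tt2\t5000\t0\t400\t390\t400\t30\ttp:A:S"
  writeLines(c(l1, l2), f)
  p <- read_paf(f)
  expect_equal(p$identity, c(760 / 800, 390 / 400))
  expect_identical(p$secondary, c(FALSE, TRUE))

  # CRLF endings parse identically
  writeLines(paste0(c(l1, l2), "\r"), f, sep = "\n")
  expect_equal(read_paf(f), p)

  writeLines("q1\t1000\t500\t400\t+\tt1\t5000\t0\t100\t90\t100\t60", f)
  expect_error(read_paf(f), "end <= start")
})

test_that("PAF, BED and link-table round trips reproduce records", {
  sim <- small_sim()
  f <- withr::local_tempfile()
  write_paf(sim$paf, f)
  back <- read_paf(f)
  expect_equal(back[names(back) != "identity"],
               sim$paf[names(sim$paf) != "identity"])

  write_bed(sim$sd, f)
  expect_equal(read_bed(f), sim$sd)

  write_links(sim$hic_links, f)
  expect_equal(read_links(f), sim$hic_links)
})

test_that("link table rejects negative counts and duplicate pairs", {
  f <- withr::local_tempfile()
  writeLines(c("contig\tchrom\tpair_count", "c1\tchr1\t-1"), f)
  expect_error(read_links(f), "negative")
  writeLines(c("contig\tchrom\tpair_count", "c1\tchr1\t5", "c1\tchr1\t7"), f)
  expect_error(read_links(f), "duplicate")
})

test_that("read_gff3_genes aggregates exons and CDS per gene", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t1100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t1100\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tID=e2;Parent=m1",
    "chr1\tsrc\texon\t901\t1100\t.\t+\t.\tID=e3;Parent=m1",
    "chr1\tsrc\tCDS\t121\t200\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\tsrc\tCDS\t301\t400\t.\t+\t0\tID=c2;Parent=m1",
    "chr2\tsrc\tgene\t51\t250\t.\t-\t.\tID=g2;extra_copy_number=2",
    "chr2\tsrc\tmRNA\t51\t250\t.\t-\t.\tID=m2;Parent=g2",
    "chr2\tsrc\texon\t51\t250\t.\t-\t.\tID=e4;Parent=m2"), f)
  g <- read_gff3_genes(f, source = "liftover")
  expect_identical(g$gene_id, c("g1", "g2"))
  expect_identical(g$start, c(100L, 50L))   # 0-based
  expect_identical(g$n_exons, c(3L, 1L))
  expect_identical(g$cds_length, c(180L, 0L))
  expect_identical(g$extra_copy_number, c(NA_integer_, 2L))
  expect_identical(unique(g$source), "liftover")
})
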