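# Terminal telomere detection and centromeric-region delineation.

# brute-force oracle: motif coverage mask over the terminal region, chained
# from the end with the same gap/purity rules, recomputed from first
# principles on a logical mask
oracle_telomere_right <- function(seq, motif = "TTAGGG", min_length = 300,
                                  min_purity = 0.6, max_interruption = 60,
                                  end_slack = 1000) {
  L <- nchar(seq)
  k <- nchar(motif)
  v <- strsplit(seq, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  hits <- which(vapply(seq_len(L - k + 1L), function(i)
    all(v[i:(i + k - 1L)] == mv), TRUE))
  if (!length(hits)) return(NULL)
  mask <- logical(L)
  for (h in hits) mask[h:(h + k - 1L)] <- TRUE
  ends <- hits + k - 1L
  if (max(ends) < L - end_slack) return(NULL)
  out_end <- max(ends)
  cur <- hits[which.max(ends)]
  repeat {
    prev <- hits[hits < cur & (cur - (hits + k)) <= max_interruption]
    if (!length(prev)) break
    cur <- min(prev)
  }
  repeat {
    len <- out_end - cur + 1L
    purity <- sum(mask[cur:out_end]) / len
    if (purity >= min_purity) break
    nxt <- hits[hits > cur]
    if (!length(nxt)) break
    cur <- min(nxt)
  }
  len <- out_end - cur + 1L
  if (len < min_length || sum(mask[cur:out_end]) / len < min_purity) {
    return(NULL)
  }
  list(start = cur - 1L, end = out_end, length = len)
}

test_that("pure terminal arrays are called with full purity", {
  set.seed(5)
  body <- random_dna(10e3)
  seq <- paste0(body, strrep("TTAGGG", 100))
  call <- detect_telomere(seq, "right")
  expect_identical(call$length, 10600L - 10000L)
  expect_equal(call$purity, 1)
  expect_identical(call$end, nchar(seq))

  left <- detect_telomere(paste0(strrep("CCCTAA", 80), body), "left")
  expect_identical(left$start, 0L)
  expect_identical(left$length, 480L)
  expect_identical(left$motif, "CCCTAA")
})

test_that("motif-free sequence yields no call at either end", {
  set.seed(6)
  seq <- gsub("TTAGGG|CCCTAA", "ACACAC", random_dna(10e3))
  expect_null(detect_telomere(seq, "right"))
  expect_null(detect_telomere(seq, "left"))
  # shorter than min_length is none, not an error
  expect_null(detect_telomere("TTAGGG", "right", min_length = 300))
})

test_that("substituted arrays are recovered close to their planted length", {
  for (s in 1:5) {
    set.seed(100 + s)
    arr0 <- strrep("TTAGGG", 500)
    arr <- paste0(random_dna(5e3),
                  telocharter:::mutate_seq(substr(arr0, 1, 3000), 0.05))
    call <- detect_telomere(arr, "right", min_purity = 0.6,
                            max_interruption = 60)
    expect_false(is.null(call))
    expect_lte(abs(call$length - 3000), 120)
    orc <- oracle_telomere_right(arr)
    expect_lte(abs(call$length - orc$length), 60)
  }
})

test_that("calls mirror under reverse complement", {
  set.seed(9)
  seq <- paste0(strrep("CCCTAA", 120), random_dna(8e3), strrep("TTAGGG", 90))
  rc <- revcomp(seq)
  for (we in c("left", "right")) {
    a <- detect_telomere(seq, we)
    b <- detect_telomere(rc, setdiff(c("left", "right"), we))
    expect_identical(a$length, b$length)
    expect_identical(a$start, nchar(seq) - b$end)
    expect_false(a$motif == b$motif)
  }
})

test_that("raising min_purity never lengthens a call", {
  set.seed(11)
  arr <- paste0(random_dna(4e3),
                telocharter:::mutate_seq(strrep("TTAGGG", 400), 0.06))
  lens <- vapply(c(0.5, 0.6, 0.7, 0.8), function(p) {
    call <- detect_telomere(arr, "right", min_purity = p,
                            max_interruption = 100)
    if (is.null(call)) 0L else call$length
  }, 0L)
  expect_true(all(diff(lens) <= 0))
})

test_that("telomere pairs are counted per chromosome", {
  chroms <- c("c1", "c2", "c3")
  calls <- rbind(tel_call("c1", "left", 0, 600), tel_call("c1", "right", 1e4, 10600),
                 tel_call("c2", "left", 0, 600), tel_call("c2", "right", 1e4, 10600),
                 tel_call("c3", "left", 0, 600), tel_call("c3", "right", 1e4, 10600))
  r <- count_telomere_pairs(calls, chroms)
  expect_identical(c(r$n_telomeres, r$n_pairs), c(6L, 3L))

  left_only <- calls[calls$which_end == "left", ]
  r2 <- count_telomere_pairs(left_only, chroms)
  expect_identical(c(r2$n_telomeres, r2$n_pairs), c(3L, 0L))
})

test_that("centromeric region merges satellite blocks adjacent to the telomere", {
  ann <- rbind(
    ann_row("c1", 10e3, 5.01e6, "GSAT_MM", "Satellite"),
    ann_row("c1", 5.01e6, 5.13e6, "SYNREP_MM", "Satellite"))
  tel <- tel_call("c1", "left", 0, 10e3)
  r <- delineate_centromere(ann, tel, merge_gap = 1e5)
  expect_equal(r$size, 5.12e6)
  expect_equal(r$major_bp, 5e6)
  expect_equal(r$minor_bp, 120e3)

  no_sat <- ann_row("c1", 100, 200, "L1MdA3", "LINE", "L1")
  expect_null(delineate_centromere(no_sat, tel))
  expect_error(delineate_centromere(ann, tel_call("cX", "left", 0, 10)),
               "no annotations")
})

test_that("censat summaries are the standard order statistics", {
  regions <- data.frame(chrom = c("a", "b", "c"), start = 0,
                        end = c(5e6, 10e6, 15e6), size = c(5e6, 10e6, 15e6),
                        major_bp = 0, minor_bp = 0)
  expect_equal(summarize_censat(regions)$median_size, 10e6)
  regions4 <- rbind(regions, data.frame(chrom = "d", start = 0, end = 20e6,
                                        size = 20e6, major_bp = 0,
                                        minor_bp = 0))
  expect_equal(summarize_censat(regions4)$median_size, 12.5e6)
  expect_error(summarize_censat(NULL), "no centromeric regions")
})

test_that("coverage anomalies are maximal above-threshold intervals", {
  depth <- list(c1 = rep(35L, 100))
  regions <- data.frame(chrom = "c1", start = 0L, end = 100L)
  expect_identical(nrow(flag_coverage_anomalies(depth, regions, 2, 35)), 0L)

  depth$c1[51:60] <- 100L   # positions [50, 60) in 0-based coordinates
  r <- flag_coverage_anomalies(depth, regions, 2, 35)
  expect_identical(nrow(r), 1L)
  expect_identical(c(r$start, r$end), c(50L, 60L))
  expect_equal(r$threshold, 70)   # 2 x 35, the collapsed-duplication cutoff
  expect_equal(r$mean_depth_inside, 100)

  expect_error(
    flag_coverage_anomalies(depth, regions, 2, 35,
                            chrom_lengths = c(c1 = 200L)),
    "does not match")
})
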