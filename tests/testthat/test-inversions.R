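# Inversion filtering, breakpoint windows, permutation enrichment, NAHR
# classification and the small-sample statistics.

inv_row <- function(chrom, start, end, name = "inv") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

test_that("filters drop short, satellite-rich and twin-priming calls", {
  calls <- rbind(inv_row("c1", 0, 1000, "short"),
                 inv_row("c1", 10e3, 20e3, "satellited"),
                 inv_row("c1", 30e3, 40e3, "l1_covered"),
                 inv_row("c1", 50e3, 60e3, "clean"))
  reps <- rbind(
    ann_row("c1", 10e3, 16e3, "GSAT_MM", "Satellite"),
    ann_row("c1", 16e3, 17e3, "(TA)n", "Simple"),
    ann_row("c1", 30.2e3, 39.9e3, "L1MdTf_I", "LINE", "L1"))   # 97% of call
  f <- filter_inversions(calls, reps)
  expect_identical(f$kept$name, "clean")
  expect_identical(f$dropped$reason[f$dropped$name == "short"], "min_length")
  expect_identical(f$dropped$reason[f$dropped$name == "satellited"],
                   "satellite_simple")
  expect_identical(f$dropped$reason[f$dropped$name == "l1_covered"],
                   "twin_priming")

  # exactly 1 kb is dropped: the length rule is strict
  f2 <- filter_inversions(inv_row("c1", 0, 1000), reps[0, ])
  expect_identical(nrow(f2$kept), 0L)
})

test_that("breakpoint windows use outside-flank and centered semantics", {
  w <- make_windows(inv_row("c1", 10e3, 20e3), w_enrich = 1000,
                    w_nahr = 500, chrom_length = 100e3)
  expect_identical(w$enrichment_flanks$start, c(9000, 20000))
  expect_identical(w$enrichment_flanks$end, c(10000, 21000))
  expect_identical(w$nahr_windows$start, c(9500, 19500))
  expect_identical(w$nahr_windows$end, c(10500, 20500))
  expect_false(any(w$enrichment_flanks$clipped))

  wc <- make_windows(inv_row("c1", 200, 5000), w_enrich = 1000,
                     w_nahr = 500, chrom_length = 100e3)
  expect_identical(wc$enrichment_flanks$start[1], 0)
  expect_identical(wc$enrichment_flanks$end[1], 200)
  expect_true(wc$enrichment_flanks$clipped[1])
})

test_that("degenerate annotation layouts give p = 1", {
  workspace <- data.frame(chrom = "c1", start = 0L, end = 10e3)
  windows <- data.frame(chrom = "c1", start = c(1000, 5000),
                        end = c(1100, 5100))
  full <- data.frame(chrom = "c1", start = 0L, end = 10e3,
                     repeat_class = "LINE")
  r <- permutation_enrichment(windows, full, workspace, classes = "LINE",
                              n_perm = 100, seed = 1)
  expect_equal(r$p, 1)
  expect_equal(r$observed, r$null_mean)

  none <- full[0, ]
  r0 <- permutation_enrichment(windows, none, workspace, classes = "LINE",
                               n_perm = 100, seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1)
})

test_that("permutation p-values are deterministic given the seed", {
  set.seed(99)
  workspace <- data.frame(chrom = "c1", start = 0L, end = 50e3)
  ann <- data.frame(chrom = "c1", start = seq(0, 45e3, by = 5e3),
                    end = seq(0, 45e3, by = 5e3) + 800,
                    repeat_class = "LTR")
  windows <- data.frame(chrom = "c1", start = c(100, 20e3, 40e3),
                        end = c(1100, 21e3, 41e3))
  a <- permutation_enrichment(windows, ann, workspace, classes = "LTR",
                              n_perm = 300, seed = 7)
  b <- permutation_enrichment(windows, ann, workspace, classes = "LTR",
                              n_perm = 300, seed = 7)
  expect_identical(a, b)
})

test_that("the permutation null mean matches exhaustive window placement", {
  # 10 kb workspace, one 1 kb annotated block, one 100 bp window: enumerate
  # every placement of the window and compare with the Monte-Carlo null
  workspace <- data.frame(chrom = "c1", start = 0L, end = 10e3)
  ann <- data.frame(chrom = "c1", start = 4000L, end = 5000L,
                    repeat_class = "SD")
  windows <- data.frame(chrom = "c1", start = 0L, end = 100L)
  n_perm <- 2000
  r <- permutation_enrichment(windows, ann, workspace, classes = "SD",
                              n_perm = n_perm, seed = 3, keep_null = TRUE)
  # exhaustive oracle over all 9,901 placements
  starts <- 0:(10e3 - 100)
  ov <- pmax(0, pmin(starts + 100, 5000) - pmax(starts, 4000))
  exact_mean <- mean(ov)
  null <- attr(r, "null")[, 1]
  se <- stats::sd(null) / sqrt(n_perm)
  expect_lt(abs(mean(null) - exact_mean), 3 * se)
})

test_that("BH-adjusted q values are monotone in the p ordering", {
  set.seed(4)
  workspace <- data.frame(chrom = "c1", start = 0L, end = 30e3)
  ann <- do.call(rbind, lapply(c("SD", "LINE", "SINE", "LTR", "Satellite"),
    function(cl) {
      s <- sample.int(29e3, 8)
      data.frame(chrom = "c1", start = s, end = s + 600, repeat_class = cl)
    }))
  windows <- data.frame(chrom = "c1", start = c(2e3, 12e3, 22e3),
                        end = c(3e3, 13e3, 23e3))
  r <- permutation_enrichment(windows, ann, workspace, n_perm = 200,
                              seed = 11)
  r <- r[order(r$p), ]
  expect_true(all(diff(r$q) >= -1e-12))
  expect_true(all(r$q >= r$p - 1e-12))
})

test_that("NAHR classification requires same-family evidence in both windows", {
  inv <- inv_row("c1", 10e3, 20e3)
  w <- make_windows(inv, chrom_length = 100e3)$nahr_windows
  l1_pair <- rbind(
    ann_row("c1", 9700, 10000, "L1MdGf_II", "LINE", "L1", "+"),
    ann_row("c1", 20000, 20300, "L1MdGf_II", "LINE", "L1", "-"))
  r <- classify_nahr(inv, w, l1_pair)
  expect_identical(r$mechanism, "LINE")
  expect_identical(r$family, "LINE/L1")

  # SD pairs take priority over TE evidence
  sds <- data.frame(chrom = "c1", start = c(9600, 20000),
                    end = c(10100, 20500), name = "p1",
                    stringsAsFactors = FALSE)
  r2 <- classify_nahr(inv, w, l1_pair, sds)
  expect_identical(r2$mechanism, "SD")

  # unmatched SD pair ids do not qualify
  sds_bad <- sds
  sds_bad$name <- c("p1", "p2")
  r3 <- classify_nahr(inv, w, l1_pair, sds_bad)
  expect_identical(r3$mechanism, "LINE")

  # evidence on one side only: none
  r4 <- classify_nahr(inv, w, l1_pair[1, ])
  expect_identical(r4$mechanism, "none")

  r5 <- classify_nahr(inv, w, l1_pair[0, ])
  expect_identical(r5$mechanism, "none")
})

test_that("mechanism summary reports NAHR and conditional class fractions", {
  calls <- data.frame(mechanism = c(rep("LINE", 3), "LTR", "SD", "SINE",
                                    rep("none", 4)))
  s <- mechanism_summary(calls)
  expect_equal(s$fraction_nahr, 0.6)
  expect_equal(s$by_mechanism$fraction_of_nahr[
    s$by_mechanism$mechanism == "LINE"], 0.5)

  s0 <- mechanism_summary(data.frame(mechanism = rep("none", 5)))
  expect_equal(s0$fraction_nahr, 0)
  expect_identical(nrow(s0$by_mechanism), 0L)
  expect_error(mechanism_summary(NULL), "no mechanism calls")
})

test_that("breakpoint profiles peak where repeats are planted", {
  invs <- inv_row("c1", 50e3, 80e3)
  genome_wide <- data.frame(chrom = "c1", start = 0L, end = 200e3,
                            repeat_class = "LINE")
  p <- breakpoint_repeat_profile(invs, genome_wide, classes = "LINE",
                                 max_offset = 3000)
  expect_true(all(p$proportion == 1))

  p0 <- breakpoint_repeat_profile(invs, genome_wide[0, ], classes = "LINE",
                                  max_offset = 3000)
  expect_true(all(p0$proportion == 0))

  # 500 bp repeats exactly at the breakpoints: peak adjacent to offset 0
  at_bp <- rbind(
    data.frame(chrom = "c1", start = 49750L, end = 50250L,
               repeat_class = "LTR"),
    data.frame(chrom = "c1", start = 79750L, end = 80250L,
               repeat_class = "LTR"))
  pr <- breakpoint_repeat_profile(invs, at_bp, classes = "LTR",
                                  max_offset = 3000)
  near <- pr$proportion[pr$offset %in% c(-1000, 0)]
  far <- pr$proportion[abs(pr$offset) >= 2000]
  expect_true(all(near == 0.25))
  expect_true(all(far == 0))
})

test_that("Mann-Whitney matches exhaustive label permutation and wilcox.test", {
  expect_equal(mwu_test(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # independent oracle: permute labels over all subsets, recompute U by
  # direct pairwise comparison
  oracle_mwu <- function(x, y) {
    pooled <- c(x, y)
    m <- length(x)
    U_of <- function(xx, yy)
      sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    u_obs <- U_of(x, y)
    mu <- m * length(y) / 2
    combs <- utils::combn(length(pooled), m)
    us <- apply(combs, 2, function(ix)
      U_of(pooled[ix], pooled[-ix]))
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  set.seed(13)
  for (i in 1:5) {
    x <- sample(1:6, 7, replace = TRUE)   # ties likely
    y <- sample(2:8, 8, replace = TRUE)
    r <- mwu_test(x, y)
    expect_identical(r$method, "exact_enumeration")
    expect_equal(r$p, oracle_mwu(x, y))
  }
  # tie-free case agrees with the exact wilcox.test distribution
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3, 7.7)
  y <- c(2.9, 4.4, 6.1, 0.9, 3.3, 8.2)
  expect_equal(mwu_test(x, y)$p, wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("Kendall tau matches brute-force pair counting and cor.test", {
  expect_equal(kendall_test(1:5, 1:5)$tau, 1)
  expect_equal(kendall_test(1:5, 5:1)$tau, -1)

  # O(n^2) concordant/discordant oracle (tau-b)
  oracle_tau <- function(x, y) {
    n <- length(x)
    conc <- disc <- tx <- ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
    (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
  }
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(8)
    y <- 0.5 * x + rnorm(8)
    r <- kendall_test(x, y)
    expect_equal(r$tau, oracle_tau(x, y))
    expect_identical(r$method, "exact_enumeration")
    # tie-free exact p agrees with cor.test's exact distribution
    expect_equal(r$p, cor.test(x, y, method = "kendall")$p.value,
                 tolerance = 1e-10)
  }
  expect_error(kendall_test(1:2, 1:2), ">=3 pairs")
})

test_that("planted mechanisms are recovered exactly at zero background", {
  sim <- small_sim()
  iv <- pipeline_inversions(sim)
  expect_equal(iv$mechanism_accuracy, 1)
  expect_equal(iv$twin_priming_filtered, 1)
  got <- iv$calls$mechanism
  expect_identical(got, iv$calls$true_mechanism)
})

test_that("background repeats cause few false mechanism calls", {
  cfg <- small_config(inversion_mechanisms = c("none", "none", "none"),
                      background_repeat_density = 0.05, seed = 271L)
  sim <- simulate_genome_pair(cfg)
  iv <- pipeline_inversions(sim)
  false_rate <- mean(iv$calls$mechanism != "none")
  expect_lt(false_rate, 0.34)   # <=1 of 3 windows hit by chance
})
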