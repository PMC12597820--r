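## Inversion-call filtering, breakpoint repeat-enrichment via segment
## randomization, NAHR (non-allelic homologous recombination) mechanism
## classification and the associated length statistics.

#' Filter inversion calls
#'
#' Removes calls not longer than `min_length` (strictly larger than 1 kb by
#' default), calls primarily composed of satellite/simple/low-complexity
#' sequence, and likely twin-priming artifacts (internally inverted L1
#' insertions) covered at least `l1_min_fraction` by L1 annotations.
#'
#' @param calls data.frame `chrom, start, end` (+ optional `name`).
#' @param repeats repeat annotations on the same assembly.
#' @param satellite_max_fraction maximal tolerated satellite+simple+low-
#'   complexity coverage fraction.
#' @param l1_min_fraction L1 coverage at or above which a call is dropped as
#'   twin priming.
#' @param min_length length that must be strictly exceeded, bp.
#' @return list with `kept` and `dropped` (the latter with a `reason`
#'   column).
#' @export
filter_inversions <- function(calls, repeats, satellite_max_fraction = 0.5,
                              l1_min_fraction = 0.95, min_length = 1000) {
  if (is.null(calls$name)) {
    calls$name <- sprintf("inv_%03d", seq_len(nrow(calls)))
  }
  reason <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    len <- v$end - v$start
    r <- repeats[repeats$chrom == v$chrom, , drop = FALSE]
    sat <- r[r$repeat_class %in% c("Satellite", "Simple", "LowComplexity"), ]
    l1 <- r[r$repeat_class == "LINE" & r$family == "L1", ]
    sat_frac <- overlap_bp0(v$start, v$end, sat$start, sat$end) / len
    l1_frac <- overlap_bp0(v$start, v$end, l1$start, l1$end) / len
    reason[i] <- if (len <= min_length) "min_length"
      else if (sat_frac > satellite_max_fraction) "satellite_simple"
      else if (l1_frac >= l1_min_fraction) "twin_priming"
      else NA_character_
  }
  kept <- calls[is.na(reason), , drop = FALSE]
  dropped <- calls[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}

#' Breakpoint windows of an inversion
#'
#' Enrichment flanks are the two `w_enrich`-bp intervals outside the
#' inversion; NAHR windows are the two `2*w_nahr`-bp intervals centered on
#' each breakpoint. All windows are clipped to the chromosome.
#'
#' @param inv one inversion row (`chrom, start, end`).
#' @param w_enrich outside-flank width, bp (1 kb default).
#' @param w_nahr half-width of the breakpoint-centered windows, bp (500
#'   default).
#' @param chrom_length chromosome length for clipping.
#' @return list with `enrichment_flanks` and `nahr_windows` data.frames
#'   (`chrom, start, end, breakpoint, clipped`).
#' @export
make_windows <- function(inv, w_enrich = 1000, w_nahr = 500, chrom_length) {
  stopifnot(w_enrich > 0, w_nahr > 0)
  clip <- function(s, e, bp) {
    cs <- max(0L, s)
    ce <- min(chrom_length, e)
    data.frame(chrom = inv$chrom, start = cs, end = ce, breakpoint = bp,
               clipped = (cs != s) || (ce != e), stringsAsFactors = FALSE)
  }
  enrich <- rbind(clip(inv$start - w_enrich, inv$start, inv$start),
                  clip(inv$end, inv$end + w_enrich, inv$end))
  nahr <- rbind(clip(inv$start - w_nahr, inv$start + w_nahr, inv$start),
                clip(inv$end - w_nahr, inv$end + w_nahr, inv$end))
  list(enrichment_flanks = enrich, nahr_windows = nahr)
}

## place each window (length preserved) uniformly at random within the
## workspace; returns data.frame(chrom, start, end)
place_windows_random <- function(widths, workspace) {
  ws_w <- workspace$end - workspace$start
  n <- length(widths)
  chrom <- character(n)
  start <- numeric(n)
  for (w in unique(widths)) {
    sel <- which(widths == w)
    slots <- ws_w - w + 1
    ok <- slots > 0
    if (!any(ok)) stop("window of ", w, " bp exceeds every workspace interval")
    idx <- which(ok)
    cum <- cumsum(slots[ok])
    u <- sample.int(cum[length(cum)], length(sel), replace = TRUE)
    j <- findInterval(u, c(0, cum), left.open = TRUE)
    off <- u - c(0, cum)[j] - 1
    chrom[sel] <- workspace$chrom[idx[j]]
    start[sel] <- workspace$start[idx[j]] + off
  }
  data.frame(chrom = chrom, start = start, end = start + widths,
             stringsAsFactors = FALSE)
}

## metric of a window set against per-chromosome coverage closures
windows_metric <- function(win, cov_fns, ann_by_chrom, metric) {
  if (metric == "bp_overlap") {
    tot <- 0
    for (ch in unique(win$chrom)) {
      f <- cov_fns[[ch]]
      if (is.null(f)) next
      s <- win$start[win$chrom == ch]
      e <- win$end[win$chrom == ch]
      tot <- tot + sum(f(s, e))
    }
    tot
  } else {
    ## count of annotations intersecting at least one window
    n <- 0L
    for (ch in unique(win$chrom)) {
      a <- ann_by_chrom[[ch]]
      if (is.null(a) || nrow(a) == 0L) next
      s <- win$start[win$chrom == ch]
      e <- win$end[win$chrom == ch]
      hit <- vapply(seq_len(nrow(a)), function(i)
        any(a$start[i] < e & a$end[i] > s), TRUE)
      n <- n + sum(hit)
    }
    n
  }
}

#' Permutation test of repeat enrichment in breakpoint windows
#'
#' The observed metric (bp overlap or intersecting-annotation count) of the
#' windows against each repeat class is compared with a null in which every
#' window is independently relocated to a uniform position within the
#' workspace (length preserved; windows may overlap each other). Two-sided
#' empirical p-values with the add-one correction, Benjamini-Hochberg
#' adjusted across classes.
#'
#' @param windows data.frame `chrom, start, end` (the enrichment flanks of
#'   all inversions).
#' @param repeats annotations with `repeat_class` (include SD intervals as
#'   class `"SD"` to test them).
#' @param workspace data.frame `chrom, start, end` of allowed placements
#'   (typically the assembled, non-N chromosome intervals).
#' @param classes repeat classes tested.
#' @param n_perm number of permutations (1,000 default).
#' @param seed integer seed for the permutation stream.
#' @param metric `"bp_overlap"` or `"count"`.
#' @param keep_null retain the per-permutation values (attribute `null`).
#' @return data.frame `class, observed, null_mean, null_sd, p, q`.
#' @export
permutation_enrichment <- function(windows, repeats, workspace,
                                   classes = c("SD", "LINE", "SINE", "LTR",
                                               "Satellite"),
                                   n_perm = 1000, seed = 1L,
                                   metric = c("bp_overlap", "count"),
                                   keep_null = FALSE) {
  metric <- match.arg(metric)
  stopifnot(n_perm >= 1)
  set.seed(seed)
  widths <- windows$end - windows$start
  prep <- function(cl) {
    a <- repeats[repeats$repeat_class == cl, , drop = FALSE]
    cov_fns <- lapply(split(a, a$chrom), function(d)
      make_coverage_fn(d$start, d$end))
    list(cov_fns = cov_fns, by_chrom = split(a, a$chrom))
  }
  preps <- lapply(classes, prep)
  names(preps) <- classes
  observed <- vapply(classes, function(cl)
    windows_metric(windows, preps[[cl]]$cov_fns, preps[[cl]]$by_chrom,
                   metric), 0)
  null <- matrix(0, nrow = n_perm, ncol = length(classes),
                 dimnames = list(NULL, classes))
  for (b in seq_len(n_perm)) {
    perm <- place_windows_random(widths, workspace)
    for (cl in classes) {
      null[b, cl] <- windows_metric(perm, preps[[cl]]$cov_fns,
                                    preps[[cl]]$by_chrom, metric)
    }
  }
  p <- vapply(classes, function(cl) {
    ge <- sum(null[, cl] >= observed[[cl]]) + 1L
    le <- sum(null[, cl] <= observed[[cl]]) + 1L
    min(1, 2 * min(ge, le) / (n_perm + 1))
  }, 0)
  out <- data.frame(class = classes, observed = unname(observed),
                    null_mean = colMeans(null),
                    null_sd = apply(null, 2, stats::sd),
                    p = unname(p), q = unname(p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (keep_null) attr(out, "null") <- null
  out
}

TE_CLASS_PRIORITY <- c("LINE", "LTR", "SINE")

#' Classify the NAHR mechanism of one inversion
#'
#' SD mechanism when segmental-duplication intervals (a matching pair when
#' pair ids are present) overlap both breakpoint windows; otherwise the TE
#' family (at `class_family` or `subfamily` granularity) with at least
#' `min_overlap` bp in both windows, choosing the family maximizing the
#' smaller of its two window overlaps; `none` when neither applies.
#'
#' @param inv one inversion row (`chrom, start, end`, optional `name`).
#' @param nahr_windows the two breakpoint-centered windows from
#'   [make_windows()].
#' @param repeats repeat annotations (TE classes LINE/LTR/SINE considered).
#' @param sds segmental-duplication intervals (`chrom, start, end`, optional
#'   `name` pair id).
#' @param family_level `"class_family"` (e.g. LINE/L1) or `"subfamily"`
#'   (repeat name).
#' @param min_overlap minimal same-family overlap per window, bp.
#' @return one-row data.frame (`name, chrom, start, end, length, mechanism,
#'   family, left_bp, right_bp`).
#' @export
classify_nahr <- function(inv, nahr_windows, repeats, sds = NULL,
                          family_level = c("class_family", "subfamily"),
                          min_overlap = 50) {
  family_level <- match.arg(family_level)
  stopifnot(nrow(nahr_windows) == 2L)
  w1 <- nahr_windows[1, ]
  w2 <- nahr_windows[2, ]
  out <- function(mechanism, family = NA_character_, lb = 0, rb = 0) {
    data.frame(name = if (!is.null(inv$name)) inv$name else NA_character_,
               chrom = inv$chrom, start = inv$start, end = inv$end,
               length = inv$end - inv$start, mechanism = mechanism,
               family = family, left_bp = lb, right_bp = rb,
               stringsAsFactors = FALSE)
  }
  ## SD first: flanking duplicated segments at both breakpoints
  if (!is.null(sds) && nrow(sds)) {
    sd <- sds[sds$chrom == inv$chrom, , drop = FALSE]
    hit <- function(w, d) d[d$start < w$end & d$end > w$start, , drop = FALSE]
    h1 <- hit(w1, sd)
    h2 <- hit(w2, sd)
    paired <- if (!is.null(sd$name) && nrow(h1) && nrow(h2)) {
      length(intersect(h1$name, h2$name)) > 0L
    } else nrow(h1) > 0L && nrow(h2) > 0L
    if (paired) {
      lb <- overlap_bp0(w1$start, w1$end, h1$start, h1$end)
      rb <- overlap_bp0(w2$start, w2$end, h2$start, h2$end)
      return(out("SD", family = "SD", lb = lb, rb = rb))
    }
  }
  te <- repeats[repeats$chrom == inv$chrom &
                  repeats$repeat_class %in% TE_CLASS_PRIORITY, , drop = FALSE]
  if (nrow(te)) {
    te$fam_key <- if (family_level == "class_family") {
      paste0(te$repeat_class, "/", te$family)
    } else te$repeat_name
    fams <- unique(te$fam_key)
    lb <- rb <- setNames(numeric(length(fams)), fams)
    for (f in fams) {
      d <- te[te$fam_key == f, ]
      lb[f] <- overlap_bp0(w1$start, w1$end, d$start, d$end)
      rb[f] <- overlap_bp0(w2$start, w2$end, d$start, d$end)
    }
    score <- pmin(lb, rb)
    qual <- names(score)[score >= min_overlap]
    if (length(qual)) {
      cls <- vapply(qual, function(f)
        te$repeat_class[te$fam_key == f][1], "")
      ord <- order(-score[qual], match(cls, TE_CLASS_PRIORITY), qual)
      best <- qual[ord[1]]
      return(out(cls[[best]], family = best,
                 lb = unname(lb[best]), rb = unname(rb[best])))
    }
  }
  out("none")
}

#' Summarize NAHR mechanism calls
#'
#' @param calls data.frame of [classify_nahr()] rows.
#' @return list with `n`, `n_nahr`, `fraction_nahr` and `by_mechanism`
#'   (counts and fractions conditional on being NAHR).
#' @export
mechanism_summary <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) stop("no mechanism calls")
  nahr <- calls[calls$mechanism != "none", , drop = FALSE]
  by_mech <- if (nrow(nahr)) {
    tb <- table(nahr$mechanism)
    data.frame(mechanism = names(tb), n = as.integer(tb),
               fraction_of_nahr = as.numeric(tb) / nrow(nahr),
               stringsAsFactors = FALSE)
  } else {
    data.frame(mechanism = character(), n = integer(),
               fraction_of_nahr = numeric(), stringsAsFactors = FALSE)
  }
  list(n = nrow(calls), n_nahr = nrow(nahr),
       fraction_nahr = nrow(nahr) / nrow(calls), by_mechanism = by_mech)
}

#' Repeat-overlap profile around inversion breakpoints
#'
#' For each offset bin of `window_bp` relative to a breakpoint (positive
#' offsets point into the inversion interior, both breakpoints oriented
#' inward), the mean fraction of window bases annotated with each class.
#'
#' @param inversions data.frame `chrom, start, end`.
#' @param repeats annotations with `repeat_class`.
#' @param classes classes profiled.
#' @param window_bp bin width, bp.
#' @param max_offset profile half-range, bp (multiple of `window_bp`).
#' @return data.frame `class, offset, proportion` (offset = bin lower edge
#'   in bp relative to the breakpoint, interior-positive).
#' @export
breakpoint_repeat_profile <- function(inversions, repeats,
                                      classes = c("SD", "LINE", "SINE",
                                                  "LTR", "Satellite"),
                                      window_bp = 1000, max_offset = 10000) {
  stopifnot(max_offset %% window_bp == 0)
  offs <- seq(-max_offset, max_offset - window_bp, by = window_bp)
  rows <- list()
  for (cl in classes) {
    a <- repeats[repeats$repeat_class == cl, , drop = FALSE]
    cov_fns <- lapply(split(a, a$chrom), function(d)
      make_coverage_fn(d$start, d$end))
    acc <- matrix(NA_real_, nrow = 2L * nrow(inversions),
                  ncol = length(offs))
    for (i in seq_len(nrow(inversions))) {
      v <- inversions[i, ]
      f <- cov_fns[[v$chrom]]
      get <- function(s, e) {
        if (is.null(f)) 0 else f(s, e)
      }
      ## left breakpoint: interior is +offset (rightward)
      s <- v$start + offs
      acc[2L * i - 1L, ] <- get(s, s + window_bp) / window_bp
      ## right breakpoint: interior is +offset (leftward)
      s2 <- v$end - offs - window_bp
      acc[2L * i, ] <- get(s2, s2 + window_bp) / window_bp
    }
    rows[[cl]] <- data.frame(class = cl, offset = offs,
                             proportion = colMeans(acc),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null by enumeration of all group-label assignments when the
#' combined sample size is at most `exact_max` (ties handled exactly);
#' otherwise the tie-corrected normal approximation of
#' [stats::wilcox.test()].
#'
#' @param x,y numeric samples.
#' @param exact_max maximal combined size for exact enumeration.
#' @return list with `U` (statistic of `x`), `p`, `method`.
#' @export
mwu_test <- function(x, y, exact_max = 16L) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("Mann-Whitney U test needs >=2 observations per group")
  }
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= exact_max) {
    ## exact two-sided p: enumerate all C(m+n, m) assignments of the pooled
    ## (possibly tied) values to group x
    mu <- m * n / 2
    combs <- utils::combn(m + n, m)
    Us <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
    return(list(U = U_obs, p = p, method = "exact_enumeration"))
  }
  w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(U = U_obs, p = w$p.value, method = "normal_approximation")
}

#' Kendall rank correlation (tau-b)
#'
#' Exact two-sided p by full permutation enumeration for `n <= exact_max`
#' (ties handled exactly); otherwise the tie-corrected normal approximation
#' of [stats::cor.test()].
#'
#' @param x,y paired numeric vectors.
#' @param exact_max maximal n for exact enumeration.
#' @return list with `tau`, `p`, `method`.
#' @export
kendall_test <- function(x, y, exact_max = 8L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("Kendall correlation needs >=3 pairs")
  tau_obs <- cor(x, y, method = "kendall")
  if (n <= exact_max) {
    perms <- permutations_of(n)
    taus <- apply(perms, 1L, function(p) cor(x, y[p], method = "kendall"))
    p <- mean(abs(taus) >= abs(tau_obs) - 1e-12)
    return(list(tau = tau_obs, p = p, method = "exact_enumeration"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  list(tau = tau_obs, p = ct$p.value, method = "normal_approximation")
}

## all permutations of 1..n as a matrix (n! rows)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Length statistics of mechanism-classified inversions
#'
#' Mann-Whitney U comparison of SD-mechanism vs TE-mechanism inversion
#' lengths, and Kendall correlation between SD-mechanism inversion length
#' and the mean length of the adjacent (evidence) SD intervals.
#'
#' @param calls [classify_nahr()] rows.
#' @param sds segmental-duplication intervals with optional `name` pair ids.
#' @param nahr_windows_fn function(inv row) returning the two NAHR windows
#'   (used to recover the evidence SD intervals); defaults to
#'   [make_windows()] with standard widths and no clipping beyond 0.
#' @param w_nahr half-width used when recovering adjacent SDs, bp.
#' @return list with `mwu` (list `U, p, method`), `kendall` (list `tau, p,
#'   method`), `sd_lengths` (per-inversion mean adjacent SD length).
#' @export
length_statistics <- function(calls, sds, w_nahr = 500) {
  sd_calls <- calls[calls$mechanism == "SD", , drop = FALSE]
  te_calls <- calls[calls$mechanism %in% TE_CLASS_PRIORITY, , drop = FALSE]
  if (nrow(sd_calls) < 2L || nrow(te_calls) < 2L) {
    stop("Mann-Whitney comparison needs >=2 SD- and >=2 TE-mechanism calls")
  }
  mwu <- mwu_test(sd_calls$length, te_calls$length)
  ## mean adjacent SD length per SD-mechanism inversion
  mean_sd_len <- vapply(seq_len(nrow(sd_calls)), function(i) {
    v <- sd_calls[i, ]
    sd <- sds[sds$chrom == v$chrom, , drop = FALSE]
    near <- sd[(sd$start < v$start + w_nahr & sd$end > v$start - w_nahr) |
                 (sd$start < v$end + w_nahr & sd$end > v$end - w_nahr), ,
               drop = FALSE]
    if (!nrow(near)) return(NA_real_)
    mean(near$end - near$start)
  }, 0)
  ok <- !is.na(mean_sd_len)
  if (sum(ok) < 3L) {
    stop("Kendall correlation needs >=3 SD-mechanism inversions with ",
         "adjacent SDs")
  }
  kd <- kendall_test(sd_calls$length[ok], mean_sd_len[ok])
  list(mwu = mwu, kendall = kd,
       sd_lengths = data.frame(name = sd_calls$name,
                               inversion_length = sd_calls$length,
                               mean_adjacent_sd_length = mean_sd_len,
                               stringsAsFactors = FALSE))
}
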