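test_that("TSS and body windows follow the strand-aware definitions", {
  w <- gene_windows("+", tss = 10000, tes = 30000)
  expect_equal(w$tss_window, c(9750, 10250))
  expect_equal(w$body_window, c(10500, 29500))
  expect_true(w$eligible)
  # mirrored on the minus strand
  wm <- gene_windows("-", tss = 30000, tes = 10000)
  expect_equal(wm$tss_window, c(29750, 30250))
  expect_equal(wm$body_window, c(10500, 29500))
  # too short for 500 + 500 trimming -> ineligible, not an error
  ws <- gene_windows("+", tss = 1000, tes = 1900)
  expect_false(ws$eligible)
})

test_that("TSS selection maximizes control signal with a 5'-most tie-break", {
  g1 <- one_gene("g1", "+", 1000, 6000, tss = list(c(1000)))
  ctrl <- segment_track(list(list(start = 900, end = 1300, value = 5)), 8000)
  expect_equal(select_tss(g1, ctrl), 1000)

  g2 <- one_gene("g2", "+", 1000, 6000, tss = list(c(1000, 2000)))
  # signal 5 around the first TSS, 1 around the second
  ctrl2 <- segment_track(list(list(start = 750, end = 1250, value = 5),
                              list(start = 1750, end = 2250, value = 1)),
                         8000)
  expect_equal(select_tss(g2, ctrl2), 1000)
  ctrl2b <- segment_track(list(list(start = 750, end = 1250, value = 1),
                               list(start = 1750, end = 2250, value = 5)),
                          8000)
  expect_equal(select_tss(g2, ctrl2b), 2000)

  # exact tie: constant control -> 5'-most, strand-aware
  flat <- segment_track(list(list(start = 0, end = 8000, value = 2)), 8000)
  expect_equal(select_tss(g2, flat), 1000)
  g3 <- one_gene("g3", "-", 1000, 6000, tss = list(c(5000, 6000)))
  expect_equal(select_tss(g3, flat), 6000)
})

test_that("PRR reproduces closed-form cases", {
  g <- one_gene("g1", "+", 1000, 4000)
  uniform <- segment_track(list(list(start = 0, end = 6000, value = 2)), 6000)
  rec <- compute_prr(uniform, g, tss = 1000)
  expect_true(rec$eligible)
  expect_equal(rec$prr, 0)
  # tss window mean 8, body mean 2 -> log2(2/8) = -2
  piece <- segment_track(list(list(start = 750, end = 1250, value = 8),
                              list(start = 1500, end = 3500, value = 2)),
                         6000)
  rec2 <- compute_prr(piece, g, tss = 1000)
  expect_equal(rec2$prr, -2)
  # short gene ineligible; flat-at-floor gene flagged no_signal
  short <- one_gene("g2", "+", 1000, 1900)
  expect_match(compute_prr(uniform, short, tss = 1000)$reason, "short")
  dead <- compute_prr(segment_track(list(list(start = 0, end = 1, value = 0)),
                                    10), g, tss = 1000)
  expect_false(dead$eligible)
  expect_match(dead$reason, "no_signal")
})

test_that("PRR equals the dense per-base oracle on random genes", {
  set.seed(31)
  len <- 2e5
  v <- runif(len, 0.05, 6)
  trk <- coverage_track(list(chr1 = v), label = "ctrl")
  starts <- round(seq(2000, len - 12000, length.out = 50))
  strands <- rep(c("+", "-"), 25)
  genes <- gene_models(sprintf("g%02d", 1:50), rep("chr1", 50), strands,
                       starts, starts + sample(2000:9000, 50, replace = TRUE))
  tab <- prr_table(trk, genes)
  for (i in 1:50) {
    tss <- genes$tss[[i]][1]
    w <- gene_windows(genes$strand[i], tss, genes$tes[i])
    m_tss <- dense_mean(v, w$tss_window[1], w$tss_window[2])
    m_body <- dense_mean(v, w$body_window[1], w$body_window[2])
    expect_equal(tab$prr[i], log2(max(m_body, 0.01) / max(m_tss, 0.01)),
                 tolerance = 1e-9)
  }
  # invariance under global positive scaling
  tab5 <- prr_table(track_scale(trk, 5), genes)
  expect_equal(tab5$prr, tab$prr, tolerance = 1e-12)
})

test_that("PRR decreases as promoter peak amplitude grows, body fixed", {
  g <- one_gene("g1", "+", 5000, 15000)
  prrs <- vapply(c(0, 2, 8, 32), function(amp) {
    x <- 1:20000
    v <- 1 + amp * exp(-(x - 5000)^2 / (2 * 100^2))
    compute_prr(coverage_track(list(chr1 = v)), g, tss = 5000)$prr
  }, numeric(1))
  expect_true(all(diff(prrs) < 0))
  expect_equal(prrs[1], 0, tolerance = 1e-6)
})

test_that("KS comparison matches the exhaustive ECDF-gap oracle", {
  mk <- function(ids, prr, cond) {
    data.frame(gene_id = ids, condition = cond, selected_tss = 0,
               tss_enrichment = 1, body_enrichment = 1, prr = prr,
               eligible = TRUE, reason = "", stringsAsFactors = FALSE)
  }
  ids <- sprintf("g%03d", 1:200)
  set.seed(5)
  pa <- rnorm(200); pb <- rnorm(200, 0.4)
  ra <- mk(ids, pa, "a"); rb <- mk(ids, pb, "b")
  cmp <- prr_compare(ra, rb)
  expect_equal(cmp$statistic, ks_d_oracle(pa, pb), tolerance = 1e-12)
  expect_equal(cmp$n, 200)
  # identical samples -> D = 0, p = 1; symmetry
  same <- prr_compare(ra, ra)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(prr_compare(rb, ra)$statistic, cmp$statistic)
  # disjoint supports -> D = 1
  r1 <- mk(ids[1:30], 1:30 / 10, "a")
  r2 <- mk(ids[1:30], 4 + 1:30 / 10, "b")
  expect_equal(prr_compare(r1, r2)$statistic, 1)
  # low-power warning under 10 shared genes
  expect_warning(prr_compare(mk(ids[1:5], 1:5, "a"), mk(ids[1:5], 2:6, "b")),
                 "low-power")
})

test_that("quartile stratification splits at reference quartiles", {
  ref <- setNames(1:8, sprintf("g%d", 1:8))
  del <- setNames(rep(0.5, 8), names(ref))
  qs <- quartile_stratify(ref, del)
  expect_equal(qs$assignments$quartile, rep(1:4, each = 2))
  expect_equal(qs$summary$n, rep(2L, 4))
  # constant reference degenerates to a single stratum with a warning
  expect_warning(q1 <- quartile_stratify(setNames(rep(2, 8), names(ref)), del),
                 "constant")
  expect_true(all(q1$assignments$quartile == 1))
  # near-balanced split for random references
  set.seed(6)
  refr <- setNames(rnorm(1000), sprintf("r%04d", 1:1000))
  delr <- setNames(rnorm(1000), names(refr))
  counts <- quartile_stratify(refr, delr)$summary$n
  expect_true(all(abs(counts - 250) <= 1))
})

test_that("intron-class stratification reproduces the one-way ANOVA oracle", {
  g <- gene_models(c("a", "b"), c("chr1", "chr1"), c("+", "+"),
                   c(0, 10000), c(6000, 20000),
                   exon_starts = list(c(0, 800), c(10000, 15300)),
                   exon_ends = list(c(300, 6000), c(10300, 20000)))
  expect_equal(g$largest_intron, c(500, 5000))
  vals <- setNames(c(1.0, 2.0), c("a", "b"))
  res <- intron_class_stratify(g, vals, class_breaks = 1000)
  expect_equal(res$summary$n, c(1L, 1L))

  # identical class means -> F exactly 0
  ids <- sprintf("g%02d", 1:6)
  g6 <- gene_models(ids, rep("chr1", 6), rep("+", 6),
                    seq(0, 5e5, length.out = 6),
                    seq(0, 5e5, length.out = 6) + 2000)
  g6$largest_intron <- c(100, 100, 100, 5000, 5000, 5000)
  v6 <- setNames(c(0, 1, 2, 0.5, 1, 1.5), ids)
  res0 <- intron_class_stratify(g6, v6, class_breaks = 1000)
  expect_equal(res0$anova$f, 0)

  # textbook sums-of-squares oracle on 3 classes
  set.seed(7)
  n <- 50
  vals3 <- c(rnorm(n, 0, 0.1), rnorm(n, 1, 0.1), rnorm(n, 2, 0.1))
  ids3 <- sprintf("h%03d", 1:(3 * n))
  g3 <- gene_models(ids3, rep("chr1", 3 * n), rep("+", 3 * n),
                    seq(0, 3e6, length.out = 3 * n),
                    seq(0, 3e6, length.out = 3 * n) + 2000)
  g3$largest_intron <- rep(c(100, 2000, 50000), each = n)
  res3 <- intron_class_stratify(g3, setNames(vals3, ids3),
                                class_breaks = c(1000, 10000))
  grp <- rep(1:3, each = n)
  gm <- mean(vals3)
  ssb <- sum(tapply(vals3, grp, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(vals3, grp, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / 2) / (ssw / (3 * n - 3))
  expect_equal(res3$anova$f, f_oracle, tolerance = 1e-9)
  expect_lt(res3$anova$p_value, 1e-12)
})

test_that("window changes and the bound-vs-unbound Welch test behave", {
  ids <- sprintf("g%02d", 1:8)
  starts <- seq(2000, 7 * 4000 + 2000, by = 4000)
  genes <- gene_models(ids, rep("chr1", 8), rep("+", 8), starts,
                       starts + 3000)
  len <- 40000
  base <- segment_track(list(list(start = 0, end = len, value = 1)), len)
  # identical tracks: all changes 0, degenerate test p = 1
  res0 <- window_change_test(base, base, genes, window = "tss",
                             bound_set = ids[1:4])
  expect_true(all(res0$changes$log2_change == 0))
  expect_equal(res0$test$p_value, 1)
  expect_equal(res0$test$statistic, 0)

  # per-gene constructed log2 changes; Welch oracle from first principles
  deltas <- c(0.8, 1.2, 1.0, 0.9, 0.1, -0.1, 0.05, 0)
  v <- rep(1, len)
  for (i in 1:8) {
    w <- c(starts[i] - 250, starts[i] + 250)
    v[(w[1] + 1):w[2]] <- 2^deltas[i]
  }
  shifted <- coverage_track(list(chr1 = v))
  res <- window_change_test(base, shifted, genes, window = "tss",
                            bound_set = ids[1:4])
  expect_equal(res$changes$log2_change, deltas, tolerance = 1e-9)
  oracle <- welch_t(deltas[1:4], deltas[5:8])
  expect_equal(res$test$statistic, oracle$t, tolerance = 1e-9)
  expect_equal(res$test$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(res$test$mean_bound - res$test$mean_unbound, 0.9625,
               tolerance = 1e-9)
  # empty group -> skipped with diagnostic
  skip_res <- window_change_test(base, shifted, genes, window = "tss",
                                 bound_set = character())
  expect_null(skip_res$test)
  expect_match(skip_res$diagnostic, "skipped")
})

test_that("change correlation matches the covariance formula", {
  set.seed(8)
  x <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  expect_equal(change_correlation(x, x)$r, 1)
  expect_equal(change_correlation(x, -x)$r, -1)
  set.seed(8)
  y <- setNames(0.5 * x + rnorm(100), names(x))
  res <- change_correlation(x, y, highlight_set = names(x)[1:10])
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(sum(res$highlight), 10)
  flat <- setNames(rep(1, 100), names(x))
  expect_false(change_correlation(x, flat)$defined)
  expect_error(change_correlation(x[1:2], y[1:2]), "3")
})
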