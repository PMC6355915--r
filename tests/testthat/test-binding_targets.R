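make_peaks <- function(contig, summit, fold, name = NULL) {
  df <- data.frame(name = if (is.null(name)) paste0("p", seq_along(summit))
                   else name,
                   contig = contig, start = summit - 100, end = summit + 100,
                   summit = summit, fold_enrichment = fold,
                   stringsAsFactors = FALSE)
  class(df) <- c("peak_calls", "data.frame")
  df
}

test_that("peak assignment applies the fold cutoff and nearest-TSS rule", {
  genes <- gene_models(c("gA", "gB"), c("chr1", "chr1"), c("+", "+"),
                       c(800, 5000), c(3000, 9000))
  # sub-cutoff peak dropped
  bs <- assign_peaks_to_genes(make_peaks("chr1", 1000, 1.9), genes)
  expect_length(bs$gene_ids, 0)
  # summit 1000: distances 200 vs 4000 -> gA
  bs2 <- assign_peaks_to_genes(make_peaks("chr1", 1000, 2.5), genes)
  expect_equal(bs2$gene_ids, "gA")
  # equidistant summit 2900: both genes receive the peak
  bs3 <- assign_peaks_to_genes(make_peaks("chr1", 2900, 2.5), genes)
  expect_setequal(bs3$gene_ids, c("gA", "gB"))
  # peak on an unannotated contig is tallied, not assigned
  expect_message(
    bs4 <- assign_peaks_to_genes(make_peaks("chr9", 1000, 2.5), genes),
    "unassigned")
  expect_length(bs4$gene_ids, 0)
  expect_length(attr(bs4, "unassigned"), 1)
})

test_that("random peak assignment equals the exhaustive nearest-TSS oracle", {
  set.seed(61)
  n_genes <- 80
  starts <- sort(sample(0:500000, n_genes))
  genes <- gene_models(sprintf("g%03d", 1:n_genes), rep("chr1", n_genes),
                       sample(c("+", "-"), n_genes, replace = TRUE),
                       starts, starts + 1000)
  summits <- sample(0:501000, 100)
  peaks <- make_peaks("chr1", summits, runif(100, 2, 9))
  bs <- assign_peaks_to_genes(peaks, genes)
  tsses <- vapply(genes$tss, `[`, numeric(1), 1)
  oracle <- lapply(summits, function(s) {
    d <- abs(s - tsses)
    genes$gene_id[d == min(d)]
  })
  oracle_map <- list()
  for (i in seq_along(summits)) {
    for (g in oracle[[i]]) {
      oracle_map[[g]] <- c(oracle_map[[g]], peaks$name[i])
    }
  }
  expect_setequal(bs$gene_ids, names(oracle_map))
  for (g in bs$gene_ids) {
    expect_setequal(bs$provenance[[g]], oracle_map[[g]])
  }
})

test_that("bound-set intersection is exact, order-invariant, idempotent", {
  s1 <- bound_set("x", c("A", "B"))
  s2 <- bound_set("y", c("B", "C"))
  s3 <- bound_set("z", "B")
  res <- intersect_bound(list(s1, s2, s3))
  expect_equal(res$intersection$gene_ids, "B")
  expect_equal(res$n_union, 3)
  # identical sets: full overlap
  same <- intersect_bound(list(s1, s1))
  expect_setequal(same$intersection$gene_ids, c("A", "B"))
  expect_equal(same$union_fraction, 1)
  # random sets against brute-force enumeration; order invariance
  set.seed(62)
  pool <- sprintf("g%03d", 1:60)
  sets <- lapply(1:3, function(i) bound_set(paste0("s", i),
                                            sample(pool, 30)))
  res_a <- intersect_bound(sets)
  res_b <- intersect_bound(rev(sets))
  brute <- pool[vapply(pool, function(g) {
    all(vapply(sets, function(s) g %in% s$gene_ids, logical(1)))
  }, logical(1))]
  expect_setequal(res_a$intersection$gene_ids, brute)
  expect_setequal(res_b$intersection$gene_ids, brute)
  # idempotent on duplicated inputs
  dup <- intersect_bound(c(sets, sets[1]))
  expect_setequal(dup$intersection$gene_ids, brute)
})

test_that("class enrichment reproduces the hypergeometric oracle", {
  # perfectly proportional table -> odds ratio 1, p = 1
  universe <- sprintf("g%02d", 1:40)
  classes <- setNames(rep(c("in", "out"), each = 20), universe)
  bound <- bound_set("b", c(universe[1:5], universe[21:25]))
  res <- class_enrichment(bound, classes, universe)
  row_in <- res[res$class == "in", ]
  expect_equal(row_in$p_value, 1)
  expect_equal(row_in$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(row_in$pct_of_bound, 50)
  expect_equal(row_in$pct_of_universe, 50)

  # diagonal table [[5,0],[0,5]] -> two-sided p = 1/126
  u10 <- sprintf("u%02d", 1:10)
  cls10 <- setNames(rep(c("in", "out"), each = 5), u10)
  b10 <- bound_set("b", u10[1:5])
  res10 <- class_enrichment(b10, cls10, u10)
  expect_equal(res10$p_value[res10$class == "in"], 1 / 126,
               tolerance = 1e-12)
  expect_equal(res10$p_value[res10$class == "in"],
               fisher_p_oracle(5, 0, 0, 5), tolerance = 1e-12)

  # reciprocal odds ratios on a two-class partition
  set.seed(63)
  bnd <- bound_set("b", sample(universe, 12))
  r2 <- class_enrichment(bnd, classes, universe)
  expect_equal(r2$odds_ratio[1], 1 / r2$odds_ratio[2], tolerance = 1e-6)
  expect_error(class_enrichment(bnd, classes[-1], universe), "class")
})

test_that("random 2x2 tables match the enumeration oracle through the API", {
  set.seed(64)
  for (iter in 1:40) {
    n <- sample(4:20, 1)
    ids <- sprintf("t%02d", 1:n)
    n_in <- sample(1:(n - 1), 1)
    n_b <- sample(1:(n - 1), 1)
    cls <- setNames(c(rep("in", n_in), rep("out", n - n_in)), ids)
    bnd <- bound_set("b", sample(ids, n_b))
    res <- class_enrichment(bnd, cls, ids)
    a <- sum(bnd$gene_ids %in% ids[cls == "in"])
    p_oracle <- fisher_p_oracle(a, n_b - a, n_in - a, n - n_in - n_b + a)
    expect_equal(res$p_value[res$class == "in"], p_oracle,
                 tolerance = 1e-9)
  }
})

test_that("pausing-index bound calls use a strict threshold", {
  g <- one_gene("g1", "+", 5000, 9000)
  for (case in list(list(v = 1.4, bound = TRUE),
                    list(v = 1.3, bound = FALSE),
                    list(v = 0, bound = FALSE))) {
    trk <- segment_track(list(list(start = 0, end = 12000, value = case$v)),
                         12000)
    res <- pausing_index_bound(trk, g)
    expect_equal(res$bound, case$bound)
    expect_equal(res$tss_mean_enrichment, case$v)
  }
})

test_that("expressed-gene filtering averages control replicates strictly", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    rep1 = c(1.5, 0.5, 1.0), rep2 = c(0.9, 0.5, 1.0))
  expect_equal(expressed_genes(tab), "a")   # mean 1.2 > 1; 0.5 no; 1.0 strict
  expect_warning(out <- expressed_genes(tab, universe = c("a", "b", "d")),
                 "missing")
  expect_equal(out, "a")
})

test_that("expression quartiles split evenly with lower-quartile ties", {
  tab <- data.frame(gene_id = sprintf("g%d", 1:8), rpkm = 1:8)
  q <- expression_quartiles(tab)
  expect_equal(unname(q), rep(1:4, each = 2))
  # ties spanning the 25th-percentile boundary all stay in the lower quartile
  tab2 <- data.frame(gene_id = sprintf("h%d", 1:8),
                     rpkm = c(1, 2, 2, 4, 5, 6, 7, 8))
  q2 <- expression_quartiles(tab2)
  expect_equal(unname(q2[2:3]), c(1L, 1L))
  set.seed(65)
  n <- 403
  tabr <- data.frame(gene_id = sprintf("r%03d", 1:n), rpkm = rlnorm(n))
  counts <- table(expression_quartiles(tabr))
  expect_true(all(abs(counts - n / 4) <= 1))
  expect_error(expression_quartiles(tab[1:3, ]), "4")
})
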