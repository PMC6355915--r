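# Dense per-base oracle: mean of v over the 0-based half-open window
# [start, end), reading 0 outside the vector. Deliberately naive.
dense_mean <- function(v, start, end) {
  s <- 0
  for (p in (start + 1):end) {
    if (p >= 1 && p <= length(v)) s <- s + v[p]
  }
  s / (end - start)
}

# single-gene annotation helper
one_gene <- function(id = "g1", strand = "+", start = 1000, end = 5000,
                     contig = "chr1", ...) {
  gene_models(id, contig, strand, start, end, ...)
}

# track that is piecewise constant: segments is a list of
# list(start, end, value) on one contig
segment_track <- function(segments, len, contig = "chr1", label = "t") {
  v <- numeric(len)
  for (s in segments) v[(s$start + 1):s$end] <- s$value
  coverage_track(stats::setNames(list(v), contig), label = label)
}

# independent Welch t oracle
welch_t <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# exhaustive two-sample KS D oracle: max ECDF gap over pooled points
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# two-sided Fisher p oracle by hypergeometric enumeration on the 2x2
# table rbind(c(a, b), c(c, d)); sums probabilities <= P(observed)
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + b          # bound genes
  n <- c_ + d         # unbound genes
  k <- a + c_         # genes in class
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
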