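# Strand-aware signal extraction used by all profile code. Downstream
# offsets are positive; for "-" genes offset o maps to base (anchor - 1 - o)
# so plus and minus placements mirror exactly.
anchored_values <- function(track, gene, anchor, upstream, downstream) {
  if (gene$strand == "+") {
    track_values(track, gene$contig, anchor - upstream, anchor + downstream)
  } else {
    rev(track_values(track, gene$contig, anchor - downstream,
                     anchor + upstream))
  }
}

gene_body_values <- function(track, gene, tss) {
  if (gene$strand == "+") {
    track_values(track, gene$contig, tss, gene$tes)
  } else {
    rev(track_values(track, gene$contig, gene$tes, tss))
  }
}

# mean-pool a vector into nb equal-occupancy bins
pool_bins <- function(v, nb) {
  b <- round(seq(0, length(v), length.out = nb + 1))
  vapply(seq_len(nb), function(j) mean(v[(b[j] + 1):b[j + 1]]), numeric(1))
}

profile_from_matrix <- function(m, x, mode, segment = NULL) {
  n <- nrow(m)
  mu <- colMeans(m)
  sem <- if (n > 1) apply(m, 2, stats::sd) / sqrt(n) else rep(0, ncol(m))
  out <- list(x = x, mean = mu, sem = sem, n_genes = n, mode = mode)
  if (!is.null(segment)) out$segment <- segment
  class(out) <- "meta_profile"
  out
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile (%s): %d positions, %d genes\n",
              x$mode, length(x$x), x$n_genes))
  invisible(x)
}

#' Scaled metagene profile
#'
#' Averages signal across genes on a common frame: `upstream` bp before the
#' TSS at base resolution, the gene body rescaled to `n_body_bins` bins by
#' mean pooling over equal-occupancy windows, and `downstream` bp after the
#' TES. The profile mean and the standard error of the mean across genes
#' are reported per position. Strand-aware throughout; flanks running off
#' the covered region read as zero.
#'
#' @param track [coverage_track()] (typically a log2 enrichment track).
#' @param genes [gene_models()] table.
#' @param upstream,downstream Flank widths (bp).
#' @param n_body_bins Number of scaled body bins.
#' @param min_body_length Genes with a shorter TSS-to-TES span are dropped
#'   (default two bp per body bin).
#' @return A `meta_profile`: `x` (position index: negative bp for the 5'
#'   flank, scaled bin index within the body, positive bp past the TES),
#'   `mean`, `sem`, `n_genes`, `segment`.
#' @export
scaled_metagene <- function(track, genes, upstream = 600, downstream = 600,
                            n_body_bins = 100,
                            min_body_length = 2 * n_body_bins) {
  keep <- abs(genes$tes - vapply(genes$tss, `[`, numeric(1), 1)) >=
    min_body_length
  genes <- genes[keep, , drop = FALSE]
  if (!nrow(genes)) stop("empty gene set after length filtering")
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    tss <- g$tss[[1]][1]
    pre <- anchored_values(track, g, tss, upstream, 0)
    body <- pool_bins(gene_body_values(track, g, tss), n_body_bins)
    post <- anchored_values(track, g, g$tes, 0, downstream)
    c(pre, body, post)
  })
  m <- do.call(rbind, rows)
  x <- c(seq(-upstream, -1), seq_len(n_body_bins),
         n_body_bins + seq_len(downstream))
  segment <- rep(c("upstream", "body", "downstream"),
                 c(upstream, n_body_bins, downstream))
  profile_from_matrix(m, x, "scaled", segment)
}

#' TSS-centered profile
#'
#' Per-base average profile in a fixed window around the TSS (no body
#' rescaling), with SEM across genes.
#'
#' @inheritParams scaled_metagene
#' @param halfwidth Window half-width (bp).
#' @return A `meta_profile` with `x` in bp relative to the TSS
#'   (`-halfwidth` to `halfwidth - 1`).
#' @export
tss_centered_profile <- function(track, genes, halfwidth = 1000) {
  if (!nrow(genes)) stop("empty gene set")
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    anchored_values(track, g, g$tss[[1]][1], halfwidth, halfwidth)
  })
  m <- do.call(rbind, rows)
  profile_from_matrix(m, seq(-halfwidth, halfwidth - 1), "tss_centered")
}

#' TSS-centered occupancy heatmap matrix
#'
#' One row per gene, columns binned across a TSS-centered window, rows
#' sorted by decreasing mean of `sort_track` over the TSS window
#' (+/- `sort_halfwidth`), ties broken by gene id.
#'
#' @inheritParams tss_centered_profile
#' @param sort_track Track whose TSS occupancy orders the rows (e.g. Pol II
#'   in the control condition).
#' @param bin_width Column bin width (bp).
#' @param sort_halfwidth Half-width of the sorting window (bp).
#' @return List: `matrix` (genes x positions, rownames = gene ids, colnames
#'   = bin-start offsets), `order` (gene ids, row order), `x` (bin starts).
#' @export
tss_heatmap_matrix <- function(track, genes, sort_track,
                               halfwidth = 1000, bin_width = 10,
                               sort_halfwidth = 250) {
  if (!nrow(genes)) stop("empty gene set")
  nb <- (2 * halfwidth) %/% bin_width
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    v <- anchored_values(track, g, g$tss[[1]][1], halfwidth, halfwidth)
    colMeans(matrix(v[seq_len(nb * bin_width)], nrow = bin_width))
  })
  m <- do.call(rbind, rows)
  key <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    tss <- g$tss[[1]][1]
    track_window_mean(sort_track, g$contig, tss - sort_halfwidth,
                      tss + sort_halfwidth)
  }, numeric(1))
  ord <- order(-key, genes$gene_id)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- genes$gene_id[ord]
  x <- seq(-halfwidth, halfwidth - 1, by = bin_width)
  colnames(m) <- x
  list(matrix = m, order = genes$gene_id[ord], x = x)
}

#' Write a profile as TSV
#' @param profile A `meta_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(x = profile$x, mean = signif(profile$mean, 6),
                   sem = signif(profile$sem, 6), n = profile$n_genes)
  if (!is.null(profile$segment)) df$segment <- profile$segment
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
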