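#' Strand-aware TSS and gene-body windows
#'
#' The TSS window spans `tss_halfwidth` bp on either side of the TSS; the
#' gene body runs from `body_offset` bp downstream of the TSS to
#' `body_offset` bp upstream of the TES, both strand-aware. Genes too short
#' to leave a positive-width body window are flagged ineligible rather than
#' raising an error.
#'
#' @param strand `"+"` or `"-"`.
#' @param tss,tes TSS and TES positions (bp, 0-based).
#' @param tss_halfwidth Half-width of the TSS window (bp).
#' @param body_offset Distance trimmed from each end of the TSS-to-TES span
#'   (bp).
#' @return List with `tss_window` and `body_window` (each `c(start, end)`,
#'   half-open) and `eligible`.
#' @export
gene_windows <- function(strand, tss, tes, tss_halfwidth = 250,
                         body_offset = 500) {
  tss_window <- c(tss - tss_halfwidth, tss + tss_halfwidth)
  body_window <- if (strand == "+") {
    c(tss + body_offset, tes - body_offset)
  } else {
    c(tes + body_offset, tss - body_offset)
  }
  list(tss_window = tss_window, body_window = body_window,
       eligible = body_window[2] > body_window[1])
}

#' Select the reference TSS per gene
#'
#' Among a gene's candidate TSS, returns the one with the highest mean
#' signal in the control condition over the +/- `halfwidth` window. Exact
#' ties break to the 5'-most candidate (smallest coordinate on "+", largest
#' on "-").
#'
#' @param gene One-row [gene_models()] slice.
#' @param control_track [coverage_track()] of the control condition.
#' @param halfwidth Window half-width (bp).
#' @return Selected TSS position (bp).
#' @export
select_tss <- function(gene, control_track, halfwidth = 250) {
  cand <- gene$tss[[1]]
  if (length(cand) == 1) return(cand)
  score <- vapply(cand, function(t) {
    track_window_mean(control_track, gene$contig, t - halfwidth, t + halfwidth)
  }, numeric(1))
  pos_rank <- if (gene$strand == "+") cand else -cand
  cand[order(-score, pos_rank)][1]
}

#' Pol II release ratio for one gene
#'
#' PRR = log2(mean body signal / mean TSS-window signal) on a linear-scale
#' track (input-normalized ratio for ChIP, or nascent coverage for 4sU-seq).
#' Window means are floored at `floor` before the ratio; genes whose body
#' window is empty, or whose windows are both at the floor, are ineligible.
#' Low PRR means strong promoter-proximal pausing; high PRR means efficient
#' release into the gene body.
#'
#' @param track Linear-scale [coverage_track()].
#' @param gene One-row [gene_models()] slice.
#' @param tss Selected TSS (see [select_tss()]); default the gene's first.
#' @param floor Positive pseudo-enrichment floor.
#' @param condition Condition label copied into the record.
#' @inheritParams gene_windows
#' @return One-row data.frame: `gene_id`, `condition`, `selected_tss`,
#'   `tss_enrichment`, `body_enrichment`, `prr`, `eligible`, `reason`.
#' @export
compute_prr <- function(track, gene, tss = gene$tss[[1]][1], floor = 0.01,
                        condition = track$label, tss_halfwidth = 250,
                        body_offset = 500) {
  stopifnot(floor > 0)
  w <- gene_windows(gene$strand, tss, gene$tes, tss_halfwidth, body_offset)
  rec <- data.frame(gene_id = gene$gene_id, condition = condition,
                    selected_tss = tss, tss_enrichment = NA_real_,
                    body_enrichment = NA_real_, prr = NA_real_,
                    eligible = FALSE, reason = "", stringsAsFactors = FALSE)
  if (!w$eligible) {
    rec$reason <- "short_gene"
    return(rec)
  }
  tss_mean <- track_window_mean(track, gene$contig, w$tss_window[1],
                                w$tss_window[2])
  body_mean <- track_window_mean(track, gene$contig, w$body_window[1],
                                 w$body_window[2])
  rec$tss_enrichment <- tss_mean
  rec$body_enrichment <- body_mean
  if (tss_mean <= floor && body_mean <= floor) {
    rec$reason <- "no_signal"
    return(rec)
  }
  rec$prr <- log2(max(body_mean, floor) / max(tss_mean, floor))
  rec$eligible <- TRUE
  rec
}

#' PRR table for a gene set
#'
#' Applies [select_tss()] (against `control_track`, by default the scored
#' track itself) and [compute_prr()] to every gene.
#'
#' @param track Linear-scale [coverage_track()] to score.
#' @param genes [gene_models()] table.
#' @param control_track Track used for TSS selection.
#' @inheritParams compute_prr
#' @return data.frame with one row per gene (see [compute_prr()]).
#' @export
prr_table <- function(track, genes, control_track = track, floor = 0.01,
                      condition = track$label, tss_halfwidth = 250,
                      body_offset = 500) {
  stopifnot(floor > 0)
  n <- nrow(genes)
  if (all(lengths(genes$tss) == 1)) {    # selection is the identity
    tss <- vapply(genes$tss, `[`, numeric(1), 1)
  } else {
    tss <- vapply(seq_len(n), function(i) {
      select_tss(genes[i, , drop = FALSE], control_track,
                 halfwidth = tss_halfwidth)
    }, numeric(1))
  }
  plus <- genes$strand == "+"
  tss_s <- tss - tss_halfwidth
  tss_e <- tss + tss_halfwidth
  body_s <- ifelse(plus, tss + body_offset, genes$tes + body_offset)
  body_e <- ifelse(plus, genes$tes - body_offset, tss - body_offset)
  eligible <- body_e > body_s
  tss_mean <- body_mean <- rep(NA_real_, n)
  for (ct in unique(genes$contig)) {
    j <- which(genes$contig == ct)
    tss_mean[j] <- track_window_means(track, ct, tss_s[j], tss_e[j])
    jb <- j[eligible[j]]
    if (length(jb)) {
      body_mean[jb] <- track_window_means(track, ct, body_s[jb], body_e[jb])
    }
  }
  no_signal <- eligible & tss_mean <= floor & body_mean <= floor
  prr <- ifelse(eligible & !no_signal,
                log2(pmax(body_mean, floor) / pmax(tss_mean, floor)),
                NA_real_)
  data.frame(gene_id = genes$gene_id, condition = condition,
             selected_tss = tss, tss_enrichment = tss_mean,
             body_enrichment = body_mean, prr = prr,
             eligible = eligible & !no_signal,
             reason = ifelse(!eligible, "short_gene",
                             ifelse(no_signal, "no_signal", "")),
             stringsAsFactors = FALSE)
}

#' Compare PRR distributions between two conditions
#'
#' Two-sample Kolmogorov-Smirnov test on the per-gene PRR values of the two
#' conditions, restricted to genes eligible in both. The asymptotic
#' two-sided p-value is used for n >= 30 per sample, the exact one below.
#'
#' @param records_a,records_b PRR tables from [prr_table()].
#' @return List: `statistic` (KS D), `p_value`, `n` shared genes, `genes`,
#'   `ecdf_a`/`ecdf_b` (functions), `low_power` flag (n < 10, with warning).
#' @export
prr_compare <- function(records_a, records_b) {
  a <- records_a[records_a$eligible, ]
  b <- records_b[records_b$eligible, ]
  shared <- intersect(a$gene_id, b$gene_id)
  xa <- a$prr[match(shared, a$gene_id)]
  xb <- b$prr[match(shared, b$gene_id)]
  low_power <- length(shared) < 10
  if (low_power) {
    warning("fewer than 10 genes eligible in both conditions; ",
            "comparison is low-power")
  }
  exact <- length(xa) < 30 && length(xb) < 30
  kt <- suppressWarnings(stats::ks.test(xa, xb, exact = exact))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(shared), genes = shared,
       ecdf_a = stats::ecdf(xa), ecdf_b = stats::ecdf(xb),
       low_power = low_power)
}

#' Stratify per-gene deltas by reference-value quartile
#'
#' Genes are split at the 25/50/75 percentiles of the reference values (for
#' pausing analyses: control-condition PRR, low to high); values lying
#' exactly on a boundary go to the lower quartile. Returns the per-gene
#' assignment and per-quartile summaries of the deltas.
#'
#' @param reference Named numeric vector (gene -> reference value).
#' @param delta Named numeric vector (gene -> change between conditions).
#' @return List: `assignments` data.frame (`gene_id`, `reference`, `delta`,
#'   `quartile`), `summary` data.frame (`quartile`, `n`, `median`, `iqr`).
#' @export
quartile_stratify <- function(reference, delta) {
  shared <- intersect(names(reference), names(delta))
  if (!length(shared)) stop("no shared gene ids")
  r <- reference[shared]
  d <- delta[shared]
  q <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (diff(range(r)) == 0) {
    warning("constant reference values; all genes assigned to quartile 1")
    quart <- rep(1L, length(r))
  } else {
    quart <- findInterval(r, q, left.open = TRUE) + 1L
  }
  assignments <- data.frame(gene_id = shared, reference = unname(r),
                            delta = unname(d), quartile = quart,
                            stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(sort(unique(quart)), function(k) {
    dk <- d[quart == k]
    data.frame(quartile = k, n = length(dk), median = stats::median(dk),
               iqr = stats::IQR(dk))
  }))
  list(assignments = assignments, summary = summ)
}

#' Stratify per-gene values by largest-intron size class
#'
#' Genes are binned by their largest intron at the supplied breakpoints
#' (value equal to a break goes to the lower class) and a one-way ANOVA is
#' run across the non-empty classes.
#'
#' @param genes [gene_models()] table (provides `largest_intron`).
#' @param values Named numeric vector (gene -> value).
#' @param class_breaks Sorted ascending breakpoints (bp).
#' @return List: `classes` data.frame (`gene_id`, `largest_intron`, `class`,
#'   `value`), `summary` (per class n/median), `anova` (`f`, `p_value`, `df`).
#' @export
intron_class_stratify <- function(genes, values, class_breaks) {
  if (is.unsorted(class_breaks, strictly = TRUE)) {
    stop("class_breaks must be sorted ascending")
  }
  shared <- intersect(genes$gene_id, names(values))
  g <- genes[match(shared, genes$gene_id), ]
  v <- values[shared]
  cls <- findInterval(g$largest_intron, class_breaks, left.open = TRUE) + 1L
  labels <- class_labels(class_breaks)
  classes <- data.frame(gene_id = shared, largest_intron = g$largest_intron,
                        class = labels[cls], value = unname(v),
                        stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_along(labels), function(k) {
    vk <- v[cls == k]
    data.frame(class = labels[k], n = length(vk),
               median = if (length(vk)) stats::median(vk) else NA_real_)
  }))
  occupied <- cls %in% which(tabulate(cls, length(labels)) >= 2)
  aov_res <- list(f = NA_real_, p_value = NA_real_, df = c(NA, NA))
  if (length(unique(cls[occupied])) >= 2) {
    ft <- stats::oneway.test(v[occupied] ~ factor(cls[occupied]),
                             var.equal = TRUE)
    aov_res <- list(f = unname(ft$statistic), p_value = ft$p.value,
                    df = unname(ft$parameter))
  }
  list(classes = classes, summary = summ, anova = aov_res)
}

class_labels <- function(breaks) {
  edges <- c(-Inf, breaks, Inf)
  vapply(seq_len(length(edges) - 1), function(i) {
    lo <- edges[i]; hi <- edges[i + 1]
    if (is.infinite(lo)) paste0("<=", format(hi, scientific = FALSE))
    else if (is.infinite(hi)) paste0(">", format(lo, scientific = FALSE))
    else paste0("(", format(lo, scientific = FALSE), ",",
                format(hi, scientific = FALSE), "]")
  }, character(1))
}

window_for_kind <- function(gene, tss, kind, tss_halfwidth, body_offset) {
  w <- gene_windows(gene$strand, tss, gene$tes, tss_halfwidth, body_offset)
  switch(kind,
         tss = list(win = w$tss_window, eligible = TRUE),
         body = list(win = w$body_window, eligible = w$eligible),
         tes = list(win = c(gene$tes - tss_halfwidth,
                            gene$tes + tss_halfwidth), eligible = TRUE))
}

#' Per-gene window changes with a bound-vs-unbound t-test
#'
#' For each gene, computes the log2 change in mean signal over the chosen
#' window (TSS +/- 250 bp, gene body, or TES +/- 250 bp) between two
#' conditions, then runs a Welch two-sample t-test between genes in
#' `bound_set` and the rest.
#'
#' @param track_a,track_b Linear-scale [coverage_track()] objects
#'   (condition A = reference, e.g. control; B = perturbation).
#' @param genes [gene_models()] table.
#' @param window `"tss"`, `"body"` or `"tes"`.
#' @param bound_set Character vector of gene ids in the bound group.
#' @param floor Positive floor applied to window means before the ratio.
#' @inheritParams gene_windows
#' @return List: `changes` data.frame (`gene_id`, `window`, `log2_change`,
#'   `group`), `test` (`statistic`, `p_value`, `df`, group means) or NULL
#'   with a `diagnostic` when a group is empty.
#' @export
window_change_test <- function(track_a, track_b, genes, window = "tss",
                               bound_set = character(), floor = 0.01,
                               tss_halfwidth = 250, body_offset = 500) {
  window <- match.arg(window, c("tss", "body", "tes"))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    tss <- select_tss(g, track_a, halfwidth = tss_halfwidth)
    wk <- window_for_kind(g, tss, window, tss_halfwidth, body_offset)
    if (!wk$eligible) return(NULL)
    ma <- max(track_window_mean(track_a, g$contig, wk$win[1], wk$win[2]), floor)
    mb <- max(track_window_mean(track_b, g$contig, wk$win[1], wk$win[2]), floor)
    data.frame(gene_id = g$gene_id, window = window,
               log2_change = log2(mb / ma),
               group = if (g$gene_id %in% bound_set) "bound" else "unbound",
               stringsAsFactors = FALSE)
  })
  changes <- do.call(rbind, rows)
  test <- NULL
  diagnostic <- NULL
  xb <- changes$log2_change[changes$group == "bound"]
  xu <- changes$log2_change[changes$group == "unbound"]
  if (length(xb) < 2 || length(xu) < 2) {
    diagnostic <- "a group has fewer than 2 genes; t-test skipped"
  } else if (stats::sd(xb) == 0 && stats::sd(xu) == 0) {
    # degenerate (e.g. identical tracks): no evidence of difference
    test <- list(statistic = 0, p_value = 1, df = NA_real_,
                 mean_bound = mean(xb), mean_unbound = mean(xu))
  } else {
    tt <- stats::t.test(xb, xu)
    test <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), mean_bound = mean(xb),
                 mean_unbound = mean(xu))
  }
  list(changes = changes, test = test, diagnostic = diagnostic)
}

#' Correlation between two sets of per-gene changes
#'
#' Pearson correlation over genes present in both vectors; a highlight set
#' (e.g. pre-EJC-bound genes) is passed through for plotting.
#'
#' @param changes_x,changes_y Named numeric vectors (gene -> change).
#' @param highlight_set Optional character vector of gene ids.
#' @return List: `r`, `p_value`, `n`, `genes`, `highlight` (logical vector),
#'   `defined` (FALSE when either vector has zero variance).
#' @export
change_correlation <- function(changes_x, changes_y,
                               highlight_set = character()) {
  shared <- intersect(names(changes_x), names(changes_y))
  if (length(shared) < 3) stop("need >= 3 shared genes")
  x <- changes_x[shared]
  y <- changes_y[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(shared),
                genes = shared, highlight = shared %in% highlight_set,
                defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(shared),
       genes = shared, highlight = shared %in% highlight_set, defined = TRUE)
}
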