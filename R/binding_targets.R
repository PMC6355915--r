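#' Bound gene sets
#'
#' A `bound_set` records the genes called bound by one factor, with the
#' supporting peak names per gene.
#'
#' @param label Set label (e.g. `"Mago-HA"`).
#' @param gene_ids Character vector of bound genes.
#' @param provenance Named list (gene -> character vector of peak names).
#' @return A `bound_set`.
#' @export
bound_set <- function(label, gene_ids, provenance = list()) {
  structure(list(label = label, gene_ids = unique(as.character(gene_ids)),
                 provenance = provenance),
            class = "bound_set")
}

#' @export
print.bound_set <- function(x, ...) {
  cat(sprintf("bound_set %s: %d genes\n", sQuote(x$label),
              length(x$gene_ids)))
  invisible(x)
}

#' Assign peaks to genes by nearest TSS
#'
#' Peaks below the fold-enrichment cutoff are dropped; each surviving peak
#' is assigned to the gene whose (nearest candidate) TSS is closest to the
#' peak summit, on the same contig. Summits equidistant between two genes
#' are assigned to both. Peaks on contigs with no annotated gene are left
#' unassigned and tallied.
#'
#' @param peaks A `peak_calls` data.frame ([read_narrowpeak()]).
#' @param genes [gene_models()] table.
#' @param fold_cutoff Minimum fold enrichment retained.
#' @param label Label for the returned set.
#' @return A [bound_set()]; attribute `unassigned` holds the names of peaks
#'   on contigs without genes.
#' @export
assign_peaks_to_genes <- function(peaks, genes, fold_cutoff = 2.0,
                                  label = "bound") {
  peaks <- peaks[peaks$fold_enrichment >= fold_cutoff, , drop = FALSE]
  prov <- list()
  unassigned <- character()
  gene_tss <- lapply(genes$tss, as.numeric)
  for (i in seq_len(nrow(peaks))) {
    on_contig <- which(genes$contig == peaks$contig[i])
    if (!length(on_contig)) {
      unassigned <- c(unassigned, peaks$name[i])
      next
    }
    d <- vapply(on_contig, function(j) {
      min(abs(peaks$summit[i] - gene_tss[[j]]))
    }, numeric(1))
    hits <- genes$gene_id[on_contig[d == min(d)]]
    for (g in hits) prov[[g]] <- c(prov[[g]], peaks$name[i])
  }
  if (length(unassigned)) {
    message(length(unassigned), " peak(s) on contigs without genes ",
            "left unassigned")
  }
  out <- bound_set(label, names(prov), prov)
  attr(out, "unassigned") <- unassigned
  out
}

#' Intersect bound sets
#'
#' The genes bound by every input set (e.g. the pre-EJC bound set as the
#' intersection of Mago-HA, Y14-HA and eIF4AIII-HA targets), plus an overlap
#' report.
#'
#' @param sets List of [bound_set()] objects (>= 2).
#' @param label Label for the intersection set.
#' @return List: `intersection` ([bound_set()]), `pairwise` (count matrix),
#'   `n_union`, `union_fraction` (|intersection| / |union|).
#' @export
intersect_bound <- function(sets, label = "intersection") {
  stopifnot(length(sets) >= 2)
  ids <- lapply(sets, function(s) s$gene_ids)
  inter <- Reduce(intersect, ids)
  uni <- Reduce(union, ids)
  labels <- vapply(sets, function(s) s$label, character(1))
  pw <- outer(seq_along(sets), seq_along(sets),
              Vectorize(function(i, j) length(intersect(ids[[i]], ids[[j]]))))
  dimnames(pw) <- list(labels, labels)
  list(intersection = bound_set(label, inter),
       pairwise = pw, n_union = length(uni),
       union_fraction = if (length(uni)) length(inter) / length(uni) else NA)
}

#' Class enrichment of a bound set (Fisher's exact test)
#'
#' For every class of a partition of the gene universe, tests whether bound
#' genes are over- or under-represented in the class with a two-sided
#' Fisher's exact test on the 2x2 table (bound/unbound x in/out of class),
#' and reports the share of bound genes in the class next to the class's
#' share of the universe.
#'
#' @param bound A [bound_set()] (genes outside the universe are ignored).
#' @param classes Named character vector (gene -> class label) covering the
#'   universe.
#' @param universe Character vector of gene ids (e.g. expressed genes).
#' @return data.frame per class: `class`, `n_class`, `n_bound_in_class`,
#'   `pct_of_bound`, `pct_of_universe`, `odds_ratio`, `p_value`.
#' @export
class_enrichment <- function(bound, classes, universe) {
  if (!all(universe %in% names(classes))) {
    stop("every universe gene must have a class label")
  }
  cls <- classes[universe]
  in_bound <- universe %in% bound$gene_ids
  n_bound <- sum(in_bound)
  out <- lapply(unique(cls), function(k) {
    in_class <- cls == k
    tab <- matrix(c(sum(in_bound & in_class), sum(in_bound & !in_class),
                    sum(!in_bound & in_class), sum(!in_bound & !in_class)),
                  nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(class = k, n_class = sum(in_class),
               n_bound_in_class = tab[1, 1],
               pct_of_bound = if (n_bound) 100 * tab[1, 1] / n_bound else NA,
               pct_of_universe = 100 * sum(in_class) / length(universe),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pausing-index bound calls from TSS enrichment
#'
#' Flags genes whose mean enrichment in the TSS +/- 250 bp window (at the
#' TSS selected against the control condition) exceeds a threshold,
#' strictly. The 1.3 default is the bound-gene criterion used for
#' pausing-index (NELF-style) re-analyses.
#'
#' @param enrichment_track Linear-scale [coverage_track()].
#' @param genes [gene_models()] table.
#' @param threshold Bound if mean enrichment > threshold (strict).
#' @param halfwidth TSS window half-width (bp).
#' @param control_track Track used for TSS selection; defaults to
#'   `enrichment_track`.
#' @return data.frame: `gene_id`, `selected_tss`, `tss_mean_enrichment`,
#'   `bound`.
#' @export
pausing_index_bound <- function(enrichment_track, genes, threshold = 1.3,
                                halfwidth = 250,
                                control_track = enrichment_track) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    tss <- select_tss(g, control_track, halfwidth = halfwidth)
    m <- track_window_mean(enrichment_track, g$contig, tss - halfwidth,
                           tss + halfwidth)
    data.frame(gene_id = g$gene_id, selected_tss = tss,
               tss_mean_enrichment = m, bound = m > threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expressed-gene filter from an RPKM table
#'
#' Genes whose mean RPKM across the control replicates is strictly above
#' the threshold.
#'
#' @param rpkm_table data.frame with a `gene_id` column and one numeric
#'   column per control replicate.
#' @param threshold Expression cutoff (RPKM, strict).
#' @param universe Optional gene ids to evaluate; genes missing from the
#'   table are treated as RPKM 0 with a warning.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(rpkm_table, threshold = 1, universe = NULL) {
  stopifnot("gene_id" %in% names(rpkm_table))
  reps <- rpkm_table[setdiff(names(rpkm_table), "gene_id")]
  avg <- rowMeans(as.matrix(reps))
  names(avg) <- rpkm_table$gene_id
  if (!is.null(universe)) {
    missing <- setdiff(universe, names(avg))
    if (length(missing)) {
      warning(length(missing), " gene(s) missing from the RPKM table; ",
              "treated as 0")
      avg <- c(avg, stats::setNames(rep(0, length(missing)), missing))
    }
    avg <- avg[universe]
  }
  names(avg)[avg > threshold]
}

#' Expression quartiles
#'
#' Splits genes into four groups at the 25/50/75 percentiles of mean RPKM,
#' labeled 1 (low) to 4 (high); values on a boundary go to the lower
#' quartile.
#'
#' @inheritParams expressed_genes
#' @return Named integer vector (gene -> quartile 1..4).
#' @export
expression_quartiles <- function(rpkm_table) {
  stopifnot("gene_id" %in% names(rpkm_table))
  if (nrow(rpkm_table) < 4) stop("need at least 4 genes")
  reps <- rpkm_table[setdiff(names(rpkm_table), "gene_id")]
  avg <- rowMeans(as.matrix(reps))
  q <- stats::quantile(avg, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  stats::setNames(findInterval(avg, q, left.open = TRUE) + 1L,
                  rpkm_table$gene_id)
}
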