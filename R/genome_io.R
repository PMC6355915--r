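#' Gene models
#'
#' A `gene_models` table is a data.frame with one row per gene and columns:
#' `gene_id`, `contig`, `strand` (`"+"`/`"-"`), `start`, `end` (0-based
#' half-open annotation span), `tss` (list column: one or more candidate
#' transcription start sites), `tes` (transcription end site), `exon_starts`
#' / `exon_ends` (list columns of sorted, non-overlapping half-open blocks),
#' `largest_intron` (bp; 0 for single-exon genes) and `length` (span bp).
#'
#' On the minus strand the TSS is the numerically larger coordinate (the
#' half-open end of the span) and the TES the smaller one; every downstream /
#' upstream window in the package is strand-aware around these anchors.
#'
#' @param gene_id Character vector.
#' @param contig Character vector.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param start,end Numeric, 0-based half-open span.
#' @param exon_starts,exon_ends Lists of numeric vectors (half-open blocks);
#'   default single-exon genes spanning `[start, end)`.
#' @param tss Optional list of candidate TSS vectors; default the strand-aware
#'   5' end of the span.
#' @return A `gene_models` data.frame.
#' @export
gene_models <- function(gene_id, contig, strand, start, end,
                        exon_starts = NULL, exon_ends = NULL, tss = NULL) {
  n <- length(gene_id)
  stopifnot(length(contig) == n, length(strand) == n,
            length(start) == n, length(end) == n,
            all(strand %in% c("+", "-")), all(end > start))
  if (is.null(exon_starts)) exon_starts <- as.list(start)
  if (is.null(exon_ends)) exon_ends <- as.list(end)
  if (anyDuplicated(gene_id)) stop("duplicated gene_id")
  li <- numeric(n)
  for (i in seq_len(n)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (length(es) != length(ee) || any(ee <= es)) {
      stop("gene ", gene_id[i], ": malformed exon blocks")
    }
    if (is.unsorted(es, strictly = TRUE) ||
        (length(es) > 1 && any(es[-1] < ee[-length(ee)]))) {
      stop("gene ", gene_id[i], ": exon blocks must be sorted, non-overlapping")
    }
    if (es[1] < start[i] || ee[length(ee)] > end[i]) {
      stop("gene ", gene_id[i], ": exon blocks outside gene span")
    }
    li[i] <- largest_intron_of(es, ee)
  }
  tss_default <- ifelse(strand == "+", start, end)
  if (is.null(tss)) tss <- as.list(tss_default)
  tes <- ifelse(strand == "+", end, start)
  for (i in seq_len(n)) {
    if (strand[i] == "-" && any(tss[[i]] < tes[i])) {
      stop("gene ", gene_id[i], ": minus-strand TSS must be >= TES")
    }
    if (strand[i] == "+" && any(tss[[i]] > tes[i])) {
      stop("gene ", gene_id[i], ": plus-strand TSS must be <= TES")
    }
  }
  df <- data.frame(gene_id = as.character(gene_id), contig = as.character(contig),
                   strand = strand, start = as.numeric(start),
                   end = as.numeric(end), tes = as.numeric(tes),
                   largest_intron = li, length = as.numeric(end - start),
                   stringsAsFactors = FALSE)
  df$tss <- lapply(tss, as.numeric)
  df$exon_starts <- lapply(exon_starts, as.numeric)
  df$exon_ends <- lapply(exon_ends, as.numeric)
  class(df) <- c("gene_models", "data.frame")
  df
}

largest_intron_of <- function(es, ee) {
  if (length(es) < 2) return(0)
  max(es[-1] - ee[-length(ee)])
}

#' Read gene models from BED12 or GTF
#'
#' BED12 records yield one gene per line (one TSS). GTF exons are grouped by
#' `gene_id`; each transcript contributes its strand-aware 5' end to the
#' gene's candidate TSS list, and exon blocks are the per-gene union. GTF
#' coordinates (1-based inclusive) are converted to 0-based half-open at the
#' boundary.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"bed12"` or `"gtf"`.
#' @return A [gene_models()] data.frame.
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "bed12") read_bed12_genes(path) else read_gtf_genes(path)
}

check_field_counts <- function(path, expected, skip_re = "^(track|browser|#)") {
  lines <- readLines(path)
  keep <- !grepl(skip_re, lines) & nzchar(trimws(lines))
  nf <- vapply(strsplit(lines[keep], "[ \t]+"), length, integer(1))
  bad <- which(nf != expected)
  if (length(bad)) {
    stop(sprintf("%s: line %d has %d fields (expected %d)",
                 path, which(keep)[bad[1]], nf[bad[1]], expected))
  }
  invisible(sum(keep))
}

read_bed12_genes <- function(path) {
  check_field_counts(path, 12)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("failed to parse BED12 ", path, ": ",
                                          conditionMessage(e)))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop(path, ": gene records must be stranded")
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  blocks <- gr$blocks   # 1-based, relative to gene start
  es <- ee <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    b <- blocks[[i]]
    es[[i]] <- start0[i] + (IRanges::start(b) - 1)
    ee[[i]] <- start0[i] + IRanges::end(b)
    if (max(ee[[i]]) > end0[i]) {
      stop(path, ": record ", i, " (", gr$name[i],
           "): blockSizes/blockStarts extend past chromEnd")
    }
  }
  gene_models(gene_id = gr$name,
              contig = as.character(GenomicRanges::seqnames(gr)),
              strand = strand, start = start0, end = end0,
              exon_starts = es, exon_ends = ee)
}

read_gtf_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF ", path, ": ",
                                          conditionMessage(e)))
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop(path, ": no exon features found")
  if (is.null(ex$gene_id)) stop(path, ": exon features lack gene_id")
  ids <- unique(ex$gene_id)
  n <- length(ids)
  contig <- strand <- character(n)
  start <- end <- numeric(n)
  es <- ee <- tss <- vector("list", n)
  for (i in seq_len(n)) {
    e <- ex[ex$gene_id == ids[i]]
    contig[i] <- as.character(GenomicRanges::seqnames(e))[1]
    strand[i] <- as.character(GenomicRanges::strand(e))[1]
    red <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(e),
                                            GenomicRanges::end(e)))
    es[[i]] <- IRanges::start(red) - 1
    ee[[i]] <- IRanges::end(red)
    start[i] <- min(es[[i]]); end[i] <- max(ee[[i]])
    tx <- if (!is.null(e$transcript_id)) e$transcript_id else "tx1"
    starts5 <- tapply(seq_along(e), tx, function(j) {
      if (strand[i] == "+") min(GenomicRanges::start(e[j])) - 1
      else max(GenomicRanges::end(e[j]))
    })
    tss[[i]] <- sort(unique(as.numeric(starts5)))
  }
  gene_models(gene_id = ids, contig = contig, strand = strand,
              start = start, end = end,
              exon_starts = es, exon_ends = ee, tss = tss)
}

#' Write gene models as BED12
#'
#' @param genes A [gene_models()] table. Only the first (5'-most) TSS is
#'   representable in BED12; the exon structure is written as blocks.
#' @param path Output path.
#' @export
write_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            genes$contig[i], as.integer(genes$start[i]),
            as.integer(genes$end[i]), genes$gene_id[i], genes$strand[i],
            as.integer(genes$start[i]), as.integer(genes$end[i]),
            length(es),
            paste0(as.integer(ee - es), ",", collapse = ""),
            paste0(as.integer(es - genes$start[i]), ",", collapse = ""))
  }, character(1))
  writeLines(lines, path)
}

#' Read a bedGraph coverage track
#'
#' Intervals must be sorted and non-overlapping per contig; uncovered bases
#' read as 0. Values must be non-negative.
#'
#' @param path bedGraph file (4 columns: contig, start, end, value).
#' @param label,assay Metadata attached to the returned track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, label = basename(path), assay = "") {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(coverage_track(list(), label = label, assay = assay))
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop(sprintf("%s: line %d has %d fields (expected 4)",
                 path, idx[bad], nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  ct <- m[, 1]
  s <- suppressWarnings(as.numeric(m[, 2]))
  e <- suppressWarnings(as.numeric(m[, 3]))
  v <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(s) | is.na(e) | is.na(v) | e <= s)[1]
  if (!is.na(bad)) stop(sprintf("%s: line %d is malformed", path, idx[bad]))
  if (any(v < 0)) {
    stop(sprintf("%s: line %d has negative value", path, idx[which(v < 0)[1]]))
  }
  vals <- list()
  for (contig in unique(ct)) {
    i <- which(ct == contig)
    o <- order(s[i])
    si <- s[i][o]; ei <- e[i][o]; vi <- v[i][o]
    if (length(si) > 1 && any(si[-1] < ei[-length(ei)])) {
      stop(sprintf("%s: overlapping intervals on %s", path, contig))
    }
    gaps <- c(si[1], si[-1] - ei[-length(ei)])
    widths <- ei - si
    rv <- as.vector(rbind(0, vi))
    rw <- as.vector(rbind(gaps, widths))
    keep_runs <- rw > 0
    vals[[contig]] <- S4Vectors::Rle(rv[keep_runs], rw[keep_runs])
  }
  coverage_track(vals, label = label, assay = assay)
}

#' Write a track as bedGraph
#'
#' Zero runs are omitted (uncovered bases are implicitly 0), so
#' `read_bedgraph(write_bedgraph(x))` reproduces the signal exactly up to
#' run-length merging of equal adjacent values.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in names(track$values)) {
    r <- track$values[[ct]]
    if (!length(r)) next
    w <- S4Vectors::runLength(r)
    v <- S4Vectors::runValue(r)
    e <- cumsum(w)
    s <- e - w
    nz <- v != 0
    if (!any(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%.17g", ct, as.integer(s[nz]),
                       as.integer(e[nz]), v[nz]), con)
  }
  invisible(path)
}

#' Read ENCODE narrowPeak peak calls
#'
#' @param path 10-column narrowPeak file.
#' @param summit_missing How to place the summit when the offset column is
#'   -1: `"midpoint"` (default) uses the interval midpoint, `"drop"` removes
#'   the record.
#' @return A `peak_calls` data.frame: `name`, `contig`, `start`, `end`
#'   (0-based half-open), `summit`, `fold_enrichment`.
#' @export
read_narrowpeak <- function(path, summit_missing = c("midpoint", "drop")) {
  summit_missing <- match.arg(summit_missing)
  check_field_counts(path, 10)
  extra <- c(signalValue = "numeric", pValue = "numeric",
             qValue = "numeric", peak = "integer")
  gr <- rtracklayer::import(path, format = "bed", extraCols = extra)
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  off <- gr$peak
  if (any(off < -1)) stop(path, ": summit offset must be >= 0 or -1")
  summit <- ifelse(off >= 0, start0 + off, start0 + (end0 - start0) %/% 2)
  df <- data.frame(name = if (!is.null(gr$name)) gr$name else
                     paste0("peak_", seq_along(gr)),
                   contig = as.character(GenomicRanges::seqnames(gr)),
                   start = start0, end = end0, summit = summit,
                   fold_enrichment = gr$signalValue,
                   stringsAsFactors = FALSE)
  if (summit_missing == "drop") df <- df[off >= 0, , drop = FALSE]
  if (any(df$summit < df$start | df$summit >= df$end)) {
    stop(path, ": summit outside peak interval")
  }
  class(df) <- c("peak_calls", "data.frame")
  df
}

#' Write peak calls as narrowPeak
#' @param peaks A `peak_calls` data.frame (see [read_narrowpeak()]).
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.17g\t-1\t-1\t%d",
                   peaks$contig, as.integer(peaks$start),
                   as.integer(peaks$end), peaks$name,
                   as.integer(pmin(1000, round(10 * peaks$fold_enrichment))),
                   peaks$fold_enrichment,
                   as.integer(peaks$summit - peaks$start))
  writeLines(lines, path)
}

#' Read a two-column contig-sizes file
#' @param path TSV with contig name and length.
#' @return Named numeric vector of contig lengths.
#' @export
read_contig_sizes <- function(path) {
  check_field_counts(path, 2)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "size"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$size), df$contig)
}
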