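#' Coverage tracks
#'
#' A `CoverageTrack` holds base-resolution, non-negative signal per contig as
#' run-length encoded vectors ([S4Vectors::Rle]). All coordinates in the
#' package are 0-based half-open (BED convention); queries outside the covered
#' region return 0. Tracks carry a free-text `label` (condition/replicate) and
#' `assay` tag so downstream tables can be annotated.
#'
#' @param values Named list of numeric vectors or [S4Vectors::Rle] objects,
#'   one per contig.
#' @param label Character scalar identifying the library.
#' @param assay Character scalar naming the assay (e.g. `"polII"`, `"input"`).
#' @return An object of class `CoverageTrack`.
#' @examples
#' trk <- coverage_track(list(chr1 = c(0, 0, 2, 2, 2)), label = "ctrl")
#' track_window_mean(trk, "chr1", 0, 5)
#' @export
coverage_track <- function(values = list(), label = "", assay = "") {
  stopifnot(is.list(values))
  if (length(values) && is.null(names(values))) {
    stop("'values' must be a named list (contig -> signal)")
  }
  vals <- lapply(values, function(v) {
    r <- if (inherits(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
    if (length(r) && min(S4Vectors::runValue(r)) < 0) {
      stop("coverage values must be non-negative")
    }
    r
  })
  structure(list(label = label, assay = assay, values = vals),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack", if (nzchar(x$label)) sQuote(x$label) else "",
      if (nzchar(x$assay)) paste0("[", x$assay, "]"), "\n")
  for (ct in names(x$values)) {
    r <- x$values[[ct]]
    cat(sprintf("  %s: %d bp covered, total signal %.4g\n",
                ct, length(r), sum(r)))
  }
  invisible(x)
}

#' @export
is_coverage_track <- function(x) inherits(x, "CoverageTrack")

track_rle <- function(track, contig) {
  r <- track$values[[contig]]
  if (is.null(r)) S4Vectors::Rle(numeric(0)) else r
}

#' Extract per-base signal over an interval
#'
#' Returns the signal over `[start, end)` as a plain numeric vector, padding
#' with zeros beyond the covered region.
#'
#' @param track A [coverage_track()].
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @return Numeric vector of length `end - start`.
#' @export
track_values <- function(track, contig, start, end) {
  stopifnot(end >= start)
  n <- end - start
  out <- numeric(n)
  if (n == 0) return(out)
  r <- track_rle(track, contig)
  lo <- max(start, 0)
  hi <- min(end, length(r))
  if (hi > lo) {
    out[(lo - start + 1):(hi - start)] <-
      as.numeric(S4Vectors::window(r, lo + 1, hi))
  }
  out
}

#' Mean signal over an interval
#'
#' @inheritParams track_values
#' @return Mean signal over `[start, end)`, counting uncovered bases as 0.
#' @export
track_window_mean <- function(track, contig, start, end) {
  stopifnot(end > start)
  r <- track_rle(track, contig)
  lo <- max(start, 0)
  hi <- min(end, length(r))
  s <- if (hi > lo) sum(S4Vectors::window(r, lo + 1, hi)) else 0
  s / (end - start)
}

pad_rle <- function(r, len) {
  if (length(r) < len) c(r, S4Vectors::Rle(0, len - length(r))) else r
}

#' Apply a binary function per base to two tracks
#'
#' Contigs are matched by name (union); the shorter track is zero-padded.
#' Used internally by the calibration/enrichment operations but exported for
#' ad hoc track algebra.
#'
#' @param a,b [coverage_track()] objects.
#' @param f Vectorized function of two numeric (Rle) arguments.
#' @param label,assay Metadata for the result.
#' @return A `CoverageTrack` (values may be negative for e.g. log ratios, so
#'   the result is built without the non-negativity check).
#' @export
track_map2 <- function(a, b, f, label = a$label, assay = a$assay) {
  contigs <- union(names(a$values), names(b$values))
  vals <- lapply(contigs, function(ct) {
    ra <- track_rle(a, ct)
    rb <- track_rle(b, ct)
    len <- max(length(ra), length(rb))
    f(pad_rle(ra, len), pad_rle(rb, len))
  })
  names(vals) <- contigs
  structure(list(label = label, assay = assay, values = vals),
            class = "CoverageTrack")
}

#' Scale a track by a constant
#' @param track A [coverage_track()].
#' @param k Multiplier.
#' @return The scaled track.
#' @export
track_scale <- function(track, k) {
  track$values <- lapply(track$values, function(r) r * k)
  track
}

#' Total signal in a track
#' @param track A [coverage_track()].
#' @return Sum of signal over all contigs.
#' @export
track_total <- function(track) {
  sum(vapply(track$values, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                             S4Vectors::runLength(r)),
             numeric(1)))
}

# Cumulative signal of the first `pos` bases of an Rle (vectorized over
# pos; pos outside [0, length] is clamped). O(runs + length(pos)).
rle_cumsum_at <- function(r, pos) {
  if (!length(r)) return(rep(0, length(pos)))
  rl <- S4Vectors::runLength(r)
  rv <- as.numeric(S4Vectors::runValue(r))
  ends <- cumsum(as.numeric(rl))
  csum <- cumsum(rv * rl)
  pos <- pmax(0, pmin(pos, length(r)))
  i <- findInterval(pos, ends)
  base <- c(0, csum)[i + 1]
  prev_end <- c(0, ends)[i + 1]
  base + (pos - prev_end) * rv[pmin(i + 1, length(rv))]
}

#' Mean signal over many intervals at once
#'
#' Vectorized counterpart of [track_window_mean()]; bases outside the
#' covered region count as 0.
#'
#' @param track A [coverage_track()].
#' @param contig Contig name (scalar).
#' @param starts,ends Parallel vectors of 0-based half-open intervals.
#' @return Numeric vector of window means.
#' @export
track_window_means <- function(track, contig, starts, ends) {
  stopifnot(length(starts) == length(ends), all(ends > starts))
  r <- track_rle(track, contig)
  (rle_cumsum_at(r, ends) - rle_cumsum_at(r, starts)) / (ends - starts)
}

# Replace each bw-wide bin by its mean (last partial bin averaged over its
# actual width). Keeps the Rle representation compact.
bin_rle_means <- function(r, bw) {
  n <- length(r)
  if (n == 0 || bw <= 1) return(r)
  # runs already aligned to the bin grid: every bin is constant already
  if (all(S4Vectors::runLength(r) %% bw == 0)) return(r)
  edges <- unique(c(seq(bw, n, by = bw), n))
  sums <- diff(c(0, rle_cumsum_at(r, edges)))
  widths <- diff(c(0, edges))
  S4Vectors::Rle(sums / widths, widths)
}
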