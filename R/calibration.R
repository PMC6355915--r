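#' Spike-in library statistics
#'
#' Read counts for one library, split by genome of origin: reads mapped to
#' the experimental genome and reads mapped to the foreign spike-in genome
#' added at a fixed fraction of the chromatin. Both IP and input libraries
#' carry such counts and are calibrated alike.
#'
#' @param library_id Character scalar.
#' @param reads_experimental,reads_spikein Non-negative counts.
#' @return A `library_stats` list.
#' @export
library_stats <- function(library_id, reads_experimental, reads_spikein) {
  stopifnot(reads_experimental >= 0, reads_spikein >= 0)
  structure(list(library_id = library_id,
                 reads_experimental = as.numeric(reads_experimental),
                 reads_spikein = as.numeric(reads_spikein)),
            class = "library_stats")
}

#' Read library statistics from TSV
#' @param path TSV with columns library_id, reads_experimental, reads_spikein.
#' @return List of [library_stats()] keyed by library_id.
#' @export
read_library_stats <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("library_id", "reads_experimental", "reads_spikein")
  if (!all(need %in% names(df))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    library_stats(df$library_id[i], df$reads_experimental[i],
                  df$reads_spikein[i])
  })
  stats::setNames(out, df$library_id)
}

#' Spike-in normalization factor
#'
#' The factor is the number of reads mapped to the spike-in (reference)
#' genome per million reads mapped to the experimental genome. At a fixed
#' spike-in chromatin fraction the factor is invariant to sequencing depth
#' but scales inversely with IP efficiency, which is what makes occupancy
#' comparable across conditions after division.
#'
#' @param stats A [library_stats()].
#' @return Numeric scalar: `reads_spikein / (reads_experimental / 1e6)`.
#' @export
spikein_factor <- function(stats) {
  if (stats$reads_experimental <= 0) {
    stop("calibration error: library ", stats$library_id,
         " has no experimental-genome reads")
  }
  if (stats$reads_spikein <= 0) {
    stop("calibration error: library ", stats$library_id,
         " has no spike-in reads (factor undefined)")
  }
  stats$reads_spikein / (stats$reads_experimental / 1e6)
}

#' Calibrate a track by its spike-in factor
#'
#' Divides every signal value by the library's spike-in factor. Applied to
#' IP and input libraries alike before enrichment is computed. Tracks are
#' expected on a per-million-reads (depth-normalized) scale, in which case
#' the calibrated signal is invariant to sequencing depth.
#'
#' @param track A [coverage_track()].
#' @param stats The library's [library_stats()].
#' @return The calibrated track.
#' @export
calibrate_track <- function(track, stats) {
  track_scale(track, 1 / spikein_factor(stats))
}

#' Calibrate a set of libraries onto a common spike-in scale
#'
#' Divides each track by its library's spike-in factor and then multiplies
#' all of them by the geometric mean of the factors. The shared constant
#' leaves every cross-library ratio (and hence enrichment and PRR) exactly
#' as under plain [calibrate_track()], while keeping signal values near
#' their original magnitude so that fixed pseudocounts and floors stated in
#' signal units remain meaningful.
#'
#' @param tracks Named list of [coverage_track()] objects.
#' @param stats Named list of [library_stats()], same names as `tracks`.
#' @return Named list of calibrated tracks.
#' @export
calibrate_libraries <- function(tracks, stats) {
  stopifnot(length(tracks) == length(stats),
            all(names(tracks) %in% names(stats)))
  factors <- vapply(stats[names(tracks)], spikein_factor, numeric(1))
  ref <- exp(mean(log(factors)))
  Map(function(trk, f) track_scale(trk, ref / f), tracks,
      factors[names(tracks)])
}

#' Log2 IP/input enrichment track
#'
#' Per base (or per fixed-width bin), `log2((ip + p) / (input + p))` with a
#' symmetric pseudocount `p`, so the enrichment is finite everywhere and
#' antisymmetric under swapping IP and input. Binning averages both tracks
#' over `bin_width` bases before the ratio.
#'
#' @param ip,input [coverage_track()] objects (calibrated).
#' @param pseudocount Positive floor added to both tracks.
#' @param bin_width Bin size in bp; 1 computes per-base.
#' @return A `CoverageTrack` of log2 ratios (values may be negative).
#' @export
log2_enrichment <- function(ip, input, pseudocount = 0.01, bin_width = 10) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("parameter error: pseudocount must be > 0")
  }
  track_map2(ip, input, function(a, b) {
    if (bin_width > 1) {
      a <- bin_rle_means(a, bin_width)
      b <- bin_rle_means(b, bin_width)
    }
    log2((a + pseudocount) / (b + pseudocount))
  }, label = ip$label, assay = paste0(ip$assay, "_log2fc"))
}

#' Linear ratio of two tracks
#'
#' `(a + p) / (b + p)` per base (or bin); the linear-scale counterpart of
#' [log2_enrichment()], used upstream of window quantification such as
#' K4me3-over-nucleosome normalization or PRR input normalization.
#'
#' @param track_a,track_b [coverage_track()] objects.
#' @inheritParams log2_enrichment
#' @return A `CoverageTrack` of ratios.
#' @export
ratio_normalize <- function(track_a, track_b, pseudocount = 0.01,
                            bin_width = 10) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("parameter error: pseudocount must be > 0")
  }
  track_map2(track_a, track_b, function(a, b) {
    if (bin_width > 1) {
      a <- bin_rle_means(a, bin_width)
      b <- bin_rle_means(b, bin_width)
    }
    (a + pseudocount) / (b + pseudocount)
  }, label = track_a$label, assay = paste0(track_a$assay, "_ratio"))
}
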