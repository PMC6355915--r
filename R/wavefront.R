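#' Bin nascent-RNA signal downstream of a TSS
#'
#' Divides the 20 kb downstream of the TSS (strand-aware) into `n_bins`
#' bins of `bin_width` bp and records the mean signal per bin. Only genes
#' longer than `min_length` (TSS-to-TES distance) are analyzed; bins
#' extending past the TES are masked invalid.
#'
#' @param track [coverage_track()] of nascent signal at one timepoint.
#' @param gene One-row [gene_models()] slice.
#' @param tss TSS to anchor at; default the gene's first.
#' @param bin_width Bin size (bp).
#' @param n_bins Number of bins.
#' @param min_length Minimum TSS-to-TES distance (bp, exclusive).
#' @return List: `gene_id`, `bin_width`, `n_bins`, `values` (strand-oriented,
#'   index 1 at the TSS-proximal bin), `valid` (logical mask), `excluded`,
#'   `reason`.
#' @export
bin_gene_signal <- function(track, gene, tss = gene$tss[[1]][1],
                            bin_width = 100, n_bins = 200,
                            min_length = 10000) {
  span <- abs(gene$tes - tss)
  out <- list(gene_id = gene$gene_id, bin_width = bin_width, n_bins = n_bins,
              values = NULL, valid = NULL, excluded = FALSE, reason = "")
  if (span <= min_length) {
    out$excluded <- TRUE
    out$reason <- "gene_too_short"
    return(out)
  }
  width <- bin_width * n_bins
  if (gene$strand == "+") {
    x <- track_values(track, gene$contig, tss, tss + width)
  } else {
    x <- rev(track_values(track, gene$contig, tss - width, tss))
  }
  out$values <- colMeans(matrix(x, nrow = bin_width))
  # bin i covers [ (i-1)*bw, i*bw ) downstream; valid while inside the gene
  out$valid <- (seq_len(n_bins) * bin_width) <= span
  out
}

# centered rolling mean with shrinking windows at the edges
roll_mean <- function(v, k) {
  n <- length(v)
  h <- (k - 1) %/% 2
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect the transcription wave front in a binned profile
#'
#' After DRB release, nascent signal forms a plateau from the TSS out to the
#' wave front and decays to background beyond it. The profile is smoothed
#' with a centered `smooth_bins` rolling mean and the interior local minima
#' (bins whose smoothed value is at most both neighbours) are enumerated.
#' The most upstream minimum within `tolerance` x (signal range) of the
#' global minimum anchors the background floor downstream of the front; the
#' front itself is then placed at the half-height crossing: walking upstream
#' from that minimum, the first bin whose smoothed signal still lies below
#' the midpoint between floor and peak. The half-height crossing reproduces
#' the plateau/floor boundary of a noiseless step exactly and is an
#' unbiased estimate of a logistic edge's center under Poisson noise.
#'
#' Profiles whose smoothed minimum never falls below half of the smoothed
#' maximum contain no resolved floor: the wave front lies beyond the
#' analyzed window and the gene is flagged.
#'
#' @param binned Output of [bin_gene_signal()].
#' @param smooth_bins Width of the centered rolling mean (bins).
#' @param tolerance Fraction of the smoothed signal range within which a
#'   local minimum counts as "at the floor".
#' @param min_valid_bins Minimum number of valid bins required.
#' @return List: `front` (bp downstream of the TSS, at the bin center; NA if
#'   undefined), `front_bin`, `flag` (`"ok"`, `"flat"`, `"no_minimum"`,
#'   `"front_beyond_window"`, `"too_few_bins"`, or the exclusion reason).
#' @export
detect_wavefront <- function(binned, smooth_bins = 5, tolerance = 0.05,
                             min_valid_bins = 20) {
  if (isTRUE(binned$excluded)) {
    return(list(front = NA_real_, front_bin = NA_integer_,
                flag = binned$reason))
  }
  undefined <- function(flag) list(front = NA_real_,
                                   front_bin = NA_integer_, flag = flag)
  v <- binned$values[binned$valid]
  n <- length(v)
  if (n < min_valid_bins) return(undefined("too_few_bins"))
  s <- roll_mean(v, smooth_bins)
  rng <- max(s) - min(s)
  if (rng == 0) return(undefined("flat"))
  if (min(s) > 0.5 * max(s)) return(undefined("front_beyond_window"))
  # scale-free signal in [0, 1]; eps keeps threshold comparisons stable
  # under multiplication of the profile by a positive constant
  u <- (s - min(s)) / rng
  eps <- 1e-9
  interior <- 2:(n - 1)
  is_min <- s[interior] <= s[interior - 1] & s[interior] <= s[interior + 1]
  minima <- interior[is_min]
  qualifying <- minima[u[minima] <= tolerance + eps]
  if (!length(qualifying)) return(undefined("no_minimum"))
  front_bin <- min(qualifying)
  while (front_bin > 1 && u[front_bin - 1] <= 0.5 + eps) {
    front_bin <- front_bin - 1L
  }
  front <- (front_bin - 1) * binned$bin_width + binned$bin_width / 2
  list(front = front, front_bin = front_bin, flag = "ok")
}

#' Elongation rate from a pair of wave fronts
#'
#' The distance covered by the wave front between the two timepoints divided
#' by the elapsed time.
#'
#' @param front_t2,front_t8 Front positions (bp downstream of the TSS) at
#'   the earlier and later timepoint.
#' @param interval Elapsed time between them (minutes).
#' @return Rate in bp/min; NA if either front is undefined or the later
#'   front lies upstream of the earlier one (regressed front).
#' @export
elongation_rate <- function(front_t2, front_t8, interval = 6) {
  if (is.na(front_t2) || is.na(front_t8) || front_t8 < front_t2) {
    return(NA_real_)
  }
  (front_t8 - front_t2) / interval
}

#' Genome-wide elongation rates from a DRB/4sU timepoint pair
#'
#' Bins each eligible gene (longer than 10 kb) at both timepoints, detects
#' both wave fronts, and derives the per-gene rate. Genes whose fronts are
#' undefined or regress between timepoints are flagged and excluded from the
#' summary.
#'
#' @param track_t2,track_t8 Nascent-signal [coverage_track()]s at the two
#'   timepoints after DRB removal.
#' @param genes [gene_models()] table.
#' @param interval Minutes between the timepoints.
#' @inheritParams bin_gene_signal
#' @inheritParams detect_wavefront
#' @return List: `rates` data.frame (`gene_id`, `front_t2_bp`, `front_t8_bp`,
#'   `rate_bp_per_min`, `flag`), `mean_rate`, `median_rate`, `n_ok`,
#'   `fraction_flagged`.
#' @export
genomewide_rates <- function(track_t2, track_t8, genes, interval = 6,
                             bin_width = 100, n_bins = 200,
                             min_length = 10000, smooth_bins = 5,
                             tolerance = 0.05) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    b2 <- bin_gene_signal(track_t2, g, bin_width = bin_width,
                          n_bins = n_bins, min_length = min_length)
    if (b2$excluded) {
      return(data.frame(gene_id = g$gene_id, front_t2_bp = NA_real_,
                        front_t8_bp = NA_real_, rate_bp_per_min = NA_real_,
                        flag = b2$reason, stringsAsFactors = FALSE))
    }
    b8 <- bin_gene_signal(track_t8, g, bin_width = bin_width,
                          n_bins = n_bins, min_length = min_length)
    f2 <- detect_wavefront(b2, smooth_bins = smooth_bins,
                           tolerance = tolerance)
    f8 <- detect_wavefront(b8, smooth_bins = smooth_bins,
                           tolerance = tolerance)
    flag <- if (f2$flag != "ok") paste0("t2_", f2$flag)
            else if (f8$flag != "ok") paste0("t8_", f8$flag)
            else if (f8$front < f2$front) "regressed_front"
            else "ok"
    data.frame(gene_id = g$gene_id, front_t2_bp = f2$front,
               front_t8_bp = f8$front,
               rate_bp_per_min = elongation_rate(f2$front, f8$front, interval),
               flag = flag, stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, rows)
  if (!any(rates$flag == "ok")) stop("no eligible genes with defined fronts")
  ok <- rates$rate_bp_per_min[rates$flag == "ok"]
  list(rates = rates, mean_rate = mean(ok), median_rate = stats::median(ok),
       n_ok = length(ok), fraction_flagged = mean(rates$flag != "ok"))
}

#' Compare per-gene elongation rates between two conditions
#'
#' Welch two-sample t-test on the per-gene rates of two [genomewide_rates()]
#' results, restricted to genes with a defined rate in both. Fronts are
#' resolved to bin centers, so per-gene rates are quantized (to
#' bin_width / interval); when both samples are constant at the same value
#' the difference is below the method's resolution and the comparison
#' reports no difference rather than failing.
#'
#' @param rates_a,rates_b Results of [genomewide_rates()].
#' @return List: `statistic`, `p_value`, `n`, `mean_a`, `mean_b`.
#' @export
compare_rates <- function(rates_a, rates_b) {
  a <- rates_a$rates[rates_a$rates$flag == "ok", ]
  b <- rates_b$rates[rates_b$rates$flag == "ok", ]
  shared <- intersect(a$gene_id, b$gene_id)
  xa <- a$rate_bp_per_min[match(shared, a$gene_id)]
  xb <- b$rate_bp_per_min[match(shared, b$gene_id)]
  tt <- tryCatch(stats::t.test(xa, xb), error = function(e) NULL)
  if (is.null(tt)) {     # (near-)constant samples: below rate resolution
    same <- isTRUE(all.equal(mean(xa), mean(xb)))
    return(list(statistic = if (same) 0 else NA_real_,
                p_value = if (same) 1 else NA_real_,
                n = length(shared), mean_a = mean(xa), mean_b = mean(xb)))
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       n = length(shared), mean_a = mean(xa), mean_b = mean(xb))
}
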