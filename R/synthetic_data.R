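#' Simulation configuration
#'
#' Defaults emulate the assays the estimators consume: a compact genome of
#' non-overlapping, strand-randomized genes with log-normal lengths and
#' intron sizes; Pol II ChIP structure of a promoter-proximal Gaussian peak
#' over a gene-body plateau with flat input and Poisson count noise on
#' 10 bp bins; spike-in read fractions; and a DRB/4sU timecourse whose
#' nascent-signal wave front advances at 1 kb/min (the elongation rate
#' reported for Drosophila S2 cells) sampled at 0/2/8/16 min after DRB
#' removal.
#'
#' @param n_genes Number of genes.
#' @param genome_length Contig length (bp).
#' @param seed Integer seed; a fixed seed makes every `simulate_*` output
#'   byte-identical.
#' @param pause_strength Promoter Gaussian peak height (counts/bp); may be a
#'   named vector keyed by condition.
#' @param body_level Gene-body plateau (counts/bp).
#' @param background ChIP background (counts/bp).
#' @param input_level Flat input coverage (counts/bp).
#' @param peak_sd Promoter peak width (Gaussian sd, bp).
#' @param spike_fraction Spike-in read fraction of `depth`.
#' @param depth Expected experimental-genome read count used for the
#'   spike-in bookkeeping and depth scaling (`depth / 1e6` multiplies the
#'   expected coverage).
#' @param elongation_rate Wave-front speed (bp/min); may be named per
#'   condition.
#' @param timepoints Minutes after DRB removal.
#' @param plateau Nascent-signal plateau behind the wave front (counts/bp).
#' @param drb_background Nascent background beyond the front (counts/bp).
#' @param edge_scale Logistic wave-front edge scale (bp); the transition
#'   spans roughly two 100-bp bins at the default.
#' @param bin_width Count-noise bin size (bp).
#' @param bound_fraction Fraction of genes in the designated bound subset.
#' @param pause_sdlog Log-normal sd of the per-gene pause-strength
#'   multiplier (mean 1, drawn once per gene and shared across conditions,
#'   so conditions differ only by their `pause_strength` scale).
#' @param frac_over_10kb If given, the length distribution's meanlog is set
#'   so this fraction of genes exceeds 10 kb; otherwise `length_meanlog`.
#' @param length_meanlog,length_sdlog Log-normal gene-length parameters
#'   (log bp).
#' @param contig Contig name.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500, genome_length = 2e7, seed = 1,
                       pause_strength = c(control = 16, knockdown = 8),
                       body_level = 2, background = 0.2, input_level = 1,
                       peak_sd = 100, spike_fraction = 0.05, depth = 1e6,
                       elongation_rate = 1000, timepoints = c(0, 2, 8, 16),
                       plateau = 5, drb_background = 0.05, edge_scale = 50,
                       bin_width = 10, bound_fraction = 0.3,
                       pause_sdlog = 0.5,
                       frac_over_10kb = NULL, length_meanlog = 9,
                       length_sdlog = 0.8, contig = "chrS") {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 0, cfg$genome_length > 0, cfg$bin_width >= 1,
            all(cfg$pause_strength >= 0), cfg$body_level >= 0,
            cfg$spike_fraction > 0, cfg$spike_fraction < 1,
            all(cfg$elongation_rate > 0))
  if (!is.null(cfg$frac_over_10kb)) {
    stopifnot(cfg$frac_over_10kb > 0, cfg$frac_over_10kb < 1)
    cfg$length_meanlog <- log(10000) -
      cfg$length_sdlog * stats::qnorm(1 - cfg$frac_over_10kb)
  }
  structure(cfg, class = "sim_config")
}

cond_param <- function(p, condition) {
  if (length(p) == 1 && is.null(names(p))) return(unname(p))
  if (!is.null(names(p)) && condition %in% names(p)) return(unname(p[condition]))
  unname(p[1])
}

# deterministic sub-stream seed for a labelled draw
stream_seed <- function(seed, label) {
  (seed + sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))) %% .Machine$integer.max
}

#' Simulate a gene annotation
#'
#' Genes with log-normal lengths are placed left to right with uniform
#' intergenic gaps and random strands; multi-exon genes get log-normal
#' intron sizes so the largest-intron classes are populated. A fixed
#' fraction of genes is designated "bound" ground truth.
#'
#' @param config A [sim_config()].
#' @return List: `genes` ([gene_models()]), `contig_sizes` (named vector),
#'   `bound_ids` (character).
#' @export
simulate_genes <- function(config) {
  set.seed(stream_seed(config$seed, "genes"))
  n <- config$n_genes
  if (n == 0) {
    return(list(genes = gene_models(character(0), character(0), character(0),
                                    numeric(0), numeric(0)),
                contig_sizes = stats::setNames(config$genome_length,
                                               config$contig),
                bound_ids = character(0)))
  }
  len <- pmax(1000, round(stats::rlnorm(n, config$length_meanlog,
                                        config$length_sdlog)))
  gaps <- round(stats::runif(n, 4000, 8000))
  starts <- 5000 + cumsum(c(0, len[-n] + gaps[-n]))
  ends <- starts + len
  if (ends[n] + 5000 > config$genome_length) {
    stop("infeasible packing: genome_length too small for ", n, " genes (",
         "need >= ", ends[n] + 5000, " bp)")
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  es <- ee <- vector("list", n)
  for (i in seq_len(n)) {
    ni <- stats::rpois(1, 2)
    if (ni == 0 || len[i] < 1500) {
      es[[i]] <- starts[i]; ee[[i]] <- ends[i]
      next
    }
    isz <- pmax(60, round(stats::rlnorm(ni, log(800), 1.1)))
    while (sum(isz) > 0.6 * len[i]) isz <- ceiling(isz / 2)
    ex_total <- len[i] - sum(isz)
    ew <- diff(round(seq(0, ex_total, length.out = ni + 2)))
    ew <- pmax(ew, 1)
    pos <- starts[i]
    s <- e <- numeric(ni + 1)
    for (k in seq_len(ni + 1)) {
      s[k] <- pos
      e[k] <- pos + ew[k]
      pos <- e[k] + if (k <= ni) isz[k] else 0
    }
    e[ni + 1] <- ends[i]   # absorb rounding in the last exon
    es[[i]] <- s; ee[[i]] <- e
  }
  ids <- sprintf("gene%04d", seq_len(n))
  genes <- gene_models(ids, rep(config$contig, n), strand, starts, ends,
                       exon_starts = es, exon_ends = ee)
  bound_ids <- sort(sample(ids, floor(config$bound_fraction * n)))
  pause_mult <- stats::setNames(
    stats::rlnorm(n, -config$pause_sdlog^2 / 2, config$pause_sdlog), ids)
  list(genes = genes,
       contig_sizes = stats::setNames(config$genome_length, config$contig),
       bound_ids = bound_ids, pause_mult = pause_mult)
}

# strand-aware gene span extended promoter_pad bp upstream of the TSS, so
# promoter-proximal plateau coverage fills the whole TSS window
padded_span <- function(gene, promoter_pad = 250) {
  if (gene$strand == "+") c(gene$start - promoter_pad, gene$end)
  else c(gene$start, gene$end + promoter_pad)
}

# bins whose center (k - 0.5) * bw falls in [a, b), clamped to [1, nb]
bins_in <- function(a, b, bw, nb) {
  k1 <- max(1L, ceiling(a / bw + 0.5))
  k2 <- min(nb, ceiling(b / bw + 0.5) - 1)
  if (k2 < k1) integer(0) else k1:k2
}

# Expected coverage (counts/bp) on the bin grid for a ChIP library. The
# body plateau extends 250 bp upstream of the TSS (promoter occupancy), so
# with pause = 0 the TSS-window and body expectations coincide.
chip_expectation <- function(genes, config, pause, pause_mult) {
  bw <- config$bin_width
  nb <- ceiling(config$genome_length / bw)
  lambda <- rep(config$background, nb)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, , drop = FALSE]
    span <- padded_span(g)
    idx <- bins_in(span[1], span[2], bw, nb)
    lambda[idx] <- lambda[idx] + config$body_level
    tss <- g$tss[[1]][1]
    w <- bins_in(tss - 6 * config$peak_sd, tss + 6 * config$peak_sd, bw, nb)
    centers_w <- (w - 0.5) * bw
    lambda[w] <- lambda[w] + pause * pause_mult[i] *
      exp(-(centers_w - tss)^2 / (2 * config$peak_sd^2))
  }
  lambda
}

poisson_track <- function(lambda, config, label, assay, normalize) {
  bw <- config$bin_width
  scale <- config$depth / 1e6
  counts <- stats::rpois(length(lambda), lambda * bw * scale)
  total <- sum(counts)
  vals <- counts / bw
  if (normalize == "rpm" && total > 0) vals <- vals * 1e6 / total
  r <- S4Vectors::Rle(vals)              # merges equal adjacent bins
  S4Vectors::runLength(r) <- S4Vectors::runLength(r) * bw
  if (length(r) > config$genome_length) {
    r <- S4Vectors::window(r, 1, config$genome_length)
  }
  trk <- structure(list(label = label, assay = assay,
                        values = stats::setNames(list(r), config$contig)),
                   class = "CoverageTrack")
  list(track = trk, total = total)
}

# Mean of the expectation profile over [a, b); vectorized over genes.
# span is a 2-column matrix (plateau region, promoter-padded).
window_expectation <- function(a, b, span, tss, config, pause) {
  width <- b - a
  body_frac <- pmax(0, pmin(b, span[, 2]) - pmax(a, span[, 1])) / width
  gauss <- pause * config$peak_sd * sqrt(2 * pi) *
    (stats::pnorm((b - tss) / config$peak_sd) -
       stats::pnorm((a - tss) / config$peak_sd)) / width
  config$background + config$body_level * body_frac + gauss
}

#' Simulate a spike-in ChIP experiment for one condition
#'
#' Expected IP coverage is `pause_strength x Gaussian(TSS, peak_sd)` plus a
#' `body_level` plateau over each gene span plus background; the input is
#' flat. Counts are Poisson per `bin_width` bin and tracks are emitted on
#' the per-million-reads scale by default (`normalize = "counts"` keeps raw
#' counts/bp for expectation checks). Spike-in reads are drawn Poisson with
#' mean `spike_fraction x depth`. The truth table carries each gene's
#' expected PRR computed analytically from the expectation profile.
#'
#' @param sim Result of [simulate_genes()] (or a bare [gene_models()] table,
#'   in which case all per-gene pause multipliers are 1).
#' @param config A [sim_config()].
#' @param condition Condition label (selects `pause_strength` when named).
#' @param normalize `"rpm"` or `"counts"`.
#' @return List: `ip`, `input` ([coverage_track()]s), `stats_ip`,
#'   `stats_input` ([library_stats()]), `truth` (data.frame `gene_id`,
#'   `expected_tss`, `expected_body`, `expected_prr`).
#' @export
simulate_chip <- function(sim, config, condition = "control",
                          normalize = c("rpm", "counts")) {
  normalize <- match.arg(normalize)
  if (inherits(sim, "gene_models")) {
    sim <- list(genes = sim,
                pause_mult = stats::setNames(rep(1, nrow(sim)), sim$gene_id))
  }
  genes <- sim$genes
  pause_mult <- sim$pause_mult[genes$gene_id]
  set.seed(stream_seed(config$seed, paste0("chip_", condition)))
  pause <- cond_param(config$pause_strength, condition)
  if (config$depth * config$body_level < 10 * nrow(genes)) {
    warning("depth may be too low for ", nrow(genes), " genes")
  }
  lam_ip <- chip_expectation(genes, config, pause, pause_mult)
  ip <- poisson_track(lam_ip, config, paste0(condition, "_ip"), "chip",
                      normalize)
  lam_in <- rep(config$input_level, length(lam_ip))
  inp <- poisson_track(lam_in, config, paste0(condition, "_input"), "input",
                       normalize)
  spike_ip <- stats::rpois(1, config$spike_fraction * config$depth)
  spike_in <- stats::rpois(1, config$spike_fraction * config$depth)
  tss <- vapply(genes$tss, `[`, numeric(1), 1)
  plus <- genes$strand == "+"
  span_lo <- ifelse(plus, genes$start - 250, genes$start)
  span_hi <- ifelse(plus, genes$end, genes$end + 250)
  body_s <- ifelse(plus, tss + 500, genes$tes + 500)
  body_e <- ifelse(plus, genes$tes - 500, tss - 500)
  eligible <- body_e > body_s
  p_g <- pause * pause_mult
  et <- window_expectation(tss - 250, tss + 250, cbind(span_lo, span_hi),
                           tss, config, p_g)
  eb <- ifelse(eligible,
               window_expectation(body_s, pmax(body_e, body_s + 1),
                                  cbind(span_lo, span_hi), tss, config, p_g),
               NA_real_)
  truth <- data.frame(gene_id = genes$gene_id, expected_tss = et,
                      expected_body = eb, expected_prr = log2(eb / et),
                      stringsAsFactors = FALSE)
  list(ip = ip$track, input = inp$track,
       stats_ip = library_stats(paste0(condition, "_ip"), ip$total, spike_ip),
       stats_input = library_stats(paste0(condition, "_input"), inp$total,
                                   spike_in),
       truth = truth)
}

#' Simulate a DRB/4sU nascent-RNA timecourse
#'
#' At `t` minutes after DRB removal the expected nascent signal over each
#' gene is a `plateau` from the TSS out to `elongation_rate x t` bp
#' downstream, decaying to background through a logistic edge of scale
#' `edge_scale`; Poisson counts per bin. The truth table records the
#' constructed front per gene and timepoint.
#'
#' @inheritParams simulate_chip
#' @param max_extent Maximum downstream extent modelled per gene (bp).
#' @return List: `tracks` (named `"t0" ...` by timepoint), `truth`
#'   (data.frame `gene_id`, `timepoint`, `front`).
#' @export
simulate_drb_timecourse <- function(genes, config, condition = "control",
                                    max_extent = 20000) {
  if (!length(config$timepoints)) stop("timepoint list is empty")
  rate <- cond_param(config$elongation_rate, condition)
  bw <- config$bin_width
  nb <- ceiling(config$genome_length / bw)
  tracks <- list()
  truth <- list()
  for (t in config$timepoints) {
    set.seed(stream_seed(config$seed, paste0("drb_", condition, "_", t)))
    lambda <- rep(config$drb_background, nb)
    for (i in seq_len(nrow(genes))) {
      g_tss <- genes$tss[[i]][1]
      extent <- min(max_extent, abs(genes$tes[i] - g_tss))
      if (genes$strand[i] == "+") {
        idx <- bins_in(g_tss, g_tss + extent, bw, nb)
        d <- (idx - 0.5) * bw - g_tss
      } else {
        idx <- bins_in(g_tss - extent, g_tss, bw, nb)
        d <- g_tss - (idx - 0.5) * bw
      }
      lambda[idx] <- lambda[idx] +
        config$plateau * stats::plogis(-(d - rate * t) / config$edge_scale)
    }
    tp <- poisson_track(lambda, config, paste0(condition, "_t", t), "4sU",
                        normalize = "counts")
    tracks[[paste0("t", t)]] <- tp$track
    truth[[paste0("t", t)]] <-
      data.frame(gene_id = genes$gene_id, timepoint = t,
                 front = pmin(rate * t, max_extent),
                 stringsAsFactors = FALSE)
  }
  list(tracks = tracks, truth = do.call(rbind, truth))
}

#' Simulate narrowPeak calls over a bound subset
#'
#' One peak per bound gene with the summit jittered around the TSS and fold
#' enrichment above the 2.0 cutoff, plus optional decoy peaks (below the
#' cutoff) at unbound genes.
#'
#' @param genes [gene_models()] table.
#' @param bound_subset Gene ids receiving true peaks.
#' @param config A [sim_config()].
#' @param summit_sd Summit jitter around the TSS (bp).
#' @param n_decoys Number of sub-cutoff decoy peaks at unbound genes.
#' @return A `peak_calls` data.frame (see [read_narrowpeak()]).
#' @export
simulate_peaks <- function(genes, bound_subset, config, summit_sd = 50,
                           n_decoys = 0) {
  stopifnot(all(bound_subset %in% genes$gene_id))
  set.seed(stream_seed(config$seed, "peaks"))
  make <- function(ids, fold_lo, fold_hi, tag) {
    if (!length(ids)) return(NULL)
    j <- match(ids, genes$gene_id)
    tss <- vapply(genes$tss[j], `[`, numeric(1), 1)
    summit <- round(tss + stats::rnorm(length(ids), 0, summit_sd))
    data.frame(name = paste0(tag, "_", ids),
               contig = genes$contig[j],
               start = summit - 150, end = summit + 150, summit = summit,
               fold_enrichment = stats::runif(length(ids), fold_lo, fold_hi),
               stringsAsFactors = FALSE)
  }
  unbound <- setdiff(genes$gene_id, bound_subset)
  decoy_ids <- if (n_decoys > 0) {
    sample(unbound, min(n_decoys, length(unbound)))
  } else character(0)
  df <- rbind(make(bound_subset, 2.5, 8, "peak"),
              make(decoy_ids, 1.2, 1.9, "decoy"))
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_calls", "data.frame")
  df
}
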