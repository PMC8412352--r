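#' Replicate-consensus peaks
#'
#' Candidate regions are the union of all replicate peaks merged at >= 1 bp
#' overlap; a region is retained when at least
#' `ceiling(min_fraction * n_replicates)` replicates contain a peak
#' overlapping it (default half, e.g. 5 of 10). Retained regions are reported
#' as merged intervals; the matrix stage centers on their midpoints.
#'
#' @param peaksets list (>= 2) of `genomic_intervals`, one per replicate.
#' @param min_fraction minimum supporting fraction of replicates, in (0, 1].
#' @return `genomic_intervals` with a `n_support` column.
#' @export
consensus_peaks <- function(peaksets, min_fraction = 0.5) {
  if (length(peaksets) < 2L) stopf("need >= 2 replicate peak sets")
  if (min_fraction <= 0 || min_fraction > 1) {
    stopf("min_fraction must be in (0, 1]")
  }
  need <- ceiling(min_fraction * length(peaksets))
  all_pk <- do.call(rbind, lapply(peaksets, function(p) {
    as.data.frame(p)[, c("chrom", "start", "end")]
  }))
  if (nrow(all_pk) == 0L) {
    return(genomic_intervals(character(), numeric(), integer(1)[0]))
  }
  out <- NULL
  for (ch in sort(unique(all_pk$chrom))) {
    sub <- all_pk[all_pk$chrom == ch, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1,
                                               end = sub$end))
    support <- rep(0L, length(merged))
    for (p in peaksets) {
      psub <- p[p$chrom == ch, , drop = FALSE]
      if (nrow(psub) == 0L) next
      ir <- IRanges::IRanges(start = psub$start + 1, end = psub$end)
      support <- support +
        (IRanges::countOverlaps(merged, ir, minoverlap = 1L) > 0L)
    }
    keep <- support >= need
    if (!any(keep)) next
    df <- data.frame(chrom = ch,
                     start = IRanges::start(merged)[keep] - 1,
                     end = IRanges::end(merged)[keep],
                     n_support = support[keep])
    out <- rbind(out, df)
  }
  if (is.null(out)) {
    return(genomic_intervals(character(), numeric(), integer(1)[0]))
  }
  res <- genomic_intervals(out$chrom, out$start, out$end,
                           name = sprintf("consensus_%04d",
                                          seq_len(nrow(out))))
  res$n_support <- out$n_support[order(out$chrom, out$start, out$end)]
  res
}

#' Peak-centered coverage matrix
#'
#' For each peak, extracts the `window_bp` region centered on the peak
#' midpoint from a coverage track and averages it into `bin_bp` bins
#' (default 4 kb windows, 10 bp bins -> 400 columns). Windows are snapped to
#' the track's bin grid; peaks whose window leaves the chromosome are
#' dropped with a message.
#'
#' @param track a `coverage_track` at resolution equal to or finer than
#'   `bin_bp` (`bin_bp` must be a multiple of the track bin size).
#' @param peaks `genomic_intervals` of (consensus) peaks.
#' @param window_bp window width (bp), divisible by `bin_bp`.
#' @param bin_bp output bin width (bp).
#' @return peaks x bins matrix; rownames are peak names (or indices),
#'   attribute `peaks` holds the retained peak table.
#' @export
coverage_matrix <- function(track, peaks, window_bp = 4000, bin_bp = 10) {
  tb <- track$bin_size
  if (bin_bp %% tb != 0) {
    stopf("bin_bp (%g) must be a multiple of the track bin size (%g)",
          bin_bp, tb)
  }
  if (window_bp %% bin_bp != 0) {
    stopf("window_bp must be divisible by bin_bp")
  }
  nbin <- window_bp / bin_bp
  k <- bin_bp / tb
  center <- (peaks$start + peaks$end) / 2
  ws <- round((center - window_bp / 2) / tb) * tb
  ok <- ws >= 0 &
    (ws + window_bp) <= track$chrom_lengths[peaks$chrom] &
    peaks$chrom %in% names(track$chrom_lengths)
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    msgf("coverage_matrix: dropping %d peak(s) with out-of-bounds windows",
         sum(!ok))
  }
  peaks <- peaks[ok, , drop = FALSE]
  ws <- ws[ok]
  m <- matrix(NA_real_, nrow = nrow(peaks), ncol = nbin)
  fine_per_window <- window_bp / tb
  for (ch in unique(peaks$chrom)) {
    rows <- which(peaks$chrom == ch)
    v <- track$values[[ch]]
    idx0 <- ws[rows] / tb
    fine_idx <- outer(idx0, seq_len(fine_per_window) - 1L, `+`) + 1L
    fine <- matrix(v[fine_idx], nrow = length(rows))
    if (k == 1) {
      m[rows, ] <- fine
    } else {
      grp <- rep(seq_len(nbin), each = k)
      m[rows, ] <- t(apply(fine, 1L, function(r) tapply(r, grp, mean)))
    }
  }
  rn <- if ("name" %in% names(peaks)) peaks$name else
    as.character(seq_len(nrow(peaks)))
  dimnames(m) <- list(rn, NULL)
  attr(m, "peaks") <- peaks
  attr(m, "window_bp") <- window_bp
  attr(m, "bin_bp") <- bin_bp
  m
}

#' Z-score a matrix by its global mean and SD
#'
#' `(x - global_mean) / global_sd` elementwise, so the output has global mean
#' 0 and SD 1; invariant to positive affine transforms of the input and
#' idempotent.
#'
#' @param m numeric matrix with >= 2 distinct values.
#' @return Z-scored matrix (attributes preserved).
#' @export
zscore_matrix <- function(m) {
  mu <- mean(m)
  s <- stats::sd(as.vector(m))
  if (!is.finite(s) || s == 0) stopf("zero global standard deviation")
  out <- (m - mu) / s
  attributes(out) <- attributes(m)
  out
}

#' Classify peaks as HP1a-proximal by surrounding HP1a signal
#'
#' Ranks peaks by their mean HP1a signal over the `window_bp` window and
#' labels the top `floor(proximal_fraction * n)` as HP1a-proximal (default
#' top decile); ties are broken by genomic order (earlier peak wins), so
#' labels are deterministic. Ranking is invariant to global z-scoring of the
#' HP1a track.
#'
#' @param peaks `genomic_intervals` of peaks.
#' @param hp1a_track HP1a reference `coverage_track` covering all windows.
#' @param window_bp averaging window (bp).
#' @param bin_bp matrix bin width used for the window average.
#' @param proximal_fraction fraction labeled proximal (default 0.10).
#' @return Character vector (`"HP1a_proximal"` / `"non_proximal"`) aligned
#'   with the peaks retained in the window extraction; attribute `peaks`
#'   carries that table, attribute `hp1a_mean` the ranking statistic.
#' @export
classify_hp1a_proximal <- function(peaks, hp1a_track, window_bp = 4000,
                                   bin_bp = 10, proximal_fraction = 0.10) {
  m <- coverage_matrix(hp1a_track, peaks, window_bp = window_bp,
                       bin_bp = bin_bp)
  kept <- attr(m, "peaks")
  score <- rowMeans(m)
  n_prox <- floor(proximal_fraction * nrow(kept))
  ord <- order(-score, kept$chrom, kept$start)
  labels <- rep("non_proximal", nrow(kept))
  if (n_prox > 0) labels[ord[seq_len(n_prox)]] <- "HP1a_proximal"
  names(labels) <- rownames(m)
  attr(labels, "peaks") <- kept
  attr(labels, "hp1a_mean") <- score
  labels
}

#' Central-window statistics per peak and replicate
#'
#' Mean z-score over the central `central_bp` of each peak window (default
#' 200 bp = 20 of 400 bins), per replicate sample; the outcome of the
#' mixed-model stage.
#'
#' @param matrices named list of z-scored peak matrices (one per sample,
#'   identical row sets).
#' @param labels class labels from [classify_hp1a_proximal()] (aligned with
#'   matrix rows).
#' @param genotypes named character vector mapping sample -> genotype.
#' @param central_bp central window width (bp).
#' @return Long data frame `peak`, `sample`, `genotype`, `class`,
#'   `z_central`.
#' @export
central_window_stats <- function(matrices, labels, genotypes,
                                 central_bp = 200) {
  stopifnot(length(matrices) >= 1L, !is.null(names(matrices)))
  bin_bp <- attr(matrices[[1L]], "bin_bp") %||%
    stopf("matrices must carry a bin_bp attribute (use coverage_matrix)")
  if (central_bp %% bin_bp != 0) {
    stopf("central_bp must be divisible by bin_bp")
  }
  nbin <- ncol(matrices[[1L]])
  ncent <- central_bp / bin_bp
  first <- floor(nbin / 2) - floor(ncent / 2) + 1L
  cols <- first:(first + ncent - 1L)
  do.call(rbind, lapply(names(matrices), function(s) {
    m <- matrices[[s]]
    stopifnot(identical(rownames(m), names(labels)))
    data.frame(peak = rownames(m),
               sample = s,
               genotype = unname(genotypes[[s]]),
               class = unname(labels),
               z_central = rowMeans(m[, cols, drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Chromosome-wide replicate-averaged z-scored profile
#'
#' Averages replicate tracks, rebins the mean track into coarse windows
#' (default 50 kb) and z-scores by the global mean and SD across all
#' chromosomes.
#'
#' @param tracks list of replicate `coverage_track`s sharing a genome.
#' @param chromwide_bin_bp coarse bin width (bp).
#' @return A `coverage_track` of z-scored coarse bins.
#' @export
chromwide_profile <- function(tracks, chromwide_bin_bp = 50000) {
  avg <- mean_tracks(tracks)
  coarse <- rebin_track(avg, chromwide_bin_bp)
  all_vals <- unlist(coarse$values, use.names = FALSE)
  mu <- mean(all_vals)
  s <- stats::sd(all_vals)
  if (!is.finite(s) || s == 0) stopf("zero global standard deviation")
  coarse$values <- lapply(coarse$values, function(v) (v - mu) / s)
  coarse
}

#' Chromosome-4 peak-fraction test
#'
#' Per replicate, the percentage of peaks on the (heterochromatic) target
#' chromosome relative to all peaks; the genotype effect on the percentage is
#' tested with an ordinary linear model `pct ~ genotype` (two-sided p on the
#' genotype coefficient).
#'
#' @param peaksets named list of per-replicate `genomic_intervals`.
#' @param genotypes named character vector mapping sample -> genotype
#'   (2 levels, >= 2 replicates each).
#' @param chrom target chromosome (default `"chr4"`).
#' @return List with `percent` (data frame `sample`, `genotype`, `pct`),
#'   `slope` (genotype coefficient, second level minus first), `p`, `fit`.
#' @export
chr4_fraction_test <- function(peaksets, genotypes, chrom = "chr4") {
  pct <- do.call(rbind, lapply(names(peaksets), function(s) {
    p <- peaksets[[s]]
    if (nrow(p) == 0L) {
      warning(sprintf("replicate %s has zero peaks; excluded", s))
      return(NULL)
    }
    data.frame(sample = s, genotype = unname(genotypes[[s]]),
               pct = 100 * sum(p$chrom == chrom) / nrow(p),
               stringsAsFactors = FALSE)
  }))
  if (length(unique(pct$genotype)) != 2L) {
    stopf("need exactly 2 genotypes")
  }
  if (any(table(pct$genotype) < 2L)) stopf("need >= 2 replicates per genotype")
  pct$genotype <- factor(pct$genotype)
  fit <- stats::lm(pct ~ genotype, data = pct)
  # a zero-residual fit warns ("essentially perfect fit"); handled below
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- co[2L, "Estimate"]
  p <- co[2L, "Pr(>|t|)"]
  if (!is.finite(p)) {
    # zero residual variance: identical percentages give an exact fit
    p <- if (abs(slope) < 1e-12) 1 else 0
  }
  list(percent = pct, slope = slope, p = p, fit = fit)
}

#' Heatmap row order: grouped by class, sorted by native central signal
#'
#' Utility for composite heatmaps: rows grouped by HP1a class (proximal
#' first), within class sorted by decreasing mean signal over a central
#' window (default 400 bp) of a reference matrix.
#'
#' @param m z-scored reference peak matrix (e.g. the native-factor ChIP).
#' @param labels class labels aligned with rows.
#' @param central_bp sorting window width (bp).
#' @return Integer row permutation.
#' @export
heatmap_row_order <- function(m, labels, central_bp = 400) {
  bin_bp <- attr(m, "bin_bp") %||% stopf("matrix must carry bin_bp")
  ncent <- central_bp / bin_bp
  nbin <- ncol(m)
  first <- floor(nbin / 2) - floor(ncent / 2) + 1L
  stat <- rowMeans(m[, first:(first + ncent - 1L), drop = FALSE])
  grp <- factor(labels, levels = c("HP1a_proximal", "non_proximal"))
  order(grp, -stat)
}
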