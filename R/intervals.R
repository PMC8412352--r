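#' Genomic interval tables and coverage tracks
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based, half-open, so `end - start` is the length in bp) and optional
#' `name` and `score`. Coverage tracks are fixed-bin vectors per chromosome.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open coordinates, `start < end`.
#' @param name,score optional per-interval annotation.
#' @return A data frame of class `genomic_intervals`, sorted by
#'   (chrom, start).
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1L && length(start) > 1L) {
    chrom <- rep(chrom, length(start))
  }
  if (length(chrom) != length(start) || length(start) != length(end)) {
    stopf("chrom, start and end must have equal length")
  }
  if (any(start < 0)) stopf("interval start must be >= 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stopf("interval start >= end at record %d (%s:%g-%g)",
          bad, chrom[bad], start[bad], end[bad])
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Length of a 1-based inclusive interval
#'
#' Printed genomic coordinates of the form `X:10,481,572-10,491,109` follow
#' the 1-based inclusive convention, so the fragment length is
#' `end - start + 1`. BED-style 0-based half-open lengths are `end - start`;
#' the two conventions are kept as explicit functions, never inferred.
#'
#' @param chrom chromosome name (carried through unused; kept so call sites
#'   read like coordinates).
#' @param start_1b,end_1b 1-based inclusive coordinates, `start_1b <= end_1b`.
#' @return Interval length in bp.
#' @examples
#' interval_length_1based("X", 10481572, 10491109) # 9538
#' @export
interval_length_1based <- function(chrom, start_1b, end_1b) {
  if (start_1b > end_1b) stopf("start_1b > end_1b (%g > %g)", start_1b, end_1b)
  if (start_1b < 1) stopf("1-based coordinates start at 1")
  as.numeric(end_1b) - as.numeric(start_1b) + 1
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' @inheritParams interval_length_1based
#' @return A `genomic_intervals` row with `start = start_1b - 1`,
#'   `end = end_1b`.
#' @export
interval_1based_to_0based <- function(chrom, start_1b, end_1b) {
  if (start_1b > end_1b) stopf("start_1b > end_1b")
  genomic_intervals(chrom, start_1b - 1, end_1b)
}

#' Construct a fixed-bin coverage track
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp.
#' @param values optional named list of per-chromosome value vectors; when
#'   omitted, all-zero bins are created. Vector `i` must have
#'   `ceiling(chrom_lengths[i] / bin_size)` entries.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(chrom_lengths, bin_size, values = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stopf("chrom_lengths must be a named vector")
  }
  assert_scalar_number(bin_size, "bin_size", min = 0, strict_min = TRUE)
  nbins <- ceiling(chrom_lengths / bin_size)
  if (is.null(values)) {
    values <- lapply(nbins, function(n) numeric(n))
  } else {
    if (!setequal(names(values), names(chrom_lengths))) {
      stopf("values must be named by the same chromosomes as chrom_lengths")
    }
    values <- values[names(chrom_lengths)]
    for (ch in names(values)) {
      if (length(values[[ch]]) != nbins[[ch]]) {
        stopf("chromosome %s needs %d bins, got %d",
              ch, nbins[[ch]], length(values[[ch]]))
      }
    }
  }
  structure(list(chrom_lengths = chrom_lengths, bin_size = bin_size,
                 values = values),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosome(s), bin_size = %g bp\n",
              length(x$chrom_lengths), x$bin_size))
  for (ch in names(x$chrom_lengths)) {
    v <- x$values[[ch]]
    cat(sprintf("  %s: %g bp, %d bins, mean %.4g\n",
                ch, x$chrom_lengths[[ch]], length(v), mean(v)))
  }
  invisible(x)
}

#' Rebin a coverage track to coarser bins
#'
#' Averages fine bins into coarse bins, length-weighting the trailing partial
#' bin of each chromosome.
#'
#' @param track a `coverage_track`.
#' @param new_bin_size target bin width in bp; must be a multiple of the
#'   track's bin size.
#' @return A `coverage_track` at the new resolution.
#' @export
rebin_track <- function(track, new_bin_size) {
  bs <- track$bin_size
  if (new_bin_size %% bs != 0) {
    stopf("new bin size (%g) must be a multiple of the track bin size (%g)",
          new_bin_size, bs)
  }
  k <- new_bin_size / bs
  vals <- lapply(names(track$chrom_lengths), function(ch) {
    v <- track$values[[ch]]
    grp <- (seq_along(v) - 1L) %/% k
    as.numeric(tapply(v, grp, mean))
  })
  names(vals) <- names(track$chrom_lengths)
  coverage_track(track$chrom_lengths, new_bin_size, vals)
}

# Mean of each replicate-averaged bin across a list of tracks sharing a genome.
mean_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (!identical(t$chrom_lengths, ref$chrom_lengths) ||
        t$bin_size != ref$bin_size) {
      stopf("tracks must share chrom_lengths and bin_size")
    }
  }
  vals <- lapply(names(ref$chrom_lengths), function(ch) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[ch]])) / length(tracks)
  })
  names(vals) <- names(ref$chrom_lengths)
  coverage_track(ref$chrom_lengths, ref$bin_size, vals)
}
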