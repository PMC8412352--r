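#' Configuration for the synthetic ChIP-seq generator
#'
#' Emulates a two-genotype FLAG-tagged factor ChIP with two planted peak
#' classes. The scaled-down genome keeps the fly karyotype shape with a small
#' heterochromatic chromosome 4; HP1a-proximal peaks are placed
#' preferentially on chr4 (`proximal_chr4_weight`), mimicking their
#' concentration in pericentromeric heterochromatin. The mutant genotype
#' (`dC`) loses coverage amplitude and peak calls specifically at proximal
#' peaks, the synthetic analog of allele-specific loss of HP1a-proximal
#' binding.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_peaks_per_class named vector `c(proximal = , nonproximal = )`.
#' @param peak_width_bp width of the true peak interval; also the SD of the
#'   Gaussian coverage bump, so the 4 kb window mean differs from the 200 bp
#'   central window.
#' @param signal_amplitude named list `genotype -> c(proximal, nonproximal)`
#'   coverage amplitudes at the peak summit.
#' @param hp1a_amplitude named vector `c(proximal = , nonproximal = )` for
#'   the HP1a reference track.
#' @param background_sd per-bin Gaussian background noise SD.
#' @param n_replicates named vector of replicates per genotype.
#' @param bin_size coverage bin width (bp).
#' @param random_intercept_sd SD of the per-sample additive offset.
#' @param dropout named list `genotype -> c(proximal, nonproximal)` per-peak
#'   probability that a replicate peak call misses a true peak.
#' @param proximal_chr4_weight fraction of proximal peaks placed on `chr4`.
#' @param seed integer seed.
#' @return A validated list of class `chip_sim_config`.
#' @export
chip_sim_config <- function(chrom_lengths = c(chr2L = 2.2e6, chr2R = 2.2e6,
                                              chr3L = 2.2e6, chr3R = 2.4e6,
                                              chrX = 2e6, chr4 = 5e5),
                            n_peaks_per_class = c(proximal = 100,
                                                  nonproximal = 900),
                            peak_width_bp = 200,
                            signal_amplitude = list(
                              wt = c(proximal = 3, nonproximal = 3),
                              dC = c(proximal = 1, nonproximal = 3)),
                            hp1a_amplitude = c(proximal = 10,
                                               nonproximal = 1),
                            background_sd = 1,
                            n_replicates = c(wt = 5, dC = 5),
                            bin_size = 10,
                            random_intercept_sd = 0.3,
                            dropout = list(
                              wt = c(proximal = 0.1, nonproximal = 0.1),
                              dC = c(proximal = 0.6, nonproximal = 0.1)),
                            proximal_chr4_weight = 0.6,
                            seed = 1L) {
  if (any(unlist(signal_amplitude) < 0) || any(hp1a_amplitude < 0)) {
    stopf("amplitudes must be >= 0")
  }
  if (!all(names(n_replicates) %in% names(signal_amplitude))) {
    stopf("signal_amplitude must cover every genotype")
  }
  if (!all(c("proximal", "nonproximal") %in% names(n_peaks_per_class))) {
    stopf("n_peaks_per_class needs 'proximal' and 'nonproximal'")
  }
  total_width <- sum(n_peaks_per_class) * peak_width_bp
  if (total_width > 0.5 * sum(chrom_lengths)) {
    stopf("genome too small for the requested peaks")
  }
  structure(list(chrom_lengths = chrom_lengths,
                 n_peaks_per_class = n_peaks_per_class,
                 peak_width_bp = peak_width_bp,
                 signal_amplitude = signal_amplitude,
                 hp1a_amplitude = hp1a_amplitude,
                 background_sd = background_sd,
                 n_replicates = n_replicates,
                 bin_size = bin_size,
                 random_intercept_sd = random_intercept_sd,
                 dropout = dropout,
                 proximal_chr4_weight = proximal_chr4_weight,
                 seed = as.integer(seed)),
            class = "chip_sim_config")
}

# Place non-overlapping peaks; proximal peaks favour chr4 when present.
# Per-chromosome counts are multinomial in the class weights; within a
# chromosome, k non-overlapping width-w intervals are placed uniformly by
# the sequential-gap construction (k sorted uniforms on the slack, plus the
# cumulative occupied width). Returns genomic_intervals with a `class`
# column.
place_peaks <- function(config) {
  chroms <- names(config$chrom_lengths)
  w <- config$peak_width_bp
  n_prox <- config$n_peaks_per_class[["proximal"]]
  n_non <- config$n_peaks_per_class[["nonproximal"]]
  len_weight <- config$chrom_lengths / sum(config$chrom_lengths)
  prox_weight <- len_weight
  if ("chr4" %in% chroms && length(chroms) > 1L && n_prox > 0) {
    others <- chroms != "chr4"
    prox_weight[others] <- (1 - config$proximal_chr4_weight) *
      len_weight[others] / sum(len_weight[others])
    prox_weight["chr4"] <- config$proximal_chr4_weight
  }
  k_prox <- if (n_prox > 0) {
    as.vector(stats::rmultinom(1, n_prox, prox_weight))
  } else {
    integer(length(chroms))
  }
  k_non <- if (n_non > 0) {
    as.vector(stats::rmultinom(1, n_non, len_weight))
  } else {
    integer(length(chroms))
  }
  names(k_prox) <- names(k_non) <- chroms
  # keep summits >= 2 kb from the ends so 4 kb windows stay in bounds
  margin <- max(2000, w)
  rows <- lapply(chroms, function(ch) {
    k <- k_prox[[ch]] + k_non[[ch]]
    if (k == 0L) return(NULL)
    usable <- config$chrom_lengths[[ch]] - 2 * margin
    slack <- usable - k * w
    if (slack <= 0) stopf("genome too small for requested peaks on %s", ch)
    start <- margin + floor(sort(stats::runif(k, 0, slack))) +
      (seq_len(k) - 1L) * w
    cls <- sample(rep(c("proximal", "nonproximal"),
                      c(k_prox[[ch]], k_non[[ch]])))
    data.frame(chrom = ch, start = start, end = start + w, class = cls,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  out <- genomic_intervals(df$chrom, df$start, df$end,
                           name = sprintf("peak_%04d", seq_len(nrow(df))))
  out$class <- df$class[order(df$chrom, df$start, df$end)]
  out
}

# Add a Gaussian bump (summit amplitude `amp`, sd = width) to a per-chrom
# value list at each peak.
add_bumps <- function(values, peaks, amps, chrom_lengths, bin_size, sd_bp) {
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    center <- (peaks$start[i] + peaks$end[i]) / 2
    lo_bin <- max(0L, floor((center - 4 * sd_bp) / bin_size))
    hi_bin <- min(length(values[[ch]]) - 1L,
                  ceiling((center + 4 * sd_bp) / bin_size))
    bins <- lo_bin:hi_bin
    mid <- (bins + 0.5) * bin_size
    values[[ch]][bins + 1L] <- values[[ch]][bins + 1L] +
      amps[i] * exp(-((mid - center)^2) / (2 * sd_bp^2))
  }
  values
}

#' Simulate a two-genotype ChIP-seq experiment with known ground truth
#'
#' Per replicate `r` of genotype `g`, binned coverage is the sum of Gaussian
#' bumps (summit amplitude `signal_amplitude[[g]][class]`, SD =
#' `peak_width_bp`) over the planted peaks, a per-sample random intercept
#' `u_r ~ Normal(0, random_intercept_sd)`, and per-bin
#' `Normal(0, background_sd)` noise. The HP1a reference track is built
#' analogously from `hp1a_amplitude` (no random intercept). Per-replicate
#' peak sets are the true intervals with independent per-peak dropout.
#'
#' @param config a `chip_sim_config`.
#' @return List with `peaks` (truth, incl. `class` column), `peaksets`
#'   (named list of per-replicate `genomic_intervals`), `tracks` (named list
#'   of per-replicate `coverage_track`), `hp1a_track`, `sample_info`
#'   (data frame `sample`, `genotype`, `replicate`) and `ground_truth`.
#' @export
simulate_chip <- function(config) {
  stopifnot(inherits(config, "chip_sim_config"))
  with_seed(config$seed, {
    peaks <- place_peaks(config)
    genotypes <- names(config$n_replicates)
    sample_info <- do.call(rbind, lapply(genotypes, function(g) {
      data.frame(sample = sprintf("%s_r%d", g,
                                  seq_len(config$n_replicates[[g]])),
                 genotype = g,
                 replicate = seq_len(config$n_replicates[[g]]),
                 stringsAsFactors = FALSE)
    }))
    bs <- config$bin_size
    empty_values <- function() {
      lapply(config$chrom_lengths, function(L) numeric(ceiling(L / bs)))
    }
    tracks <- list()
    peaksets <- list()
    for (i in seq_len(nrow(sample_info))) {
      g <- sample_info$genotype[i]
      amps <- config$signal_amplitude[[g]][peaks$class]
      u_r <- stats::rnorm(1, 0, config$random_intercept_sd)
      vals <- empty_values()
      vals <- add_bumps(vals, peaks, amps, config$chrom_lengths, bs,
                        config$peak_width_bp)
      vals <- lapply(vals, function(v) {
        v + u_r + stats::rnorm(length(v), 0, config$background_sd)
      })
      tracks[[sample_info$sample[i]]] <-
        coverage_track(config$chrom_lengths, bs, vals)
      keep <- stats::runif(nrow(peaks)) >=
        config$dropout[[g]][peaks$class]
      kept <- peaks[keep, , drop = FALSE]
      peaksets[[sample_info$sample[i]]] <-
        genomic_intervals(kept$chrom, kept$start, kept$end, name = kept$name)
    }
    hp_amps <- config$hp1a_amplitude[peaks$class]
    hp_vals <- add_bumps(empty_values(), peaks, hp_amps,
                         config$chrom_lengths, bs, config$peak_width_bp)
    hp_vals <- lapply(hp_vals, function(v) {
      v + stats::rnorm(length(v), 0, config$background_sd)
    })
    hp1a_track <- coverage_track(config$chrom_lengths, bs, hp_vals)
    list(peaks = peaks, peaksets = peaksets, tracks = tracks,
         hp1a_track = hp1a_track, sample_info = sample_info,
         ground_truth = list(class = stats::setNames(peaks$class, peaks$name),
                             config = config))
  })
}
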