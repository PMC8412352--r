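# Independent brute-force oracles, deliberately naive implementations.

# Benjamini-Hochberg by the step-up definition: sort p ascending, compute
# p_(i) * n / i, enforce monotonicity from the largest rank down, cap at 1.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord] * n / seq_len(n)
  for (i in (n - 1):1) {
    if (n == 1) break
    ranked[i] <- min(ranked[i], ranked[i + 1])
  }
  ranked <- pmin(ranked, 1)
  out <- numeric(n)
  out[ord] <- ranked
  out
}

# Exclusive intersections by enumerating all 2^k - 1 set combinations and
# intersecting / subtracting explicitly.
exclusive_intersections_oracle <- function(sets) {
  k <- length(sets)
  nm <- names(sets)
  res <- list()
  for (mask in 1:(2^k - 1)) {
    inn <- nm[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    outn <- setdiff(nm, inn)
    members <- Reduce(intersect, sets[inn])
    for (o in outn) members <- setdiff(members, sets[[o]])
    if (length(members)) {
      res[[paste(inn, collapse = "&")]] <- sort(members)
    }
  }
  res
}

# Ordinary equal-variance two-sample t statistic.
ordinary_t <- function(x, y) {
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Tiny protein-groups fixture with controllable flags/missingness.
make_pg_fixture <- function() {
  intens <- matrix(c(1024, 2048, NA, 512,
                     4096, NA, 8192, 256,
                     128, 64, 32, 16,
                     2, 4, 8, 16,
                     100, 200, 300, 400), ncol = 4, byrow = TRUE,
                   dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  protein_groups(
    protein_id = paste0("P", 1:5),
    intensities = intens,
    gene_name = c("gA", "gB", "gC", "gD", "gE"),
    reverse_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    contaminant_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    site_only_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE))
}

# Tiny two-genotype sample map.
chip_genotypes <- function(sim) {
  stats::setNames(sim$sample_info$genotype, sim$sample_info$sample)
}

# Small ChIP config for fast unit tests.
small_chip_config <- function(seed = 1L, ...) {
  chip_sim_config(
    chrom_lengths = c(chr2L = 3e5, chr3R = 3e5, chr4 = 1e5),
    n_peaks_per_class = c(proximal = 6, nonproximal = 54),
    n_replicates = c(wt = 3, dC = 3),
    seed = seed, ...)
}

# Direct generative null table for the random-intercept model: no genotype
# effect, a real class effect and per-sample intercepts.
lmm_null_table <- function(n_peaks = 40, n_per_gt = 3, ri_sd = 0.5,
                           resid_sd = 1, class_effect = 1) {
  samples <- c(sprintf("wt_r%d", seq_len(n_per_gt)),
               sprintf("dC_r%d", seq_len(n_per_gt)))
  genotype <- rep(c("wt", "dC"), each = n_per_gt)
  u <- stats::rnorm(length(samples), 0, ri_sd)
  cls <- rep(c("HP1a_proximal", "non_proximal"),
             c(max(1, floor(0.1 * n_peaks)),
               n_peaks - max(1, floor(0.1 * n_peaks))))
  df <- expand.grid(peak = sprintf("pk%03d", seq_len(n_peaks)),
                    sample = samples, stringsAsFactors = FALSE)
  df$genotype <- genotype[match(df$sample, samples)]
  df$class <- cls[match(df$peak, sprintf("pk%03d", seq_len(n_peaks)))]
  df$z_central <- u[match(df$sample, samples)] +
    ifelse(df$class == "HP1a_proximal", class_effect, 0) +
    stats::rnorm(nrow(df), 0, resid_sd)
  df
}
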