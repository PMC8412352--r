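test_that("consensus peaks honor the replicate-support threshold", {
  # one region in 5/10 replicates (kept), one in 4/10 (dropped)
  mk <- function(with_a, with_b) {
    df <- data.frame(chrom = character(), start = numeric(),
                     end = numeric())
    if (with_a) df <- rbind(df, data.frame(chrom = "chr2L", start = 100,
                                           end = 300))
    if (with_b) df <- rbind(df, data.frame(chrom = "chr2L", start = 5000,
                                           end = 5200))
    if (nrow(df) == 0) {
      genomic_intervals(character(), numeric(), integer(1)[0])
    } else {
      genomic_intervals(df$chrom, df$start, df$end)
    }
  }
  reps <- c(lapply(1:5, function(i) mk(TRUE, i <= 4)),
            lapply(1:5, function(i) mk(FALSE, FALSE)))
  cons <- consensus_peaks(reps, min_fraction = 0.5)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 100)
  expect_equal(cons$n_support, 5)

  # identical replicates: output equals the (merged) input
  same <- lapply(1:4, function(i) {
    genomic_intervals(c("chr2L", "chr3R"), c(10, 50), c(40, 99))
  })
  out <- consensus_peaks(same)
  expect_equal(as.data.frame(out)[, c("chrom", "start", "end")],
               as.data.frame(same[[1]])[, c("chrom", "start", "end")])

  # monotone: raising the threshold never yields more peaks
  sim <- simulate_chip(small_chip_config(seed = 6))
  n <- sapply(c(0.3, 0.5, 0.8, 1), function(f) {
    nrow(consensus_peaks(sim$peaksets, min_fraction = f))
  })
  expect_true(all(diff(n) <= 0))
})

test_that("coverage matrix extracts centered windows at the right binning", {
  cl <- c(chrA = 20000)
  flat <- coverage_track(cl, 10, list(chrA = rep(3, 2000)))
  pk <- genomic_intervals("chrA", c(7900, 11900), c(8100, 12100),
                          name = c("p1", "p2"))
  m <- coverage_matrix(flat, pk, window_bp = 4000, bin_bp = 10)
  expect_equal(dim(m), c(2, 400))
  expect_true(all(m == 3))

  # synthetic Gaussian bump peaks at the central bins
  v <- rep(0, 2000)
  mids <- (seq_len(2000) - 0.5) * 10
  v <- 5 * exp(-((mids - 8000)^2) / (2 * 150^2))
  tr <- coverage_track(cl, 10, list(chrA = v))
  g <- coverage_matrix(tr, pk[1, ], window_bp = 4000, bin_bp = 10)
  expect_true(which.max(g[1, ]) %in% 200:201)

  # out-of-bounds windows are dropped with a message
  edge <- genomic_intervals("chrA", 100, 300, name = "edge")
  expect_message(
    m2 <- coverage_matrix(flat, rbind(as.data.frame(pk[1, ]),
                                      as.data.frame(edge))[c(2, 1), ],
                          4000, 10),
    "out-of-bounds")
  expect_equal(nrow(m2), 1)
})

test_that("z-scoring yields global mean 0 / sd 1 and is affine-invariant and idempotent", {
  set.seed(9)
  m <- matrix(rnorm(600, 4, 3), 20, 30)
  z <- zscore_matrix(m)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(as.vector(z)) - 1), 1e-9)
  expect_equal(zscore_matrix(2.5 * m + 7), z, tolerance = 1e-9)
  expect_equal(zscore_matrix(z), z, tolerance = 1e-9)
  # two-value matrix with equal counts -> plus/minus 1
  tv <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(sort(unique(as.vector(zscore_matrix(tv)))),
               c(-1, 1) * sqrt(3) / 2, tolerance = 1e-12)
  expect_error(zscore_matrix(matrix(1, 2, 2)), "zero")
})

test_that("top-decile HP1a classification is exact in count and deterministic", {
  sim <- simulate_chip(small_chip_config(seed = 10))
  lab <- suppressMessages(
    classify_hp1a_proximal(sim$peaks, sim$hp1a_track))
  expect_equal(sum(lab == "HP1a_proximal"), floor(0.10 * length(lab)))
  # planted recovery: proximal amplitudes 10 vs 1 separate cleanly
  truth <- ifelse(sim$peaks$class == "proximal", "HP1a_proximal",
                  "non_proximal")
  expect_gte(mean(lab == truth), 0.95)
  # constant track: deterministic tie-broken labels, stable across runs
  flat <- coverage_track(sim$hp1a_track$chrom_lengths,
                         sim$hp1a_track$bin_size,
                         lapply(sim$hp1a_track$values, function(v) v * 0 + 2))
  expect_error(zscore_matrix(matrix(2, 2, 2)), "zero")
  l1 <- classify_hp1a_proximal(sim$peaks, flat)
  l2 <- classify_hp1a_proximal(sim$peaks, flat)
  expect_identical(l1, l2)
  expect_equal(sum(l1 == "HP1a_proximal"), floor(0.10 * length(l1)))
})

test_that("central-window statistics average the central bins only", {
  cl <- c(chrA = 20000)
  pk <- genomic_intervals("chrA", 7900, 8100, name = "p1")
  # flat zero matrix -> all statistics 0
  flat <- coverage_track(cl, 10, list(chrA = rep(0, 2000)))
  m <- coverage_matrix(flat, pk, 4000, 10)
  expect_equal(ncol(m), 400)
  stats_df <- central_window_stats(list(s1 = m),
                                   labels = setNames("non_proximal", "p1"),
                                   genotypes = c(s1 = "wt"))
  expect_equal(stats_df$z_central, 0)
  # 200 bp / 10 bp = 20 central bins; Gaussian row: central mean > window mean
  mids <- (seq_len(2000) - 0.5) * 10
  tr <- coverage_track(cl, 10,
                       list(chrA = 4 * exp(-((mids - 8000)^2) / (2 * 200^2))))
  g <- coverage_matrix(tr, pk, 4000, 10)
  s <- central_window_stats(list(s1 = g),
                            labels = setNames("non_proximal", "p1"),
                            genotypes = c(s1 = "wt"))
  expect_gt(s$z_central, mean(g[1, ]))
  # explicit count of central columns
  cw <- 200 / 10
  expect_equal(cw, 20)
})

test_that("the random-intercept LMM matches OLS when sample variance is zero", {
  set.seed(15)
  df <- lmm_null_table(n_peaks = 30, n_per_gt = 3, ri_sd = 0)
  fit <- fit_random_intercept_lmm(df, interaction = FALSE)
  ols <- lm(z_central ~ genotype + class, data = df)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  expect_gte(fit$varcomp[["sigma2_sample"]], 0)
})

test_that("the LMM recovers a planted genotype-by-class interaction", {
  set.seed(16)
  covered <- 0L
  n_sim <- 40
  for (i in seq_len(n_sim)) {
    df <- lmm_null_table(n_peaks = 60, n_per_gt = 3, ri_sd = 0.3)
    # plant interaction: wt gains +2 at proximal peaks only; with factor
    # levels (dC, wt) x (HP1a_proximal, non_proximal) the interaction
    # coefficient is (wt,non - wt,prox) - (dC,non - dC,prox) = -2
    sel <- df$genotype == "wt" & df$class == "HP1a_proximal"
    df$z_central[sel] <- df$z_central[sel] + 2
    fit <- fit_random_intercept_lmm(df, interaction = TRUE)
    fe <- fit$fixed_effects
    row <- fe[grepl(":", fe$term), ]
    ci <- row$estimate + c(-1, 1) * qt(0.975, row$df) * row$se
    if (ci[1] <= -2 && -2 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered / n_sim, 0.85)
})

test_that("LMM fixed effects agree with an independent nlme fit", {
  skip_if_not_installed("nlme")
  set.seed(17)
  df <- lmm_null_table(n_peaks = 50, n_per_gt = 4, ri_sd = 0.5)
  fit <- fit_random_intercept_lmm(df, interaction = TRUE)
  alt <- nlme::lme(z_central ~ genotype * class, random = ~ 1 | sample,
                   data = df, method = "REML")
  expect_equal(unname(coef(fit)), unname(nlme::fixef(alt)), tolerance = 1e-4)
  expect_equal(fit$varcomp[["sigma2_resid"]], alt$sigma^2, tolerance = 1e-3)
})

test_that("chromosome-wide profiles are replicate means, binned and z-scored", {
  cl <- c(chrA = 200000, chrB = 100000)
  set.seed(18)
  t1 <- coverage_track(cl, 100, list(chrA = rnorm(2000), chrB = rnorm(1000)))
  t2 <- coverage_track(cl, 100, list(chrA = rnorm(2000), chrB = rnorm(1000)))
  prof <- chromwide_profile(list(t1, t2), chromwide_bin_bp = 50000)
  vals <- unlist(prof$values)
  expect_equal(length(prof$values$chrA), 4)
  expect_lt(abs(mean(vals)), 1e-9)
  expect_lt(abs(sd(vals) - 1), 1e-9)
  # single replicate reduces to binning that track
  single <- chromwide_profile(list(t1), chromwide_bin_bp = 50000)
  manual <- rebin_track(t1, 50000)
  mv <- unlist(manual$values)
  expect_equal(unlist(single$values), (mv - mean(mv)) / sd(mv),
               tolerance = 1e-9)
  # planted enrichment shows up as elevated z in the planted region
  v <- t1$values$chrA
  v[1:500] <- v[1:500] + 5
  t3 <- coverage_track(cl, 100, list(chrA = v, chrB = t1$values$chrB))
  z <- chromwide_profile(list(t3), 50000)
  expect_gt(min(z$values$chrA[1]), max(z$values$chrB))
})

test_that("chromosome-4 peak fractions and the genotype linear model", {
  mk <- function(n4, ntot) {
    genomic_intervals(c(rep("chr4", n4), rep("chr2L", ntot - n4)),
                      seq_len(ntot) * 1000, seq_len(ntot) * 1000 + 200)
  }
  ps <- list(a1 = mk(5, 100), a2 = mk(5, 100), b1 = mk(5, 100),
             b2 = mk(5, 100))
  gt <- c(a1 = "wt", a2 = "wt", b1 = "dC", b2 = "dC")
  res <- chr4_fraction_test(ps, gt)
  expect_equal(res$percent$pct, rep(5, 4))
  expect_equal(res$slope, 0)
  expect_gt(res$p, 0.99)

  ps2 <- list(a1 = mk(10, 100), a2 = mk(11, 100), a3 = mk(10, 100),
              b1 = mk(2, 100), b2 = mk(3, 100), b3 = mk(2, 100))
  gt2 <- c(a1 = "wt", a2 = "wt", a3 = "wt", b1 = "dC", b2 = "dC", b3 = "dC")
  res2 <- chr4_fraction_test(ps2, gt2)
  expect_lt(res2$p, 0.05)
  # genotype coding: slope is second factor level minus first (wt - dC > 0)
  expect_gt(res2$slope, 0)
})

test_that("heatmap row order groups proximal peaks first, sorted by central signal", {
  m <- matrix(0, 4, 400, dimnames = list(paste0("p", 1:4), NULL))
  attr(m, "bin_bp") <- 10
  m[1, 180:220] <- 1
  m[2, 180:220] <- 3
  m[3, 180:220] <- 2
  m[4, 180:220] <- 5
  labels <- c(p1 = "non_proximal", p2 = "HP1a_proximal",
              p3 = "non_proximal", p4 = "HP1a_proximal")
  ord <- heatmap_row_order(m, labels, central_bp = 400)
  expect_equal(rownames(m)[ord], c("p4", "p2", "p3", "p1"))
})
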