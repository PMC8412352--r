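test_that("flag filtering removes exactly the flagged rows", {
  pg <- make_pg_fixture()
  kept <- suppressMessages(filter_protein_groups(pg))
  expect_equal(kept$protein_id, c("P1", "P2", "P5"))
  clean <- protein_groups(pg$protein_id, pg$intensities)
  expect_equal(suppressMessages(filter_protein_groups(clean))$protein_id,
               pg$protein_id)
})

test_that("log2 transform maps observed cells and preserves missingness", {
  pg <- make_pg_fixture()
  m <- log2_transform(pg)
  expect_equal(m["P1", "s1"], 10)            # 1024
  expect_true(is.na(m["P1", "s3"]))
  expect_equal(log2_transform(matrix(1, dimnames = list("p", "s")))[1], 0)
  expect_error(log2_transform(matrix(-2, dimnames = list("p", "s"))),
               "positive")
})

test_that("shifted-Gaussian imputation draws from Normal(m - 1.8 sd, (0.3 sd)^2)", {
  set.seed(1)
  n <- 6000
  obs <- rnorm(n, mean = 20, sd = 1)
  m <- cbind(a = c(obs, rep(NA, n)), b = rnorm(2 * n, 20, 1))
  rownames(m) <- paste0("p", seq_len(2 * n))
  imp <- impute_shifted_gaussian(m, shift = 1.8, scale = 0.3, seed = 4)
  # observed cells bit-identical
  expect_identical(imp[seq_len(n), "a"], m[seq_len(n), "a"])
  expect_identical(imp[, "b"], m[, "b"])
  drawn <- imp[n + seq_len(n), "a"]
  m_s <- mean(obs); sd_s <- sd(obs)
  se_mean <- 0.3 * sd_s / sqrt(n)
  expect_lt(abs(mean(drawn) - (m_s - 1.8 * sd_s)), 3 * se_mean)
  se_sd <- 0.3 * sd_s / sqrt(2 * (n - 1))
  expect_lt(abs(sd(drawn) - 0.3 * sd_s), 3 * se_sd)
})

test_that("imputation degenerate limits and error cases", {
  m <- cbind(a = c(10, 20, NA, NA), b = c(1, 2, 3, 4))
  rownames(m) <- paste0("p", 1:4)
  # shift 0, scale -> 0+: imputed values collapse to the column mean
  imp <- impute_shifted_gaussian(m, shift = 0, scale = 1e-12, seed = 1)
  expect_equal(unname(imp[3:4, "a"]), c(15, 15), tolerance = 1e-6)
  # no missing cells: identity regardless of seed
  full <- m; full[is.na(full)] <- 5
  expect_identical(impute_shifted_gaussian(full, seed = 1),
                   impute_shifted_gaussian(full, seed = 99))
  bad <- cbind(a = c(1, NA, NA), b = c(1, 2, 3))
  rownames(bad) <- paste0("p", 1:3)
  expect_error(impute_shifted_gaussian(bad), "a")
})

test_that("imputation is deterministic given the seed", {
  m <- matrix(rnorm(50, 20), 10, 5,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:5)))
  m[sample(50, 15)] <- NA
  m[1, ] <- 20:24  # keep >= 2 observed per column
  expect_identical(impute_shifted_gaussian(m, seed = 7),
                   impute_shifted_gaussian(m, seed = 7))
  expect_false(identical(impute_shifted_gaussian(m, seed = 7),
                         impute_shifted_gaussian(m, seed = 8)))
})

test_that("median normalization equalizes column medians at the grand median", {
  m <- cbind(a = c(9, 10, 11), b = c(11, 12, 13))
  out <- median_normalize(m)
  expect_equal(unname(apply(out, 2, median)), c(11, 11))
  # already equal -> identity
  eq <- cbind(a = c(1, 2, 3), b = c(0, 2, 5))
  expect_equal(median_normalize(eq), eq)
  set.seed(2)
  r <- matrix(rnorm(200), 20, 10)
  med <- apply(median_normalize(r), 2, median)
  expect_lt(max(abs(med - med[1])), 1e-9)
})

test_that("per-protein OLS returns group means and residual variance", {
  m <- rbind(p1 = c(1, 3, 10, 14), p2 = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  fit <- fit_linear_model(m, c("A", "A", "B", "B"))
  expect_equal(fit$df, 2)
  expect_equal(unname(fit$means["p1", ]), c(2, 12))
  expect_equal(unname(fit$s2[["p2"]]), 0)
  expect_equal(unname(fit$s2[["p1"]]), (2 + 8) / 2)
  expect_error(fit_linear_model(m, c("A", "A", "A", "A")), "2 groups")
})

test_that("moderated t reduces to the ordinary t when d0 = 0", {
  set.seed(3)
  m <- matrix(rnorm(40 * 8, 20), 40, 8,
              dimnames = list(paste0("p", 1:40), paste0("s", 1:8)))
  grp <- rep(c("A", "B"), each = 4)
  fit <- fit_linear_model(m, grp)
  mod0 <- moderation_model(d0 = 0, s0_sq = 1, fit$s2, fit$df)
  mt <- moderated_t(fit$means[, "A"] - fit$means[, "B"], mod0, 1 / 4 + 1 / 4)
  tt <- sapply(seq_len(nrow(m)), function(i) {
    ordinary_t(m[i, grp == "A"], m[i, grp == "B"])
  })
  expect_lt(max(abs(mt$t - tt)), 1e-9)
})

test_that("d0 = Inf makes every posterior variance the prior variance", {
  mod <- moderation_model(d0 = Inf, s0_sq = 0.7, s2 = c(0.1, 2, 5), df = 4)
  expect_equal(mod$s2_post, rep(0.7, 3))
})

test_that("eBayes hyperparameters and posteriors match limma's squeezeVar", {
  skip_if_not_installed("limma")
  set.seed(42)
  n <- 2000; d <- 6
  s2 <- (0.05 * 5 / rchisq(n, 5)) * rchisq(n, d) / d
  mod <- ebayes_moderate(s2, d)
  sv <- limma::squeezeVar(s2, d)
  expect_equal(mod$d0, sv$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, sv$var.prior, tolerance = 1e-6)
  expect_equal(mod$s2_post, sv$var.post, tolerance = 1e-8)
})

test_that("full moderated-t path matches limma lmFit + eBayes", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(rnorm(500 * 8), 500, 8,
              dimnames = list(paste0("p", 1:500), paste0("s", 1:8)))
  grp <- rep(c("A", "B"), each = 4)
  fit <- fit_linear_model(m, grp)
  mod <- ebayes_moderate(fit$s2, fit$df)
  mt <- moderated_t(fit$means[, "B"] - fit$means[, "A"], mod, 1 / 4 + 1 / 4)
  eb <- limma::eBayes(limma::lmFit(m, stats::model.matrix(~grp)))
  expect_lt(max(abs(mt$t - eb$t[, 2])), 1e-9)
  expect_lt(max(abs(mt$p - eb$p.value[, 2])), 1e-9)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup_oracle(p))
    expect_true(all(adj >= p))
  }
})

test_that("pooled-control enrichment recovers a planted core effect", {
  hits <- 0L
  n_sim <- 60
  for (s in seq_len(n_sim)) {
    sim <- simulate_apms(apms_sim_config(
      n_background_proteins = 60, core_complex = "HMR", baits = "HMR",
      bait_specific_interactors = list(HMR = character(0)),
      n_replicates_per_bait = c(HMR = 4), n_controls = 4,
      log2_enrichment_core = 5, noise_sd = 0.5,
      detection_midpoint = -100, seed = 1000 + s))
    fit <- suppressMessages(apms_enrich(sim$protein_groups, sim$sheet, "HMR"))
    fc <- fit$results$HMR$log2fc[fit$results$HMR$protein_id == "HMR"]
    # sampling SD of the 4-vs-4 mean difference: noise_sd * sqrt(1/4 + 1/4)
    if (abs(fc - 5) < 3 * 0.5 * sqrt(0.5)) hits <- hits + 1L
    if (s <= 10) {
      bg <- fit$results$HMR$log2fc[fit$results$HMR$protein_id != "HMR"]
      expect_lt(abs(median(bg)), 0.5)
    }
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("a protein present only in controls gets a negative log2fc", {
  sim <- simulate_apms(apms_sim_config(
    n_background_proteins = 80, core_complex = "HMR", baits = "HMR",
    bait_specific_interactors = list(HMR = character(0)),
    n_replicates_per_bait = c(HMR = 4), n_controls = 4,
    detection_midpoint = -100, seed = 5))
  pg <- sim$protein_groups
  # plant depletion: knock the protein out of every IP sample
  ip <- sim$sheet$sample_id[!sim$sheet$is_control]
  pg$intensities["BG0001", ip] <- NA
  fit <- suppressMessages(apms_enrich(pg, sim$sheet, "HMR"))
  expect_lt(fit$results$HMR$log2fc[fit$results$HMR$protein_id == "BG0001"], 0)
})

test_that("preprocessing drops fully missing proteins and touches only missing cells", {
  sim <- simulate_apms(apms_sim_config(n_background_proteins = 100, seed = 3))
  pg <- sim$protein_groups
  pg$intensities["BG0002", ] <- NA
  prep <- suppressMessages(prepare_intensities(pg, sim$sheet))
  expect_false("BG0002" %in% rownames(prep$matrix))
  expect_equal(prep$n_dropped_all_missing, 1L)
  # observed cells survive log2 + imputation unchanged; normalization adds a
  # single per-column constant, so prep - raw is constant on observed cells
  raw <- log2(pg$intensities[rownames(prep$matrix), colnames(prep$matrix)])
  for (j in seq_len(ncol(raw))) {
    obs_j <- !is.na(raw[, j])
    d <- prep$matrix[obs_j, j] - raw[obs_j, j]
    expect_lt(diff(range(d)), 1e-9)
  }
})
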