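#' Remove decoy, contaminant and site-only protein groups
#'
#' Drops every row flagged as reverse (decoy), potential contaminant or
#' "only identified by site"; the three standard MaxQuant quality filters.
#'
#' @param pg a `protein_groups` object.
#' @return Filtered `protein_groups`; removal counts are reported via
#'   `message()` and attached as attribute `filter_counts`.
#' @export
filter_protein_groups <- function(pg) {
  drop <- pg$reverse_flag | pg$contaminant_flag | pg$site_only_flag
  counts <- c(reverse = sum(pg$reverse_flag),
              contaminant = sum(pg$contaminant_flag),
              site_only = sum(pg$site_only_flag),
              removed = sum(drop))
  msgf("filter_protein_groups: removed %d/%d rows (reverse %d, contaminant %d, site-only %d)",
       counts[["removed"]], length(drop), counts[["reverse"]],
       counts[["contaminant"]], counts[["site_only"]])
  keep <- !drop
  out <- protein_groups(pg$protein_id[keep],
                        pg$intensities[keep, , drop = FALSE],
                        gene_name = pg$gene_name[keep])
  attr(out, "filter_counts") <- counts
  out
}

#' Log2-transform linear intensities
#'
#' Observed cells become `log2(value)`; missing cells stay missing.
#'
#' @param pg a `protein_groups` object (or a positive numeric matrix with
#'   `NA` for missing).
#' @return Numeric matrix (proteins x samples) of log2 intensities.
#' @export
log2_transform <- function(pg) {
  m <- if (inherits(pg, "protein_groups")) pg$intensities else as.matrix(pg)
  if (any(m <= 0, na.rm = TRUE)) stopf("intensities must be positive")
  log2(m)
}

#' Impute left-censored missing values from a down-shifted Gaussian
#'
#' Missing-not-at-random proteomics missingness is concentrated below the
#' detection limit, so missing cells in sample `s` are drawn from
#' `Normal(m_s - shift * sd_s, (scale * sd_s)^2)`, where `m_s` and `sd_s`
#' are the mean and SD of the observed values of that sample column.
#' Defaults `shift = 1.8`, `scale = 0.3` are the standard manual-imputation
#' setting for label-free AP-MS. Observed cells are untouched; the draw is
#' deterministic given `seed`.
#'
#' @param mat log2 intensity matrix with `NA` for missing.
#' @param shift down-shift in units of the per-sample SD (>= 0).
#' @param scale SD multiplier of the imputation distribution (> 0).
#' @param seed RNG seed (recorded; default 0).
#' @return Complete numeric matrix.
#' @export
impute_shifted_gaussian <- function(mat, shift = 1.8, scale = 0.3, seed = 0L) {
  assert_scalar_number(shift, "shift", min = 0)
  assert_scalar_number(scale, "scale", min = 0, strict_min = TRUE)
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 2L)) {
    stopf("sample(s) with < 2 observed values: %s",
          paste(colnames(mat)[n_obs < 2L], collapse = ", "))
  }
  all_missing <- rowSums(!is.na(mat)) == 0L
  if (any(all_missing)) {
    # should have been dropped upstream; formula still applies but flag it
    msgf("impute_shifted_gaussian: %d fully missing row(s) imputed from column statistics alone",
         sum(all_missing))
  }
  with_seed(seed, {
    for (j in seq_len(ncol(mat))) {
      miss <- is.na(mat[, j])
      if (!any(miss)) next
      m_s <- mean(mat[, j], na.rm = TRUE)
      sd_s <- stats::sd(mat[, j], na.rm = TRUE)
      mat[miss, j] <- stats::rnorm(sum(miss),
                                   mean = m_s - shift * sd_s,
                                   sd = scale * sd_s)
    }
    mat
  })
}

#' Median-normalize sample columns
#'
#' Shifts each sample column additively so that its median equals the grand
#' median of the pre-normalization column medians; corrects loading/depth
#' differences on the log2 scale.
#'
#' @param mat complete numeric matrix (post-imputation).
#' @return Matrix with equal column medians.
#' @export
median_normalize <- function(mat) {
  if (anyNA(mat)) stopf("median_normalize expects a complete matrix")
  med <- apply(mat, 2L, stats::median)
  target <- stats::median(med)
  sweep(mat, 2L, med - target, `-`)
}

#' Per-protein ordinary least squares on group indicators
#'
#' Fits the one-way group-means model to every protein row: group means,
#' residual variance `s_g^2 = RSS / (n - k)` and residual degrees of freedom
#' `d_g = n - k`.
#'
#' @param mat complete proteins x samples matrix.
#' @param groups character/factor of length `ncol(mat)` assigning each sample
#'   to a group.
#' @return List with `means` (proteins x groups), `s2` (residual variances),
#'   `df` (residual df, scalar), `n_per_group`.
#' @export
fit_linear_model <- function(mat, groups) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(mat)) stopf("groups must match sample columns")
  if (any(table(groups) == 0L)) stopf("every group needs >= 1 sample")
  if (nlevels(groups) < 2L) stopf("need >= 2 groups")
  n <- ncol(mat)
  k <- nlevels(groups)
  if (n <= k) stopf("need more samples (%d) than groups (%d)", n, k)
  ind <- stats::model.matrix(~ 0 + groups)
  colnames(ind) <- levels(groups)
  n_per_group <- colSums(ind)
  means <- mat %*% ind %*% diag(1 / n_per_group, k)
  colnames(means) <- levels(groups)
  fitted <- means %*% t(ind)
  rss <- rowSums((mat - fitted)^2)
  list(means = means, s2 = rss / (n - k), df = n - k,
       n_per_group = n_per_group)
}

# Newton inversion of the trigamma function (solve trigamma(x) = target);
# trigamma is positive, decreasing and convex on (0, Inf).
trigamma_inverse <- function(target) {
  vapply(target, function(t) {
    if (!is.finite(t) || t <= 0) return(Inf)
    if (t > 1e7) return(1 / sqrt(t))
    x <- 0.5 + 1 / t
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / t) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-protein variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` of
#' the scaled inverse chi-square variance prior by matching the first two
#' moments of `log(s_g^2)` via digamma/trigamma inversion, then forms the
#' posterior (moderated) variances
#' `s_tilde^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`.
#'
#' @param s2 per-protein residual variances.
#' @param df residual degrees of freedom (scalar or per-protein).
#' @return Object of class `moderation_model`: `d0`, `s0_sq`, `s2`, `df`,
#'   `s2_post`, `df_total = d0 + df`.
#' @export
ebayes_moderate <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- df > 0 & is.finite(s2) & s2 > 0
  if (sum(ok) < 10L) stopf("need >= 10 proteins with positive df and variance")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (sum(ok) - 1) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    if (!is.finite(evar)) {
      warning("non-finite trigamma inversion; falling back to d0 = Inf")
    }
    # no excess dispersion beyond sampling noise: infinite prior df, prior
    # variance the plain mean of the observed variances
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  }
  moderation_model(d0, s0_sq, s2, df)
}

#' @rdname ebayes_moderate
#' @param d0 prior degrees of freedom (> 0, may be `Inf` or 0).
#' @param s0_sq prior variance.
#' @export
moderation_model <- function(d0, s0_sq, s2, df) {
  df <- rep_len(df, length(s2))
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  # the pooled prior cannot carry more information than the whole ensemble:
  # cap the total df at the summed residual df
  df_total <- pmin(d0 + df, sum(df))
  structure(list(d0 = d0, s0_sq = s0_sq, s2 = s2, df = df,
                 s2_post = s2_post, df_total = df_total),
            class = "moderation_model")
}

#' @export
print.moderation_model <- function(x, ...) {
  cat(sprintf("moderation_model: d0 = %.4g, s0^2 = %.4g, %d proteins, residual df %s\n",
              x$d0, x$s0_sq, length(x$s2),
              paste(unique(x$df), collapse = "/")))
  invisible(x)
}

#' Moderated t-statistics for a two-group contrast
#'
#' `t_g = log2fc_g / sqrt(s_tilde_g^2 * c_g)` on `d0 + d_g` degrees of
#' freedom, with `c_g` the contrast variance multiplier (for a difference of
#' two group means, `1/n1 + 1/n2`).
#'
#' @param log2fc per-protein contrast estimates.
#' @param model a `moderation_model`.
#' @param c_g contrast variance multiplier.
#' @return data frame with `log2fc`, `t`, `p` (two-sided).
#' @export
moderated_t <- function(log2fc, model, c_g) {
  t_stat <- log2fc / sqrt(model$s2_post * c_g)
  df_tot <- model$df_total
  p <- 2 * stats::pt(-abs(t_stat), df = df_tot)
  data.frame(log2fc = log2fc, t = t_stat, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Prepare an AP-MS intensity matrix for modelling
#'
#' Runs the preprocessing chain in its canonical order:
#' filter flagged rows, drop proteins missing in every sample, log2
#' transform, impute missing values from the down-shifted Gaussian, then
#' median-normalize. Imputation statistics are per-sample, so imputation
#' precedes normalization.
#'
#' @param pg a `protein_groups` object.
#' @param sheet a `sample_sheet`; its `sample_id`s select and order columns.
#' @param shift,scale,seed imputation parameters
#'   (see [impute_shifted_gaussian()]).
#' @return List with `matrix` (complete, normalized log2 intensities),
#'   `filter_counts`, `n_dropped_all_missing`.
#' @export
prepare_intensities <- function(pg, sheet, shift = 1.8, scale = 0.3,
                                seed = 0L) {
  missing_cols <- setdiff(sheet$sample_id, colnames(pg$intensities))
  if (length(missing_cols)) {
    stopf("sample sheet sample(s) absent from intensity table: %s",
          paste(missing_cols, collapse = ", "))
  }
  pg <- filter_protein_groups(pg)
  mat <- log2_transform(pg)[, sheet$sample_id, drop = FALSE]
  all_missing <- rowSums(!is.na(mat)) == 0L
  if (any(all_missing)) {
    msgf("prepare_intensities: dropping %d protein(s) missing in every sample",
         sum(all_missing))
    mat <- mat[!all_missing, , drop = FALSE]
  }
  mat <- impute_shifted_gaussian(mat, shift = shift, scale = scale,
                                 seed = seed)
  mat <- median_normalize(mat)
  list(matrix = mat,
       filter_counts = attr(pg, "filter_counts"),
       n_dropped_all_missing = sum(all_missing))
}

#' Enrichment of one bait IP series versus pooled controls
#'
#' Contrasts the mean of a bait's IP samples against the mean of all pooled
#' control samples (IgG and mock IPs) on the log2 scale. The per-protein
#' residual variance is pooled across all experiment groups in the sheet
#' (each bait series one group, all controls one group), moderated with
#' empirical Bayes, and BH-adjusted across all retained proteins.
#'
#' @param mat complete normalized log2 matrix (see [prepare_intensities()]).
#' @param sheet a `sample_sheet` covering `colnames(mat)`.
#' @param bait experiment label (a value of `sheet$bait`) to contrast.
#' @return data frame of class `enrichment_result`: `protein_id`, `contrast`,
#'   `log2fc`, `t`, `p`, `p_adj`, plus attributes `n_ip`, `n_ctrl`,
#'   `moderation` (the fitted `moderation_model`).
#' @export
enrich_vs_pooled_controls <- function(mat, sheet, bait) {
  sheet <- sheet[match(colnames(mat), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stopf("sheet must describe every matrix column")
  groups <- ifelse(sheet$is_control, "CTRL",
                   paste(sheet$bait, sheet$condition, sep = "."))
  ip_group <- unique(groups[sheet$bait == bait & !sheet$is_control])
  if (length(ip_group) != 1L) {
    stopf("bait '%s' must map to exactly one non-control group (found %d)",
          bait, length(ip_group))
  }
  n_ip <- sum(groups == ip_group)
  n_ctrl <- sum(groups == "CTRL")
  if (n_ip < 2L) stopf("bait '%s' needs >= 2 IP samples", bait)
  if (n_ctrl < 2L) stopf("need >= 2 pooled control samples")
  fit <- fit_linear_model(mat, groups)
  mod <- ebayes_moderate(fit$s2, fit$df)
  log2fc <- fit$means[, ip_group] - fit$means[, "CTRL"]
  res <- moderated_t(log2fc, mod, c_g = 1 / n_ip + 1 / n_ctrl)
  out <- data.frame(protein_id = rownames(mat),
                    contrast = paste0(bait, "_vs_CTRL"),
                    log2fc = res$log2fc, t = res$t, p = res$p,
                    p_adj = bh_adjust(res$p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_ip") <- n_ip
  attr(out, "n_ctrl") <- n_ctrl
  attr(out, "moderation") <- mod
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Full AP-MS enrichment analysis for one or more baits
#'
#' End-to-end wrapper: [prepare_intensities()] once, then
#' [enrich_vs_pooled_controls()] per bait.
#'
#' @inheritParams prepare_intensities
#' @param baits experiment labels to contrast; defaults to every non-control
#'   bait in the sheet.
#' @return Object of class `apms_fit`: list with `results` (named list of
#'   `enrichment_result`), `matrix`, `sheet`, preprocessing metadata.
#' @export
apms_enrich <- function(pg, sheet, baits = NULL, shift = 1.8, scale = 0.3,
                        seed = 0L) {
  prep <- prepare_intensities(pg, sheet, shift = shift, scale = scale,
                              seed = seed)
  if (is.null(baits)) baits <- unique(sheet$bait[!sheet$is_control])
  results <- lapply(baits, function(b) {
    enrich_vs_pooled_controls(prep$matrix, sheet, b)
  })
  names(results) <- baits
  structure(list(results = results, matrix = prep$matrix, sheet = sheet,
                 filter_counts = prep$filter_counts,
                 n_dropped_all_missing = prep$n_dropped_all_missing,
                 impute_params = list(shift = shift, scale = scale,
                                      seed = seed)),
            class = "apms_fit")
}

#' @export
print.apms_fit <- function(x, ...) {
  cat(sprintf("apms_fit: %d proteins, %d samples, %d contrast(s)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$results)))
  for (b in names(x$results)) {
    r <- x$results[[b]]
    cat(sprintf("  %s: n_ip = %d, n_ctrl = %d, %d proteins with p_adj < 0.05\n",
                r$contrast[1L], attr(r, "n_ip"), attr(r, "n_ctrl"),
                sum(r$p_adj < 0.05)))
  }
  invisible(x)
}

#' @export
summary.apms_fit <- function(object, log2fc_min = 2.5, p_adj_max = 0.05, ...) {
  data.frame(
    contrast = vapply(object$results, function(r) r$contrast[1L], ""),
    n_ip = vapply(object$results, function(r) attr(r, "n_ip"), 0L),
    n_ctrl = vapply(object$results, function(r) attr(r, "n_ctrl"), 0L),
    n_gated = vapply(object$results, function(r) {
      length(gate_interactors(r, log2fc_min, p_adj_max))
    }, 0L),
    row.names = NULL)
}

#' Per-replicate log2 fold-changes of one bait versus the control mean
#'
#' For replicate-resolved statistics (e.g. SEM of diagonal offsets), each IP
#' replicate contributes its own enrichment: replicate column minus the mean
#' of all control columns.
#'
#' @inheritParams enrich_vs_pooled_controls
#' @return proteins x replicates matrix of per-replicate log2 fold-changes.
#' @export
replicate_log2fc <- function(mat, sheet, bait) {
  sheet <- sheet[match(colnames(mat), sheet$sample_id), , drop = FALSE]
  ip <- sheet$sample_id[sheet$bait == bait & !sheet$is_control]
  ctrl <- sheet$sample_id[sheet$is_control]
  if (length(ip) == 0L) stopf("no IP samples for bait '%s'", bait)
  if (length(ctrl) == 0L) stopf("no control samples")
  ctrl_mean <- rowMeans(mat[, ctrl, drop = FALSE])
  mat[, ip, drop = FALSE] - ctrl_mean
}
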