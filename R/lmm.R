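#' Random-intercept linear mixed model on central-window statistics
#'
#' Fits `z_central ~ genotype + class (+ genotype:class) + (1 | sample)` by
#' REML: genotype and peak class are fixed effects, the per-sample intercept
#' absorbs replicate-level shifts (sequencing depth, IP efficiency).
#' P-values for the fixed effects are Wald t-tests on Satterthwaite degrees
#' of freedom (with a normal-approximation fallback).
#'
#' @param data data frame from [central_window_stats()] (columns
#'   `z_central`, `genotype`, `class`, `sample`).
#' @param interaction include the genotype x class interaction (default
#'   `TRUE`; the main-effects model is the alternative reading of the
#'   design).
#' @param df_method `"satterthwaite"` or `"wald_normal"`.
#' @return Object of class `chip_lmm`: `fixed_effects` (data frame with
#'   `term`, `estimate`, `se`, `df`, `p`), `varcomp`
#'   (`sigma2_sample`, `sigma2_resid`), `df_method`, `model` (the underlying
#'   fit), `formula`.
#' @export
fit_random_intercept_lmm <- function(data,
                                     interaction = TRUE,
                                     df_method = c("satterthwaite",
                                                   "wald_normal")) {
  df_method <- match.arg(df_method)
  need <- c("z_central", "genotype", "class", "sample")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("data lacks column(s): %s",
                          paste(miss, collapse = ", "))
  data$genotype <- factor(data$genotype)
  data$class <- factor(data$class)
  if (nlevels(data$genotype) < 2L) stopf("need >= 2 genotypes")
  if (nlevels(data$class) < 2L) stopf("both peak classes must be present")
  n_per_gt <- rowSums(table(data$genotype,
                            data$sample) > 0)
  if (any(n_per_gt < 2L)) stopf("need >= 2 samples per genotype")
  fml <- if (interaction) {
    z_central ~ genotype * class + (1 | sample)
  } else {
    z_central ~ genotype + class + (1 | sample)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    lmerTest::lmer(fml, data = data, REML = TRUE, control = ctrl),
    error = function(e) stopf("mixed-model fit failed: %s", conditionMessage(e))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_sample <- vc$vcov[vc$grp == "sample"]
  sigma2_resid <- vc$vcov[vc$grp == "Residual"]
  co <- if (df_method == "satterthwaite") {
    as.data.frame(summary(fit, ddf = "Satterthwaite")$coefficients)
  } else {
    cc <- as.data.frame(summary(fit, ddf = "lme4")$coefficients)
    cc$df <- Inf
    cc$`Pr(>|t|)` <- 2 * stats::pnorm(-abs(cc$`t value`))
    cc
  }
  fixed <- data.frame(term = rownames(co),
                      estimate = co$Estimate,
                      se = co$`Std. Error`,
                      df = co$df,
                      t = co$`t value`,
                      p = co$`Pr(>|t|)`,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fixed_effects = fixed,
                 varcomp = c(sigma2_sample = sigma2_sample,
                             sigma2_resid = sigma2_resid),
                 df_method = df_method,
                 formula = fml,
                 model = fit),
            class = "chip_lmm")
}

#' @export
print.chip_lmm <- function(x, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  cat(sprintf("  sigma2_sample = %.4g, sigma2_resid = %.4g, df method: %s\n",
              x$varcomp[["sigma2_sample"]], x$varcomp[["sigma2_resid"]],
              x$df_method))
  fe <- x$fixed_effects
  for (i in seq_len(nrow(fe))) {
    cat(sprintf("  %-28s %9.4f (se %.4f, df %.1f, p = %.3g)\n",
                fe$term[i], fe$estimate[i], fe$se[i], fe$df[i], fe$p[i]))
  }
  invisible(x)
}

#' @export
coef.chip_lmm <- function(object, ...) {
  stats::setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' Extract the p-value of one fixed-effect term
#'
#' @param x a `chip_lmm`.
#' @param term regular expression matched against term names (e.g.
#'   `"genotype"` for the main effect, `":"` for the interaction).
#' @return Numeric p-value.
#' @export
lmm_term_p <- function(x, term) {
  fe <- x$fixed_effects
  hit <- grepl(term, fe$term)
  if (term == "genotype") hit <- hit & !grepl(":", fe$term)
  if (sum(hit) != 1L) {
    stopf("term '%s' matches %d fixed effect(s)", term, sum(hit))
  }
  fe$p[hit]
}
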