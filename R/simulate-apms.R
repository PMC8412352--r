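#' Configuration for the synthetic AP-MS generator
#'
#' Defaults emulate the reciprocal-IP study design the pipeline targets: six
#' bait IP series against a shared pooled-control set, a planted six-member
#' core complex (the baits themselves), ten bait-specific interactors per
#' bait on a shared log-normal background proteome, and logistic
#' intensity-dependent (MNAR, left-censored) dropout. Replicate counts follow
#' the reference design (HMR 8, LHR 4, NLP 3, BOH1 4, BOH2 5, HP1a 4).
#'
#' @param n_background_proteins size of the shared background proteome.
#' @param core_complex protein ids of the planted core complex.
#' @param baits experiment labels; one IP series each.
#' @param bait_proteins named map experiment label -> bait protein id
#'   (default: the labels themselves).
#' @param conditions named map experiment label -> condition label
#'   (default `"native"`).
#' @param bait_specific_interactors named list: experiment label -> ids of
#'   planted bait-specific preys (default `"<label>_sp1..10"`).
#' @param n_replicates_per_bait named integer map of IP replicates.
#' @param n_controls number of pooled mock/IgG control samples (>= 2).
#' @param log2_enrichment_core log2 effect of core members in every bait IP.
#' @param log2_enrichment_specific log2 effect of a bait-specific prey in its
#'   own bait's IPs.
#' @param abundance_mean,abundance_sd baseline log2-iBAQ distribution.
#' @param noise_sd replicate noise SD (log2 units).
#' @param detection_midpoint,detection_slope logistic MNAR model: a latent
#'   log2 intensity `x` is observed with probability
#'   `plogis((x - midpoint) * slope)`.
#' @param seed integer seed; all randomness flows from it.
#' @return A validated list of class `apms_sim_config`.
#' @export
apms_sim_config <- function(n_background_proteins = 1000,
                            core_complex = c("HMR", "LHR", "NLP", "BOH1",
                                             "BOH2", "HP1a"),
                            baits = c("HMR", "LHR", "NLP", "BOH1", "BOH2",
                                      "HP1a"),
                            bait_proteins = NULL,
                            conditions = NULL,
                            bait_specific_interactors = NULL,
                            n_replicates_per_bait = c(HMR = 8, LHR = 4,
                                                      NLP = 3, BOH1 = 4,
                                                      BOH2 = 5, HP1a = 4),
                            n_controls = 8,
                            log2_enrichment_core = 5,
                            log2_enrichment_specific = 4,
                            abundance_mean = 25,
                            abundance_sd = 2,
                            noise_sd = 0.5,
                            detection_midpoint = 21,
                            detection_slope = 1.5,
                            seed = 1L) {
  if (is.null(bait_proteins)) {
    bait_proteins <- stats::setNames(baits, baits)
  }
  if (is.null(conditions)) {
    conditions <- stats::setNames(rep("native", length(baits)), baits)
  }
  if (is.null(bait_specific_interactors)) {
    bait_specific_interactors <- lapply(baits, function(b) {
      paste0(b, "_sp", 1:10)
    })
    names(bait_specific_interactors) <- baits
  }
  assert_scalar_number(log2_enrichment_core, "log2_enrichment_core", min = 0)
  assert_scalar_number(log2_enrichment_specific, "log2_enrichment_specific",
                       min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE)
  if (n_controls < 2) stopf("n_controls must be >= 2")
  if (!all(baits %in% names(n_replicates_per_bait))) {
    stopf("n_replicates_per_bait must cover every bait")
  }
  background <- sprintf("BG%04d", seq_len(n_background_proteins))
  planted <- c(core_complex, unlist(bait_specific_interactors,
                                    use.names = FALSE))
  if (any(planted %in% background)) {
    stopf("ground-truth ids must be disjoint from background ids")
  }
  if (anyDuplicated(planted)) stopf("planted protein ids must be unique")
  structure(list(
    n_background_proteins = n_background_proteins,
    background = background,
    core_complex = core_complex,
    baits = baits,
    bait_proteins = bait_proteins,
    conditions = conditions,
    bait_specific_interactors = bait_specific_interactors,
    n_replicates_per_bait = n_replicates_per_bait,
    n_controls = n_controls,
    log2_enrichment_core = log2_enrichment_core,
    log2_enrichment_specific = log2_enrichment_specific,
    abundance_mean = abundance_mean,
    abundance_sd = abundance_sd,
    noise_sd = noise_sd,
    detection_midpoint = detection_midpoint,
    detection_slope = detection_slope,
    seed = as.integer(seed)
  ), class = "apms_sim_config")
}

#' Simulate an AP-MS experiment with known ground truth
#'
#' Latent log2 intensity of protein `p` in sample `s`:
#' `baseline_p + enrichment(p, s) + Normal(0, noise_sd)`, where enrichment is
#' the core effect when `p` is a core-complex member and `s` is any bait IP,
#' the bait-specific effect when `p` is planted for that sample's bait, and
#' 0 otherwise (all controls). A cell is observed with probability
#' `plogis((latent - detection_midpoint) * detection_slope)`, so low-abundance
#' values drop out more (left-censored MNAR). Linear intensities are
#' `2^latent`.
#'
#' @param config an `apms_sim_config`.
#' @return List with `protein_groups`, `sheet` (a `sample_sheet`) and
#'   `ground_truth` (list: `core_complex`, `bait_specific`, `baseline`,
#'   `latent` matrix).
#' @export
simulate_apms <- function(config) {
  stopifnot(inherits(config, "apms_sim_config"))
  proteins <- c(config$core_complex,
                unlist(config$bait_specific_interactors, use.names = FALSE),
                config$background)
  samples <- character()
  bait_of <- character()
  cond_of <- character()
  repl_of <- integer()
  is_ctrl <- logical()
  for (b in config$baits) {
    nr <- config$n_replicates_per_bait[[b]]
    samples <- c(samples, sprintf("%s_r%d", b, seq_len(nr)))
    bait_of <- c(bait_of, rep(b, nr))
    cond_of <- c(cond_of, rep(config$conditions[[b]], nr))
    repl_of <- c(repl_of, seq_len(nr))
    is_ctrl <- c(is_ctrl, rep(FALSE, nr))
  }
  samples <- c(samples, sprintf("CTRL_r%d", seq_len(config$n_controls)))
  bait_of <- c(bait_of, rep("other", config$n_controls))
  cond_of <- c(cond_of, rep("control", config$n_controls))
  repl_of <- c(repl_of, seq_len(config$n_controls))
  is_ctrl <- c(is_ctrl, rep(TRUE, config$n_controls))

  with_seed(config$seed, {
    baseline <- stats::rnorm(length(proteins), config$abundance_mean,
                             config$abundance_sd)
    names(baseline) <- proteins
    enr <- matrix(0, nrow = length(proteins), ncol = length(samples),
                  dimnames = list(proteins, samples))
    ip_cols <- which(!is_ctrl)
    enr[config$core_complex, ip_cols] <- config$log2_enrichment_core
    for (b in config$baits) {
      sp <- config$bait_specific_interactors[[b]]
      cols <- samples[bait_of == b & !is_ctrl]
      if (length(sp) && length(cols)) {
        enr[sp, cols] <- enr[sp, cols] + config$log2_enrichment_specific
      }
    }
    latent <- baseline + enr +
      matrix(stats::rnorm(length(proteins) * length(samples), 0,
                          config$noise_sd),
             nrow = length(proteins))
    dimnames(latent) <- list(proteins, samples)
    p_obs <- stats::plogis((latent - config$detection_midpoint) *
                             config$detection_slope)
    observed <- matrix(stats::runif(length(latent)) < p_obs,
                       nrow = nrow(latent), dimnames = dimnames(latent))
    intens <- 2^latent
    intens[!observed] <- NA_real_
    sheet <- sample_sheet(data.frame(
      sample_id = samples, bait = bait_of, condition = cond_of,
      replicate = repl_of, is_control = is_ctrl,
      stringsAsFactors = FALSE))
    pg <- protein_groups(proteins, intens)
    list(protein_groups = pg, sheet = sheet,
         ground_truth = list(core_complex = config$core_complex,
                             bait_specific = config$bait_specific_interactors,
                             baseline = baseline, latent = latent,
                             observed = observed))
  })
}
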