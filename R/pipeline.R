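#' Default analysis parameters
#'
#' The full parameter set with its canonical defaults: enrichment gate
#' (log2FC > 2.5, adjusted p < 0.05), raw-p inclusion (0.05) and
#' differential threshold (1.5 log2 units), imputation (shift 1.8, scale
#' 0.3), consensus fraction (0.5), matrix windows (4000/10/200 bp),
#' proximal fraction (0.10) and chromosome-wide bin (50 kb).
#'
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(
    log2fc_min = 2.5,
    p_adj_max = 0.05,
    raw_p_max = 0.05,
    diff_log2fc_max = 1.5,
    shift = 1.8,
    scale = 0.3,
    min_fraction = 0.5,
    window_bp = 4000,
    bin_bp = 10,
    central_bp = 200,
    proximal_fraction = 0.10,
    chromwide_bin_bp = 50000
  )
}

#' Validate a run configuration
#'
#' Accepts a YAML path or a list. Unknown keys are rejected; missing keys
#' receive the defaults of [default_params()] plus `seed = 0` and
#' `out_dir = "."`. Referenced input paths must exist at validation time.
#'
#' @param config YAML file path or named list. Recognized keys: every
#'   [default_params()] entry plus `stages` (subset of
#'   `c("simulate_apms", "apms", "interactome", "simulate_chip", "chip")`),
#'   `protein_groups`, `samples` (input paths), `baits`, `seed`, `out_dir`.
#' @return Validated list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  known <- c(names(default_params()),
             "stages", "protein_groups", "samples", "baits", "seed",
             "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  defaults <- c(default_params(),
                list(stages = c("simulate_apms", "apms", "interactome",
                                "simulate_chip", "chip"),
                     protein_groups = NULL, samples = NULL, baits = NULL,
                     seed = 0L, out_dir = "."))
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[k] <- defaults[k]
  }
  num_keys <- names(default_params())
  for (k in num_keys) {
    if (!is.numeric(config[[k]]) || length(config[[k]]) != 1L) {
      stopf("config key '%s' must be a single number", k)
    }
  }
  bad_stage <- setdiff(config$stages, defaults$stages)
  if (length(bad_stage)) stopf("unknown stage(s): %s",
                               paste(bad_stage, collapse = ", "))
  for (k in c("protein_groups", "samples")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      stopf("config key '%s' references a missing file: %s", k, config[[k]])
    }
  }
  config$seed <- as.integer(config$seed)
  structure(config, class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' End-to-end ChIP analysis
#'
#' Runs the full ChIP arm on in-memory objects: replicate-consensus peaks,
#' per-sample z-scored peak matrices, HP1a-proximal classification,
#' central-window statistics and the random-intercept mixed model.
#'
#' @param peaksets named list of per-replicate `genomic_intervals`.
#' @param tracks named list of per-replicate `coverage_track`s (same names).
#' @param hp1a_track HP1a reference `coverage_track`.
#' @param genotypes named character vector mapping sample -> genotype.
#' @param params parameter list (see [default_params()]).
#' @param interaction include the genotype x class interaction in the model.
#' @return List with `consensus`, `labels`, `matrices` (z-scored), `stats`,
#'   `lmm`, `chr4`.
#' @export
chip_pipeline <- function(peaksets, tracks, hp1a_track, genotypes,
                          params = default_params(), interaction = TRUE) {
  stopifnot(identical(sort(names(peaksets)), sort(names(tracks))))
  consensus <- consensus_peaks(peaksets, min_fraction = params$min_fraction)
  labels <- classify_hp1a_proximal(consensus, hp1a_track,
                                   window_bp = params$window_bp,
                                   bin_bp = params$bin_bp,
                                   proximal_fraction =
                                     params$proximal_fraction)
  kept <- attr(labels, "peaks")
  matrices <- lapply(tracks, function(t) {
    zscore_matrix(coverage_matrix(t, kept, window_bp = params$window_bp,
                                  bin_bp = params$bin_bp))
  })
  stats <- central_window_stats(matrices, labels, genotypes,
                                central_bp = params$central_bp)
  lmm <- fit_random_intercept_lmm(stats, interaction = interaction)
  chr4 <- tryCatch(chr4_fraction_test(peaksets, genotypes),
                   error = function(e) NULL)
  list(consensus = consensus, labels = labels, matrices = matrices,
       stats = stats, lmm = lmm, chr4 = chr4)
}

#' Run the configured pipeline stages and write a manifest
#'
#' Executes the declared stages in order, materializes every intermediate
#' artifact under `out_dir`, and writes `manifest.json` (config snapshot,
#' package version, per-stage row counts, md5 checksums of all outputs).
#' The configured seed is the only entropy source, so identical configs
#' reproduce identical outputs.
#'
#' @param config a `run_config` (see [validate_config()]), list or YAML
#'   path.
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   package_version =
                     as.character(utils::packageVersion("hmrtools")),
                   counts = list(), outputs = character())
  out <- function(...) file.path(config$out_dir, ...)
  fail_stage <- function(stage, e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  }
  apms_sim <- NULL
  fit <- NULL

  if ("simulate_apms" %in% config$stages) {
    apms_sim <- tryCatch({
      sim <- simulate_apms(apms_sim_config(seed = config$seed))
      write_protein_groups(sim$protein_groups, out("proteinGroups.txt"))
      write_sample_sheet(sim$sheet, out("samples.csv"))
      jsonlite::write_json(sim$ground_truth[c("core_complex",
                                              "bait_specific")],
                           out("apms_ground_truth.json"), auto_unbox = TRUE)
      sim
    }, error = function(e) fail_stage("simulate_apms", e))
    manifest$counts$apms_proteins <- length(apms_sim$protein_groups$protein_id)
  }

  if ("apms" %in% config$stages) {
    fit <- tryCatch({
      if (!is.null(apms_sim)) {
        pg <- apms_sim$protein_groups
        sheet <- apms_sim$sheet
      } else {
        if (is.null(config$protein_groups) || is.null(config$samples)) {
          stopf("apms stage needs 'protein_groups' and 'samples' inputs")
        }
        pg <- read_protein_groups(config$protein_groups)
        sheet <- read_sample_sheet(config$samples)
      }
      baits <- config$baits %||% unique(sheet$bait[!sheet$is_control])
      f <- apms_enrich(pg, sheet, baits = baits, shift = config$shift,
                       scale = config$scale, seed = config$seed)
      for (b in names(f$results)) {
        write_tsv(as.data.frame(f$results[[b]]),
                  out(sprintf("enrichment_%s.tsv", b)))
      }
      f
    }, error = function(e) fail_stage("apms", e))
    manifest$counts$apms_retained <- nrow(fit$matrix)
    manifest$counts$apms_contrasts <- length(fit$results)
  }

  if ("interactome" %in% config$stages) {
    tryCatch({
      if (is.null(fit)) stopf("interactome stage needs the apms stage")
      sets <- interactor_sets(fit, log2fc_min = config$log2fc_min,
                              p_adj_max = config$p_adj_max)
      inter <- exclusive_intersections(sets)
      consensus <- suppressWarnings(consensus_complex(sets))
      net <- export_network_edges(sets, fit$results)
      membership <- data.frame(
        protein_id = sort(unique(unlist(sets))), stringsAsFactors = FALSE)
      for (b in names(sets)) {
        membership[[b]] <- as.integer(membership$protein_id %in% sets[[b]])
      }
      write_tsv(membership, out("upset_membership.tsv"))
      write_tsv(inter, out("upset_intersections.tsv"))
      write_tsv(net$edges, out("network_edges.tsv"))
      write_tsv(net$nodes, out("network_nodes.tsv"))
      jsonlite::write_json(list(consensus = consensus,
                                near_miss = consensus_near_miss(sets)),
                           out("consensus.json"), auto_unbox = TRUE)
      manifest$counts$consensus_size <- length(consensus)
    }, error = function(e) fail_stage("interactome", e))
  }

  chip_sim <- NULL
  if ("simulate_chip" %in% config$stages) {
    chip_sim <- tryCatch({
      sim <- simulate_chip(chip_sim_config(seed = config$seed))
      for (s in names(sim$peaksets)) {
        write_bed(sim$peaksets[[s]], out(sprintf("peaks_%s.bed", s)))
      }
      jsonlite::write_json(
        list(class = as.list(sim$ground_truth$class)),
        out("chip_ground_truth.json"), auto_unbox = TRUE)
      sim
    }, error = function(e) fail_stage("simulate_chip", e))
    manifest$counts$chip_true_peaks <- nrow(chip_sim$peaks)
  }

  if ("chip" %in% config$stages) {
    tryCatch({
      if (is.null(chip_sim)) {
        stopf("chip stage currently requires the simulate_chip stage")
      }
      genotypes <- stats::setNames(chip_sim$sample_info$genotype,
                                   chip_sim$sample_info$sample)
      res <- chip_pipeline(chip_sim$peaksets, chip_sim$tracks,
                           chip_sim$hp1a_track, genotypes,
                           params = config)
      cons_out <- as.data.frame(res$consensus)
      cons_out$class <- unname(res$labels[match(cons_out$name,
                                                names(res$labels))])
      write_tsv(cons_out, out("consensus_peaks.tsv"))
      write_tsv(res$stats, out("central_window_stats.tsv"))
      jsonlite::write_json(
        list(fixed_effects = res$lmm$fixed_effects,
             varcomp = as.list(res$lmm$varcomp),
             df_method = res$lmm$df_method,
             chr4 = if (!is.null(res$chr4)) {
               list(slope = res$chr4$slope, p = res$chr4$p)
             }),
        out("chip_lmm.json"), auto_unbox = TRUE, digits = NA)
      manifest$counts$chip_consensus_peaks <- nrow(res$consensus)
    }, error = function(e) fail_stage("chip", e))
  }

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   file.path(config$out_dir, "manifest.json"))
  manifest$outputs <- stats::setNames(
    as.vector(tools::md5sum(files)), basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
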