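#' Gate significant interactors of one contrast
#'
#' Applies the enrichment cut-off: `log2fc > log2fc_min` (strict) and
#' `p_adj < p_adj_max` (strict). Defaults 2.5 and 0.05.
#'
#' @param results an `enrichment_result` data frame (one bait contrast).
#' @param log2fc_min minimum log2 fold-change (exclusive).
#' @param p_adj_max maximum BH-adjusted p (exclusive).
#' @return Character vector of gated protein ids.
#' @export
gate_interactors <- function(results, log2fc_min = 2.5, p_adj_max = 0.05) {
  stopifnot(all(c("protein_id", "log2fc", "p_adj") %in% names(results)))
  results$protein_id[results$log2fc > log2fc_min &
                       results$p_adj < p_adj_max]
}

#' Gated interactor sets for all baits
#'
#' One gated set per bait; each bait's own protein is always a member of its
#' set (the bait is trivially self-enriched in its own IP).
#'
#' @param fit an `apms_fit`, or a named list of `enrichment_result` tables.
#' @param log2fc_min,p_adj_max gate thresholds (see [gate_interactors()]).
#' @param bait_proteins named character vector mapping bait labels to their
#'   own protein ids; defaults to the bait labels themselves.
#' @return Named list of character sets, class `interactor_sets`.
#' @export
interactor_sets <- function(fit, log2fc_min = 2.5, p_adj_max = 0.05,
                            bait_proteins = NULL) {
  results <- if (inherits(fit, "apms_fit")) fit$results else fit
  if (is.null(names(results))) stopf("results must be named by bait")
  if (is.null(bait_proteins)) {
    bait_proteins <- stats::setNames(names(results), names(results))
  }
  sets <- lapply(names(results), function(b) {
    s <- gate_interactors(results[[b]], log2fc_min, p_adj_max)
    bp <- bait_proteins[[b]]
    if (!is.null(bp) && bp %in% results[[b]]$protein_id) s <- union(s, bp)
    sort(unique(s))
  })
  names(sets) <- names(results)
  structure(sets, class = "interactor_sets")
}

#' @export
print.interactor_sets <- function(x, ...) {
  cat("interactor_sets:\n")
  for (b in names(x)) cat(sprintf("  %s: %d protein(s)\n", b, length(x[[b]])))
  invisible(x)
}

#' Exclusive (UpSet-style) set intersections
#'
#' Partitions the union of all sets: every protein is assigned to exactly one
#' cell, the exact combination of sets containing it, and cells are counted.
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @return data frame with `combination` (set names joined by `&`), `degree`
#'   (number of sets in the combination) and `count`, sorted by decreasing
#'   count; member ids are attached as attribute `members` (named list).
#' @export
exclusive_intersections <- function(sets) {
  sets <- unclass(sets)
  if (length(sets) < 2L) stopf("need >= 2 sets")
  if (is.null(names(sets))) stopf("sets must be named")
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0L) {
    out <- data.frame(combination = character(), degree = integer(),
                      count = integer())
    attr(out, "members") <- list()
    return(out)
  }
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(sets)))
  key <- apply(membership, 1L, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  members <- split(universe, key)
  out <- data.frame(combination = names(members),
                    degree = lengths(strsplit(names(members), "&",
                                              fixed = TRUE)),
                    count = lengths(members),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Consensus complex: proteins gated in every bait's set
#'
#' The full-intersection cell of the exclusive-intersection partition over
#' all reciprocal IPs; the working definition of the complex.
#'
#' @param sets an `interactor_sets` (or named list) with one set per bait.
#' @return Sorted character vector of consensus protein ids.
#' @export
consensus_complex <- function(sets) {
  sets <- unclass(sets)
  if (any(lengths(sets) == 0L)) {
    warning(sprintf("empty gated set(s): %s; consensus will be empty",
                    paste(names(sets)[lengths(sets) == 0L], collapse = ", ")))
  }
  sort(Reduce(intersect, sets))
}

#' Near-miss table: proteins gated in all but one bait
#'
#' Diagnostic companion of [consensus_complex()]: proteins present in
#' exactly `k - 1` of the `k` sets, with the missing bait named; surfaces
#' borderline subunits whose enrichment is weaker in one IP.
#'
#' @inheritParams consensus_complex
#' @return data frame `protein_id`, `n_sets`, `missing_from`.
#' @export
consensus_near_miss <- function(sets) {
  sets <- unclass(sets)
  k <- length(sets)
  universe <- sort(unique(unlist(sets)))
  inset <- vapply(sets, function(s) universe %in% s,
                  logical(length(universe)))
  inset <- matrix(inset, nrow = length(universe),
                  dimnames = list(universe, names(sets)))
  n_sets <- rowSums(inset)
  idx <- which(n_sets == k - 1L)
  data.frame(
    protein_id = universe[idx],
    n_sets = n_sets[idx],
    missing_from = vapply(idx, function(i) names(sets)[!inset[i, ]][1L], ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bait-normalize an enrichment profile
#'
#' Expresses every protein's enrichment relative to the bait protein's own
#' enrichment: `normalized_p = log2fc_p - log2fc_bait` (a log2 ratio of
#' enrichments). The bait maps to 0; global additive shifts cancel.
#'
#' @param results an `enrichment_result`, or a named numeric vector of
#'   log2 fold-changes.
#' @param bait_protein protein id of the bait.
#' @return Named numeric vector of bait-normalized enrichments.
#' @export
bait_normalize <- function(results, bait_protein) {
  fc <- if (is.data.frame(results)) {
    stats::setNames(results$log2fc, results$protein_id)
  } else {
    results
  }
  if (!bait_protein %in% names(fc) || !is.finite(fc[[bait_protein]])) {
    stopf("bait protein '%s' absent or non-finite", bait_protein)
  }
  fc - fc[[bait_protein]]
}

#' Offsets from the diagonal between two bait-normalized conditions
#'
#' In a two-condition scatter of bait-normalized enrichments, a protein whose
#' relative association is unchanged sits on the diagonal; the per-replicate
#' offset `normalized_b - normalized_a` measures the change, summarized as
#' mean and SEM over replicate experiments. Positive mean = stronger relative
#' association in condition b.
#'
#' @param profiles_a,profiles_b proteins x replicates matrices of
#'   bait-normalized per-replicate enrichments (see [replicate_log2fc()] and
#'   [bait_normalize()]); rows are matched by name.
#' @return data frame `protein_id`, `mean_offset`, `sem` (`NA` when a single
#'   replicate pair contributes), `n`.
#' @export
diagonal_offset <- function(profiles_a, profiles_b) {
  common <- intersect(rownames(profiles_a), rownames(profiles_b))
  dropped <- setdiff(union(rownames(profiles_a), rownames(profiles_b)), common)
  if (length(dropped)) {
    msgf("diagonal_offset: excluding %d protein(s) absent in one condition",
         length(dropped))
  }
  a <- profiles_a[common, , drop = FALSE]
  b <- profiles_b[common, , drop = FALSE]
  n <- min(ncol(a), ncol(b))
  # paired by replicate index up to the smaller replicate count
  off <- b[, seq_len(n), drop = FALSE] - a[, seq_len(n), drop = FALSE]
  data.frame(
    protein_id = common,
    mean_offset = rowMeans(off),
    sem = if (n >= 2L) apply(off, 1L, stats::sd) / sqrt(n)
          else rep(NA_real_, length(common)),
    n = n, row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential gate between two conditions of the same bait
#'
#' A protein enters the comparison when it is enriched versus control at raw
#' `p < raw_p_max` in at least one condition; it is labeled differential when
#' the between-condition log2 fold-change `delta = log2fc_alt - log2fc_ref`
#' clears `diff_log2fc_max` in the requested direction (`"two.sided"`:
#' `|delta| > threshold`; `"less"`/`"greater"`: signed).
#'
#' @param results_ref,results_alt `enrichment_result` tables for the
#'   reference and alternative condition, computed on the same proteome.
#' @param raw_p_max inclusion threshold on the raw p-value (default 0.05).
#' @param diff_log2fc_max differential-label threshold in log2 units
#'   (default 1.5).
#' @param direction `"two.sided"`, `"less"` (alt below ref) or `"greater"`.
#' @return data frame `protein_id`, `log2fc_ref`, `log2fc_alt`, `delta`,
#'   `included`, `differential`.
#' @export
differential_gate <- function(results_ref, results_alt, raw_p_max = 0.05,
                              diff_log2fc_max = 1.5,
                              direction = c("two.sided", "less", "greater")) {
  direction <- match.arg(direction)
  if (!identical(sort(results_ref$protein_id), sort(results_alt$protein_id))) {
    stopf("both contrasts must cover the same proteome")
  }
  alt <- results_alt[match(results_ref$protein_id, results_alt$protein_id), ]
  delta <- alt$log2fc - results_ref$log2fc
  included <- results_ref$p < raw_p_max | alt$p < raw_p_max
  differential <- switch(direction,
    two.sided = abs(delta) > diff_log2fc_max,
    less = delta < -diff_log2fc_max,
    greater = delta > diff_log2fc_max)
  data.frame(protein_id = results_ref$protein_id,
             log2fc_ref = results_ref$log2fc,
             log2fc_alt = alt$log2fc,
             delta = delta,
             included = included,
             differential = included & differential,
             stringsAsFactors = FALSE)
}

#' Export the bait-prey network as an edge list
#'
#' One edge per (bait, gated prey) pair, deduplicated; node attributes flag
#' consensus-complex membership. Layout is left to downstream tools.
#'
#' @param sets an `interactor_sets`.
#' @param results optional named list of `enrichment_result` tables supplying
#'   edge weights (the prey's log2fc in that bait's contrast).
#' @return List with `edges` (`source`, `target`, `weight`) and `nodes`
#'   (`node`, `is_bait`, `in_consensus`).
#' @export
export_network_edges <- function(sets, results = NULL) {
  consensus <- suppressWarnings(consensus_complex(sets))
  edges <- do.call(rbind, lapply(names(sets), function(b) {
    prey <- setdiff(sets[[b]], b)
    if (length(prey) == 0L) return(NULL)
    w <- if (!is.null(results) && b %in% names(results)) {
      r <- results[[b]]
      r$log2fc[match(prey, r$protein_id)]
    } else {
      rep(NA_real_, length(prey))
    }
    data.frame(source = b, target = prey, weight = w,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric())
  }
  nodes <- sort(unique(c(names(sets), edges$source, edges$target)))
  list(edges = edges,
       nodes = data.frame(node = nodes,
                          is_bait = nodes %in% names(sets),
                          in_consensus = nodes %in% consensus,
                          stringsAsFactors = FALSE))
}
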