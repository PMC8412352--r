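#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated `proteinGroups.txt` dialect: one row per protein
#' group, per-sample intensity columns named `"<intensity_prefix><sample>"`
#' (default `"iBAQ "`), and the decoy/contaminant flag columns `Reverse`,
#' `Potential contaminant` and `Only identified by site` (dotted MaxQuant
#' variants are accepted) holding `"+"` or empty. Zero or empty intensities
#' are non-detections and become missing (`NA`).
#'
#' @param path path to a tab-separated file.
#' @param intensity_prefix exact column-name prefix locating intensity
#'   columns; the remainder of the column name is the sample id.
#' @return A `protein_groups` object: list with `protein_id`, `gene_name`,
#'   logical vectors `reverse_flag`, `contaminant_flag`, `site_only_flag`,
#'   and `intensities`, a proteins x samples numeric matrix (linear scale,
#'   `NA` = missing).
#' @export
read_protein_groups <- function(path, intensity_prefix = "iBAQ ") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  id_col <- intersect(c("Protein IDs", "Protein.IDs", "protein_id"), names(df))
  if (length(id_col) == 0L) {
    stopf("no protein-id column ('Protein IDs') in %s", path)
  }
  id_col <- id_col[1L]
  int_cols <- names(df)[startsWith(names(df), intensity_prefix)]
  if (length(int_cols) == 0L) {
    stopf("no intensity columns with prefix '%s' in %s", intensity_prefix, path)
  }
  samples <- substring(int_cols, nchar(intensity_prefix) + 1L)
  if (anyDuplicated(samples)) {
    stopf("duplicate sample column(s): %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  intens <- vapply(int_cols, function(cn) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    v[is.na(v) | v == 0] <- NA_real_
    v
  }, numeric(nrow(df)))
  intens <- matrix(intens, nrow = nrow(df),
                   dimnames = list(NULL, samples))
  if (any(intens < 0, na.rm = TRUE)) stopf("negative intensity in %s", path)
  flag <- function(variants) {
    cn <- intersect(variants, names(df))
    if (length(cn) == 0L) {
      msgf("flag column %s absent; defaulting to FALSE", variants[1L])
      return(rep(FALSE, nrow(df)))
    }
    trimws(df[[cn[1L]]]) == "+"
  }
  gene_col <- intersect(c("Gene names", "Gene.names", "gene_name"), names(df))
  pg <- protein_groups(
    protein_id = df[[id_col]],
    gene_name = if (length(gene_col)) df[[gene_col[1L]]] else
      rep(NA_character_, nrow(df)),
    intensities = intens,
    reverse_flag = flag(c("Reverse")),
    contaminant_flag = flag(c("Potential contaminant", "Potential.contaminant")),
    site_only_flag = flag(c("Only identified by site",
                            "Only.identified.by.site"))
  )
  pg
}

#' Construct a protein-groups object
#'
#' @param protein_id unique protein-group identifiers.
#' @param intensities proteins x samples numeric matrix, linear scale,
#'   strictly positive where present, `NA` = missing.
#' @param gene_name optional gene symbols.
#' @param reverse_flag,contaminant_flag,site_only_flag logical filter flags.
#' @return A `protein_groups` object.
#' @export
protein_groups <- function(protein_id, intensities, gene_name = NULL,
                           reverse_flag = NULL, contaminant_flag = NULL,
                           site_only_flag = NULL) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id)) stopf("protein_id values must be unique")
  n <- length(protein_id)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != n) stopf("intensity rows != number of proteins")
  if (is.null(colnames(intensities))) stopf("intensities need sample names")
  if (any(intensities <= 0, na.rm = TRUE)) {
    stopf("intensities must be strictly positive where present")
  }
  rownames(intensities) <- protein_id
  default <- function(x) if (is.null(x)) rep(FALSE, n) else as.logical(x)
  structure(list(
    protein_id = protein_id,
    gene_name = if (is.null(gene_name)) rep(NA_character_, n)
                else as.character(gene_name),
    intensities = intensities,
    reverse_flag = default(reverse_flag),
    contaminant_flag = default(contaminant_flag),
    site_only_flag = default(site_only_flag)
  ), class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf(
    "protein_groups: %d proteins x %d samples (%.1f%% missing); flagged: %d\n",
    length(x$protein_id), ncol(x$intensities),
    100 * mean(is.na(x$intensities)),
    sum(x$reverse_flag | x$contaminant_flag | x$site_only_flag)))
  invisible(x)
}

#' Write a protein-groups object as a proteinGroups-dialect TSV
#'
#' @param pg a `protein_groups` object.
#' @param path output path.
#' @param intensity_prefix column prefix for intensity columns.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(pg, path, intensity_prefix = "iBAQ ") {
  flag_chr <- function(f) ifelse(f, "+", "")
  out <- data.frame(`Protein IDs` = pg$protein_id,
                    `Gene names` = ifelse(is.na(pg$gene_name), "",
                                          pg$gene_name),
                    check.names = FALSE, stringsAsFactors = FALSE)
  ints <- pg$intensities
  ints[is.na(ints)] <- 0
  for (s in colnames(ints)) {
    out[[paste0(intensity_prefix, s)]] <-
      format(ints[, s], trim = TRUE, digits = 15, scientific = FALSE)
  }
  out[["Reverse"]] <- flag_chr(pg$reverse_flag)
  out[["Potential contaminant"]] <- flag_chr(pg$contaminant_flag)
  out[["Only identified by site"]] <- flag_chr(pg$site_only_flag)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id, bait, condition, replicate, is_control`.
#' `bait` is the experiment label (e.g. the bait protein of an IP series),
#' `condition` one of `native`, `overexpressed_wt`, `mutant_dC`, `mutant_2`,
#' `control`.
#'
#' @param path CSV path.
#' @return A validated data frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df data frame with the sample-sheet columns.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "bait", "condition", "replicate", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sample sheet lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("sample_id values must be unique")
  df$is_control <- as.logical(df$is_control)
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1, na.rm = TRUE)) stopf("replicate must be >= 1")
  if (!any(df$is_control)) stopf("sample sheet needs at least one control")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname read_sample_sheet
#' @param sheet a `sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED3+ file into a genomic-intervals table
#'
#' 0-based half-open; output is sorted by (chrom, start). Records with
#' `start >= end` raise a format error.
#'
#' @param path BED path.
#' @return A `genomic_intervals` data frame (possibly 0-row).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(genomic_intervals(character(), numeric(), integer(1)[0]))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(parts))
  if (ncol_min < 3L) stopf("BED needs >= 3 columns: %s", path)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) stopf("non-numeric BED coordinates in %s",
                                        path)
  name <- if (ncol_min >= 4L) vapply(parts, `[[`, "", 4L) else NULL
  score <- if (ncol_min >= 5L) {
    suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
  } else NULL
  genomic_intervals(chrom, start, end, name = name, score = score)
}

#' Write a genomic-intervals table as BED
#'
#' @param intervals a `genomic_intervals` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end",
            intersect(c("name", "score"), names(intervals)))
  df <- as.data.frame(intervals)[, cols, drop = FALSE]
  # BED has no header; name column must precede score
  if ("score" %in% cols && !"name" %in% cols) {
    df$name <- "."
    df <- df[, c("chrom", "start", "end", "name", "score")]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph into a fixed-bin coverage track
#'
#' Records (0-based half-open, arbitrary widths) are averaged into fixed
#' `bin_size` bins, weighting each record by the length of its overlap with
#' the bin; uncovered stretches stay 0. Total signal is conserved:
#' `sum(values * bin_size) == sum(record_value * record_length)`.
#'
#' @param path bedGraph path (4 columns).
#' @param bin_size target bin width (bp).
#' @param chrom_lengths named vector of chromosome lengths.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths) {
  track <- coverage_track(chrom_lengths, bin_size)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric")),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) return(track)
  if (any(df$start >= df$end)) stopf("bedGraph record with start >= end")
  unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
  if (length(unknown)) stopf("bedGraph chromosome(s) not in chrom_lengths: %s",
                             paste(unknown, collapse = ", "))
  if (any(df$end > chrom_lengths[df$chrom])) {
    stopf("bedGraph record extends beyond chromosome length")
  }
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    v <- track$values[[ch]]
    first <- floor(sub$start / bin_size)
    last <- floor((sub$end - 1) / bin_size)
    one <- first == last
    if (any(one)) {
      w <- (sub$end[one] - sub$start[one]) * sub$value[one]
      agg <- rowsum(w, group = first[one])
      idx <- as.integer(rownames(agg)) + 1L
      v[idx] <- v[idx] + agg[, 1L]
    }
    for (i in which(!one)) {
      bins <- first[i]:last[i]
      lo <- pmax(bins * bin_size, sub$start[i])
      hi <- pmin((bins + 1) * bin_size, sub$end[i])
      v[bins + 1L] <- v[bins + 1L] + (hi - lo) * sub$value[i]
    }
    track$values[[ch]] <- v
  }
  # accumulated signal mass -> per-bin mean; dividing by the nominal bin
  # width everywhere keeps sum(values * bin_size) equal to the record mass,
  # also in a trailing partial bin
  for (ch in names(track$values)) {
    track$values[[ch]] <- track$values[[ch]] / bin_size
  }
  track
}

#' Write a coverage track as bedGraph
#'
#' Consecutive equal-valued bins are run-length collapsed; zero runs are
#' omitted (bedGraph convention: uncovered means 0).
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$chrom_lengths)) {
    v <- track$values[[ch]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    start <- starts_bin[keep] * track$bin_size
    end <- pmin(ends_bin[keep] * track$bin_size, track$chrom_lengths[[ch]])
    writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                       format(start, trim = TRUE, scientific = FALSE),
                       format(end, trim = TRUE, scientific = FALSE),
                       format(r$values[keep], trim = TRUE, digits = 15,
                              scientific = FALSE)), con)
  }
  invisible(path)
}
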