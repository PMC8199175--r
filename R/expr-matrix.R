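#' Expression matrix container
#'
#' A `mir_expr` object bundles a numeric miRNA-by-sample matrix with per-sample
#' metadata. Values are either raw read counts (`unit = "counts"`) or reads per
#' million (`unit = "rpm"`). Every downstream stage of the analysis consumes
#' and returns this container.
#'
#' @param values Numeric matrix, miRNAs in rows (rownames = miRNA IDs),
#'   samples in columns (colnames = sample IDs). All values must be finite and
#'   non-negative.
#' @param samples Data frame of per-sample metadata with columns `sample_id`,
#'   `patient_id`, `group`, `cohort` and `total_reads`; one row per matrix
#'   column, in matrix column order (reordered to match if necessary).
#' @param unit `"counts"` or `"rpm"`.
#'
#' @return A `mir_expr` object.
#' @export
#' @examples
#' m <- matrix(c(0, 10, 5, 0), nrow = 2,
#'             dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' meta <- tibble::tibble(sample_id = c("s1", "s2"), patient_id = c("p1", "p2"),
#'                        group = c("ANL", "LUAD"), cohort = "discovery",
#'                        total_reads = c(6e6, 7e6))
#' mir_expr(m, meta)
mir_expr <- function(values, samples, unit = c("counts", "rpm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "oncofetal_format_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have miRNA rownames and sample colnames.",
          class = "oncofetal_format_error")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Duplicate miRNA IDs in matrix.", class = "oncofetal_format_error")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Duplicate sample IDs in matrix.", class = "oncofetal_format_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("Expression values must be finite (missing cells are an error).",
          class = "oncofetal_format_error")
  }
  if (any(values < 0)) {
    abort("Expression values must be non-negative.",
          class = "oncofetal_format_error")
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "patient_id", "group", "cohort", "total_reads")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    abort(paste0("Sample metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "oncofetal_metadata_error")
  }
  absent <- setdiff(colnames(values), samples$sample_id)
  if (length(absent)) {
    abort(paste0("Sample(s) in matrix absent from metadata: ",
                 paste(absent, collapse = ", ")),
          class = "oncofetal_metadata_error")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$group) || anyNA(samples$cohort)) {
    abort("Every sample needs a group and a cohort label.",
          class = "oncofetal_metadata_error")
  }
  structure(list(values = values, samples = samples, unit = unit),
            class = "mir_expr")
}

#' @export
print.mir_expr <- function(x, ...) {
  cat(sprintf("<mir_expr> %d miRNAs x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  grp <- table(x$samples$cohort, x$samples$group)
  print(grp)
  invisible(x)
}

#' @export
dim.mir_expr <- function(x) dim(x$values)

#' Subset a `mir_expr` by miRNAs and/or samples
#'
#' @param x A [mir_expr()] object.
#' @param i,j miRNA and sample indices (names, logical or integer).
#' @param ... Ignored.
#' @return A `mir_expr` with the selected rows/columns.
#' @export
`[.mir_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  mir_expr(v, x$samples[match(colnames(v), x$samples$sample_id), ], unit = x$unit)
}

#' Long-format view of an expression matrix
#'
#' @param x A [mir_expr()] object.
#' @param ... Ignored.
#' @return A tibble with one row per (miRNA, sample) cell: `mirna_id`,
#'   `sample_id`, `value`, `unit`, joined with the sample metadata.
#' @method tidy mir_expr
#' @export
tidy.mir_expr <- function(x, ...) {
  long <- tibble(
    mirna_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    unit = x$unit
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' @importFrom tibble as_tibble
#' @method as_tibble mir_expr
#' @export
as_tibble.mir_expr <- function(x, ...) tidy.mir_expr(x, ...)

#' Read a count matrix and its sample metadata from TSV
#'
#' The matrix file has a `mirna_id` first column and one column per sample;
#' the metadata file must describe every sample. Cells must be non-negative
#' numbers; an empty cell is an error, not a zero.
#'
#' @param matrix_path Path to the count matrix TSV.
#' @param meta_path Path to the sample metadata TSV (columns `sample_id`,
#'   `patient_id`, `group`, `cohort`, `total_reads`).
#' @return A counts-unit [mir_expr()].
#' @export
read_count_matrix <- function(matrix_path, meta_path) {
  mat_df <- readr::read_tsv(matrix_path, col_types = readr::cols(
    .default = readr::col_double(),
    mirna_id = readr::col_character()
  ), progress = FALSE)
  if (names(mat_df)[1] != "mirna_id") {
    abort("First column of the count matrix must be 'mirna_id'.",
          class = "oncofetal_format_error")
  }
  if (anyNA(mat_df)) {
    abort("Count matrix contains missing or non-numeric cells.",
          class = "oncofetal_format_error")
  }
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    patient_id = readr::col_character(),
    group = readr::col_character(),
    cohort = readr::col_character(),
    total_reads = readr::col_double()
  ), progress = FALSE)
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(values) <- mat_df$mirna_id
  mir_expr(values, meta, unit = "counts")
}

#' Write an expression matrix and metadata to TSV
#'
#' Emits the same dialect [read_count_matrix()] reads (tab-separated, `.`
#' decimal, LF line endings) so that write-then-read round-trips exactly.
#'
#' @param m A [mir_expr()].
#' @param matrix_path,meta_path Output paths.
#' @return `m`, invisibly.
#' @export
write_matrix <- function(m, matrix_path, meta_path) {
  df <- tibble(mirna_id = rownames(m$values))
  df <- dplyr::bind_cols(df, as_tibble(m$values))
  readr::write_tsv(df, matrix_path, eol = "\n", progress = FALSE)
  readr::write_tsv(m$samples, meta_path, eol = "\n", progress = FALSE)
  invisible(m)
}

#' Drop samples sequenced below a read-depth threshold
#'
#' Samples whose `total_reads` fall strictly below `min_reads` (default five
#' million) are excluded. If `total_reads` is missing the column sums of the
#' count matrix are used instead, with a warning.
#'
#' @param m A counts-unit [mir_expr()].
#' @param min_reads Minimum depth; samples with `total_reads >= min_reads`
#'   are kept.
#' @return The filtered [mir_expr()]. Removed sample IDs are reported via a
#'   message and attached as attribute `removed_samples`.
#' @export
filter_low_depth <- function(m, min_reads = 5e6) {
  stopifnot(inherits(m, "mir_expr"))
  if (m$unit != "counts") {
    abort("filter_low_depth() expects a counts-unit matrix.",
          class = "oncofetal_unit_error")
  }
  totals <- m$samples$total_reads
  if (anyNA(totals)) {
    warn("total_reads missing for some samples; falling back to column sums.")
    cs <- colSums(m$values)
    totals[is.na(totals)] <- cs[is.na(totals)]
  }
  keep <- totals >= min_reads
  if (!any(keep)) {
    abort("Depth filter removed every sample.", class = "oncofetal_empty_cohort_error")
  }
  removed <- m$samples$sample_id[!keep]
  if (length(removed)) {
    message(sprintf("filter_low_depth: removed %d sample(s): %s",
                    length(removed), paste(removed, collapse = ", ")))
  }
  out <- m[, keep]
  attr(out, "removed_samples") <- removed
  out
}

#' Collapse replicate samples of a patient to their mean
#'
#' Samples sharing (`patient_id`, `group`) are replaced by one pseudo-sample
#' whose counts are the arithmetic mean of the replicate counts (real-valued
#' means are kept) and whose `total_reads` is the mean of the replicate
#' totals. Patients with a single sample pass through unchanged.
#'
#' @param m A counts-unit [mir_expr()] with `patient_id` populated.
#' @return A [mir_expr()] with one column per (patient, group).
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "mir_expr"))
  if (m$unit != "counts") {
    abort("average_replicates() expects a counts-unit matrix.",
          class = "oncofetal_unit_error")
  }
  smp <- m$samples
  span <- dplyr::summarise(dplyr::group_by(smp, .data$patient_id),
                           n_groups = dplyr::n_distinct(.data$group),
                           .groups = "drop")
  if (any(span$n_groups > 1)) {
    bad <- span$patient_id[span$n_groups > 1]
    abort(paste0("Replicates span multiple groups for patient(s): ",
                 paste(bad, collapse = ", ")),
          class = "oncofetal_metadata_error")
  }
  key <- paste(smp$patient_id, smp$group, sep = "\r")
  first_idx <- !duplicated(key)
  if (all(first_idx)) return(m)
  ukey <- key[first_idx]
  grp <- factor(key, levels = ukey)
  # column-group means: values %*% indicator / n
  ind <- vapply(ukey, function(k) as.numeric(key == k), numeric(length(key)))
  n_per <- colSums(ind)
  avg <- (m$values %*% ind) %*% diag(1 / n_per, length(n_per))
  colnames(avg) <- smp$sample_id[first_idx]
  new_meta <- smp[first_idx, ]
  new_meta$total_reads <- as.vector(tapply(smp$total_reads, grp, mean))
  mir_expr(avg, new_meta, unit = "counts")
}

#' Normalize counts to reads per million
#'
#' Each sample column is scaled by its own total of miRNA-assigned reads:
#' `rpm[i, j] = counts[i, j] / sum(counts[, j]) * 1e6`. The `total_reads`
#' metadata plays no role here; normalization is self-contained in the matrix.
#'
#' @param m A counts-unit [mir_expr()].
#' @return An rpm-unit [mir_expr()]; every column sums to 1e6.
#' @export
normalize_rpm <- function(m) {
  stopifnot(inherits(m, "mir_expr"))
  if (m$unit != "counts") {
    abort("normalize_rpm() expects a counts-unit matrix.",
          class = "oncofetal_unit_error")
  }
  cs <- colSums(m$values)
  if (any(cs == 0)) {
    abort(paste0("Sample(s) with zero total counts cannot be normalized: ",
                 paste(colnames(m$values)[cs == 0], collapse = ", ")),
          class = "oncofetal_degenerate_sample_error")
  }
  v <- sweep(m$values, 2, cs, "/") * 1e6
  mir_expr(v, m$samples, unit = "rpm")
}

#' Presence/absence expression call per miRNA in one sample group
#'
#' A miRNA is called expressed in a group when at least 1 RPM is observed in
#' at least 10% of that group's samples; both comparisons are inclusive and
#' the fraction is exact (no rounding to whole samples).
#'
#' @param m An rpm-unit [mir_expr()].
#' @param group Group label (e.g. `"FL"`, `"ANL"`, `"LUAD"`).
#' @param min_rpm Per-sample positivity threshold (default 1 RPM, inclusive).
#' @param min_fraction Detection fraction threshold (default 0.10, inclusive).
#' @return A tibble with columns `mirna_id`, `group`, `n_samples`,
#'   `fraction_positive`, `expressed`.
#' @export
detect_expressed <- function(m, group, min_rpm = 1, min_fraction = 0.10) {
  stopifnot(inherits(m, "mir_expr"))
  if (m$unit != "rpm") {
    abort("detect_expressed() expects an rpm-unit matrix.",
          class = "oncofetal_unit_error")
  }
  in_group <- m$samples$group == group
  if (!any(in_group)) {
    abort(paste0("No samples in group '", group, "'."),
          class = "oncofetal_metadata_error")
  }
  sub <- m$values[, in_group, drop = FALSE]
  frac <- rowMeans(sub >= min_rpm)
  tibble(
    mirna_id = rownames(m$values),
    group = group,
    n_samples = sum(in_group),
    fraction_positive = unname(frac),
    expressed = unname(frac >= min_fraction)
  )
}

#' Expression calls for every group in a matrix
#'
#' @inheritParams detect_expressed
#' @return Row-bound [detect_expressed()] tibbles, one block per group.
#' @export
detect_expressed_all <- function(m, min_rpm = 1, min_fraction = 0.10) {
  groups <- sort(unique(m$samples$group))
  purrr::map_dfr(groups, ~detect_expressed(m, .x, min_rpm, min_fraction))
}
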