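# small fixture builders, generated in code

make_meta <- function(sample_ids, group = "LUAD", cohort = "discovery",
                      patient_id = sample_ids, total_reads = 6e6) {
  tibble::tibble(sample_id = sample_ids, patient_id = patient_id,
                 group = group, cohort = cohort, total_reads = total_reads)
}

make_expr <- function(values, group, unit = "counts", cohort = "discovery",
                      patient_id = NULL, total_reads = 6e6) {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("miR-%02d", seq_len(nrow(values)))
  }
  if (is.null(patient_id)) patient_id <- colnames(values)
  meta <- make_meta(colnames(values), group = group, cohort = cohort,
                    patient_id = patient_id, total_reads = total_reads)
  mir_expr(values, meta, unit = unit)
}

random_expr <- function(n_mir = 8, n_samp = 6, group = "LUAD",
                        max_count = 1000, unit = "counts") {
  v <- matrix(sample.int(max_count, n_mir * n_samp, replace = TRUE) - 1,
              nrow = n_mir)
  make_expr(v, group = group, unit = unit)
}

# one-miRNA LUAD matrix whose designated miRNA sits near the 1-RPM positivity
# boundary, giving a mixed positive/negative split (plus a filler miRNA that
# absorbs the remaining library mass)
borderline_survival_matrix <- function(n = 379, target_mean_rpm = 1,
                                       dispersion = 0.2, seed = 42) {
  withr::with_seed(seed, {
    lib <- round(runif(n, 5e6, 2e7))
    marker <- stats::rnbinom(n, mu = target_mean_rpm * lib / 1e6,
                             size = 1 / dispersion)
    filler <- lib - marker
    v <- rbind(marker = marker, filler = pmax(filler, 1))
    colnames(v) <- sprintf("LUAD_%03d", seq_len(n))
    normalize_rpm(make_expr(v, group = "LUAD", total_reads = lib))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
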