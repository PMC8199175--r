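#' Classify miRNAs as oncofetal across two cohorts
#'
#' A miRNA is oncofetal when all three criteria hold:
#'
#' * (a) overexpressed in both discovery LUAD vs ANL and discovery FL vs ANL;
#' * (b) overexpressed in validation LUAD vs ANL;
#' * (c) not expressed (fewer than 10% of samples with RPM >= 1) in both the
#'   discovery and the validation ANL group.
#'
#' @param de_discovery DE results for the discovery cohort (tibble from
#'   [de_discovery()]) containing the `LUAD_vs_ANL` and `FL_vs_ANL`
#'   comparisons.
#' @param de_validation DE results for the validation cohort containing the
#'   `LUAD_vs_ANL` comparison.
#' @param calls_discovery_anl,calls_validation_anl Expression calls for the
#'   ANL group of each cohort, from [detect_expressed()].
#' @return A tibble `mirna_id`, `crit_a`, `crit_b`, `crit_c`, `oncofetal`.
#' @export
classify_oncofetal <- function(de_discovery, de_validation,
                               calls_discovery_anl, calls_validation_anl) {
  ids <- unique(de_discovery$mirna_id)
  pull_status <- function(de, cmp) {
    sub <- de[de$comparison == cmp, ]
    miss <- setdiff(ids, sub$mirna_id)
    if (length(miss)) {
      abort(paste0("miRNA(s) missing from comparison ", cmp, ": ",
                   paste(utils::head(miss, 5), collapse = ", ")),
            class = "oncofetal_consistency_error")
    }
    sub$status[match(ids, sub$mirna_id)]
  }
  pull_expressed <- function(calls, label) {
    miss <- setdiff(ids, calls$mirna_id)
    if (length(miss)) {
      abort(paste0("miRNA(s) missing from ", label, " expression calls: ",
                   paste(utils::head(miss, 5), collapse = ", ")),
            class = "oncofetal_consistency_error")
    }
    calls$expressed[match(ids, calls$mirna_id)]
  }
  luad_disc <- pull_status(de_discovery, "LUAD_vs_ANL")
  fl_disc <- pull_status(de_discovery, "FL_vs_ANL")
  luad_val <- pull_status(de_validation, "LUAD_vs_ANL")
  expr_disc <- pull_expressed(calls_discovery_anl, "discovery ANL")
  expr_val <- pull_expressed(calls_validation_anl, "validation ANL")
  crit_a <- luad_disc == "over" & fl_disc == "over"
  crit_b <- luad_val == "over"
  crit_c <- !expr_disc & !expr_val
  tibble(mirna_id = ids, crit_a = crit_a, crit_b = crit_b, crit_c = crit_c,
         oncofetal = crit_a & crit_b & crit_c)
}

#' Contingency table of DE status between two comparisons
#'
#' Cross-tabulates per-miRNA status (`over`/`under`/`ns`) in one comparison
#' (rows) against another (columns), typically LUAD vs ANL against FL vs ANL,
#' to quantify tumour/fetal congruence. Optionally collapses to a 2x2
#' significant/ns table.
#'
#' @param de_rows,de_cols DE result tibbles (single comparison each).
#' @param collapse If `TRUE`, collapse `over`/`under` into one `sig` level.
#' @return An integer contingency matrix.
#' @export
congruence_table <- function(de_rows, de_cols, collapse = FALSE) {
  common <- intersect(de_rows$mirna_id, de_cols$mirna_id)
  a <- de_rows$status[match(common, de_rows$mirna_id)]
  b <- de_cols$status[match(common, de_cols$mirna_id)]
  lv <- c("over", "under", "ns")
  if (collapse) {
    a <- ifelse(a == "ns", "ns", "sig")
    b <- ifelse(b == "ns", "ns", "sig")
    lv <- c("sig", "ns")
  }
  table(factor(a, levels = lv), factor(b, levels = lv))
}

#' Exact test of independence on an r x c contingency table
#'
#' Freeman–Halton extension of Fisher's exact test (two-sided). Tables with a
#' grand total of at most `exact_max` are tested exactly; larger tables use a
#' seeded Monte Carlo estimate with at least one million draws. The method
#' used is recorded in the result.
#'
#' @param tab Non-negative integer matrix.
#' @param exact_max Largest grand total for which the exact test is used.
#' @param mc_draws Monte Carlo replicates beyond `exact_max`.
#' @param seed Seed for the Monte Carlo branch.
#' @return A tibble `p_value`, `method` (`"exact"` or `"monte_carlo"`),
#'   `n_total`.
#' @export
congruence_test <- function(tab, exact_max = 500, mc_draws = 1e6, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) {
    abort("Contingency entries must be non-negative.",
          class = "oncofetal_domain_error")
  }
  n <- sum(tab)
  if (n < 1) {
    abort("Contingency table is empty.", class = "oncofetal_domain_error")
  }
  # degenerate margins carry no information; independence holds trivially
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tab2 <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab2) < 2 || ncol(tab2) < 2) {
    return(tibble(p_value = 1, method = "exact", n_total = n))
  }
  if (n <= exact_max) {
    res <- tryCatch(
      stats::fisher.test(tab2, workspace = 2e7),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      return(tibble(p_value = res$p.value, method = "exact", n_total = n))
    }
  }
  p <- with_substream(seed, {
    stats::fisher.test(tab2, simulate.p.value = TRUE, B = mc_draws)$p.value
  })
  tibble(p_value = p, method = "monte_carlo", n_total = n)
}

#' Count hits whose locus is contained in a genomic region
#'
#' Containment is full (start and end both inside the region) and strand is
#' ignored; mature miRNA loci are ~22 bp, so containment and overlap rarely
#' differ.
#'
#' @param hits Character vector of miRNA IDs.
#' @param annotation Tibble with columns `mirna_id`, `chrom`, `start`, `end`
#'   (e.g. from [read_annotation()]).
#' @param region A single-row tibble from [parse_locus()] or a locus string.
#' @return Integer count of contained hits.
#' @export
count_in_region <- function(hits, annotation, region) {
  if (is.character(region)) region <- parse_locus(region)
  if (length(hits) == 0) return(0L)
  miss <- setdiff(hits, annotation$mirna_id)
  if (length(miss)) {
    abort(paste0("Hit(s) without annotation: ", paste(miss, collapse = ", ")),
          class = "oncofetal_consistency_error")
  }
  ann <- annotation[match(hits, annotation$mirna_id), ]
  sum(ann$chrom == region$chrom &
        ann$start >= region$start &
        ann$end <= region$end)
}

#' Genes targeted by at least a minimum number of panel miRNAs
#'
#' @param target_table Tibble of predicted miRNA-to-gene pairs with columns
#'   `mirna_id` and `gene_symbol`; duplicate pairs are collapsed.
#' @param min_mirnas Minimum number of distinct targeting miRNAs (default 3).
#' @return Character vector of gene symbols, sorted lexicographically.
#' @export
shared_targets <- function(target_table, min_mirnas = 3) {
  pairs <- dplyr::distinct(target_table, .data$mirna_id, .data$gene_symbol)
  counts <- dplyr::count(pairs, .data$gene_symbol)
  sort(counts$gene_symbol[counts$n >= min_mirnas])
}
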