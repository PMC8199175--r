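#' Fold change between group means
#'
#' Ratio of mean RPM, first-named group in the numerator. A small epsilon
#' (default 0.01 RPM) is added to both means so that presence/absence
#' contrasts — the rule rather than the exception for oncofetal candidates,
#' whose normal-lung means are near zero — stay finite.
#'
#' @param rpm_a,rpm_b Numeric vectors (one miRNA) or matrices
#'   (miRNA x samples) of untransformed RPM.
#' @param epsilon Stabilizer added to both means, in RPM.
#' @return Fold change(s), `(mean(a) + epsilon) / (mean(b) + epsilon)`.
#' @export
#' @examples
#' fold_change(c(18, 22), c(9, 11))  # 2.0009...
fold_change <- function(rpm_a, rpm_b, epsilon = 0.01) {
  ma <- if (is.matrix(rpm_a)) rowMeans(rpm_a) else mean(rpm_a)
  mb <- if (is.matrix(rpm_b)) rowMeans(rpm_b) else mean(rpm_b)
  (ma + epsilon) / (mb + epsilon)
}

log_transform <- function(rpm, pseudocount = 1) log2(rpm + pseudocount)

#' Row-wise one-way ANOVA with pairwise post-hoc tests
#'
#' Fixed-effects one-way ANOVA on `log2(RPM + pseudocount)` per miRNA, with
#' pairwise post-hoc p-values by Fisher's LSD (pairwise t statistics using
#' the pooled ANOVA error variance and its residual degrees of freedom) or
#' Tukey's HSD. Post-hoc p-values are reported only when the omnibus test is
#' significant at `alpha`; otherwise they are set to 1.
#'
#' @param m An rpm-unit [mir_expr()] (or a numeric RPM matrix if `groups` is
#'   given as a vector of per-column labels).
#' @param groups Group labels to include (for a `mir_expr`) or per-column
#'   label vector (for a plain matrix).
#' @param posthoc `"lsd"` (default) or `"tukey"`.
#' @param pseudocount Added to RPM before the log2 transform.
#' @param alpha Omnibus significance gate for reporting post-hoc p-values.
#' @return A tibble with one row per miRNA and group pair: `mirna_id`,
#'   `statistic` (omnibus F), `p_omnibus`, `comparison` (`"A_vs_B"`),
#'   `p_posthoc`.
#' @export
anova_posthoc <- function(m, groups = c("FL", "ANL", "LUAD"),
                          posthoc = c("lsd", "tukey"),
                          pseudocount = 1, alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  if (inherits(m, "mir_expr")) {
    if (m$unit != "rpm") {
      abort("anova_posthoc() expects an rpm-unit matrix.",
            class = "oncofetal_unit_error")
    }
    keep <- m$samples$group %in% groups
    values <- m$values[, keep, drop = FALSE]
    labels <- m$samples$group[keep]
  } else {
    values <- m
    labels <- groups
    groups <- unique(labels)
  }
  counts_per <- table(labels)[groups]
  if (any(is.na(counts_per)) || any(counts_per < 2)) {
    abort("Each group needs at least 2 samples.",
          class = "oncofetal_config_error")
  }
  y <- log_transform(values, pseudocount)
  k <- length(groups)
  n_tot <- ncol(y)
  n_g <- as.numeric(counts_per)
  means <- vapply(groups,
                  function(g) rowMeans(y[, labels == g, drop = FALSE]),
                  numeric(nrow(y)))
  if (!is.matrix(means)) means <- matrix(means, nrow = 1)
  grand <- rowSums(sweep(means, 2, n_g, "*")) / n_tot
  ssb <- rowSums(sweep((means - grand)^2, 2, n_g, "*"))
  ssw <- rowSums(y^2) - rowSums(sweep(means^2, 2, n_g, "*"))
  ssw <- pmax(ssw, 0)  # guard tiny negative from roundoff
  df1 <- k - 1
  df2 <- n_tot - k
  mse <- ssw / df2
  f_stat <- ifelse(ssw > 0, (ssb / df1) / mse,
                   ifelse(ssb > 0, Inf, 0))
  p_omni <- ifelse(is.infinite(f_stat), 0,
                   ifelse(f_stat == 0, 1, pf(f_stat, df1, df2, lower.tail = FALSE)))

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    i <- match(pr[1], groups); j <- match(pr[2], groups)
    diff <- means[, i] - means[, j]
    if (posthoc == "lsd") {
      se <- sqrt(mse * (1 / n_g[i] + 1 / n_g[j]))
      t_stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
      p_pair <- ifelse(is.infinite(t_stat), 0,
                       2 * pt(abs(t_stat), df2, lower.tail = FALSE))
    } else {
      se <- sqrt(mse / 2 * (1 / n_g[i] + 1 / n_g[j]))
      q_stat <- ifelse(se > 0, abs(diff) / se, ifelse(diff == 0, 0, Inf))
      p_pair <- ifelse(is.infinite(q_stat), 0,
                       stats::ptukey(q_stat, nmeans = k, df = df2,
                                     lower.tail = FALSE))
    }
    p_pair <- ifelse(p_omni < alpha, p_pair, 1)
    tibble(mirna_id = rownames(values),
           statistic = unname(f_stat),
           p_omnibus = unname(p_omni),
           comparison = paste0(pr[1], "_vs_", pr[2]),
           p_posthoc = unname(pmin(p_pair, 1)))
  })
  out
}

#' Row-wise Welch two-sample t-test
#'
#' Unpaired t on `log2(RPM + pseudocount)` with the Welch (unequal-variance)
#' correction and Welch–Satterthwaite degrees of freedom; two-sided p.
#'
#' @param rpm_a,rpm_b Numeric matrices (miRNA x samples) or vectors of
#'   untransformed RPM; at least 2 samples per group.
#' @param pseudocount Added to RPM before the log2 transform.
#' @return A tibble `statistic` (t, sign of a minus b), `df`, `p_value`
#'   (one row per miRNA; rownames of `rpm_a` used as `mirna_id` if present).
#' @export
welch_t <- function(rpm_a, rpm_b, pseudocount = 1) {
  if (!is.matrix(rpm_a)) rpm_a <- matrix(rpm_a, nrow = 1)
  if (!is.matrix(rpm_b)) rpm_b <- matrix(rpm_b, nrow = 1)
  if (ncol(rpm_a) < 2 || ncol(rpm_b) < 2) {
    abort("Each group needs at least 2 samples.",
          class = "oncofetal_config_error")
  }
  a <- log_transform(rpm_a, pseudocount)
  b <- log_transform(rpm_b, pseudocount)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  diff <- ma - mb
  t_stat <- ifelse(se2 > 0, diff / sqrt(se2),
                   ifelse(diff == 0, 0, Inf * sign(diff)))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(is.infinite(t_stat), 0,
              ifelse(t_stat == 0 & se2 == 0, 1,
                     2 * pt(abs(t_stat), df, lower.tail = FALSE)))
  tibble(mirna_id = rownames(rpm_a) %||% as.character(seq_len(nrow(rpm_a))),
         statistic = unname(t_stat), df = unname(df), p_value = unname(p))
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, returned in input order.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (monotone step-up, clipped at 1).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].", class = "oncofetal_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Over/under/ns status calls from fold change and p-value
#'
#' A miRNA is `over` when fold change exceeds `fc_threshold` (strictly) with
#' `p < alpha`, `under` when fold change is strictly below `1/fc_threshold`
#' with `p < alpha`, and `ns` otherwise. The p-value supplied should already
#' be the scheme-appropriate one (post-hoc p for the discovery scheme,
#' BH-adjusted p for the validation scheme).
#'
#' @param fc Fold changes (first-named group over second).
#' @param p Scheme-appropriate p-values.
#' @param alpha Significance threshold (default 0.05, strict).
#' @param fc_threshold Fold-change threshold (default 2, strict).
#' @return Character vector in `{"over", "under", "ns"}`.
#' @export
call_de_status <- function(fc, p, alpha = 0.05, fc_threshold = 2) {
  dplyr::case_when(
    fc > fc_threshold & p < alpha ~ "over",
    fc < 1 / fc_threshold & p < alpha ~ "under",
    TRUE ~ "ns"
  )
}

split_comparison <- function(comparison) {
  parts <- stringr::str_split_fixed(comparison, "_vs_", 2)
  if (any(parts == "")) {
    abort("Comparison labels must look like 'A_vs_B'.",
          class = "oncofetal_config_error")
  }
  parts
}

group_rpm <- function(m, group) {
  idx <- m$samples$group == group
  if (!any(idx)) {
    abort(paste0("No samples in group '", group, "'."),
          class = "oncofetal_metadata_error")
  }
  m$values[, idx, drop = FALSE]
}

#' Discovery-scheme differential expression (ANOVA + post-hoc)
#'
#' For each requested pairwise comparison: fold change on untransformed mean
#' RPM, significance from the one-way ANOVA post-hoc test across all three
#' groups, and a status call requiring FC > `fc_threshold` (or < its
#' reciprocal) with post-hoc p < `alpha`. No multiplicity adjustment is
#' applied in this scheme.
#'
#' @param m An rpm-unit [mir_expr()] with FL, ANL and LUAD samples.
#' @param comparisons Character vector of `"A_vs_B"` labels.
#' @inheritParams anova_posthoc
#' @param fc_epsilon Stabilizer for [fold_change()].
#' @param fc_threshold Fold-change threshold for status calls.
#' @return A tibble `mirna_id`, `comparison`, `fc`, `p_raw`, `p_adj` (NA for
#'   this scheme), `status`.
#' @export
de_discovery <- function(m, comparisons = c("LUAD_vs_ANL", "FL_vs_ANL"),
                         groups = c("FL", "ANL", "LUAD"),
                         posthoc = c("lsd", "tukey"), pseudocount = 1,
                         alpha = 0.05, fc_epsilon = 0.01, fc_threshold = 2) {
  posthoc <- match.arg(posthoc)
  aov_res <- anova_posthoc(m, groups = groups, posthoc = posthoc,
                           pseudocount = pseudocount, alpha = alpha)
  purrr::map_dfr(comparisons, function(cmp) {
    pr <- split_comparison(cmp)
    fc <- fold_change(group_rpm(m, pr[1]), group_rpm(m, pr[2]),
                      epsilon = fc_epsilon)
    # post-hoc p is symmetric in the pair; match either orientation
    ph <- aov_res[aov_res$comparison %in%
                    c(paste0(pr[1], "_vs_", pr[2]),
                      paste0(pr[2], "_vs_", pr[1])), ]
    ph <- ph[match(rownames(m$values), ph$mirna_id), ]
    tibble(mirna_id = rownames(m$values),
           comparison = cmp,
           fc = unname(fc),
           p_raw = ph$p_posthoc,
           p_adj = NA_real_,
           status = call_de_status(unname(fc), ph$p_posthoc,
                                   alpha = alpha, fc_threshold = fc_threshold))
  })
}

#' Validation-scheme differential expression (Welch t + BH)
#'
#' Unpaired Welch t-test per miRNA with Benjamini–Hochberg adjustment across
#' all tested miRNAs; status requires FC > `fc_threshold` (or < its
#' reciprocal) with BH-adjusted p < `alpha`.
#'
#' @param m An rpm-unit [mir_expr()] with the two groups present.
#' @param comparison A single `"A_vs_B"` label (default `"LUAD_vs_ANL"`).
#' @inheritParams de_discovery
#' @return A tibble `mirna_id`, `comparison`, `fc`, `p_raw`, `p_adj`,
#'   `status`.
#' @export
de_validation <- function(m, comparison = "LUAD_vs_ANL", pseudocount = 1,
                          alpha = 0.05, fc_epsilon = 0.01, fc_threshold = 2) {
  if (m$unit != "rpm") {
    abort("de_validation() expects an rpm-unit matrix.",
          class = "oncofetal_unit_error")
  }
  pr <- split_comparison(comparison)
  a <- group_rpm(m, pr[1]); b <- group_rpm(m, pr[2])
  wt <- welch_t(a, b, pseudocount = pseudocount)
  fc <- fold_change(a, b, epsilon = fc_epsilon)
  p_adj <- bh_adjust(wt$p_value)
  tibble(mirna_id = rownames(m$values),
         comparison = comparison,
         fc = unname(fc),
         p_raw = wt$p_value,
         p_adj = p_adj,
         status = call_de_status(unname(fc), p_adj,
                                 alpha = alpha, fc_threshold = fc_threshold))
}
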