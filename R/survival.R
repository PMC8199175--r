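#' Dichotomize patients by miRNA expression positivity
#'
#' A sample is positive for a miRNA when its RPM is at least 1 (inclusive),
#' negative below 1. Only LUAD samples are scored.
#'
#' @param m An rpm-unit [mir_expr()].
#' @param mirna_id A single miRNA ID present in `m`.
#' @param min_rpm Positivity threshold (default 1 RPM, inclusive).
#' @return A tibble `sample_id`, `patient_id`, `rpm`, `stratum`
#'   (`"positive"`/`"negative"`).
#' @export
dichotomize <- function(m, mirna_id, min_rpm = 1) {
  stopifnot(inherits(m, "mir_expr"))
  if (m$unit != "rpm") {
    abort("dichotomize() expects an rpm-unit matrix.",
          class = "oncofetal_unit_error")
  }
  if (!mirna_id %in% rownames(m$values)) {
    abort(paste0("miRNA '", mirna_id, "' absent from matrix."),
          class = "oncofetal_consistency_error")
  }
  luad <- m$samples$group == "LUAD"
  if (!any(luad)) {
    abort("No LUAD samples present.", class = "oncofetal_metadata_error")
  }
  rpm <- m$values[mirna_id, luad]
  tibble(sample_id = m$samples$sample_id[luad],
         patient_id = m$samples$patient_id[luad],
         rpm = unname(rpm),
         stratum = ifelse(rpm >= min_rpm, "positive", "negative"))
}

#' Kaplan–Meier product-limit estimate
#'
#' @param time Non-negative follow-up times.
#' @param event Logical/0-1 event indicators (TRUE = death observed).
#' @return A `km_curve` tibble with columns `time` (distinct event/censoring
#'   times, ascending), `n_risk`, `n_event`, `n_censor` and `survival`
#'   (non-increasing, 1 before the first event).
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) {
    abort("At least one patient is required.", class = "oncofetal_domain_error")
  }
  if (any(time < 0)) {
    abort("Follow-up times must be non-negative.",
          class = "oncofetal_domain_error")
  }
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time the at-risk sets are
#' pooled, expected events and hypergeometric variances accumulated, and the
#' statistic referred to a chi-square distribution with one degree of
#' freedom. Ties are handled by the pooled-at-risk convention (events at a
#' time precede censorings at the same time). Two strata with no events at
#' all return statistic 0, p 1.
#'
#' @param time Follow-up times for all patients.
#' @param event Event indicators.
#' @param group Two-level stratum vector.
#' @return A one-row tibble `statistic` (chi-square), `df`, `p_value`,
#'   `n`, `n_events`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    abort("Exactly two non-empty strata are required.",
          class = "oncofetal_domain_error")
  }
  if (any(time < 0)) {
    abort("Follow-up times must be non-negative.",
          class = "oncofetal_domain_error")
  }
  event <- as.integer(event)
  if (sum(event) == 0) {
    return(tibble(statistic = 0, df = 1L, p_value = 1,
                  n = length(time), n_events = 0L))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble(statistic = unname(fit$chisq), df = 1L,
         p_value = pchisq(fit$chisq, df = 1, lower.tail = FALSE),
         n = length(time), n_events = sum(event))
}

#' Univariate survival screen across a miRNA panel
#'
#' For each panel miRNA, LUAD patients are dichotomized at RPM >= 1 and the
#' two strata compared with a log-rank test. No multiplicity correction is
#' applied by default (each miRNA is a separate univariate hypothesis);
#' Benjamini–Hochberg can be switched on. miRNAs whose split leaves a single
#' stratum are reported as untestable and never flagged.
#'
#' @param m An rpm-unit [mir_expr()] with LUAD samples.
#' @param surv Tibble with columns `sample_id`, `time`, `event`; rows are
#'   joined to LUAD samples by `sample_id`. Patients without survival data
#'   are dropped with a message.
#' @param panel Character vector of miRNA IDs to screen.
#' @param alpha Significance threshold (default 0.05).
#' @param adjust If `TRUE`, flag on BH-adjusted p-values instead.
#' @param min_rpm Positivity threshold passed to [dichotomize()].
#' @return A tibble `mirna_id`, `n_pos`, `n_neg`, `statistic`, `p_value`,
#'   `testable`, `flagged`.
#' @export
survival_screen <- function(m, surv, panel, alpha = 0.05, adjust = FALSE,
                            min_rpm = 1) {
  miss <- setdiff(panel, rownames(m$values))
  if (length(miss)) {
    abort(paste0("Panel miRNA(s) absent from matrix: ",
                 paste(miss, collapse = ", ")),
          class = "oncofetal_consistency_error")
  }
  luad_ids <- m$samples$sample_id[m$samples$group == "LUAD"]
  if (length(luad_ids) == 0) {
    abort("No LUAD samples present.", class = "oncofetal_metadata_error")
  }
  matched <- intersect(luad_ids, surv$sample_id)
  if (length(matched) == 0) {
    abort("Survival rows could not be joined to any LUAD sample.",
          class = "oncofetal_consistency_error")
  }
  dropped <- length(luad_ids) - length(matched)
  if (dropped > 0) {
    message(sprintf("survival_screen: %d LUAD patient(s) without survival data dropped.",
                    dropped))
  }
  sv <- surv[match(matched, surv$sample_id), ]
  out <- purrr::map_dfr(panel, function(id) {
    d <- dichotomize(m, id, min_rpm = min_rpm)
    strat <- d$stratum[match(matched, d$sample_id)]
    n_pos <- sum(strat == "positive")
    n_neg <- sum(strat == "negative")
    if (n_pos == 0 || n_neg == 0) {
      return(tibble(mirna_id = id, n_pos = n_pos, n_neg = n_neg,
                    statistic = NA_real_, p_value = NA_real_,
                    testable = FALSE))
    }
    lr <- logrank_test(sv$time, sv$event, strat)
    tibble(mirna_id = id, n_pos = n_pos, n_neg = n_neg,
           statistic = lr$statistic, p_value = lr$p_value, testable = TRUE)
  })
  p_use <- if (adjust) {
    pv <- out$p_value
    pv[out$testable] <- bh_adjust(pv[out$testable])
    pv
  } else {
    out$p_value
  }
  out$flagged <- !is.na(p_use) & p_use < alpha
  out
}
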