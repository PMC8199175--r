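# independent brute-force oracles, deliberately written by the most direct
# route available (definitions, enumeration, O(n^2) scans) rather than via
# the code paths they check

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[ord[i]] <- min(1, min(cand))
  }
  q
}

# all non-negative integer matrices with the given margins
enumerate_tables <- function(row_sums, col_sums) {
  if (length(row_sums) == 1) {
    return(list(matrix(col_sums, nrow = 1)))
  }
  out <- list()
  first_rows <- compositions_bounded(row_sums[1], col_sums)
  for (fr in first_rows) {
    rest <- enumerate_tables(row_sums[-1], col_sums - fr)
    for (tb in rest) out[[length(out) + 1]] <- rbind(fr, tb, deparse.level = 0)
  }
  out
}

# all ways to write `total` as a sum of length(bounds) entries with entry i
# at most bounds[i]
compositions_bounded <- function(total, bounds) {
  if (length(bounds) == 1) {
    if (total <= bounds[1]) return(list(total)) else return(list())
  }
  out <- list()
  for (v in 0:min(total, bounds[1])) {
    rest <- compositions_bounded(total - v, bounds[-1])
    for (r in rest) out[[length(out) + 1]] <- c(v, r)
  }
  out
}

log_table_prob <- function(tab) {
  n <- sum(tab)
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(n) - sum(lfactorial(tab))
}

# two-sided exact p: total probability of tables no more probable than the
# observed one, over all tables with the same margins
oracle_fisher <- function(tab) {
  tabs <- enumerate_tables(rowSums(tab), colSums(tab))
  lp <- vapply(tabs, log_table_prob, numeric(1))
  lp_obs <- log_table_prob(tab)
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# per-row one-way ANOVA via stats::aov
oracle_anova <- function(y_row, groups) {
  fit <- stats::aov(y_row ~ factor(groups))
  s <- summary(fit)[[1]]
  list(f = s[["F value"]][1], p = s[["Pr(>F)"]][1])
}

# pairwise t with the pooled ANOVA error variance (Fisher's LSD)
oracle_lsd <- function(y_row, groups, g1, g2) {
  fit <- stats::aov(y_row ~ factor(groups))
  mse <- summary(fit)[[1]][["Mean Sq"]][2]
  df2 <- fit$df.residual
  m1 <- mean(y_row[groups == g1]); m2 <- mean(y_row[groups == g2])
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  t_stat <- (m1 - m2) / sqrt(mse * (1 / n1 + 1 / n2))
  2 * stats::pt(abs(t_stat), df2, lower.tail = FALSE)
}

# O(n^2) pairwise AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# product-limit estimator from the definition (events before censorings at
# tied times)
oracle_km <- function(time, event) {
  times <- sort(unique(time))
  s <- 1
  out <- data.frame(time = numeric(0), survival = numeric(0))
  for (t in times) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    if (d > 0) s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# two-group log-rank from the observed-minus-expected tabulation
oracle_logrank <- function(time, event, group) {
  group <- as.character(group)
  g1 <- sort(unique(group))[1]
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
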