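test_that("fold change is an epsilon-stabilized ratio of group means", {
  expect_equal(fold_change(c(10, 10), c(10, 10)), 1)
  # presence/absence contrast: 20 vs 0 with epsilon 0.01
  expect_equal(fold_change(c(20, 20), c(0, 0)), 20.01 / 0.01)
  expect_equal(fold_change(c(20, 20), c(0, 0)), 2001)
  # reciprocity
  withr::with_seed(71, {
    for (rep in 1:20) {
      a <- runif(5, 0, 100); b <- runif(7, 0, 100)
      expect_equal(fold_change(a, b) * fold_change(b, a), 1)
    }
  })
  # row-wise on matrices
  m <- matrix(1:6, 2, dimnames = list(c("x", "y"), NULL))
  expect_equal(unname(fold_change(m, m * 2)),
               unname((rowMeans(m) + 0.01) / (rowMeans(m) * 2 + 0.01)))
})

test_that("row-wise ANOVA matches aov and LSD matches the pooled-variance formula", {
  withr::with_seed(81, {
    groups <- rep(c("FL", "ANL", "LUAD"), times = c(5, 8, 6))
    for (rep in 1:35) {
      v <- matrix(runif(4 * length(groups), 0, 200), nrow = 4,
                  dimnames = list(paste0("m", 1:4), NULL))
      colnames(v) <- sprintf("s%02d", seq_along(groups))
      res <- anova_posthoc(v, groups = groups, alpha = 1)  # alpha 1: ungated
      y <- log2(v + 1)
      for (i in 1:4) {
        o <- oracle_anova(y[i, ], groups)
        row <- res[res$mirna_id == paste0("m", i) &
                     res$comparison == "FL_vs_ANL", ]
        expect_equal(row$statistic, o$f, tolerance = 1e-10)
        expect_equal(row$p_omnibus, o$p, tolerance = 1e-10)
        expect_equal(row$p_posthoc, oracle_lsd(y[i, ], groups, "FL", "ANL"),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("ANOVA handles degenerate and two-group cases", {
  # identical values everywhere: F = 0, p = 1
  v <- matrix(5, 2, 9, dimnames = list(c("a", "b"), sprintf("s%d", 1:9)))
  groups <- rep(c("FL", "ANL", "LUAD"), each = 3)
  res <- anova_posthoc(v, groups = groups)
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p_omnibus == 1))
  expect_true(all(res$p_posthoc == 1))

  # two-group limit: F equals the square of the pooled-variance t
  withr::with_seed(91, {
    g2 <- rep(c("ANL", "LUAD"), times = c(6, 7))
    v2 <- matrix(runif(3 * 13, 0, 50), nrow = 3,
                 dimnames = list(paste0("m", 1:3), sprintf("s%02d", 1:13)))
    res2 <- anova_posthoc(v2, groups = g2, alpha = 1)
    y2 <- log2(v2 + 1)
    for (i in 1:3) {
      tt <- stats::t.test(y2[i, g2 == "ANL"], y2[i, g2 == "LUAD"],
                          var.equal = TRUE)
      row <- res2[res2$mirna_id == paste0("m", i), ]
      expect_equal(row$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(row$p_omnibus, tt$p.value, tolerance = 1e-10)
    }
  })

  # post-hoc p gated to 1 when the omnibus test is not significant
  withr::with_seed(92, {
    g <- rep(c("FL", "ANL", "LUAD"), each = 4)
    v3 <- matrix(runif(12, 10, 11), nrow = 1,
                 dimnames = list("m1", sprintf("s%02d", 1:12)))
    res3 <- anova_posthoc(v3, groups = g, alpha = 1e-12)
    expect_true(all(res3$p_posthoc == 1))
  })
})

test_that("row-wise Welch t matches t.test", {
  withr::with_seed(101, {
    for (rep in 1:35) {
      na <- sample(3:10, 1); nb <- sample(3:10, 1)
      a <- matrix(runif(3 * na, 0, 100), nrow = 3,
                  dimnames = list(paste0("m", 1:3), NULL))
      b <- matrix(runif(3 * nb, 0, 100), nrow = 3)
      res <- welch_t(a, b)
      for (i in 1:3) {
        tt <- stats::t.test(log2(a[i, ] + 1), log2(b[i, ] + 1))
        expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-10)
        expect_equal(res$df[i], unname(tt$parameter), tolerance = 1e-10)
        expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
      }
    }
  })
  # symmetric swap negates t, preserves p
  a <- matrix(runif(8), 1); b <- matrix(runif(6), 1)
  expect_equal(welch_t(a, b)$statistic, -welch_t(b, a)$statistic)
  expect_equal(welch_t(a, b)$p_value, welch_t(b, a)$p_value)
  # identical constant groups: t = 0, p = 1
  cst <- matrix(3, 1, 5)
  expect_equal(welch_t(cst, cst)$p_value, 1)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "oncofetal_domain_error")
  withr::with_seed(111, {
    for (rep in 1:120) {
      p <- runif(sample(1:30, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(q >= p))
      expect_true(all(q <= 1))
    }
  })
})

test_that("status calls use strict fold-change and p thresholds", {
  expect_equal(call_de_status(2, 0.001), "ns")       # fc boundary is strict
  expect_equal(call_de_status(3, 0.04), "over")
  expect_equal(call_de_status(0.3, 0.01), "under")
  expect_equal(call_de_status(0.5, 0.01), "ns")
  expect_equal(call_de_status(3, 0.05), "ns")        # alpha boundary strict
  expect_equal(call_de_status(c(3, 0.1, 1), c(0.01, 0.01, 0.01)),
               c("over", "under", "ns"))
})

test_that("planted over/under sets are recovered with high sensitivity and specificity", {
  on_map <- list(oncofetal = c("FL", "LUAD"), fetal_only = "FL",
                 tumour_only = "LUAD", under_in_both = "ANL",
                 ubiquitous = c("FL", "ANL", "LUAD"), silent = character(0))
  sens <- spec <- numeric(0)
  for (seed in 1:5) {
    sim <- generate_cohorts(sim_config(seed = seed))
    rpm <- suppressMessages(normalize_rpm(sim$discovery))
    de <- de_discovery(rpm, comparisons = "LUAD_vs_ANL")
    truth <- sim$truth
    on_luad <- vapply(truth$class, function(cl) "LUAD" %in% on_map[[cl]],
                      logical(1))
    on_anl <- vapply(truth$class, function(cl) "ANL" %in% on_map[[cl]],
                     logical(1))
    planted <- ifelse(on_luad & !on_anl, "over",
                      ifelse(!on_luad & on_anl, "under", "ns"))
    called <- de$status[match(truth$mirna_id, de$mirna_id)]
    is_de <- planted != "ns"
    sens <- c(sens, mean(called[is_de] == planted[is_de]))
    spec <- c(spec, mean(called[!is_de] == "ns"))
  }
  expect_gte(mean(sens), 0.95)
  expect_gte(mean(spec), 0.99)
})
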