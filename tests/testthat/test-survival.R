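test_that("positivity dichotomization uses an inclusive RPM >= 1 boundary", {
  v <- matrix(c(1.0, 0.999, 0, 5), 1,
              dimnames = list("m1", c("s1", "s2", "s3", "s4")))
  m <- make_expr(v, group = "LUAD", unit = "rpm")
  d <- dichotomize(m, "m1")
  expect_equal(d$stratum, c("positive", "negative", "negative", "positive"))
  expect_error(dichotomize(m, "nope"), class = "oncofetal_consistency_error")
  expect_error(dichotomize(make_expr(v, group = "LUAD"), "m1"),
               class = "oncofetal_unit_error")

  withr::with_seed(191, {
    for (rep in 1:20) {
      m2 <- random_expr(n_mir = 5, n_samp = 8, unit = "rpm", max_count = 4)
      d2 <- dichotomize(m2, rownames(m2$values)[1])
      expect_equal(d2$stratum,
                   unname(ifelse(m2$values[1, ] >= 1, "positive", "negative")))
    }
  })
})

test_that("the product-limit estimate matches a hand computation", {
  # all censored: survival identically 1
  km0 <- km_estimate(c(2, 5, 7), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  # single patient with an event at t = 5
  km1 <- km_estimate(5, 1)
  expect_equal(km1$survival, 0)
  expect_equal(km1$time, 5)

  withr::with_seed(201, {
    for (rep in 1:40) {
      n <- sample(3:10, 1)
      time <- sample(1:8, n, replace = TRUE)
      event <- sample(c(0, 1), n, replace = TRUE)
      km <- km_estimate(time, event)
      o <- oracle_km(time, event)
      got <- km$survival[match(o$time, km$time)]
      expect_equal(got, o$survival, tolerance = 1e-12)
      expect_true(all(diff(km$survival) <= 1e-12))
      expect_true(all(km$survival >= 0 & km$survival <= 1))
    }
  })
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "oncofetal_domain_error")
})

test_that("the log-rank test matches the observed-minus-expected tabulation", {
  # identical strata: statistic exactly 0
  time <- c(1, 3, 5, 7); event <- c(1, 0, 1, 1)
  lr <- logrank_test(c(time, time), c(event, event),
                     rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # ten-patient worked example with ties
  t10 <- c(1, 2, 2, 4, 5, 5, 6, 8, 9, 9)
  e10 <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  g10 <- rep(c("pos", "neg"), each = 5)
  got <- logrank_test(t10, e10, g10)
  o <- oracle_logrank(t10, e10, g10)
  expect_equal(got$statistic, o$chi2, tolerance = 1e-9)
  expect_equal(got$p_value, o$p, tolerance = 1e-9)

  withr::with_seed(211, {
    for (rep in 1:40) {
      n <- sample(6:20, 1)
      time <- sample(1:10, n, replace = TRUE)
      event <- sample(c(0, 1), n, replace = TRUE, prob = c(0.3, 0.7))
      group <- sample(c("a", "b"), n, replace = TRUE)
      if (length(unique(group)) < 2 || sum(event) == 0) next
      got <- logrank_test(time, event, group)
      o <- oracle_logrank(time, event, group)
      expect_equal(got$statistic, o$chi2, tolerance = 1e-9)
      # label swap leaves the statistic unchanged
      swapped <- logrank_test(time, event, ifelse(group == "a", "b", "a"))
      expect_equal(swapped$statistic, got$statistic, tolerance = 1e-12)
      # time-unit rescaling leaves the statistic unchanged
      rescaled <- logrank_test(time * 30.44, event, group)
      expect_equal(rescaled$statistic, got$statistic, tolerance = 1e-12)
    }
  })

  # no events anywhere: statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), c("a", "a", "b", "b"))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
})

test_that("the log-rank p agrees with a permutation null on small tables", {
  withr::with_seed(221, {
    time <- c(2, 3, 3, 5, 6, 8, 9, 11, 12, 14)
    event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
    group <- rep(c("a", "b"), 5)
    obs <- logrank_test(time, event, group)$statistic
    perm <- replicate(10000, {
      g <- sample(group)
      logrank_test(time, event, g)$statistic
    })
    p_perm <- mean(perm >= obs - 1e-12)
    p_asym <- logrank_test(time, event, group)$p_value
    expect_lt(abs(p_perm - p_asym), 3 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.05)
  })
})

test_that("the survival screen flags associated miRNAs and reports untestable splits", {
  m <- borderline_survival_matrix(n = 150, seed = 8)
  cfg <- sim_config(seed = 23)  # HR = 3 by default
  surv <- generate_survival(cfg, m, "marker")
  sv <- tibble::tibble(sample_id = surv$sample_id, time = surv$time,
                       event = as.integer(surv$event))
  res <- survival_screen(m, sv, panel = c("marker", "filler"))
  expect_true(res$testable[res$mirna_id == "marker"])
  # filler is positive in every sample: untestable, never flagged
  filler <- res[res$mirna_id == "filler", ]
  expect_false(filler$testable)
  expect_false(filler$flagged)
  expect_true(is.na(filler$p_value))

  expect_error(survival_screen(m, sv, panel = "absent"),
               class = "oncofetal_consistency_error")

  # patients without survival rows are dropped with a message
  expect_message(survival_screen(m, sv[-1, ], panel = "marker"), "dropped")
})
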