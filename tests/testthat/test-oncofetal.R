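de_row <- function(id, cmp, status) {
  tibble::tibble(mirna_id = id, comparison = cmp, fc = 3, p_raw = 0.01,
                 p_adj = 0.01, status = status)
}

call_row <- function(id, frac) {
  tibble::tibble(mirna_id = id, group = "ANL", n_samples = 20,
                 fraction_positive = frac, expressed = frac >= 0.10)
}

test_that("the three-criterion oncofetal definition is applied exactly", {
  dd <- dplyr::bind_rows(de_row("m1", "LUAD_vs_ANL", "over"),
                         de_row("m1", "FL_vs_ANL", "over"))
  dv <- de_row("m1", "LUAD_vs_ANL", "over")

  # all criteria met: ANL fraction below 0.10 in both cohorts
  res <- classify_oncofetal(dd, dv, call_row("m1", 0.05), call_row("m1", 0.05))
  expect_true(res$oncofetal)

  # ANL fraction exactly 0.10 in one cohort: expressed, criterion c fails
  res2 <- classify_oncofetal(dd, dv, call_row("m1", 0.10), call_row("m1", 0.05))
  expect_true(res2$crit_a && res2$crit_b)
  expect_false(res2$crit_c)
  expect_false(res2$oncofetal)

  # not over in FL: criterion a fails
  dd3 <- dplyr::bind_rows(de_row("m1", "LUAD_vs_ANL", "over"),
                          de_row("m1", "FL_vs_ANL", "ns"))
  expect_false(classify_oncofetal(dd3, dv, call_row("m1", 0.05),
                                  call_row("m1", 0.05))$oncofetal)

  # under in validation: criterion b fails
  dv4 <- de_row("m1", "LUAD_vs_ANL", "under")
  expect_false(classify_oncofetal(dd, dv4, call_row("m1", 0.05),
                                  call_row("m1", 0.05))$oncofetal)

  # missing miRNA in any input is a consistency error
  expect_error(classify_oncofetal(dd, de_row("other", "LUAD_vs_ANL", "over"),
                                  call_row("m1", 0.05), call_row("m1", 0.05)),
               class = "oncofetal_consistency_error")
})

test_that("relaxing the ANL positivity threshold can only grow the oncofetal set", {
  sim <- generate_cohorts(sim_config(seed = 2))
  rpm_d <- normalize_rpm(sim$discovery)
  rpm_v <- normalize_rpm(sim$validation)
  dd <- de_discovery(rpm_d)
  dv <- de_validation(rpm_v)
  sets <- lapply(c(0.05, 0.10, 0.30, 1.0), function(fr) {
    cd <- detect_expressed(rpm_d, "ANL", min_fraction = fr)
    cv <- detect_expressed(rpm_v, "ANL", min_fraction = fr)
    res <- classify_oncofetal(dd, dv, cd, cv)
    res$mirna_id[res$oncofetal]
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("the exact independence test matches margin-fixed enumeration", {
  # worked 2x2 example
  tab <- matrix(c(1, 11, 9, 3), 2)
  got <- congruence_test(tab)
  expect_equal(got$method, "exact")
  expect_equal(got$p_value, oracle_fisher(tab), tolerance = 1e-9)

  withr::with_seed(121, {
    for (rep in 1:60) {
      tab <- matrix(rpois(4, 4), 2)
      if (sum(tab) == 0) next
      expect_equal(congruence_test(tab)$p_value, oracle_fisher(tab),
                   tolerance = 1e-9)
    }
    for (rep in 1:40) {
      tab <- matrix(rpois(9, 2), 3)
      if (sum(tab) == 0 || sum(tab) > 40) next
      expect_equal(congruence_test(tab)$p_value, oracle_fisher(tab),
                   tolerance = 1e-9)
    }
  })
})

test_that("the independence test respects label symmetry and independence structure", {
  tab <- matrix(c(8, 2, 3, 12, 5, 1, 2, 2, 9), 3)
  expect_equal(congruence_test(tab)$p_value,
               congruence_test(tab[c(2, 1, 3), ])$p_value)
  expect_equal(congruence_test(tab)$p_value,
               congruence_test(t(tab))$p_value)
  # outer-product margins: independence, p near 1
  ind <- outer(c(10, 20, 30), c(6, 3, 3)) / 6
  expect_gt(congruence_test(round(ind))$p_value, 0.5)
  expect_error(congruence_test(matrix(c(-1, 2, 3, 4), 2)),
               class = "oncofetal_domain_error")
})

test_that("large tables fall back to a seeded Monte Carlo estimate", {
  tab <- matrix(c(200, 50, 40, 400), 2)
  got <- congruence_test(tab, seed = 7, mc_draws = 1e5)
  expect_equal(got$method, "monte_carlo")
  got2 <- congruence_test(tab, seed = 7, mc_draws = 1e5)
  expect_identical(got$p_value, got2$p_value)
  # agrees with the exact network-algorithm p on this table
  expect_equal(got$p_value, stats::fisher.test(tab)$p.value, tolerance = 0.01)
})

test_that("region containment counts full containment, strand ignored", {
  ann <- read_annotation(system.file("extdata", "oncofetal_panel_loci.tsv",
                                     package = "oncofetal"))
  expect_equal(nrow(ann), 13)
  region <- "chr14+:100800000-101100000"
  expect_equal(count_in_region(ann$mirna_id, ann, region), 5)
  expect_equal(count_in_region(character(0), ann, region), 0L)
  expect_error(count_in_region("missing-mir", ann, region),
               class = "oncofetal_consistency_error")

  # order and strand invariance + brute-force scan on random loci
  withr::with_seed(131, {
    reg <- parse_locus("chr5+:1000-2000")
    for (rep in 1:25) {
      n <- 30
      ann2 <- tibble::tibble(
        mirna_id = paste0("m", 1:n),
        chrom = sample(c("chr5", "chr6"), n, replace = TRUE),
        strand = sample(c("+", "-"), n, replace = TRUE),
        start = sample(500:2500, n, replace = TRUE)
      )
      ann2$end <- ann2$start + sample(0:600, n, replace = TRUE)
      expected <- sum(ann2$chrom == "chr5" & ann2$start >= 1000 &
                        ann2$end <= 2000)
      expect_equal(count_in_region(ann2$mirna_id, ann2, reg), expected)
      perm <- sample(n)
      expect_equal(count_in_region(ann2$mirna_id[perm], ann2, reg), expected)
    }
  })
})

test_that("shared-target filtering thresholds on distinct panel miRNAs", {
  tt <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3", "m1", "m2", "m1", "m1"),
    gene_symbol = c("G1", "G1", "G1", "G2", "G2", "G3", "G3")  # G3 duplicated pair
  )
  expect_equal(shared_targets(tt, min_mirnas = 3), "G1")
  expect_equal(shared_targets(tt, min_mirnas = 2), c("G1", "G2"))
  expect_equal(shared_targets(tt, min_mirnas = 1), c("G1", "G2", "G3"))

  withr::with_seed(141, {
    for (rep in 1:20) {
      tt2 <- tibble::tibble(
        mirna_id = sample(paste0("m", 1:6), 50, replace = TRUE),
        gene_symbol = sample(paste0("G", 1:10), 50, replace = TRUE)
      )
      got <- shared_targets(tt2, min_mirnas = 3)
      counts <- table(unique(tt2)$gene_symbol)
      expect_equal(got, sort(names(counts)[counts >= 3]))
    }
  })
})
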