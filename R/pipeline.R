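#' Default pipeline configuration
#'
#' Every threshold of the analysis in one auditable place: the 5-million-read
#' depth filter, the RPM >= 1 in >= 10% detection rule, fold change > 2, the
#' alpha of 0.05 for both testing schemes, the designated genomic cluster
#' region, classifier and survival settings, and either a `simulate` block or
#' a `paths` block naming input TSVs.
#'
#' @param seed Integer seed threaded through every stochastic stage.
#' @return A nested named list (class `pipeline_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(),          # passed to sim_config(); NULL when using paths
    paths = NULL,               # list(discovery_matrix, discovery_meta,
                                #      validation_matrix, validation_meta,
                                #      annotation, survival)
    depth = list(min_reads = 5e6),
    detect = list(min_rpm = 1, min_fraction = 0.10),
    de = list(pseudocount = 1, fc_epsilon = 0.01, posthoc = "lsd",
              alpha = 0.05, fc_threshold = 2),
    congruence = list(collapse = FALSE),
    region = "chr14+:100800000-101100000",
    classifier = list(enabled = TRUE, cost = 1, pseudocount = 1),
    survival = list(enabled = TRUE, alpha = 0.05, adjust = FALSE)
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration
#'
#' Accepts a `pipeline_config`, a plain named list, or a path to a YAML file.
#' Unknown keys are rejected; thresholds are checked against their domains.
#'
#' @param config Configuration object, list or YAML path.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "oncofetal_config_error")
  }
  merged <- utils::modifyList(unclass(base), config, keep.null = TRUE)
  for (blk in c("depth", "detect", "de", "congruence", "classifier",
                "survival")) {
    unknown <- setdiff(names(merged[[blk]]), names(base[[blk]]))
    if (length(unknown)) {
      abort(paste0("Unknown config key(s) in '", blk, "': ",
                   paste(unknown, collapse = ", ")),
            class = "oncofetal_config_error")
    }
  }
  with(merged, {
    if (depth$min_reads < 0) {
      abort("depth.min_reads must be non-negative.",
            class = "oncofetal_config_error")
    }
    if (detect$min_fraction < 0 || detect$min_fraction > 1 ||
        detect$min_rpm < 0) {
      abort("detect thresholds out of domain.",
            class = "oncofetal_config_error")
    }
    if (de$fc_threshold <= 0 || de$alpha <= 0 || de$alpha >= 1 ||
        de$fc_epsilon < 0 || de$pseudocount < 0 ||
        !de$posthoc %in% c("lsd", "tukey")) {
      abort("de thresholds out of domain.", class = "oncofetal_config_error")
    }
    if (classifier$cost <= 0) {
      abort("classifier.cost must be positive.",
            class = "oncofetal_config_error")
    }
    if (survival$alpha <= 0 || survival$alpha >= 1) {
      abort("survival.alpha out of domain.", class = "oncofetal_config_error")
    }
  })
  parse_locus(merged$region)  # validates the region string
  if (is.null(merged$paths) && is.null(merged$simulate)) {
    abort("Either a simulate block or a paths block is required.",
          class = "oncofetal_config_error")
  }
  structure(merged, class = "pipeline_config")
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ",
                 conditionMessage(e)),
          class = "oncofetal_stage_error")
  })
}

#' Run the end-to-end oncofetal discovery pipeline
#'
#' Executes, in order: depth filter, replicate averaging, RPM normalization,
#' per-group expression calls, differential expression under both cohort
#' schemes, three-criterion oncofetal classification, tumour/fetal congruence
#' test, cluster-region localization, and (optionally) panel-SVM training
#' with ROC evaluation on the validation cohort and a univariate survival
#' screen. All tabular outputs are written as TSV, summaries as JSON, plus a
#' machine-readable run manifest. Outputs are a pure function of config and
#' seed: re-running with the same configuration reproduces every file
#' byte for byte.
#'
#' @param config A `pipeline_config`, plain list, or YAML path
#'   (see [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The run manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  inputs <- stage("input", {
    if (!is.null(cfg$paths)) {
      p <- cfg$paths
      list(discovery = read_count_matrix(p$discovery_matrix, p$discovery_meta),
           validation = read_count_matrix(p$validation_matrix,
                                          p$validation_meta),
           annotation = if (!is.null(p$annotation)) {
             read_annotation(p$annotation)
           },
           survival = if (!is.null(p$survival)) {
             readr::read_tsv(p$survival, col_types = readr::cols(
               sample_id = readr::col_character(),
               time = readr::col_double(),
               event = readr::col_integer()
             ), progress = FALSE)
           },
           truth = NULL)
    } else {
      sim <- generate_cohorts(do.call(sim_config,
                                      c(cfg$simulate, list(seed = cfg$seed))))
      ann <- dplyr::bind_cols(sim$truth[, c("mirna_id", "locus")],
                              parse_locus(sim$truth$locus))
      list(discovery = sim$discovery, validation = sim$validation,
           annotation = ann, survival = NULL, truth = sim$truth)
    }
  })

  prep <- stage("preprocess", {
    purrr::map(inputs[c("discovery", "validation")], function(m) {
      m |> filter_low_depth(cfg$depth$min_reads) |>
        average_replicates() |>
        normalize_rpm()
    })
  })
  counts$discovery_samples <- ncol(prep$discovery$values)
  counts$validation_samples <- ncol(prep$validation$values)

  calls <- stage("detect", {
    dplyr::bind_rows(
      dplyr::mutate(detect_expressed_all(prep$discovery,
                                         cfg$detect$min_rpm,
                                         cfg$detect$min_fraction),
                    cohort = "discovery"),
      dplyr::mutate(detect_expressed_all(prep$validation,
                                         cfg$detect$min_rpm,
                                         cfg$detect$min_fraction),
                    cohort = "validation")
    )
  })
  readr::write_tsv(calls, file.path(out_dir, "expression_calls.tsv"),
                   progress = FALSE)
  counts$expression_calls <- nrow(calls)

  de <- stage("diffexp", {
    dd <- de_discovery(prep$discovery,
                       comparisons = c("LUAD_vs_ANL", "FL_vs_ANL"),
                       posthoc = cfg$de$posthoc,
                       pseudocount = cfg$de$pseudocount,
                       alpha = cfg$de$alpha, fc_epsilon = cfg$de$fc_epsilon,
                       fc_threshold = cfg$de$fc_threshold)
    dv <- de_validation(prep$validation, comparison = "LUAD_vs_ANL",
                        pseudocount = cfg$de$pseudocount,
                        alpha = cfg$de$alpha, fc_epsilon = cfg$de$fc_epsilon,
                        fc_threshold = cfg$de$fc_threshold)
    list(discovery = dd, validation = dv)
  })
  readr::write_tsv(de$discovery, file.path(out_dir, "de_discovery.tsv"),
                   progress = FALSE)
  readr::write_tsv(de$validation, file.path(out_dir, "de_validation.tsv"),
                   progress = FALSE)
  counts$de_discovery <- nrow(de$discovery)
  counts$de_validation <- nrow(de$validation)

  onco <- stage("oncofetal", {
    classify_oncofetal(
      de$discovery, de$validation,
      calls[calls$cohort == "discovery" & calls$group == "ANL", ],
      calls[calls$cohort == "validation" & calls$group == "ANL", ]
    )
  })
  readr::write_tsv(onco, file.path(out_dir, "oncofetal_calls.tsv"),
                   progress = FALSE)
  counts$oncofetal_calls <- nrow(onco)
  counts$oncofetal_positive <- sum(onco$oncofetal)
  hits <- onco$mirna_id[onco$oncofetal]

  cong <- stage("congruence", {
    tab <- congruence_table(
      de$discovery[de$discovery$comparison == "LUAD_vs_ANL", ],
      de$discovery[de$discovery$comparison == "FL_vs_ANL", ],
      collapse = cfg$congruence$collapse
    )
    res <- congruence_test(tab, seed = cfg$seed)
    list(table = unclass(tab), result = res)
  })
  jsonlite::write_json(
    list(table = cong$table, p_value = cong$result$p_value,
         method = cong$result$method, n_total = cong$result$n_total),
    file.path(out_dir, "congruence.json"),
    auto_unbox = TRUE, digits = NA
  )

  counts$cluster_region_hits <- stage("region", {
    if (is.null(inputs$annotation)) {
      NA_integer_
    } else {
      count_in_region(hits, inputs$annotation, cfg$region)
    }
  })

  if (isTRUE(cfg$classifier$enabled) && length(hits) >= 1) {
    roc <- stage("classifier", {
      scorer <- train_panel_svm(prep$discovery, panel = hits,
                                cost = cfg$classifier$cost,
                                pseudocount = cfg$classifier$pseudocount)
      write_scorer(scorer, file.path(out_dir, "scorer.json"))
      sc <- score_samples(scorer, prep$validation,
                          pseudocount = cfg$classifier$pseudocount)
      sc <- sc[sc$group %in% c("ANL", "LUAD"), ]
      roc_auc(sc$score, sc$group == "LUAD")
    })
    readr::write_tsv(roc$curve, file.path(out_dir, "roc_curve.tsv"),
                     progress = FALSE)
    jsonlite::write_json(glance(roc), file.path(out_dir, "roc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    counts$validation_auc <- roc$auc
  }

  if (isTRUE(cfg$survival$enabled) && length(hits) >= 1) {
    screen <- stage("survival", {
      surv <- inputs$survival
      if (is.null(surv)) {
        sim_cfg <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
        surv <- generate_survival(sim_cfg, prep$validation, hits)
      }
      survival_screen(prep$validation, surv, panel = hits,
                      alpha = cfg$survival$alpha,
                      adjust = cfg$survival$adjust)
    })
    readr::write_tsv(screen, file.path(out_dir, "survival_screen.tsv"),
                     progress = FALSE)
    counts$survival_flagged <- sum(screen$flagged)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oncofetal")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
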