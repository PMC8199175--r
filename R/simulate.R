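#' Simulation configuration for two-cohort miRNA studies
#'
#' Builds the configuration consumed by [generate_cohorts()] and
#' [generate_survival()]. Defaults emulate a discovery cohort of 25 fetal
#' lung (FL), 77 adult non-neoplastic lung (ANL) and 63 lung adenocarcinoma
#' (LUAD) samples, and a validation cohort of 38 ANL and 389 LUAD samples,
#' with six planted miRNA classes:
#'
#' * `oncofetal`: expressed in FL and LUAD, silent in ANL;
#' * `fetal_only`: expressed in FL only;
#' * `tumour_only`: expressed in LUAD only;
#' * `under_in_both`: expressed in ANL only (under-expressed in FL and LUAD);
#' * `ubiquitous`: expressed everywhere (dominates the read mass, as a few
#'   abundant miRNAs do in real small RNA-seq libraries);
#' * `silent`: expressed nowhere.
#'
#' @param group_sizes Named list of per-cohort named group sizes.
#' @param class_counts Named integer vector of miRNAs per planted class.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param expressed_mean_rpm Nominal mean RPM of an "on" cell for the focal
#'   classes, before the per-miRNA lognormal abundance factor.
#' @param silent_mean_rpm Nominal mean RPM of an "off" cell.
#' @param mean_sdlog Standard deviation (log scale) of the per-miRNA
#'   lognormal abundance factor applied to focal "on" means.
#' @param library_size_range Two integers; per-sample library sizes are drawn
#'   uniformly from this range.
#' @param cluster_region Locus string for the designated genomic cluster that
#'   receives a fraction of the planted oncofetal loci (mimicking the
#'   imprinted C14MC cluster at 14q32).
#' @param cluster_fraction Fraction of oncofetal miRNAs whose locus is placed
#'   inside `cluster_region`.
#' @param survival List with `baseline_hazard` (events per time unit for
#'   miRNA-negative patients), `hazard_ratio` (multiplicative hazard for
#'   miRNA-positive patients) and `censoring_rate` (independent exponential
#'   censoring; 0 means no censoring).
#' @param seed Integer master seed; independent substreams are derived from
#'   it for counts, loci and survival so that the count matrices do not
#'   change when survival generation is added.
#' @return A `sim_config` list.
#' @export
sim_config <- function(group_sizes = list(
                         discovery = c(FL = 25, ANL = 77, LUAD = 63),
                         validation = c(ANL = 38, LUAD = 389)
                       ),
                       class_counts = c(oncofetal = 13, fetal_only = 30,
                                        tumour_only = 30, under_in_both = 20,
                                        ubiquitous = 80, silent = 30),
                       nb_dispersion = 0.2,
                       expressed_mean_rpm = 50,
                       silent_mean_rpm = 0.05,
                       mean_sdlog = 0.5,
                       library_size_range = c(5e6, 2e7),
                       cluster_region = "chr14+:100800000-101100000",
                       cluster_fraction = 5 / 13,
                       survival = list(baseline_hazard = 0.001,
                                       hazard_ratio = 3,
                                       censoring_rate = 0.002),
                       seed = 1L) {
  cfg <- list(group_sizes = group_sizes, class_counts = class_counts,
              nb_dispersion = nb_dispersion,
              expressed_mean_rpm = expressed_mean_rpm,
              silent_mean_rpm = silent_mean_rpm,
              mean_sdlog = mean_sdlog,
              library_size_range = library_size_range,
              cluster_region = cluster_region,
              cluster_fraction = cluster_fraction,
              survival = survival, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (cohort in names(cfg$group_sizes)) {
    gs <- cfg$group_sizes[[cohort]]
    if (any(gs <= 0)) {
      abort(paste0("Cohort '", cohort, "' has a group with 0 samples."),
            class = "oncofetal_config_error")
    }
  }
  if (any(cfg$class_counts < 0)) {
    abort("class_counts must be non-negative.", class = "oncofetal_config_error")
  }
  if (cfg$nb_dispersion <= 0) {
    abort("nb_dispersion must be positive.", class = "oncofetal_config_error")
  }
  if (cfg$expressed_mean_rpm <= 0 || cfg$silent_mean_rpm < 0) {
    abort("Mean RPM parameters out of domain.", class = "oncofetal_config_error")
  }
  if (cfg$survival$hazard_ratio <= 0 || cfg$survival$baseline_hazard <= 0 ||
      cfg$survival$censoring_rate < 0) {
    abort("Survival parameters out of domain.", class = "oncofetal_config_error")
  }
  invisible(cfg)
}

# deterministic substream seed, stable across sessions
derive_seed <- function(seed, purpose) {
  strtoi(substr(rlang::hash(list(as.integer(seed), purpose)), 1, 7), 16L)
}

with_substream <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# which groups a planted class is "on" in
class_on_groups <- function() {
  list(oncofetal = c("FL", "LUAD"),
       fetal_only = "FL",
       tumour_only = "LUAD",
       under_in_both = "ANL",
       ubiquitous = c("FL", "ANL", "LUAD"),
       silent = character(0))
}

#' Generate synthetic discovery and validation cohorts
#'
#' Counts follow a negative-binomial model. For each miRNA and group, the
#' nominal mean RPM is `expressed_mean_rpm` (times a per-miRNA lognormal
#' abundance factor) where the miRNA's class is "on" and `silent_mean_rpm`
#' where it is "off". Ubiquitous miRNAs carry the remaining read mass: their
#' heavy-tailed abundances are scaled so each group's nominal RPM totals one
#' million, which makes realized RPM agree with the nominal means after
#' within-matrix normalization. Counts are
#' `NB(mu = mean_rpm * library_size / 1e6, dispersion)` with per-sample
#' library sizes drawn uniformly from `library_size_range`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `discovery` and `validation` (counts-unit
#'   [mir_expr()] objects) and `truth`, a tibble of `mirna_id`, `class`,
#'   `locus` and `in_cluster` (planted ground truth).
#' @export
generate_cohorts <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  classes <- rep(names(cfg$class_counts), times = cfg$class_counts)
  n_mir <- length(classes)
  if (n_mir == 0) abort("No miRNAs configured.", class = "oncofetal_config_error")
  mirna_ids <- sprintf("sim-miR-%03d", seq_len(n_mir))
  on_map <- class_on_groups()

  truth_loci <- with_substream(derive_seed(cfg$seed, "loci"), {
    simulate_loci(mirna_ids, classes, cfg)
  })

  out <- with_substream(derive_seed(cfg$seed, "counts"), {
    # per-miRNA abundance factor, shared across cohorts
    factor_focal <- rlnorm(n_mir, meanlog = 0, sdlog = cfg$mean_sdlog)
    ubiq <- classes == "ubiquitous"
    ubiq_base <- rlnorm(sum(ubiq), meanlog = 0, sdlog = 1.5)

    groups_all <- c("FL", "ANL", "LUAD")
    mean_rpm <- matrix(cfg$silent_mean_rpm, nrow = n_mir, ncol = 3,
                       dimnames = list(mirna_ids, groups_all))
    for (g in groups_all) {
      on <- vapply(classes, function(cl) g %in% on_map[[cl]], logical(1)) & !ubiq
      mean_rpm[on, g] <- cfg$expressed_mean_rpm * factor_focal[on]
      if (any(ubiq)) {
        resid <- 1e6 - sum(mean_rpm[!ubiq, g])
        mean_rpm[ubiq, g] <- ubiq_base / sum(ubiq_base) * resid
      }
    }

    cohorts <- purrr::imap(cfg$group_sizes, function(gs, cohort) {
      sample_meta <- purrr::imap_dfr(as.list(gs), function(n, g) {
        tibble(sample_id = sprintf("%s_%s_%03d", cohort, g, seq_len(n)),
               patient_id = sprintf("%s_pt_%s_%03d", cohort, g, seq_len(n)),
               group = g, cohort = cohort, total_reads = NA_real_)
      })
      n_samp <- nrow(sample_meta)
      libs <- round(runif(n_samp, cfg$library_size_range[1],
                          cfg$library_size_range[2]))
      sample_meta$total_reads <- libs
      mu <- mean_rpm[, sample_meta$group, drop = FALSE] *
        rep(libs / 1e6, each = n_mir)
      counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                               size = 1 / cfg$nb_dispersion),
                       nrow = n_mir,
                       dimnames = list(mirna_ids, sample_meta$sample_id))
      mir_expr(counts, sample_meta, unit = "counts")
    })
    cohorts
  })

  c(out, list(truth = truth_loci))
}

simulate_loci <- function(mirna_ids, classes, cfg) {
  n <- length(mirna_ids)
  region <- parse_locus(cfg$cluster_region)
  width <- 22L
  chrom <- paste0("chr", sample(setdiff(1:22, 14), n, replace = TRUE))
  start <- floor(runif(n, 1e6, 2e8))
  in_cluster <- rep(FALSE, n)
  onco <- which(classes == "oncofetal")
  n_in <- round(cfg$cluster_fraction * length(onco))
  if (n_in > 0) {
    picked <- onco[seq_len(n_in)]
    in_cluster[picked] <- TRUE
    chrom[picked] <- region$chrom
    start[picked] <- floor(runif(n_in, region$start,
                                 region$end - width))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  loci <- tibble(chrom = chrom, strand = strand,
                 start = start, end = start + width)
  tibble(mirna_id = mirna_ids, class = classes,
         locus = format_locus(loci), in_cluster = in_cluster)
}

#' Generate survival data linked to miRNA positivity
#'
#' For each LUAD sample in `m`, an exponential event time is drawn with
#' hazard `baseline_hazard * hazard_ratio^positive`, where a patient is
#' positive when any designated miRNA has RPM >= 1 in their sample.
#' Censoring is independent exponential at `censoring_rate` (0 disables it).
#'
#' @param cfg A [sim_config()]; its `survival` block and seed are used.
#' @param m An rpm-unit [mir_expr()] containing LUAD samples.
#' @param positive_mirnas Character vector of designated miRNA IDs.
#' @param seed Optional override of the survival substream seed.
#' @return A tibble `sample_id`, `patient_id`, `positive`, `time`, `event`.
#' @export
generate_survival <- function(cfg, m, positive_mirnas, seed = NULL) {
  stopifnot(inherits(m, "mir_expr"))
  if (m$unit != "rpm") {
    abort("generate_survival() expects an rpm-unit matrix.",
          class = "oncofetal_unit_error")
  }
  missing_ids <- setdiff(positive_mirnas, rownames(m$values))
  if (length(missing_ids)) {
    abort(paste0("Designated miRNA(s) absent from matrix: ",
                 paste(missing_ids, collapse = ", ")),
          class = "oncofetal_consistency_error")
  }
  luad <- m$samples$group == "LUAD"
  if (!any(luad)) {
    abort("No LUAD samples present.", class = "oncofetal_config_error")
  }
  sub <- m$values[positive_mirnas, luad, drop = FALSE]
  positive <- apply(sub >= 1, 2, any)
  n <- sum(luad)
  sv <- cfg$survival
  with_substream(seed %||% derive_seed(cfg$seed, "survival"), {
    hazard <- sv$baseline_hazard * sv$hazard_ratio^positive
    t_event <- rexp(n, rate = hazard)
    t_cens <- if (sv$censoring_rate > 0) {
      rexp(n, rate = sv$censoring_rate)
    } else {
      rep(Inf, n)
    }
    tibble(sample_id = m$samples$sample_id[luad],
           patient_id = m$samples$patient_id[luad],
           positive = unname(positive),
           time = pmin(t_event, t_cens),
           event = t_event <= t_cens)
  })
}
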