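#' Linear panel scorer
#'
#' A linear scorer holds an ordered miRNA panel, one weight per panel member,
#' an intercept, a decision cut-off and a descriptor of the feature transform
#' its weights assume. The sample score is
#' `intercept + sum(weights * features)` accumulated in panel order.
#'
#' @param panel Character vector of miRNA IDs, in scoring order.
#' @param weights Numeric vector, one weight per panel member.
#' @param intercept Additive constant (default 0).
#' @param cutoff Decision threshold; `NA` when not defined.
#' @param feature_transform Descriptor of the expected feature scale
#'   (default `"log2(rpm+1)"`).
#' @return A `linear_scorer` object.
#' @export
linear_scorer <- function(panel, weights, intercept = 0, cutoff = NA_real_,
                          feature_transform = "log2(rpm+1)") {
  if (length(panel) != length(weights)) {
    abort("panel and weights must have the same length.",
          class = "oncofetal_config_error")
  }
  structure(list(panel = as.character(panel), weights = as.numeric(weights),
                 intercept = as.numeric(intercept), cutoff = as.numeric(cutoff),
                 feature_transform = feature_transform),
            class = "linear_scorer")
}

#' @export
print.linear_scorer <- function(x, ...) {
  cat(sprintf("<linear_scorer> %d-miRNA panel, intercept %.4g, cutoff %s\n",
              length(x$panel), x$intercept,
              ifelse(is.na(x$cutoff), "unset", format(x$cutoff))))
  print(tidy(x), n = length(x$panel))
  invisible(x)
}

#' @method tidy linear_scorer
#' @export
tidy.linear_scorer <- function(x, ...) {
  tibble(term = x$panel, estimate = x$weights)
}

#' The published 13-miRNA lung oncofetal panel scorer
#'
#' The reference SVM score reported for the lung oncofetal miRNA panel, as a
#' fixed literal formula: no intercept was published and no numeric cut-off
#' (only a decision line was drawn), so the intercept is 0 and the cut-off is
#' left unset. Expression values enter on a log2 RPM scale.
#'
#' @return A [linear_scorer()] with the 13 published coefficients.
#' @export
#' @examples
#' s <- oncofetal_panel_scorer()
#' tidy(s)
oncofetal_panel_scorer <- function() {
  linear_scorer(
    panel = c("hsa-miR-301b", "hsa-miR-323b", "hsa-miR-329", "hsa-miR-380",
              "hsa-miR-433", "hsa-miR-543", "hsa-miR-627", "hsa-miR-6516",
              "hsa-miR-1290", "hsa-miR-1343", "hsa-miR-3170", "hsa-miR-4787",
              "hsa-miR-5684"),
    weights = c(1.24, 0.86, -0.47, -0.24, -0.42, -0.26, 0.01, 1.12,
                0.44, 0.34, 1.01, 0.97, 0.02),
    intercept = 0, cutoff = NA_real_,
    feature_transform = "log2(rpm)"
  )
}

#' Score a feature vector with a linear scorer
#'
#' @param scorer A [linear_scorer()].
#' @param features Named numeric vector of transformed expression values;
#'   must cover every panel miRNA.
#' @return The scalar score, accumulated left-to-right in panel order.
#' @export
score <- function(scorer, features) {
  miss <- setdiff(scorer$panel, names(features))
  if (length(miss)) {
    abort(paste0("Missing panel feature(s): ", paste(miss, collapse = ", ")),
          class = "oncofetal_consistency_error")
  }
  x <- as.numeric(features[scorer$panel])
  s <- scorer$intercept
  for (i in seq_along(x)) s <- s + scorer$weights[i] * x[i]
  s
}

#' Score every sample of an expression matrix
#'
#' Applies the scorer's feature transform (`log2(rpm + pseudocount)`) to the
#' panel rows of an rpm-unit matrix and scores each sample.
#'
#' @param scorer A [linear_scorer()].
#' @param m An rpm-unit [mir_expr()] containing every panel miRNA.
#' @param pseudocount Added to RPM before the log2 transform (default 1, so
#'   absent miRNAs contribute 0).
#' @return A tibble `sample_id`, `group`, `score`.
#' @export
score_samples <- function(scorer, m, pseudocount = 1) {
  stopifnot(inherits(m, "mir_expr"))
  if (m$unit != "rpm") {
    abort("score_samples() expects an rpm-unit matrix.",
          class = "oncofetal_unit_error")
  }
  miss <- setdiff(scorer$panel, rownames(m$values))
  if (length(miss)) {
    abort(paste0("Panel miRNA(s) absent from matrix: ",
                 paste(miss, collapse = ", ")),
          class = "oncofetal_consistency_error")
  }
  feat <- log_transform(m$values[scorer$panel, , drop = FALSE], pseudocount)
  scores <- scorer$intercept + drop(crossprod(feat, scorer$weights))
  tibble(sample_id = m$samples$sample_id, group = m$samples$group,
         score = unname(scores))
}

#' Fit a soft-margin linear SVM panel scorer
#'
#' Trains a linear support vector machine (hinge loss, L2 penalty) on
#' already-transformed features and returns the separating hyperplane as a
#' [linear_scorer()]. The scorer is oriented so that the positive class
#' scores higher; the decision cut-off is the signed-distance boundary, 0.
#' Solving the convex problem is deterministic; no seed is needed.
#'
#' @param x Numeric feature matrix, samples in rows, panel miRNAs in columns.
#' @param y Logical (or two-level) class vector; `TRUE` (or the level given
#'   by `positive`) is the class that should score high.
#' @param cost Soft-margin cost parameter C (default 1).
#' @param positive The positive class label (default `TRUE` for logical `y`).
#' @param feature_transform Descriptor recorded in the scorer.
#' @return A [linear_scorer()] with per-miRNA weights and intercept.
#' @export
fit_linear_svm <- function(x, y, cost = 1, positive = NULL,
                           feature_transform = "log2(rpm+1)") {
  x <- as.matrix(x)
  y <- as.vector(y)
  classes <- unique(y)
  if (length(classes) < 2) {
    abort("Both classes must be present to train.",
          class = "oncofetal_training_error")
  }
  if (length(classes) > 2) {
    abort("Binary classification only.", class = "oncofetal_training_error")
  }
  if (is.null(positive)) {
    positive <- if (is.logical(y)) TRUE else classes[2]
  }
  fit <- e1071::svm(x, factor(y), kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient so the designated positive class scores higher
  pos_mean <- mean(x[y == positive, , drop = FALSE] %*% w + b)
  neg_mean <- mean(x[y != positive, , drop = FALSE] %*% w + b)
  if (pos_mean < neg_mean) {
    w <- -w
    b <- -b
  }
  linear_scorer(panel = colnames(x) %||% paste0("f", seq_along(w)),
                weights = unname(w), intercept = b, cutoff = 0,
                feature_transform = feature_transform)
}

#' Train the panel SVM on a cohort's ANL and LUAD samples
#'
#' Convenience wrapper: extracts the panel rows of an rpm-unit matrix,
#' transforms to `log2(rpm + pseudocount)`, restricts to the ANL and LUAD
#' groups (fetal samples are never classifier inputs) and fits
#' [fit_linear_svm()] with LUAD as the positive class.
#'
#' @param m An rpm-unit [mir_expr()].
#' @param panel Character vector of panel miRNA IDs.
#' @param cost Soft-margin cost C.
#' @param pseudocount Added to RPM before the log2 transform.
#' @return A [linear_scorer()].
#' @export
train_panel_svm <- function(m, panel, cost = 1, pseudocount = 1) {
  keep <- m$samples$group %in% c("ANL", "LUAD")
  sub <- m[panel, keep]
  x <- t(log_transform(sub$values, pseudocount))
  y <- sub$samples$group == "LUAD"
  fit_linear_svm(x, y, cost = cost, positive = TRUE)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann–Whitney rank statistic (ties counted one half):
#' the probability that a random positive scores above a random negative.
#' The curve sweeps every distinct score as a threshold (score >= threshold
#' predicts positive).
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical vector; `TRUE` marks positives.
#' @return A `roc_result`: list with `curve` (tibble `threshold`, `fpr`,
#'   `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be present.", class = "oncofetal_domain_error")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           fpr = sum(pred & !labels) / n_neg,
           tpr = sum(pred & labels) / n_pos)
  })
  structure(list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Serialize a linear scorer to JSON
#'
#' @param scorer A [linear_scorer()].
#' @param path Output path.
#' @return `scorer`, invisibly.
#' @export
write_scorer <- function(scorer, path) {
  jsonlite::write_json(unclass(scorer), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(scorer)
}

#' Read a linear scorer from JSON
#'
#' @param path Path written by [write_scorer()].
#' @return A [linear_scorer()].
#' @export
read_scorer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_scorer(panel = x$panel, weights = x$weights,
                intercept = x$intercept,
                cutoff = x$cutoff %||% NA_real_,
                feature_transform = x$feature_transform)
}
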