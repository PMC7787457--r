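# Decision thresholds and evaluation metrics.
#
# Next-step metrics (AUROC, AUPRC) are computed over the pooled "unrolled"
# (patient, step) records of a split. Trajectory metrics are computed per
# forecast year, pooling the two 6-month steps of each year across patients
# and binarizing at one of four thresholds: frequency (positive fraction of
# training time steps), conservative (mean risk score over true HF steps),
# balanced (midpoint of the positive and negative mean scores), and
# optimized (validation-set F1 grid search).

#' F1 score of binarized predictions
#'
#' Harmonic mean of precision and recall, defined as 0 when
#' precision + recall is 0 (e.g. no predicted and no true positives).
#'
#' @param labels Binary labels.
#' @param predictions Binary predictions (same length).
#' @return Scalar in \[0, 1\].
#' @export
f1_score <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop_hftraj("labels and predictions have different lengths", "contract_error")
  }
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney pairwise statistic: the probability that a random
#' positive is scored above a random negative, with ties counting one half.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param labels Binary labels (both classes must be present).
#' @param scores Numeric scores.
#' @return Scalar in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  pos <- labels == 1
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop_hftraj("undefined metric: both classes must be present", "undefined_metric")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: the step-function area over the
#' precision-recall points, without linear interpolation. Tied scores are
#' processed as one block.
#'
#' @inheritParams auroc
#' @return Scalar in (0, 1\].
#' @export
auprc <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) {
    stop_hftraj("undefined metric: both classes must be present", "undefined_metric")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  # block ends where the score changes
  block_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[block_end]
  n_at <- block_end
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Compute the four decision thresholds
#'
#' Frequency: positive time-step fraction `k / (m + k)` of the training
#' scores. Conservative: mean score over the true HF steps. Balanced:
#' midpoint of the positive-mean and negative-mean scores. Optimized:
#' validation-F1 grid search over `seq(0, 1, by = grid_step)`, ties broken
#' toward the smallest threshold (requires `validation_scores`).
#'
#' @param train_scores Data frame with `label` and `score` columns (the
#'   pooled training-split records; see [predict_next_step()]).
#' @param validation_scores Optional data frame with `label`, `score` for
#'   the optimized threshold.
#' @param grid_step Grid resolution for the optimized threshold.
#' @return An `hf_thresholds` list with `frequency`, `conservative`,
#'   `balanced`, `optimized` (NA when no validation set is given) and a
#'   `provenance` record.
#' @export
compute_thresholds <- function(train_scores, validation_scores = NULL,
                               grid_step = 0.001) {
  lab <- train_scores$label; sc <- train_scores$score
  k <- sum(lab == 1); m <- sum(lab == 0)
  if (k == 0) {
    stop_hftraj("undefined mean positive score: no positive time steps",
                "undefined_metric")
  }
  p_bar <- mean(sc[lab == 1])
  n_bar <- if (m > 0) mean(sc[lab == 0]) else NA_real_
  optimized <- NA_real_
  if (!is.null(validation_scores)) {
    grid <- seq(0, 1, by = grid_step)
    vs <- validation_scores$score; vl <- validation_scores$label
    sp <- sort(vs[vl == 1]); sn <- sort(vs[vl == 0])
    np <- length(sp)
    tp <- np - findInterval(grid, sp, left.open = TRUE)
    fp <- length(sn) - findInterval(grid, sn, left.open = TRUE)
    fn <- np - tp
    prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
    rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
    f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
    optimized <- grid[which.max(f1)]
  }
  structure(list(
    frequency = k / (m + k),
    conservative = p_bar,
    balanced = (p_bar + n_bar) / 2,
    optimized = optimized,
    provenance = list(
      n_train_steps = k + m, n_positive = k,
      validation_used = !is.null(validation_scores), grid_step = grid_step
    )
  ), class = "hf_thresholds")
}

#' @export
print.hf_thresholds <- function(x, ...) {
  cat("<hf_thresholds>\n")
  cat(sprintf("  frequency    %.4f\n  conservative %.4f\n  balanced     %.4f\n",
              x$frequency, x$conservative, x$balanced))
  cat(sprintf("  optimized    %s\n",
              if (is.na(x$optimized)) "NA (no validation set)"
              else sprintf("%.3f", x$optimized)))
  invisible(x)
}

resolve_threshold <- function(threshold, kind = NULL) {
  if (inherits(threshold, "hf_thresholds")) {
    kind <- kind %||% "conservative"
    thr <- threshold[[kind]]
    if (is.null(thr) || is.na(thr)) {
      stop_hftraj(paste0("threshold '", kind, "' is not available"),
                  "contract_error")
    }
    thr
  } else {
    as.numeric(threshold)
  }
}

#' Next-step evaluation of a model on a cohort split
#'
#' Pools predictions over all (patient, step) pairs of the split and
#' reports AUROC and AUPRC (plus prevalence and pool size) as a one-row
#' tibble.
#'
#' @param model A trained `hf_model` or `hf_baseline`.
#' @param cohort A cohort with a `split` column (unless `split = NULL`).
#' @param split Split to evaluate on (default `"test"`).
#' @return One-row tibble with `auroc`, `auprc`, `n_steps`, `n_positive`,
#'   `prevalence`.
#' @export
evaluate_next_step <- function(model, cohort, split = "test") {
  preds <- if (inherits(model, "hf_baseline")) {
    predict(model, cohort, split = split)
  } else {
    predict_next_step(model, cohort, split = split)
  }
  tibble(
    auroc = auroc(preds$label, preds$score),
    auprc = auprc(preds$label, preds$score),
    n_steps = nrow(preds),
    n_positive = sum(preds$label == 1),
    prevalence = mean(preds$label == 1)
  )
}

#' Per-year evaluation of rolled-out trajectories
#'
#' Aligns forecasts with the true future labels of the (age-restricted)
#' cohort and evaluates each forecast year: year y pools forecast steps
#' 2y - 1 and 2y across patients (all steps up to 2y when
#' `cumulative = TRUE`), binarizes at the chosen threshold, and reports F1,
#' precision and recall plus AUROC/AUPRC (NA when a year's pool contains a
#' single class).
#'
#' @param forecasts An `hf_forecast` tibble from [batch_rollout()].
#' @param cohort The cohort supplying true labels (the same age window and
#'   split the forecasts were produced from).
#' @param threshold A numeric threshold or an `hf_thresholds` object.
#' @param kind Threshold name when `threshold` is an `hf_thresholds`.
#' @param years Number of forecast years to evaluate (default 10).
#' @param cumulative Evaluate years cumulatively (1..y) instead of per-year.
#' @param min_age Age window start used when the forecasts were produced.
#' @param split Optional split restriction matching the forecasts.
#' @return A tibble with one row per year: `year`, `n_steps`, `n_positive`,
#'   `precision`, `recall`, `f1`, `auroc`, `auprc`, `threshold`.
#' @export
evaluate_trajectory <- function(forecasts, cohort, threshold, kind = NULL,
                                years = 10, cumulative = FALSE, min_age = 40,
                                split = NULL) {
  thr <- resolve_threshold(threshold, kind)
  if (nrow(forecasts) == 0) {
    stop_hftraj("no forecasts to evaluate", "contract_error")
  }
  if (max(forecasts$step_ahead) < 2 * years) {
    stop_hftraj("forecast horizon shorter than the requested number of years",
                "contract_error")
  }
  sub <- as_tibble(cohort)
  if (!is.null(split)) sub <- dplyr::filter(sub, .data$split == !!split)
  truth <- restrict_to_age_window(sub, min_age = min_age)
  joined <- dplyr::inner_join(
    as_tibble(forecasts),
    dplyr::select(as_tibble(truth), "patient_id", target_step = "step",
                  label = "hf"),
    by = c("patient_id", "target_step")
  )
  rows <- lapply(seq_len(years), function(y) {
    steps <- if (cumulative) seq_len(2 * y) else c(2 * y - 1, 2 * y)
    pool <- dplyr::filter(joined, .data$step_ahead %in% steps)
    lab <- pool$label
    sc <- pool$hf_prob
    pred <- as.numeric(sc >= thr)
    tp <- sum(lab == 1 & pred == 1); fp <- sum(lab == 0 & pred == 1)
    fn <- sum(lab == 1 & pred == 0)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    two_class <- length(unique(lab)) == 2
    tibble(
      year = y, n_steps = length(lab), n_positive = sum(lab == 1),
      precision = precision, recall = recall,
      f1 = f1_score(lab, pred),
      auroc = if (two_class) auroc(lab, sc) else NA_real_,
      auprc = if (two_class) auprc(lab, sc) else NA_real_,
      threshold = thr
    )
  })
  dplyr::bind_rows(rows)
}
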