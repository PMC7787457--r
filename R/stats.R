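# Cohort-comparison statistics: enrichment of clinical characteristics in
# HF+ versus HF- patients, reported as base-2 log proportion ratios with
# exact binomial enrichment p-values against a fixed background rate.

#' Base-2 log proportion ratio between two cohort arms
#'
#' Computes `log2((count_pos / n_pos) / (count_neg / n_neg))`: the log fold
#' difference in prevalence of a characteristic between patients with and
#' without HF. Antisymmetric under swapping the arms. Vectorized over rows.
#'
#' @param count_pos,n_pos Cases and arm size among HF+ patients.
#' @param count_neg,n_neg Cases and arm size among HF- patients.
#' @return Numeric vector of log2 ratios.
#' @export
log2_proportion_ratio <- function(count_pos, n_pos, count_neg, n_neg) {
  counts <- cbind(count_pos, n_pos, count_neg, n_neg)
  if (any(counts <= 0)) {
    stop_hftraj("log2_proportion_ratio requires all four counts positive",
                "undefined_ratio")
  }
  if (any(count_pos > n_pos) || any(count_neg > n_neg)) {
    stop_hftraj("count exceeds arm size", "contract_error")
  }
  log2((count_pos / n_pos) / (count_neg / n_neg))
}

#' Exact binomial enrichment test against a background rate
#'
#' Exact tail probability of observing `count` cases in `n` trials at
#' `background_rate`. By default the test is one-sided in the direction of
#' the observed deviation from the expected count; the sidedness can be
#' fixed explicitly. Vectorized over `count` and `n`.
#'
#' @param count Observed case count(s), `0 <= count <= n`.
#' @param n Number of trials.
#' @param background_rate Null success probability in (0, 1); the HF+
#'   fraction of the full cohort, 9160 / (9160 + 74953) ~ 0.109, is the
#'   conventional background for HF enrichment.
#' @param alternative `"auto"` (one-sided toward the observed deviation),
#'   `"greater"`, `"less"`, or `"two.sided"`.
#' @return Numeric vector of p-values.
#' @export
binomial_enrichment_test <- function(count, n, background_rate,
                                     alternative = c("auto", "greater",
                                                     "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (background_rate <= 0 || background_rate >= 1) {
    stop_hftraj("background_rate must lie strictly in (0, 1)", "contract_error")
  }
  if (any(count < 0) || any(count > n)) {
    stop_hftraj("count must satisfy 0 <= count <= n", "contract_error")
  }
  one <- function(k, m) {
    side <- alternative
    if (side == "auto") {
      side <- if (k >= m * background_rate) "greater" else "less"
    }
    switch(side,
      greater = stats::pbinom(k - 1, m, background_rate, lower.tail = FALSE),
      less = stats::pbinom(k, m, background_rate),
      two.sided = stats::binom.test(k, m, background_rate,
                                    alternative = "two.sided")$p.value
    )
  }
  mapply(one, count, n)
}

#' Compare characteristic prevalence between HF+ and HF- arms
#'
#' Tidy wrapper over [log2_proportion_ratio()] and
#' [binomial_enrichment_test()]: takes one row per characteristic with the
#' four contingency counts and returns the table augmented with the log2
#' prevalence ratio and the enrichment p-value of the HF+ arm against the
#' background rate.
#'
#' @param contingency A data frame with columns `label`, `count_hf_pos`,
#'   `n_hf_pos`, `count_hf_neg`, `n_hf_neg`.
#' @param background_rate Null rate for the binomial test; defaults to the
#'   HF+ arm fraction `n_hf_pos / (n_hf_pos + n_hf_neg)` per row.
#' @param alternative Passed to [binomial_enrichment_test()].
#' @return The input tibble with `log_ratio` and `p_value` columns.
#' @export
compare_prevalence <- function(contingency, background_rate = NULL,
                               alternative = "auto") {
  x <- as_tibble(contingency)
  needed <- c("label", "count_hf_pos", "n_hf_pos", "count_hf_neg", "n_hf_neg")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop_hftraj(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
                "schema_error")
  }
  rate <- background_rate %||% (x$n_hf_pos / (x$n_hf_pos + x$n_hf_neg))
  x$log_ratio <- log2_proportion_ratio(x$count_hf_pos, x$n_hf_pos,
                                       x$count_hf_neg, x$n_hf_neg)
  # the test asks whether the characteristic's carriers are enriched for HF:
  # among count_hf_pos + count_hf_neg carriers, count_hf_pos are HF+
  x$p_value <- mapply(function(k, m, r) {
    binomial_enrichment_test(k, m, r, alternative = alternative)
  }, x$count_hf_pos, x$count_hf_pos + x$count_hf_neg,
     if (length(rate) == 1) rep(rate, nrow(x)) else rate)
  x
}
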