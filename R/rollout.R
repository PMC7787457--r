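# Auto-regressive trajectory forecasting.
#
# A forward pass over the observed window builds the hidden state; future
# steps then feed the model's own predictions back as inputs: the predicted
# HF probability replaces the observed HF input (optionally binarized at a
# threshold), and for the multi-task variant the predicted acute
# co-morbidity probabilities replace those three input channels. All other
# covariates are frozen at their last observed values; age can optionally
# advance by 0.5 years per step.

# incremental stateful forward: one time step for a batch
model_state_init <- function(model, n) {
  H <- model$spec$hidden_width
  switch(model$spec$variant,
    dhtm = list(h = lapply(seq_len(model$spec$n_recurrent_layers),
                           function(l) matrix(0, n, H))),
    dhtm_c = list(h1 = matrix(0, n, H), h2 = matrix(0, n, H)),
    lstm = list(h = lapply(seq_len(model$spec$n_recurrent_layers),
                           function(l) matrix(0, n, H)),
                c = lapply(seq_len(model$spec$n_recurrent_layers),
                           function(l) matrix(0, n, H)))
  )
}

model_state_step <- function(model, state, x) {
  par <- model$params
  spec <- model$spec
  if (spec$variant == "dhtm") {
    s <- dense_forward(par$dense, x)
    for (l in seq_along(par$layers)) {
      lp <- par$layers[[l]]
      u <- if (spec$use_layer_norm) ln_forward(lp$ln, s)$out else s
      h <- gru_cell_forward(lp$gru, state$h[[l]], u)$h
      state$h[[l]] <- h
      s <- if (spec$use_residual) s + h else h
    }
    p <- sigmoid(dense_forward(par$head, s))
    list(state = state, hf_prob = p, cm_prob = NULL)
  } else if (spec$variant == "dhtm_c") {
    g1 <- gru_cell_forward(par$gru1, state$h1, dense_forward(par$dense1, x))$h
    cm_logit <- dense_forward(par$head_cm, g1)
    cm_p <- sigmoid(cm_logit)
    g2 <- gru_cell_forward(par$gru2, state$h2, dense_forward(par$dense2, cm_logit))$h
    p <- sigmoid(dense_forward(par$head_hf, cbind(g1, g2, cm_p)))
    state$h1 <- g1; state$h2 <- g2
    list(state = state, hf_prob = p, cm_prob = cm_p)
  } else {
    s <- dense_forward(par$dense, x)
    for (l in seq_along(par$layers)) {
      st <- lstm_cell_forward(par$layers[[l]]$lstm, state$h[[l]],
                              state$c[[l]], s)
      state$h[[l]] <- st$h; state$c[[l]] <- st$c
      s <- st$h
    }
    p <- sigmoid(dense_forward(par$head, s))
    list(state = state, hf_prob = p, cm_prob = NULL)
  }
}

acute_cm_input_idx <- function() match(acute_cm_columns(), input_columns())

# X_obs: list over observed steps of N x 20 matrices (encoding scale)
rollout_batch <- function(model, X_obs, horizon, advance_age = FALSE,
                          binarize_feedback = NULL) {
  n <- nrow(X_obs[[1]])
  state <- model_state_init(model, n)
  res <- NULL
  for (t in seq_along(X_obs)) {
    res <- model_state_step(model, state, X_obs[[t]])
    state <- res$state
  }
  hf <- matrix(NA_real_, n, horizon)
  cm <- if (model$spec$variant == "dhtm_c") {
    array(NA_real_, c(n, horizon, model$spec$n_acute_cm))
  } else NULL
  if (horizon == 0) return(list(hf_prob = hf, cm_prob = cm))

  x_next <- X_obs[[length(X_obs)]]
  age_idx <- match("age", input_columns())
  hf_idx <- match("hf", input_columns())
  cm_idx <- acute_cm_input_idx()
  age_step <- 0.5 * model$encoding$age_scale
  for (k in seq_len(horizon)) {
    hf[, k] <- res$hf_prob[, 1]
    if (!is.null(cm)) cm[, k, ] <- res$cm_prob
    if (k == horizon) break
    fb <- res$hf_prob[, 1]
    if (!is.null(binarize_feedback)) {
      fb <- as.numeric(fb >= binarize_feedback)
    }
    x_next[, hf_idx] <- fb
    if (!is.null(res$cm_prob)) {
      cmfb <- res$cm_prob
      if (!is.null(binarize_feedback)) {
        cmfb <- (cmfb >= binarize_feedback) + 0
      }
      x_next[, cm_idx] <- cmfb
    }
    if (advance_age) x_next[, age_idx] <- x_next[, age_idx] + age_step
    res <- model_state_step(model, state, x_next)
    state <- res$state
  }
  list(hf_prob = hf, cm_prob = cm)
}

timeline_to_inputs <- function(timeline, age_scale) {
  timeline <- dplyr::arrange(as_tibble(timeline), .data$step)
  cov <- as.matrix(timeline[covariate_columns()])
  cov[, "age"] <- cov[, "age"] * age_scale
  inputs <- cbind(cov, hf = timeline$hf)
  colnames(inputs) <- input_columns()
  inputs
}

#' Roll out a multi-year HF risk trajectory for one patient
#'
#' Builds the hidden state on the observed prefix (all observed steps,
#' including their HF labels, enter as inputs), then predicts `horizon`
#' future steps auto-regressively. The first forecast element is the
#' model's output at the last observed step (HF risk one step ahead).
#'
#' @param model A trained `hf_model`.
#' @param observed A single patient's observed rows (cohort columns),
#'   length >= 1.
#' @param horizon Number of 6-month steps to forecast (>= 0).
#' @param advance_age If `TRUE`, the age input advances 0.5 years per
#'   forecast step instead of staying frozen at the last observed value.
#' @param binarize_feedback Optional threshold: feed back `prob >=
#'   threshold` instead of the raw probability.
#' @return An `hf_forecast` tibble with one row per forecast step:
#'   `patient_id`, `step_ahead` (1..horizon), `target_step` (index in the
#'   observed timeline's step numbering), `hf_prob` and, for the multi-task
#'   variant, `cm_prob_*` columns.
#' @export
rollout <- function(model, observed, horizon, advance_age = FALSE,
                    binarize_feedback = NULL) {
  if (horizon < 0) stop_hftraj("horizon must be >= 0", "contract_error")
  observed <- as_tibble(observed)
  if (nrow(observed) == 0) {
    stop_hftraj("empty observed window", "contract_error")
  }
  inputs <- timeline_to_inputs(observed, model$encoding$age_scale)
  rb <- rollout_batch(model, seq_to_list(inputs), horizon,
                      advance_age = advance_age,
                      binarize_feedback = binarize_feedback)
  out <- tibble(
    patient_id = rep(observed$patient_id[1], horizon),
    step_ahead = seq_len(horizon),
    target_step = max(observed$step) + seq_len(horizon),
    hf_prob = if (horizon > 0) rb$hf_prob[1, ] else numeric(0)
  )
  if (!is.null(rb$cm_prob) && horizon > 0) {
    for (j in seq_along(acute_cm_columns())) {
      out[[paste0("cm_prob_", acute_cm_columns()[j])]] <- rb$cm_prob[1, , j]
    }
  }
  class(out) <- unique(c("hf_forecast", class(out)))
  out
}

#' Roll out trajectories for every eligible patient of a cohort
#'
#' Task-2 evaluation protocol: each patient's first `observed_years` of
#' records from `min_age` on form the observed window; the following
#' `horizon_years` are forecast (15 observed years -> 30 steps, 10 forecast
#' years -> 20 steps, by default). Patients whose timeline does not cover
#' the observed window are skipped and reported.
#'
#' @param model A trained `hf_model`.
#' @param cohort A cohort.
#' @param observed_years,horizon_years Window lengths in years.
#' @param min_age Age at which the observed window starts.
#' @param split Optional split restriction.
#' @inheritParams rollout
#' @return A list with `forecasts` (an `hf_forecast` tibble; `target_step`
#'   refers to the age-restricted, re-based step index) and `skipped`
#'   (patient ids with insufficient observed data).
#' @export
batch_rollout <- function(model, cohort, observed_years = 15,
                          horizon_years = 10, min_age = 40, split = NULL,
                          advance_age = FALSE, binarize_feedback = NULL) {
  sub <- as_tibble(cohort)
  if (!is.null(split)) sub <- dplyr::filter(sub, .data$split == !!split)
  considered <- unique(sub$patient_id)
  sub <- restrict_to_age_window(sub, min_age = min_age)
  obs_steps <- as.integer(round(observed_years / 0.5))
  horizon <- as.integer(round(horizon_years / 0.5))
  lens <- dplyr::count(sub, .data$patient_id)
  eligible <- lens$patient_id[lens$n >= obs_steps]
  skipped <- setdiff(considered, eligible)
  if (length(eligible) == 0) {
    return(list(forecasts = tibble(), skipped = skipped))
  }
  obs <- dplyr::filter(sub, .data$patient_id %in% eligible,
                       .data$step < obs_steps) |>
    dplyr::arrange(.data$patient_id, .data$step)
  tls <- cohort_timelines(obs)
  mats <- lapply(tls, timeline_to_inputs, age_scale = model$encoding$age_scale)
  N <- length(mats)
  X_obs <- lapply(seq_len(obs_steps), function(t) {
    do.call(rbind, lapply(mats, function(m) m[t, , drop = FALSE]))
  })
  rb <- rollout_batch(model, X_obs, horizon, advance_age = advance_age,
                      binarize_feedback = binarize_feedback)
  ids <- names(tls)
  out <- tibble(
    patient_id = rep(ids, each = horizon),
    step_ahead = rep(seq_len(horizon), times = N),
    target_step = obs_steps - 1L + rep(seq_len(horizon), times = N),
    hf_prob = as.numeric(t(rb$hf_prob))
  )
  if (!is.null(rb$cm_prob)) {
    for (j in seq_along(acute_cm_columns())) {
      out[[paste0("cm_prob_", acute_cm_columns()[j])]] <-
        as.numeric(t(rb$cm_prob[, , j]))
    }
  }
  class(out) <- unique(c("hf_forecast", class(out)))
  list(forecasts = out, skipped = skipped)
}
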