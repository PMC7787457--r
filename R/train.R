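# Training: patient-level splits, mini-batch gradient descent with Adam,
# and the static (last-step) baselines.
#
# Sequences have variable length, so batches are padded to the batch
# maximum and a step-level mask zeroes the loss (and its gradient) on
# padded steps. The reduction is the sum over time steps and channels and
# the mean over patients in the batch.

#' Training configuration
#'
#' @param epochs Training epochs (default 30).
#' @param batch_size Patients per mini-batch.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is provided.
#' @param seed Seed controlling initialization, batch order and any
#'   downstream randomness; training is deterministic given the seed under
#'   single-threaded execution.
#' @param fractions Patient-level split fractions (train, validation, test);
#'   must sum to 1.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30, batch_size = 64, learning_rate = 1e-3,
                         optimizer = "adam", seed = 1L,
                         fractions = c(train = 0.6375, validation = 0.1125,
                                       test = 0.25)) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop_hftraj("split fractions must sum to 1", "contract_error")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), fractions = fractions),
            class = "train_config")
}

#' Assign patients to train/validation/test splits
#'
#' Patient-level random partition: every time step of a patient lands in
#' that patient's split. Sizes are `floor(n * fraction)` for validation and
#' test, with the remainder assigned to train.
#'
#' @param cohort A cohort.
#' @param fractions Named fractions for `train`, `validation`, `test`.
#' @param seed Seed making the partition reproducible.
#' @return The cohort with a `split` column.
#' @export
split_cohort <- function(cohort,
                         fractions = c(train = 0.6375, validation = 0.1125,
                                       test = 0.25),
                         seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop_hftraj("split fractions must sum to 1", "contract_error")
  }
  ids <- unique(cohort$patient_id)
  n <- length(ids)
  if (n < length(fractions)) {
    stop_hftraj("fewer patients than splits", "contract_error")
  }
  n_val <- floor(n * fractions[["validation"]])
  n_test <- floor(n * fractions[["test"]])
  set.seed(derive_seed(seed, "split"))
  shuffled <- sample(ids)
  assign <- stats::setNames(rep("train", n), shuffled)
  if (n_val > 0) assign[shuffled[seq_len(n_val)]] <- "validation"
  if (n_test > 0) assign[shuffled[n_val + seq_len(n_test)]] <- "test"
  out <- as_tibble(cohort)
  out$split <- unname(assign[out$patient_id])
  class(out) <- unique(c("hf_cohort", class(out)))
  out
}

# encode every timeline of a (sub)cohort once
prepare_sequences <- function(cohort, age_scale, include_cm_targets) {
  tls <- cohort_timelines(cohort)
  lapply(tls, function(tl) {
    enc <- encode_inputs(tl, include_cm_targets = include_cm_targets,
                         age_scale = age_scale)
    enc$patient_id <- tl$patient_id[1]
    enc
  })
}

# pad a set of sequences into time-major matrices plus a validity mask
pad_batch <- function(seqs) {
  N <- length(seqs)
  lens <- vapply(seqs, function(s) nrow(s$inputs), integer(1))
  Tmax <- max(lens)
  D <- ncol(seqs[[1]]$inputs)
  multi <- is.matrix(seqs[[1]]$targets)
  C <- if (multi) ncol(seqs[[1]]$targets) else 1L
  X <- lapply(seq_len(Tmax), function(t) matrix(0, N, D))
  Y <- lapply(seq_len(Tmax), function(t) matrix(0, N, C))
  mask <- matrix(0, N, Tmax)
  for (i in seq_len(N)) {
    Ti <- lens[i]
    for (t in seq_len(Ti)) {
      X[[t]][i, ] <- seqs[[i]]$inputs[t, ]
      Y[[t]][i, ] <- if (multi) seqs[[i]]$targets[t, ] else seqs[[i]]$targets[t]
    }
    mask[i, seq_len(Ti)] <- 1
  }
  list(X = X, Y = Y, mask = mask, lens = lens)
}

# one Adam update over an arbitrarily nested parameter list
adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mhat <- m2 / (1 - beta1^t)
      vhat <- v2 / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  walk(params, grads, state$m, state$v)
}

batch_loss_and_grads <- function(model, batch, loss_cfg) {
  N <- nrow(batch$mask)
  multi <- model$spec$variant == "dhtm_c"
  fwd <- model_forward_batch(model, batch$X, keep_cache = TRUE)
  Tn <- length(batch$X)
  per_elem <- function(y, p) {
    if (loss_cfg$kind == "focal") {
      pc <- clamp_prob(p)
      -loss_cfg$alpha * (1 - pc)^loss_cfg$beta * y * log(pc) -
        (1 - loss_cfg$alpha) * pc^loss_cfg$beta * (1 - y) * log(1 - pc)
    } else {
      pc <- clamp_prob(p)
      -y * log(pc) - (1 - y) * log(1 - pc)
    }
  }
  hf_loss <- 0; cm_loss <- 0
  dlogits <- vector("list", Tn)
  dcm_probs <- if (multi) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    mk <- batch$mask[, t]
    y_hf <- batch$Y[[t]][, 1]
    p_hf <- fwd$probs[[t]][, 1]
    hf_loss <- hf_loss + sum(per_elem(y_hf, p_hf) * mk)
    dlogits[[t]] <- matrix(loss_grad_logit(y_hf, p_hf, loss_cfg) * mk / N,
                           ncol = 1)
    if (multi) {
      y_cm <- batch$Y[[t]][, -1, drop = FALSE]
      p_cm <- fwd$cm_probs[[t]]
      cm_loss <- cm_loss + sum(per_elem(y_cm, p_cm) * mk)
      dcm_probs[[t]] <- loss_grad_prob(y_cm, p_cm, loss_cfg) * mk / N
    }
  }
  grads <- if (multi) {
    dhtmc_backward_batch(model, fwd$cache, dlogits, dcm_probs)
  } else if (model$spec$variant == "dhtm") {
    dhtm_backward_batch(model, fwd$cache, dlogits)
  } else {
    lstm_backward_batch(model, fwd$cache, dlogits)
  }
  list(hf_loss = hf_loss, cm_loss = cm_loss, grads = grads)
}

#' Train a trajectory model
#'
#' Teacher-forced next-step training: the observed covariates and HF label
#' at step i are the inputs, the HF label (and, for the multi-task variant,
#' the acute co-morbidity indicators) at step i + 1 are the targets.
#' Optimization is mini-batch Adam on the configured loss; the returned
#' model carries a per-epoch loss history (total, HF component and, for the
#' multi-task variant, the co-morbidity component, each as per-patient mean
#' of the summed step losses).
#'
#' @param cohort A cohort; when a `split` column is present only `train`
#'   patients are used.
#' @param spec A [model_spec()].
#' @param loss A [loss_config()].
#' @param config A [train_config()].
#' @param age_scale Age multiplier of the encoding contract.
#' @return A trained `hf_model` with `history` tibble.
#' @export
train_model <- function(cohort, spec = model_spec(),
                        loss = loss_config(), config = train_config(),
                        age_scale = 0.01) {
  sub <- if ("split" %in% names(cohort)) {
    dplyr::filter(as_tibble(cohort), .data$split == "train")
  } else as_tibble(cohort)
  if (nrow(sub) == 0) stop_hftraj("empty training split", "contract_error")

  model <- new_model(spec, seed = derive_seed(config$seed, "init"),
                     age_scale = age_scale)
  seqs <- prepare_sequences(sub, age_scale, spec$variant == "dhtm_c")
  n_pat <- length(seqs)
  set.seed(derive_seed(config$seed, "train"))
  state <- list(m = zeros_like(model$params), v = zeros_like(model$params))
  step_count <- 0
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    order_idx <- sample.int(n_pat)
    batch_starts <- seq(1, n_pat, by = config$batch_size)
    tot_hf <- 0; tot_cm <- 0
    for (bs in batch_starts) {
      idx <- order_idx[bs:min(bs + config$batch_size - 1, n_pat)]
      batch <- pad_batch(seqs[idx])
      res <- batch_loss_and_grads(model, batch, loss)
      tot_hf <- tot_hf + res$hf_loss
      tot_cm <- tot_cm + res$cm_loss
      if (!is.finite(res$hf_loss + res$cm_loss)) {
        stop_hftraj(sprintf("training diverged (non-finite loss) at epoch %d",
                            epoch), "training_error")
      }
      if (config$learning_rate > 0) {
        step_count <- step_count + 1
        upd <- adam_update(model$params, res$grads, state,
                           config$learning_rate, step_count)
        model$params <- upd$p
        state$m <- upd$m; state$v <- upd$v
      }
    }
    history[[epoch]] <- tibble(
      epoch = epoch,
      loss = (tot_hf + tot_cm) / n_pat,
      hf_loss = tot_hf / n_pat,
      cm_loss = if (spec$variant == "dhtm_c") tot_cm / n_pat else NA_real_
    )
  }
  model$history <- dplyr::bind_rows(history)
  model$loss_config <- loss
  model$train_config <- config
  model
}

#' Pooled next-step predictions of a recurrent model on a cohort
#'
#' Runs the model over each timeline and returns one row per (patient,
#' target step) with the observed label and the predicted probability --
#' the "unrolled" records over which next-step metrics and decision
#' thresholds are computed.
#'
#' @param model A trained `hf_model`.
#' @param cohort A cohort.
#' @param split Optional split name to restrict to (requires a `split`
#'   column).
#' @return A tibble with `patient_id`, `step` (the predicted step), `label`,
#'   `score`.
#' @export
predict_next_step <- function(model, cohort, split = NULL) {
  sub <- as_tibble(cohort)
  if (!is.null(split)) {
    if (!"split" %in% names(sub)) {
      stop_hftraj("cohort has no split column", "contract_error")
    }
    sub <- dplyr::filter(sub, .data$split == !!split)
  }
  seqs <- prepare_sequences(sub, model$encoding$age_scale, FALSE)
  chunks <- split(seq_along(seqs), ceiling(seq_along(seqs) / 512))
  out <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    batch <- pad_batch(seqs[idx])
    fwd <- model_forward_batch(model, batch$X)
    rows <- lapply(seq_along(idx), function(i) {
      Ti <- batch$lens[i]
      tibble(
        patient_id = seqs[[idx[i]]]$patient_id,
        step = seq_len(Ti),
        label = vapply(seq_len(Ti), function(t) batch$Y[[t]][i, 1], numeric(1)),
        score = vapply(seq_len(Ti), function(t) fwd$probs[[t]][i, 1], numeric(1))
      )
    })
    out[[ci]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

#' Fit a static last-step baseline
#'
#' Flattens every timeline into independent (input at step i -> HF at step
#' i + 1) rows and fits either an L2-regularized logistic regression (ridge)
#' or a linear support-vector machine with penalty `C = 1`; SVM decision
#' values are mapped through a sigmoid to give scores on the probability
#' scale.
#'
#' @param cohort A cohort (rows with `split == "train"` when present).
#' @param kind `"logreg_l2"` or `"linear_svm"`.
#' @param lambda Ridge penalty for the logistic baseline.
#' @param cost SVM penalization parameter C (default 1).
#' @param age_scale Age multiplier of the encoding contract.
#' @return An `hf_baseline` with a [predict()] method.
#' @export
fit_static_baseline <- function(cohort, kind = c("logreg_l2", "linear_svm"),
                                lambda = 1e-4, cost = 1, age_scale = 0.01) {
  kind <- match.arg(kind)
  sub <- if ("split" %in% names(cohort)) {
    dplyr::filter(as_tibble(cohort), .data$split == "train")
  } else as_tibble(cohort)
  if (nrow(sub) == 0) stop_hftraj("empty training split", "contract_error")
  seqs <- prepare_sequences(sub, age_scale, FALSE)
  x <- do.call(rbind, lapply(seqs, `[[`, "inputs"))
  y <- unlist(lapply(seqs, `[[`, "targets"))
  if (length(unique(y)) < 2) {
    stop_hftraj("degenerate fit: training labels contain a single class",
                "degenerate_fit")
  }
  varying <- which(apply(x, 2, function(col) stats::var(col) > 0))
  if (kind == "logreg_l2" && length(varying) < 2) {
    # constant design: intercept-only logistic model
    fit <- list(intercept_only = TRUE, p = mean(y))
  } else if (kind == "logreg_l2") {
    # ridge solutions converge reliably along a decreasing lambda path
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda * c(1000, 100, 10, 1),
                          standardize = FALSE)
  } else {
    fit <- e1071::svm(x, factor(y), kernel = "linear", cost = cost,
                      scale = FALSE)
  }
  structure(list(kind = kind, fit = fit, lambda = lambda,
                 encoding = list(input_columns = input_columns(),
                                 age_scale = age_scale)),
            class = "hf_baseline")
}

#' @export
predict.hf_baseline <- function(object, newdata, split = NULL, ...) {
  sub <- as_tibble(newdata)
  if (!is.null(split)) sub <- dplyr::filter(sub, .data$split == !!split)
  seqs <- prepare_sequences(sub, object$encoding$age_scale, FALSE)
  x <- do.call(rbind, lapply(seqs, `[[`, "inputs"))
  score <- if (object$kind == "logreg_l2" &&
               isTRUE(object$fit$intercept_only)) {
    rep(object$fit$p, nrow(x))
  } else if (object$kind == "logreg_l2") {
    as.numeric(stats::predict(object$fit, newx = x, type = "response",
                              s = object$lambda))
  } else {
    dv <- attr(stats::predict(object$fit, x, decision.values = TRUE),
               "decision.values")
    # orient decision values so larger means the positive class
    sgn <- if (colnames(dv)[1] %in% c("0/1")) -1 else 1
    sigmoid(sgn * as.numeric(dv))
  }
  tibble(
    patient_id = unlist(lapply(seqs, function(s) rep(s$patient_id, nrow(s$inputs)))),
    step = unlist(lapply(seqs, function(s) seq_len(nrow(s$inputs)))),
    label = unname(unlist(lapply(seqs, `[[`, "targets"))),
    score = unname(score)
  )
}

#' Baseline coefficients
#'
#' @param object An `hf_baseline`.
#' @param ... Unused.
#' @return Named numeric vector of linear coefficients (logistic baseline
#'   includes `(Intercept)`).
#' @export
coef.hf_baseline <- function(object, ...) {
  if (object$kind == "logreg_l2") {
    cf <- as.matrix(glmnet::coef.glmnet(object$fit, s = object$lambda))
    stats::setNames(as.numeric(cf), rownames(cf))
  } else {
    w <- crossprod(object$fit$SV, object$fit$coefs)
    stats::setNames(as.numeric(w), object$encoding$input_columns)
  }
}
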