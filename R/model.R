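# Model architectures.
#
# Three variants share the wiring dense-in -> recurrence -> sigmoid-out:
#
#   dhtm    dense(20 -> H) -> [LN -> GRU -> residual add] x L -> affine -> sigmoid
#   dhtm_c  two-branch multi-task network: branch 1 predicts the 3 acute
#           co-morbidities (dense -> GRU -> affine -> sigmoid); its
#           pre-sigmoid output feeds branch 2 (dense -> GRU); the HF head is
#           an affine + sigmoid over [GRU1 out, GRU2 out, predicted CMs].
#           No residual connections or layer normalization: the per-step
#           co-morbidity loss already provides frequent gradient feedback.
#   lstm    dense(20 -> H) -> stacked LSTM -> affine -> sigmoid (baseline)
#
# Residual connections use the pre-norm placement: block(s) = s + GRU(LN(s)),
# which keeps an unobstructed gradient path through deep stacks.

#' Architecture specification
#'
#' @param variant `"dhtm"`, `"dhtm_c"` or `"lstm"`.
#' @param hidden_width Hidden units per recurrent layer (default 64).
#' @param n_recurrent_layers Number of recurrent layers, 1..4 (default 2;
#'   `dhtm_c` has a fixed two-branch topology and ignores this).
#' @param use_residual,use_layer_norm Residual connections and layer
#'   normalization around each recurrent block; only the `dhtm` variant
#'   supports them and they default to on for it.
#' @param input_width Input dimension (19 covariates + previous-step HF).
#' @param n_acute_cm Number of acute co-morbidity channels predicted by
#'   `dhtm_c`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(variant = c("dhtm", "dhtm_c", "lstm"),
                       hidden_width = 64,
                       n_recurrent_layers = 2,
                       use_residual = NULL,
                       use_layer_norm = NULL,
                       input_width = 20,
                       n_acute_cm = 3) {
  variant <- match.arg(variant)
  if (variant == "dhtm") {
    use_residual <- use_residual %||% TRUE
    use_layer_norm <- use_layer_norm %||% TRUE
  } else {
    if (isTRUE(use_residual) || isTRUE(use_layer_norm)) {
      stop_hftraj(
        "residual connections and layer normalization are available only for the dhtm variant",
        "contract_error"
      )
    }
    use_residual <- FALSE
    use_layer_norm <- FALSE
  }
  if (n_recurrent_layers < 1 || n_recurrent_layers > 4) {
    stop_hftraj("n_recurrent_layers must be between 1 and 4", "contract_error")
  }
  structure(list(
    variant = variant,
    hidden_width = as.integer(hidden_width),
    n_recurrent_layers = as.integer(n_recurrent_layers),
    use_residual = use_residual,
    use_layer_norm = use_layer_norm,
    input_width = as.integer(input_width),
    n_acute_cm = as.integer(n_acute_cm)
  ), class = "model_spec")
}

init_model_params <- function(spec, seed = 1L) {
  set.seed(seed)
  H <- spec$hidden_width
  D <- spec$input_width
  if (spec$variant == "dhtm") {
    layers <- lapply(seq_len(spec$n_recurrent_layers), function(l) {
      p <- list(gru = gru_params(H, H))
      if (spec$use_layer_norm) p$ln <- ln_params(H)
      p
    })
    list(dense = dense_params(H, D), layers = layers,
         head = dense_params(1, H))
  } else if (spec$variant == "dhtm_c") {
    C <- spec$n_acute_cm
    list(dense1 = dense_params(H, D), gru1 = gru_params(H, H),
         head_cm = dense_params(C, H),
         dense2 = dense_params(H, C), gru2 = gru_params(H, H),
         head_hf = dense_params(1, 2 * H + C))
  } else {
    layers <- lapply(seq_len(spec$n_recurrent_layers),
                     function(l) list(lstm = lstm_params(H, H)))
    list(dense = dense_params(H, D), layers = layers,
         head = dense_params(1, H))
  }
}

#' Create an untrained model
#'
#' @param spec A [model_spec()].
#' @param seed Seed for the fan-in-scaled uniform weight initialization
#'   (biases start at zero).
#' @param age_scale Multiplier applied to the age input; part of the
#'   encoding contract stored with the model (default 0.01 keeps age
#'   commensurate with the binary covariates).
#' @return An `hf_model`.
#' @export
new_model <- function(spec, seed = 1L, age_scale = 0.01) {
  structure(list(
    spec = spec,
    params = init_model_params(spec, seed = seed),
    encoding = list(input_columns = input_columns(), age_scale = age_scale),
    history = NULL
  ), class = "hf_model")
}

# ---- batched forward passes (with caches for backprop) --------------------

# X: list over time of N x 20 input matrices
dhtm_forward_batch <- function(model, X, keep_cache = FALSE) {
  spec <- model$spec; par <- model$params
  stream <- lapply(X, function(x) dense_forward(par$dense, x))
  cache <- list(X = X, stream_in = list())
  streams <- list(stream)
  layer_caches <- list()
  for (l in seq_along(par$layers)) {
    lp <- par$layers[[l]]
    if (spec$use_layer_norm) {
      lnres <- lapply(stream, function(s) ln_forward(lp$ln, s))
      u <- lapply(lnres, `[[`, "out")
      ln_cache <- lapply(lnres, `[[`, "cache")
    } else {
      u <- stream
      ln_cache <- NULL
    }
    gres <- gru_layer_forward(lp$gru, u)
    g <- gres$out
    new_stream <- if (spec$use_residual) {
      Map(`+`, stream, g)
    } else g
    layer_caches[[l]] <- list(ln = ln_cache, gru = gres$cache, u = u)
    stream <- new_stream
    streams[[l + 1]] <- stream
  }
  logits <- lapply(stream, function(s) dense_forward(par$head, s))
  probs <- lapply(logits, sigmoid)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) {
    out$cache <- list(streams = streams, layers = layer_caches, X = X)
  }
  out
}

dhtm_backward_batch <- function(model, cache, dlogits) {
  spec <- model$spec; par <- model$params
  grads <- zeros_like(par)
  streams <- cache$streams
  L <- length(par$layers)
  top <- streams[[L + 1]]
  ds <- vector("list", length(dlogits))
  for (t in seq_along(dlogits)) {
    hb <- dense_backward(par$head, top[[t]], dlogits[[t]])
    grads$head$W <- grads$head$W + hb$grads$W
    grads$head$b <- grads$head$b + hb$grads$b
    ds[[t]] <- hb$dX
  }
  for (l in rev(seq_len(L))) {
    lp <- par$layers[[l]]
    lc <- cache$layers[[l]]
    gb <- gru_layer_backward(lp$gru, lc$gru, ds)
    for (nm in names(gb$grads)) {
      grads$layers[[l]]$gru[[nm]] <- grads$layers[[l]]$gru[[nm]] + gb$grads[[nm]]
    }
    du <- gb$dx
    if (spec$use_layer_norm) {
      dsl <- vector("list", length(du))
      for (t in seq_along(du)) {
        lb <- ln_backward(lp$ln, lc$ln[[t]], du[[t]])
        grads$layers[[l]]$ln$g <- grads$layers[[l]]$ln$g + lb$grads$g
        grads$layers[[l]]$ln$b <- grads$layers[[l]]$ln$b + lb$grads$b
        dsl[[t]] <- lb$dX
      }
      du <- dsl
    }
    ds <- if (spec$use_residual) Map(`+`, ds, du) else du
  }
  for (t in seq_along(ds)) {
    db <- dense_backward(par$dense, cache$X[[t]], ds[[t]])
    grads$dense$W <- grads$dense$W + db$grads$W
    grads$dense$b <- grads$dense$b + db$grads$b
  }
  grads
}

dhtmc_forward_batch <- function(model, X, keep_cache = FALSE) {
  par <- model$params
  x1 <- lapply(X, function(x) dense_forward(par$dense1, x))
  g1res <- gru_layer_forward(par$gru1, x1)
  g1 <- g1res$out
  cm_logits <- lapply(g1, function(h) dense_forward(par$head_cm, h))
  cm_probs <- lapply(cm_logits, sigmoid)
  x2 <- lapply(cm_logits, function(cl) dense_forward(par$dense2, cl))
  g2res <- gru_layer_forward(par$gru2, x2)
  g2 <- g2res$out
  concat <- Map(function(a, b, cp) cbind(a, b, cp), g1, g2, cm_probs)
  hf_logits <- lapply(concat, function(cc) dense_forward(par$head_hf, cc))
  hf_probs <- lapply(hf_logits, sigmoid)
  out <- list(probs = hf_probs, logits = hf_logits,
              cm_probs = cm_probs, cm_logits = cm_logits)
  if (keep_cache) {
    out$cache <- list(X = X, x1 = x1, g1 = g1, g1_cache = g1res$cache,
                      cm_logits = cm_logits, cm_probs = cm_probs,
                      x2 = x2, g2 = g2, g2_cache = g2res$cache,
                      concat = concat)
  }
  out
}

# dlogits_hf / dcm_probs_loss: per-step gradients of the loss w.r.t. the HF
# logit and the CM probabilities (the CM loss attaches to the probabilities;
# the HF head additionally consumes them through the concatenation)
dhtmc_backward_batch <- function(model, cache, dlogits_hf, dcm_probs_loss) {
  par <- model$params
  spec <- model$spec
  H <- spec$hidden_width
  C <- spec$n_acute_cm
  grads <- zeros_like(par)
  Tn <- length(dlogits_hf)

  dg1 <- vector("list", Tn)
  dg2 <- vector("list", Tn)
  dcm_prob <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    hb <- dense_backward(par$head_hf, cache$concat[[t]], dlogits_hf[[t]])
    grads$head_hf$W <- grads$head_hf$W + hb$grads$W
    grads$head_hf$b <- grads$head_hf$b + hb$grads$b
    dcc <- hb$dX
    dg1[[t]] <- dcc[, seq_len(H), drop = FALSE]
    dg2[[t]] <- dcc[, H + seq_len(H), drop = FALSE]
    dcm_prob[[t]] <- dcc[, 2 * H + seq_len(C), drop = FALSE] +
      dcm_probs_loss[[t]]
  }

  g2b <- gru_layer_backward(par$gru2, cache$g2_cache, dg2)
  for (nm in names(g2b$grads)) {
    grads$gru2[[nm]] <- grads$gru2[[nm]] + g2b$grads[[nm]]
  }
  dcm_logit <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    db2 <- dense_backward(par$dense2, cache$cm_logits[[t]], g2b$dx[[t]])
    grads$dense2$W <- grads$dense2$W + db2$grads$W
    grads$dense2$b <- grads$dense2$b + db2$grads$b
    p <- cache$cm_probs[[t]]
    dcm_logit[[t]] <- db2$dX + dcm_prob[[t]] * p * (1 - p)
  }
  for (t in seq_len(Tn)) {
    cb <- dense_backward(par$head_cm, cache$g1[[t]], dcm_logit[[t]])
    grads$head_cm$W <- grads$head_cm$W + cb$grads$W
    grads$head_cm$b <- grads$head_cm$b + cb$grads$b
    dg1[[t]] <- dg1[[t]] + cb$dX
  }
  g1b <- gru_layer_backward(par$gru1, cache$g1_cache, dg1)
  for (nm in names(g1b$grads)) {
    grads$gru1[[nm]] <- grads$gru1[[nm]] + g1b$grads[[nm]]
  }
  for (t in seq_len(Tn)) {
    db1 <- dense_backward(par$dense1, cache$X[[t]], g1b$dx[[t]])
    grads$dense1$W <- grads$dense1$W + db1$grads$W
    grads$dense1$b <- grads$dense1$b + db1$grads$b
  }
  grads
}

lstm_forward_batch <- function(model, X, keep_cache = FALSE) {
  par <- model$params
  stream <- lapply(X, function(x) dense_forward(par$dense, x))
  layer_caches <- list()
  streams <- list(stream)
  for (l in seq_along(par$layers)) {
    lres <- lstm_layer_forward(par$layers[[l]]$lstm, stream)
    layer_caches[[l]] <- lres$cache
    stream <- lres$out
    streams[[l + 1]] <- stream
  }
  logits <- lapply(stream, function(s) dense_forward(par$head, s))
  probs <- lapply(logits, sigmoid)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) out$cache <- list(streams = streams, layers = layer_caches, X = X)
  out
}

lstm_backward_batch <- function(model, cache, dlogits) {
  par <- model$params
  grads <- zeros_like(par)
  L <- length(par$layers)
  top <- cache$streams[[L + 1]]
  ds <- vector("list", length(dlogits))
  for (t in seq_along(dlogits)) {
    hb <- dense_backward(par$head, top[[t]], dlogits[[t]])
    grads$head$W <- grads$head$W + hb$grads$W
    grads$head$b <- grads$head$b + hb$grads$b
    ds[[t]] <- hb$dX
  }
  for (l in rev(seq_len(L))) {
    lb <- lstm_layer_backward(par$layers[[l]]$lstm, cache$layers[[l]], ds)
    for (nm in names(lb$grads)) {
      grads$layers[[l]]$lstm[[nm]] <- grads$layers[[l]]$lstm[[nm]] + lb$grads[[nm]]
    }
    ds <- lb$dx
  }
  for (t in seq_along(ds)) {
    db <- dense_backward(par$dense, cache$X[[t]], ds[[t]])
    grads$dense$W <- grads$dense$W + db$grads$W
    grads$dense$b <- grads$dense$b + db$grads$b
  }
  grads
}

model_forward_batch <- function(model, X, keep_cache = FALSE) {
  switch(model$spec$variant,
    dhtm = dhtm_forward_batch(model, X, keep_cache),
    dhtm_c = dhtmc_forward_batch(model, X, keep_cache),
    lstm = lstm_forward_batch(model, X, keep_cache)
  )
}

# ---- user-facing single-sequence forward passes ---------------------------

check_inputs_matrix <- function(model, inputs) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != model$spec$input_width) {
    stop_hftraj(sprintf("inputs must have %d columns, got %d",
                        model$spec$input_width, ncol(inputs)),
                "contract_error")
  }
  inputs
}

seq_to_list <- function(inputs) {
  lapply(seq_len(nrow(inputs)), function(t) inputs[t, , drop = FALSE])
}

#' Forward pass of a trajectory model over one input sequence
#'
#' Runs the model over a T x 20 matrix of per-step inputs (19 covariates
#' plus the previous-step HF indicator) and returns the per-step predicted
#' probability of HF at the following step. The output at position i depends
#' only on inputs 1..i (causal recurrence).
#'
#' `dhtmc_forward()` additionally returns the three acute co-morbidity
#' probabilities per step.
#'
#' @param model An `hf_model` of the matching variant.
#' @param inputs Numeric T x 20 matrix (already on the model's encoding
#'   scale; see [encode_inputs()]).
#' @return `dhtm_forward()`/`lstm_forward()`: numeric vector of length T of
#'   HF probabilities in (0, 1). `dhtmc_forward()`: a list with `hf_prob`
#'   (length T) and `cm_prob` (T x 3 matrix).
#' @export
dhtm_forward <- function(model, inputs) {
  if (model$spec$variant != "dhtm") {
    stop_hftraj("model variant is not dhtm", "contract_error")
  }
  inputs <- check_inputs_matrix(model, inputs)
  res <- dhtm_forward_batch(model, seq_to_list(inputs))
  vapply(res$probs, function(p) p[1, 1], numeric(1))
}

#' @rdname dhtm_forward
#' @export
dhtmc_forward <- function(model, inputs) {
  if (model$spec$variant != "dhtm_c") {
    stop_hftraj("model variant is not dhtm_c", "contract_error")
  }
  inputs <- check_inputs_matrix(model, inputs)
  res <- dhtmc_forward_batch(model, seq_to_list(inputs))
  list(
    hf_prob = vapply(res$probs, function(p) p[1, 1], numeric(1)),
    cm_prob = do.call(rbind, lapply(res$cm_probs, function(p) p[1, ]))
  )
}

#' @rdname dhtm_forward
#' @export
lstm_forward <- function(model, inputs) {
  if (model$spec$variant != "lstm") {
    stop_hftraj("model variant is not lstm", "contract_error")
  }
  inputs <- check_inputs_matrix(model, inputs)
  res <- lstm_forward_batch(model, seq_to_list(inputs))
  vapply(res$probs, function(p) p[1, 1], numeric(1))
}

#' Inspect first-layer input weights
#'
#' Returns the weights of the first dense layer connecting each of the 20
#' input variables to the hidden units. These weights gate how strongly each
#' input drives the hidden activities; on models trained with informative
#' acute co-morbidities, those rows carry visibly larger magnitudes.
#'
#' @param model An `hf_model`.
#' @param magnitude If `TRUE` return absolute values.
#' @return A matrix of shape (input width x hidden width) with input
#'   variables as row names.
#' @export
inspect_input_weights <- function(model, magnitude = FALSE) {
  W <- switch(model$spec$variant,
    dhtm_c = model$params$dense1$W,
    model$params$dense$W
  )
  out <- t(W)
  rownames(out) <- model$encoding$input_columns
  if (magnitude) abs(out) else out
}

#' @export
print.hf_model <- function(x, ...) {
  cat(sprintf("<hf_model> variant=%s hidden=%d layers=%d%s%s\n",
              x$spec$variant, x$spec$hidden_width, x$spec$n_recurrent_layers,
              if (x$spec$use_residual) " +residual" else "",
              if (x$spec$use_layer_norm) " +layer_norm" else ""))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; final loss %.5f\n",
                nrow(x$history), x$history$loss[nrow(x$history)]))
  }
  invisible(x)
}
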