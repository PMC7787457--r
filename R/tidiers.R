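# broom-style tidiers for fitted objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained trajectory model
#'
#' Returns the first dense layer's input weights in long form: one row per
#' (input variable, hidden unit) with the signed weight and its magnitude --
#' the quantities inspected in Hinton-style plots of what the network reads
#' from each input.
#'
#' @param x An `hf_model`.
#' @param ... Unused.
#' @return A tibble with `input`, `unit`, `weight`, `magnitude`.
#' @export
tidy.hf_model <- function(x, ...) {
  W <- inspect_input_weights(x)
  tibble(
    input = rep(rownames(W), times = ncol(W)),
    unit = rep(seq_len(ncol(W)), each = nrow(W)),
    weight = as.numeric(W),
    magnitude = abs(as.numeric(W))
  )
}

#' @rdname tidy.hf_model
#' @export
glance.hf_model <- function(x, ...) {
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  out <- tibble(
    variant = x$spec$variant,
    hidden_width = x$spec$hidden_width,
    n_recurrent_layers = x$spec$n_recurrent_layers,
    n_parameters = n_par,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)],
    final_hf_loss = if (is.null(x$history)) NA_real_ else
      x$history$hf_loss[nrow(x$history)],
    final_cm_loss = if (is.null(x$history)) NA_real_ else
      x$history$cm_loss[nrow(x$history)]
  )
  out
}

#' Tidy a static baseline
#'
#' @param x An `hf_baseline`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.hf_baseline <- function(x, ...) {
  cf <- coef(x)
  tibble(term = names(cf), estimate = as.numeric(cf))
}
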