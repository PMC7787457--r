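# internal helpers shared across modules

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a reproducible child seed from a global seed and a stage label;
# kept below 2^31 so it is a valid R integer
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    simulate = 101L, split = 211L, init = 307L, train = 401L,
    shuffle = 503L, rollout = 601L, evaluate = 701L
  )
  off <- offsets[[stage]] %||% 997L
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

stop_hftraj <- function(msg, class) {
  rlang::abort(msg, class = paste0("hftraj_", class))
}
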