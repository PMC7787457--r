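# Primitive layers with hand-derived backward passes.
#
# All layers operate on batches: a time step is an N x D matrix (patients in
# rows), a sequence is a list of such matrices. Weight orientation follows
# the gate convention W[H x (H + D)] acting on the concatenation
# [state, input]. Gradients are exact (verified against central finite
# differences in the test suite).

# broadcast a length-H vector across the rows of an N x H matrix
addb <- function(M, b) M + rep(b, each = nrow(M))
mulb <- function(M, g) M * rep(g, each = nrow(M))

init_matrix <- function(nrow, ncol) {
  # uniform fan-in scaling; biases are zero-initialized elsewhere
  lim <- 1 / sqrt(ncol)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

zeros_like <- function(p) {
  rapply(p, function(x) array(0, dim = dim(x) %||% length(x)), how = "replace")
}

# ---- gated recurrent unit -------------------------------------------------

gru_params <- function(hidden, input) {
  list(
    W_z = init_matrix(hidden, hidden + input),
    W_r = init_matrix(hidden, hidden + input),
    W_h = init_matrix(hidden, hidden + input),
    b_z = numeric(hidden), b_r = numeric(hidden), b_h = numeric(hidden)
  )
}

#' One step of a gated recurrent unit
#'
#' Computes the GRU recurrence: update gate
#' `z = sigmoid(W_z [h_prev, x] + b_z)` controlling how much past state to
#' keep, reset gate `r = sigmoid(W_r [h_prev, x] + b_r)` controlling how much
#' past state enters the candidate memory
#' `h~ = tanh(W_h [r * h_prev, x] + b_h)`, and the new state as the convex
#' combination `(1 - z) * h_prev + z * h~`.
#'
#' @param params List with weight matrices `W_z`, `W_r`, `W_h` of shape
#'   `hidden x (hidden + input)` and optional bias vectors `b_z`, `b_r`,
#'   `b_h`.
#' @param h_prev Previous hidden state: a length-`hidden` vector or an
#'   `N x hidden` matrix of batched states.
#' @param x Current input: a length-`input` vector or `N x input` matrix.
#' @return The next hidden state, same shape as `h_prev`.
#' @export
gru_step <- function(params, h_prev, x) {
  vec_in <- is.null(dim(h_prev))
  if (vec_in) h_prev <- matrix(h_prev, nrow = 1)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  H <- ncol(h_prev)
  if (ncol(params$W_z) != H + ncol(x) || nrow(params$W_z) != H) {
    stop_hftraj("gru_step: weight dimensions do not match state/input widths",
                "contract_error")
  }
  out <- gru_cell_forward(params, h_prev, x)$h
  if (vec_in) drop(out) else out
}

gru_cell_forward <- function(params, h_prev, x) {
  a <- cbind(h_prev, x)
  z <- sigmoid(addb(tcrossprod(a, params$W_z), params$b_z %||% 0))
  r <- sigmoid(addb(tcrossprod(a, params$W_r), params$b_r %||% 0))
  ah <- cbind(r * h_prev, x)
  htil <- tanh(addb(tcrossprod(ah, params$W_h), params$b_h %||% 0))
  h <- (1 - z) * h_prev + z * htil
  list(h = h, z = z, r = r, htil = htil)
}

# forward over a sequence; X is a list of N x D matrices
gru_layer_forward <- function(params, X, h0 = NULL) {
  N <- nrow(X[[1]])
  H <- nrow(params$W_z)
  h <- h0 %||% matrix(0, N, H)
  out <- vector("list", length(X))
  cache <- vector("list", length(X))
  for (t in seq_along(X)) {
    st <- gru_cell_forward(params, h, X[[t]])
    cache[[t]] <- c(st, list(h_prev = h, x = X[[t]]))
    h <- st$h
    out[[t]] <- h
  }
  list(out = out, cache = cache, h_last = h)
}

# backward through time; dout is a list of N x H gradients w.r.t. outputs
gru_layer_backward <- function(params, cache, dout) {
  H <- nrow(params$W_z)
  grads <- list(W_z = params$W_z * 0, W_r = params$W_r * 0,
                W_h = params$W_h * 0,
                b_z = numeric(H), b_r = numeric(H), b_h = numeric(H))
  dx <- vector("list", length(cache))
  dh <- NULL
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    d <- dout[[t]]
    if (!is.null(dh)) d <- d + dh
    z <- cc$z; r <- cc$r; htil <- cc$htil; h_prev <- cc$h_prev; x <- cc$x
    a <- cbind(h_prev, x)

    dz <- d * (htil - h_prev)
    dhtil <- d * z
    dh_prev <- d * (1 - z)

    dpre_h <- dhtil * (1 - htil^2)
    ah <- cbind(r * h_prev, x)
    grads$W_h <- grads$W_h + crossprod(dpre_h, ah)
    grads$b_h <- grads$b_h + colSums(dpre_h)
    dah <- dpre_h %*% params$W_h
    drh <- dah[, seq_len(H), drop = FALSE]
    dxt <- dah[, -seq_len(H), drop = FALSE]
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r

    dpre_r <- dr * r * (1 - r)
    grads$W_r <- grads$W_r + crossprod(dpre_r, a)
    grads$b_r <- grads$b_r + colSums(dpre_r)
    da <- dpre_r %*% params$W_r

    dpre_z <- dz * z * (1 - z)
    grads$W_z <- grads$W_z + crossprod(dpre_z, a)
    grads$b_z <- grads$b_z + colSums(dpre_z)
    da <- da + dpre_z %*% params$W_z

    dh_prev <- dh_prev + da[, seq_len(H), drop = FALSE]
    dxt <- dxt + da[, -seq_len(H), drop = FALSE]

    dx[[t]] <- dxt
    dh <- dh_prev
  }
  list(grads = grads, dx = dx, dh0 = dh)
}

# ---- LSTM -----------------------------------------------------------------

lstm_params <- function(hidden, input) {
  list(
    W_i = init_matrix(hidden, hidden + input),
    W_f = init_matrix(hidden, hidden + input),
    W_o = init_matrix(hidden, hidden + input),
    W_g = init_matrix(hidden, hidden + input),
    b_i = numeric(hidden), b_f = numeric(hidden), b_o = numeric(hidden),
    b_g = numeric(hidden)
  )
}

lstm_cell_forward <- function(params, h_prev, c_prev, x) {
  a <- cbind(h_prev, x)
  i <- sigmoid(addb(tcrossprod(a, params$W_i), params$b_i))
  f <- sigmoid(addb(tcrossprod(a, params$W_f), params$b_f))
  o <- sigmoid(addb(tcrossprod(a, params$W_o), params$b_o))
  g <- tanh(addb(tcrossprod(a, params$W_g), params$b_g))
  cc <- f * c_prev + i * g
  h <- o * tanh(cc)
  list(h = h, c = cc, i = i, f = f, o = o, g = g)
}

lstm_layer_forward <- function(params, X, h0 = NULL, c0 = NULL) {
  N <- nrow(X[[1]])
  H <- nrow(params$W_i)
  h <- h0 %||% matrix(0, N, H)
  cc <- c0 %||% matrix(0, N, H)
  out <- vector("list", length(X))
  cache <- vector("list", length(X))
  for (t in seq_along(X)) {
    st <- lstm_cell_forward(params, h, cc, X[[t]])
    cache[[t]] <- c(st, list(h_prev = h, c_prev = cc, x = X[[t]]))
    h <- st$h; cc <- st$c
    out[[t]] <- h
  }
  list(out = out, cache = cache, h_last = h, c_last = cc)
}

lstm_layer_backward <- function(params, cache, dout) {
  H <- nrow(params$W_i)
  grads <- list(W_i = params$W_i * 0, W_f = params$W_f * 0,
                W_o = params$W_o * 0, W_g = params$W_g * 0,
                b_i = numeric(H), b_f = numeric(H), b_o = numeric(H),
                b_g = numeric(H))
  dx <- vector("list", length(cache))
  dh <- NULL; dc <- NULL
  for (t in rev(seq_along(cache))) {
    cch <- cache[[t]]
    d <- dout[[t]]
    if (!is.null(dh)) d <- d + dh
    tc <- tanh(cch$c)
    dcc <- (if (is.null(dc)) 0 else dc) + d * cch$o * (1 - tc^2)
    do_ <- d * tc
    di <- dcc * cch$g
    df <- dcc * cch$c_prev
    dg <- dcc * cch$i
    dc <- dcc * cch$f

    a <- cbind(cch$h_prev, cch$x)
    dpre_i <- di * cch$i * (1 - cch$i)
    dpre_f <- df * cch$f * (1 - cch$f)
    dpre_o <- do_ * cch$o * (1 - cch$o)
    dpre_g <- dg * (1 - cch$g^2)

    grads$W_i <- grads$W_i + crossprod(dpre_i, a)
    grads$W_f <- grads$W_f + crossprod(dpre_f, a)
    grads$W_o <- grads$W_o + crossprod(dpre_o, a)
    grads$W_g <- grads$W_g + crossprod(dpre_g, a)
    grads$b_i <- grads$b_i + colSums(dpre_i)
    grads$b_f <- grads$b_f + colSums(dpre_f)
    grads$b_o <- grads$b_o + colSums(dpre_o)
    grads$b_g <- grads$b_g + colSums(dpre_g)

    da <- dpre_i %*% params$W_i + dpre_f %*% params$W_f +
      dpre_o %*% params$W_o + dpre_g %*% params$W_g
    dh <- da[, seq_len(H), drop = FALSE]
    dx[[t]] <- da[, -seq_len(H), drop = FALSE]
  }
  list(grads = grads, dx = dx)
}

# ---- dense and layer normalization ---------------------------------------

dense_params <- function(out_width, in_width) {
  list(W = init_matrix(out_width, in_width), b = numeric(out_width))
}

dense_forward <- function(params, X) addb(tcrossprod(X, params$W), params$b)

dense_backward <- function(params, X, dY) {
  list(grads = list(W = crossprod(dY, X), b = colSums(dY)),
       dX = dY %*% params$W)
}

ln_params <- function(width) list(g = rep(1, width), b = numeric(width))

ln_forward <- function(params, X, eps = 1e-5) {
  H <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(out = addb(mulb(xhat, params$g), params$b),
       cache = list(xhat = xhat, istd = istd))
}

ln_backward <- function(params, cache, dY) {
  H <- ncol(dY)
  xhat <- cache$xhat; istd <- cache$istd
  dxhat <- mulb(dY, params$g)
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dX <- (istd / H) * (H * dxhat - s1 - xhat * s2)
  list(grads = list(g = colSums(dY * xhat), b = colSums(dY)), dX = dX)
}
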