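test_that("gru_step matches closed forms at zero weights", {
  H <- 4
  p <- list(W_z = matrix(0, H, H + 3), W_r = matrix(0, H, H + 3),
            W_h = matrix(0, H, H + 3),
            b_z = numeric(H), b_r = numeric(H), b_h = numeric(H))
  v <- c(0.3, -0.2, 0.8, -0.9)
  # z = 0.5 and h~ = 0 everywhere, so the new state is 0.5 * h_prev
  expect_equal(gru_step(p, v, c(1, 2, 3)), 0.5 * v)
  expect_equal(gru_step(p, rep(0, H), c(1, 2, 3)), rep(0, H))
  expect_error(gru_step(p, v, c(1, 2)), class = "hftraj_contract_error")
})

test_that("gru_step equals the scalar formula oracle on random instances", {
  set.seed(21)
  for (i in 1:10) {
    H <- sample(2:5, 1); D <- sample(2:6, 1)
    p <- list(W_z = matrix(rnorm(H * (H + D), sd = 0.5), H),
              W_r = matrix(rnorm(H * (H + D), sd = 0.5), H),
              W_h = matrix(rnorm(H * (H + D), sd = 0.5), H),
              b_z = rnorm(H), b_r = rnorm(H), b_h = rnorm(H))
    h <- runif(H, -1, 1); x <- rnorm(D)
    expect_equal(gru_step(p, h, x), gru_step_scalar(p, h, x), tolerance = 1e-12)
    # the new state is a convex combination of bounded terms
    expect_true(all(abs(gru_step(p, h, x)) < 1))
  }
})

test_that("forward passes respect the zero-head and arity contracts", {
  set.seed(3)
  x <- matrix(rnorm(5 * 20), 5, 20)
  for (variant in c("dhtm", "dhtm_c", "lstm")) {
    m <- zero_head(new_model(model_spec(variant, hidden_width = 6), seed = 2))
    out <- switch(variant,
      dhtm = dhtm_forward(m, x),
      dhtm_c = dhtmc_forward(m, x)$hf_prob,
      lstm = lstm_forward(m, x)
    )
    expect_equal(out, rep(0.5, 5))
  }
  mc <- new_model(model_spec("dhtm_c", hidden_width = 6), seed = 2)
  res <- dhtmc_forward(mc, x)
  expect_length(res$hf_prob, 5)
  expect_equal(dim(res$cm_prob), c(5, 3))
  expect_true(all(res$hf_prob > 0 & res$hf_prob < 1))
  expect_true(all(res$cm_prob > 0 & res$cm_prob < 1))
  expect_error(dhtm_forward(mc, x), class = "hftraj_contract_error")
  expect_error(dhtm_forward(new_model(model_spec("dhtm"), 1), x[, 1:7]),
               class = "hftraj_contract_error")
})

test_that("outputs are causal: perturbing step j leaves outputs before j unchanged", {
  set.seed(4)
  x <- matrix(rnorm(8 * 20), 8, 20)
  x2 <- x; x2[5, ] <- x2[5, ] + 10
  for (variant in c("dhtm", "dhtm_c", "lstm")) {
    m <- new_model(model_spec(variant, hidden_width = 5), seed = 6)
    f <- switch(variant, dhtm = dhtm_forward, lstm = lstm_forward,
                dhtm_c = function(mm, xx) dhtmc_forward(mm, xx)$hf_prob)
    expect_equal(f(m, x)[1:4], f(m, x2)[1:4])
    expect_false(isTRUE(all.equal(f(m, x)[5:8], f(m, x2)[5:8])))
  }
})

test_that("a plain single-layer DHTM equals the composed gru_step oracle", {
  spec <- model_spec("dhtm", hidden_width = 3, n_recurrent_layers = 1,
                     use_residual = FALSE, use_layer_norm = FALSE)
  m <- new_model(spec, seed = 9)
  set.seed(10)
  x <- matrix(rnorm(6 * 20), 6, 20)
  got <- dhtm_forward(m, x)
  # hand-rolled composition: dense -> gru_step chain -> affine -> sigmoid
  h <- rep(0, 3)
  manual <- numeric(6)
  for (t in 1:6) {
    u <- as.numeric(m$params$dense$W %*% x[t, ] + m$params$dense$b)
    h <- gru_step_scalar(m$params$layers[[1]]$gru, h, u)
    manual[t] <- 1 / (1 + exp(-(sum(m$params$head$W * h) + m$params$head$b)))
  }
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("the LSTM forward equals the scalar recurrence oracle", {
  spec <- model_spec("lstm", hidden_width = 3, n_recurrent_layers = 1)
  m <- new_model(spec, seed = 12)
  set.seed(13)
  x <- matrix(rnorm(5 * 20), 5, 20)
  got <- lstm_forward(m, x)
  h <- cc <- rep(0, 3)
  manual <- numeric(5)
  for (t in 1:5) {
    u <- as.numeric(m$params$dense$W %*% x[t, ] + m$params$dense$b)
    st <- lstm_step_scalar(m$params$layers[[1]]$lstm, h, cc, u)
    h <- st$h; cc <- st$c
    manual[t] <- 1 / (1 + exp(-(sum(m$params$head$W * h) + m$params$head$b)))
  }
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("the DHTM+C two-branch wiring equals a hand-rolled composition", {
  m <- new_model(model_spec("dhtm_c", hidden_width = 3), seed = 14)
  set.seed(15)
  x <- matrix(rnorm(4 * 20), 4, 20)
  got <- dhtmc_forward(m, x)
  sig <- function(v) 1 / (1 + exp(-v))
  h1 <- h2 <- rep(0, 3)
  p <- m$params
  for (t in 1:4) {
    u1 <- as.numeric(p$dense1$W %*% x[t, ] + p$dense1$b)
    h1 <- gru_step_scalar(p$gru1, h1, u1)
    cm_logit <- as.numeric(p$head_cm$W %*% h1 + p$head_cm$b)
    cm_p <- sig(cm_logit)
    u2 <- as.numeric(p$dense2$W %*% cm_logit + p$dense2$b)
    h2 <- gru_step_scalar(p$gru2, h2, u2)
    hf <- sig(sum(p$head_hf$W * c(h1, h2, cm_p)) + p$head_hf$b)
    expect_equal(got$hf_prob[t], hf, tolerance = 1e-10)
    expect_equal(got$cm_prob[t, ], cm_p, tolerance = 1e-10)
  }
})

test_that("residual blocks with zero GRU weights pass the dense stream through", {
  spec <- model_spec("dhtm", hidden_width = 4, n_recurrent_layers = 2)
  m <- new_model(spec, seed = 16)
  for (l in seq_along(m$params$layers)) {
    for (nm in c("W_z", "W_r", "W_h", "b_z", "b_r", "b_h")) {
      m$params$layers[[l]]$gru[[nm]][] <- 0
    }
  }
  set.seed(17)
  x <- matrix(rnorm(3 * 20), 3, 20)
  got <- dhtm_forward(m, x)
  # with zero GRU weights and zero initial state every block adds zero,
  # so the head sees exactly the dense features
  manual <- apply(x, 1, function(row) {
    s <- as.numeric(m$params$dense$W %*% row + m$params$dense$b)
    1 / (1 + exp(-(sum(m$params$head$W * s) + m$params$head$b)))
  })
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  pad_batch <- hftraj:::pad_batch
  batch_loss_and_grads <- hftraj:::batch_loss_and_grads
  setval <- function(lst, path, i, delta) {
    if (length(path) == 1) {
      lst[[path]][i] <- lst[[path]][i] + delta
      lst
    } else {
      lst[[path[1]]] <- setval(lst[[path[1]]], path[-1], i, delta)
      lst
    }
  }
  for (variant in c("dhtm", "dhtm_c", "lstm")) {
    spec <- model_spec(variant, hidden_width = 3, n_recurrent_layers = 2)
    m <- new_model(spec, seed = 7)
    mk <- function(T_len) list(
      inputs = matrix(rnorm(T_len * 20), T_len, 20),
      targets = if (variant == "dhtm_c") {
        matrix(rbinom(T_len * 4, 1, 0.3), T_len, 4)
      } else rbinom(T_len, 1, 0.3),
      patient_id = "x"
    )
    batch <- pad_batch(list(mk(4), mk(3)))
    lc <- loss_config("focal")
    res <- batch_loss_and_grads(m, batch, lc)
    loss_at <- function(model) {
      r <- batch_loss_and_grads(model, batch, lc)
      (r$hf_loss + r$cm_loss) / nrow(batch$mask)
    }
    eps <- 1e-5
    check <- function(path, p, g) {
      if (is.list(p)) {
        for (nm in names(p)) check(c(path, nm), p[[nm]], g[[nm]])
        return(invisible())
      }
      for (i in sample(length(p), min(2, length(p)))) {
        m2 <- m
        m2$params <- setval(m$params, path, i, eps)
        lp <- loss_at(m2)
        m2$params <- setval(m$params, path, i, -eps)
        lm <- loss_at(m2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[i], num, tolerance = 1e-3)
      }
    }
    check(character(0), m$params, res$grads)
  }
})

test_that("inspect_input_weights returns the labelled first-layer matrix", {
  m <- new_model(model_spec("dhtm"), seed = 1)
  W <- inspect_input_weights(m)
  expect_equal(dim(W), c(20, 64))
  expect_equal(rownames(W), input_columns())
  expect_true(all(inspect_input_weights(m, magnitude = TRUE) >= 0))
  mc <- new_model(model_spec("dhtm_c", hidden_width = 8), seed = 1)
  expect_equal(dim(inspect_input_weights(mc)), c(20, 8))
})

test_that("model_spec enforces the variant constraints", {
  expect_error(model_spec("lstm", use_residual = TRUE),
               class = "hftraj_contract_error")
  expect_error(model_spec("dhtm_c", use_layer_norm = TRUE),
               class = "hftraj_contract_error")
  expect_error(model_spec("dhtm", n_recurrent_layers = 9),
               class = "hftraj_contract_error")
  sp <- model_spec("dhtm")
  expect_true(sp$use_residual && sp$use_layer_norm)
})
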