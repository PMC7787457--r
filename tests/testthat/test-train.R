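test_that("split_cohort partitions patients with the floor-then-train rule", {
  co <- simulate_cohort(sim_config(n_patients = 1000, n_steps = 4, seed = 1))
  sp <- split_cohort(co, seed = 3)
  sizes <- table(dplyr::distinct(tibble::as_tibble(sp), patient_id, split)$split)
  expect_equal(as.integer(sizes[c("train", "validation", "test")]),
               c(638L, 112L, 250L))
  # patient-level: every step of a patient shares its split
  per_pat <- tapply(sp$split, sp$patient_id, function(s) length(unique(s)))
  expect_true(all(per_pat == 1))
  # deterministic under the seed, different otherwise
  expect_identical(sp$split, split_cohort(co, seed = 3)$split)
  expect_false(identical(sp$split, split_cohort(co, seed = 4)$split))
  expect_error(split_cohort(co[1:4, ]), class = "hftraj_contract_error")
  expect_error(split_cohort(co, fractions = c(train = 0.5, validation = 0.1,
                                              test = 0.1)),
               class = "hftraj_contract_error")
})

small_planted_cohort <- function(n = 120, steps = 16, seed = 2) {
  split_cohort(simulate_cohort(sim_config(n_patients = n, n_steps = steps,
                                          planted_effect = 20, seed = seed)),
               seed = seed)
}

test_that("a zero learning rate leaves parameters untouched", {
  co <- small_planted_cohort()
  spec <- model_spec("dhtm", hidden_width = 4)
  m0 <- new_model(spec, seed = hftraj:::derive_seed(1L, "init"))
  m <- train_model(co, spec, loss_config(),
                   train_config(epochs = 1, learning_rate = 0, seed = 1))
  expect_equal(m$params, m0$params)
  expect_equal(nrow(m$history), 1)
})

test_that("training descends and is deterministic under a seed", {
  co <- small_planted_cohort()
  tc <- train_config(epochs = 3, batch_size = 32, seed = 5)
  m <- train_model(co, model_spec("dhtm", hidden_width = 6), loss_config(), tc)
  expect_lt(m$history$loss[3], m$history$loss[1])
  m2 <- train_model(co, model_spec("dhtm", hidden_width = 6), loss_config(), tc)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)
})

test_that("the multi-task model reports a decreasing CM loss component", {
  co <- small_planted_cohort(n = 200)
  m <- train_model(co, model_spec("dhtm_c", hidden_width = 8), loss_config(),
                   train_config(epochs = 5, batch_size = 32, seed = 6))
  expect_false(any(is.na(m$history$cm_loss)))
  expect_lt(m$history$cm_loss[5], m$history$cm_loss[1])
})

test_that("prediction pooling is invariant to patient order", {
  co <- small_planted_cohort(n = 40, steps = 8)
  m <- train_model(co, model_spec("dhtm", hidden_width = 4), loss_config(),
                   train_config(epochs = 1, seed = 1))
  p1 <- predict_next_step(m, co)
  shuffled <- co[order(rev(seq_len(nrow(co)))), ]
  p2 <- predict_next_step(m, shuffled)
  p2 <- p2[match(paste(p1$patient_id, p1$step),
                 paste(p2$patient_id, p2$step)), ]
  expect_equal(p1$score, p2$score)
})

test_that("the logistic baseline is intercept-only on constant features", {
  # every pair has identical inputs, so the fitted probability must equal
  # the class prevalence
  hf_list <- c(rep(list(c(0, 1)), 6), rep(list(c(0, 0)), 14))
  co <- make_cohort(hf_list)
  co$split <- "train"
  bl <- fit_static_baseline(co, "logreg_l2")
  pr <- predict(bl, co)
  expect_equal(pr$score, rep(0.3, 20), tolerance = 0.02)
})

test_that("both baselines separate a linearly separable cohort", {
  # diabetes perfectly predicts next-step HF
  mk <- function(i, diabetic) {
    make_timeline(c(0, diabetic, 0, diabetic), patient_id = sprintf("S%02d", i),
                  cm = list(cm_diabetes = diabetic))
  }
  co <- dplyr::bind_rows(lapply(1:20, function(i) mk(i, as.integer(i <= 10)))) |>
    as_cohort()
  co$split <- "train"
  for (kind in c("logreg_l2", "linear_svm")) {
    bl <- fit_static_baseline(co, kind)
    pr <- predict(bl, co)
    expect_equal(as.numeric(pr$score > 0.5), pr$label,
                 info = kind)
  }
})

test_that("the logistic baseline recovers known generative coefficients", {
  set.seed(44)
  n <- 5000
  diabetes <- rbinom(n, 1, 0.4)
  kidney <- rbinom(n, 1, 0.3)
  hf_prev <- rbinom(n, 1, 0.2)
  truth <- c(intercept = -2, cm_diabetes = 1.2, cm_kidney = -0.8, hf = 1.5)
  eta <- truth[1] + truth[2] * diabetes + truth[3] * kidney + truth[4] * hf_prev
  y2 <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  co <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_timeline(c(hf_prev[i], y2[i]), patient_id = sprintf("R%05d", i),
                  cm = list(cm_diabetes = diabetes[i], cm_kidney = kidney[i]))
  })) |> as_cohort()
  bl <- fit_static_baseline(co, "logreg_l2", lambda = 1e-4)
  cf <- coef(bl)
  # oracle standard errors from an unpenalized refit
  g <- glm(y2 ~ diabetes + kidney + hf_prev, family = binomial)
  se <- summary(g)$coefficients[, "Std. Error"]
  expect_lt(abs(cf[["cm_diabetes"]] - truth[2]), 3 * se[2])
  expect_lt(abs(cf[["cm_kidney"]] - truth[3]), 3 * se[3])
  expect_lt(abs(cf[["hf"]] - truth[4]), 3 * se[4])
})

test_that("degenerate single-class training is rejected", {
  co <- make_cohort(list(c(0, 0, 0), c(0, 0, 0)))
  co$split <- "train"
  expect_error(fit_static_baseline(co, "logreg_l2"),
               class = "hftraj_degenerate_fit")
})
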