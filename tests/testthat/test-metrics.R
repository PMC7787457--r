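# exhaustive pairwise oracle for the ROC area
auroc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# direct average-precision oracle: walk the unique thresholds in descending
# order and sum precision * recall-increment
auprc_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0; area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(labels == 1 & pred)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

test_that("f1_score matches hand counts and conventions", {
  expect_equal(f1_score(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(f1_score(c(1, 0, 1), c(0, 0, 0)), 0)
  expect_equal(f1_score(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(f1_score(c(0, 0), c(0, 0)), 0)
  expect_error(f1_score(c(1, 0), c(1, 0, 0)), class = "hftraj_contract_error")
})

test_that("auroc equals the exhaustive pairwise statistic", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  set.seed(51)
  for (i in 1:10) {
    lab <- c(0, 1, rbinom(6, 1, 0.5))
    sc <- round(runif(8), 1)  # coarse grid forces ties
    expect_equal(auroc(lab, sc), auroc_oracle(lab, sc))
  }
  expect_error(auroc(rep(1, 4), runif(4)), class = "hftraj_undefined_metric")
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(52)
  lab <- rbinom(50, 1, 0.3); lab[1:2] <- c(0, 1)
  sc <- rnorm(50)
  a <- auroc(lab, sc)
  expect_equal(auroc(lab, exp(sc)), a)
  expect_equal(auroc(lab, 3 * sc - 7), a)
  expect_equal(auroc(lab, atan(sc)), a)
})

test_that("auroc agrees with an established implementation", {
  set.seed(53)
  lab <- rbinom(200, 1, 0.2); lab[1:2] <- c(0, 1)
  sc <- runif(200)
  ref <- as.numeric(suppressMessages(pROC::auc(lab, sc)))
  expect_equal(auroc(lab, sc), ref, tolerance = 1e-10)
})

test_that("auprc equals the step-function oracle and its bounds", {
  expect_equal(auprc(c(0, 0, 1), c(0.1, 0.2, 0.9)), 1)
  set.seed(54)
  for (i in 1:10) {
    lab <- c(0, 1, rbinom(8, 1, 0.4))
    sc <- round(runif(10), 1)
    expect_equal(auprc(lab, sc), auprc_oracle(lab, sc))
  }
  # random scores concentrate near the class prevalence
  lab <- rbinom(4000, 1, 0.15)
  expect_lt(abs(auprc(lab, runif(4000)) - mean(lab)), 0.05)
  expect_error(auprc(rep(0, 5), runif(5)), class = "hftraj_undefined_metric")
})

test_that("the four thresholds follow their defining formulas", {
  tr <- tibble::tibble(label = c(1, 1, 1, rep(0, 7)),
                       score = c(0.8, 0.6, 0.7, 0.1, 0.3, 0.2, 0.1, 0.2, 0.1, 0.4))
  th <- compute_thresholds(tr)
  expect_equal(th$frequency, 0.3)
  expect_equal(th$conservative, 0.7)
  expect_equal(th$balanced, (0.7 + 0.2) / 2)
  expect_true(is.na(th$optimized))

  tr2 <- tibble::tibble(label = c(1, 1, 0, 0), score = c(0.8, 0.6, 0.1, 0.3))
  th2 <- compute_thresholds(tr2)
  expect_equal(th2$conservative, 0.7)
  expect_equal(th2$balanced, 0.45)

  # perfectly separated validation scores: optimized threshold sits strictly
  # between the groups (ties broken toward the smallest grid value) at F1 = 1
  val <- tibble::tibble(label = c(0, 0, 1, 1), score = c(0.2, 0.3, 0.8, 0.9))
  th3 <- compute_thresholds(tr2, val)
  expect_gt(th3$optimized, 0.3)
  expect_lte(th3$optimized, 0.8)
  expect_equal(f1_score(val$label, as.numeric(val$score >= th3$optimized)), 1)
  # smallest-threshold tie break: 0.301 is the first grid point with F1 = 1
  expect_equal(th3$optimized, 0.301)

  expect_error(compute_thresholds(tibble::tibble(label = c(0, 0),
                                                 score = c(0.1, 0.2))),
               class = "hftraj_undefined_metric")
})

test_that("conservative >= balanced exactly when positives score above negatives", {
  set.seed(55)
  for (i in 1:10) {
    lab <- c(0, 1, rbinom(40, 1, 0.3))
    sc <- runif(42)
    th <- compute_thresholds(tibble::tibble(label = lab, score = sc))
    p_bar <- mean(sc[lab == 1]); n_bar <- mean(sc[lab == 0])
    expect_equal(th$conservative >= th$balanced, p_bar >= n_bar)
  }
})

test_that("per-year trajectory evaluation matches hand-counted confusion tables", {
  # 3 patients, 30 observed steps + 4 forecast steps (2 years)
  mk <- function(id, future_hf) {
    make_timeline(c(rep(0, 30), future_hf), patient_id = id)
  }
  co <- as_cohort(dplyr::bind_rows(
    mk("A", c(1, 0, 0, 1)), mk("B", c(0, 0, 1, 0)), mk("C", c(0, 0, 0, 0))
  ))
  fc <- tibble::tibble(
    patient_id = rep(c("A", "B", "C"), each = 4),
    step_ahead = rep(1:4, 3),
    target_step = rep(30:33, 3),
    hf_prob = c(0.9, 0.2, 0.1, 0.8,   # A: hits both events
                0.1, 0.1, 0.2, 0.1,   # B: misses its year-2 event
                0.1, 0.9, 0.1, 0.1)   # C: one false alarm in year 1
  )
  rep1 <- evaluate_trajectory(fc, co, threshold = 0.5, years = 2)
  # year 1 pools steps 1-2: labels A=(1,0), B=(0,0), C=(0,0);
  # predictions A=(1,0), B=(0,0), C=(0,1) -> tp=1 fp=1 fn=0
  expect_equal(rep1$precision[1], 0.5)
  expect_equal(rep1$recall[1], 1)
  expect_equal(rep1$f1[1], 2 / 3)
  # year 2 pools steps 3-4: labels A=(0,1), B=(1,0), C=(0,0);
  # predictions A=(0,1), B=(0,0), C=(0,0) -> tp=1 fp=0 fn=1
  expect_equal(rep1$precision[2], 1)
  expect_equal(rep1$recall[2], 0.5)
  expect_equal(rep1$f1[2], 2 / 3)
  expect_equal(rep1$n_steps, c(6, 6))

  # threshold 0 predicts everything positive: recall 1 in both years
  rep0 <- evaluate_trajectory(fc, co, threshold = 0, years = 2)
  expect_equal(rep0$recall, c(1, 1))
  # a constant forecast below the threshold recalls nothing
  fc2 <- fc; fc2$hf_prob <- 0.5
  rep2 <- evaluate_trajectory(fc2, co, threshold = 0.6, years = 2)
  expect_equal(rep2$recall, c(0, 0))
  # perfect forecasts reach F1 = 1 every year
  fc3 <- fc
  fc3$hf_prob <- c(1, 0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0)
  rep3 <- evaluate_trajectory(fc3, co, threshold = 0.5, years = 2)
  expect_equal(rep3$f1, c(1, 1))
  # cumulative mode pools years 1..y
  repc <- evaluate_trajectory(fc, co, threshold = 0.5, years = 2,
                              cumulative = TRUE)
  expect_equal(repc$n_steps, c(6, 12))

  expect_error(evaluate_trajectory(fc, co, threshold = 0.5, years = 5),
               class = "hftraj_contract_error")
})

test_that("evaluate_next_step pools unrolled records and reports both areas", {
  co <- split_cohort(simulate_cohort(sim_config(n_patients = 60, n_steps = 10,
                                                planted_effect = 20, seed = 5)),
                     seed = 5)
  m <- new_model(model_spec("dhtm", hidden_width = 4), seed = 2)
  ev <- evaluate_next_step(m, co, split = "test")
  expect_true(all(c("auroc", "auprc", "n_steps", "prevalence") %in% names(ev)))
  expect_true(ev$auroc >= 0 && ev$auroc <= 1)
  n_test <- sum(co$split == "test")
  n_pat_test <- length(unique(co$patient_id[co$split == "test"]))
  expect_equal(ev$n_steps, n_test - n_pat_test)
})
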