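# fixtures built in code: tiny valid cohorts and hand-set model weights

# a valid single-patient timeline with the given hf sequence
make_timeline <- function(hf, patient_id = "P1", age_start = 40,
                          sex_m = 1, lesion = "lesion_other",
                          cm = NULL, surgery = NULL) {
  T_len <- length(hf)
  tl <- tibble::tibble(
    patient_id = patient_id,
    step = 0:(T_len - 1),
    age = age_start + 0.5 * (0:(T_len - 1)),
    sex_m = sex_m, sex_f = 1 - sex_m,
    lesion_severe = 0, lesion_shunt = 0, lesion_valve = 0, lesion_other = 0
  )
  tl[[lesion]] <- 1
  for (col in cm_columns()) tl[[col]] <- 0
  if (!is.null(cm)) for (col in names(cm)) tl[[col]] <- cm[[col]]
  tl$surgery <- surgery %||% 0
  tl$hf <- hf
  tl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_cohort <- function(hf_list, age_start = 40) {
  dplyr::bind_rows(lapply(seq_along(hf_list), function(i) {
    make_timeline(hf_list[[i]], patient_id = sprintf("P%02d", i),
                  age_start = age_start)
  })) |> as_cohort()
}

# deterministic small weights for hand-checked forward passes
fill_mat <- function(nr, nc, scale = 0.1) {
  matrix(scale * sin(seq_len(nr * nc)), nr, nc)
}

zero_head <- function(model) {
  if (model$spec$variant == "dhtm_c") {
    model$params$head_hf$W[] <- 0
    model$params$head_hf$b[] <- 0
  } else {
    model$params$head$W[] <- 0
    model$params$head$b[] <- 0
  }
  model
}

# scalar reference implementation of one GRU step (independent oracle:
# element-by-element evaluation of the four gate formulas)
gru_step_scalar <- function(params, h_prev, x) {
  H <- length(h_prev)
  a <- c(h_prev, x)
  z <- r <- numeric(H)
  for (j in seq_len(H)) {
    z[j] <- 1 / (1 + exp(-(sum(params$W_z[j, ] * a) + params$b_z[j])))
    r[j] <- 1 / (1 + exp(-(sum(params$W_r[j, ] * a) + params$b_r[j])))
  }
  ah <- c(r * h_prev, x)
  htil <- numeric(H)
  for (j in seq_len(H)) {
    htil[j] <- tanh(sum(params$W_h[j, ] * ah) + params$b_h[j])
  }
  (1 - z) * h_prev + z * htil
}

# Published cohort-comparison table used as a worked-example oracle: counts
# of each characteristic among the 9160 HF+ and 74953 HF- patients, with the
# printed log2 prevalence ratios.
table1_rows <- function() {
  tibble::tribble(
    ~label,                        ~count_hf_pos, ~count_hf_neg, ~log_ratio,
    "Death",                       3557,          5066,          2.52,
    "Severe lesion",               970,           8530,          -0.10,
    "Shunt lesion",                2025,          40445,         -1.29,
    "Valve lesion",                1811,          11754,         0.33,
    "Other lesion",                4354,          14224,         1.32,
    "Acute myocardial infarction", 2724,          2714,          3.04,
    "Coronary artery disease",     5447,          6986,          2.67,
    "Arrhythmia",                  4155,          3699,          3.20,
    "Ventricular arrhythmias",     992,           846,           3.26,
    "Pulmonary hypertension",      2771,          2182,          3.38,
    "Infective endocarditis",      637,           837,           2.64,
    "Diabetes",                    2799,          3490,          2.71,
    "Stroke",                      2215,          3610,          2.33,
    "Chronic liver disease",       557,           765,           2.57,
    "Chronic kidney disease",      2788,          1717,          3.73,
    "Sepsis",                      988,           1923,          2.07
  ) |>
    dplyr::mutate(n_hf_pos = 9160, n_hf_neg = 74953)
}

# scalar LSTM step oracle
lstm_step_scalar <- function(p, h_prev, c_prev, x) {
  a <- c(h_prev, x)
  sig <- function(v) 1 / (1 + exp(-v))
  H <- length(h_prev)
  i <- f <- o <- g <- numeric(H)
  for (j in seq_len(H)) {
    i[j] <- sig(sum(p$W_i[j, ] * a) + p$b_i[j])
    f[j] <- sig(sum(p$W_f[j, ] * a) + p$b_f[j])
    o[j] <- sig(sum(p$W_o[j, ] * a) + p$b_o[j])
    g[j] <- tanh(sum(p$W_g[j, ] * a) + p$b_g[j])
  }
  cc <- f * c_prev + i * g
  list(h = o * tanh(cc), c = cc)
}
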