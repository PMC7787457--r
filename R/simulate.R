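# Synthetic longitudinal cohort generator.
#
# Real congenital-heart-disease claims records cannot be redistributed, so
# the package ships a simulator that reproduces the statistics downstream
# code depends on: patient-level marginal frequencies of the 11
# co-morbidities and the 4 lesion types, the recurrent HFH count
# distribution (~47% of HF patients with exactly one hospitalization, ~20%
# with two, ~10% with three, ~15% with five or more), temporal clustering of
# recurrent HFHs, coupling of event burden to the observable co-morbidity
# profile, and an optional planted link from acute co-morbidities at one
# step to HF at the next so that learnability tests have recoverable signal.
#
# Two HF generation modes:
#   * mixture mode (default): each patient draws a total HFH count from the
#     configured mixture (every simulated patient is HF-positive, as in the
#     study cohort); counts are coupled to the patient's static co-morbidity
#     burden; the first event is placed with planted-effect weighting and
#     recurrences follow after short geometric gaps (clustered recurrence).
#   * base-rate mode (hf_base_rate non-NULL): per-step logistic hazard
#     log-odds = qlogis(hf_base_rate) + log(planted_effect) * (acute CMs at
#     the previous step); used for marginal-frequency property checks.

#' Simulation configuration
#'
#' @param n_patients Number of patients.
#' @param n_steps Time steps per patient (6-month bins; 56 ~ 28 years of
#'   follow-up).
#' @param age_start Age in years at step 0 (modelling starts at 40).
#' @param cm_prevalence Named vector of 11 patient-level co-morbidity
#'   prevalences (names of [cm_columns()]).
#' @param lesion_probs Named vector of 4 lesion-type probabilities.
#' @param hfh_count_mixture Probabilities over total HFH counts
#'   \{1, 2, 3, 4, >=5\} for HF+ patients; renormalized if needed. The >=5
#'   tail is spread over 5..12 by a truncated geometric (p = 0.5).
#' @param hf_base_rate If non-`NULL`, switches to base-rate mode: a
#'   homogeneous per-step logistic HF hazard (0 gives an all-negative
#'   cohort) instead of the count-mixture recurrence process.
#' @param planted_effect Odds multiplier linking each acute co-morbidity at
#'   step i to HF at step i + 1; values <= 1 (including the conventional 0)
#'   disable the planted signal. In mixture mode a value > 1 both weights
#'   event placement toward steps following acute co-morbidity flags and
#'   activates acute precipitant flares (see `trigger_prob`).
#' @param recurrence_gap_p Geometric parameter of the gap between
#'   successive HFHs: a recurrence follows the previous event after
#'   `1 + Geom(recurrence_gap_p)` steps. The default 0.75 (mean gap ~1.3
#'   steps, ~8 months) encodes the tight temporal clustering of recurrent
#'   HF hospitalizations (about half of HF patients are readmitted within
#'   6 months).
#' @param age_doubling_years First-event placement odds double every this
#'   many years of age (HF incidence rises steeply with age; the study
#'   cohort's mean age at first HFH is over 60). `Inf` disables the tilt.
#'   Default 10.
#' @param onset_before_first Probability that a carried chronic
#'   co-morbidity's onset falls before the patient's first HFH rather than
#'   uniformly over follow-up; deterioration typically precedes the first
#'   admission. Default 0.8.
#' @param trigger_prob Probability that an HFH of a patient carrying at
#'   least one acute co-morbidity is preceded by an acute flare (the carried
#'   co-morbidity is set at the previous step). Encodes acute precipitants
#'   of HF admission (reported for the majority of admissions); active only
#'   when `planted_effect > 1`. Default 0.6.
#' @param burden_noise_sd Noise standard deviation of the comonotonic
#'   couplings between a patient's HFH count and (a) their static
#'   co-morbidity burden and (b) their acute co-morbidity carriership
#'   (smaller = tighter coupling; all marginal distributions are exactly
#'   preserved). Default 1.
#' @param cm_mode `"patient"`: draw carrier status per patient at the stated
#'   prevalence, carriers of acute co-morbidities then have per-step events;
#'   `"hazard"`: draw acute events independently per step at the hazard
#'   implied by the patient-level prevalence.
#' @param acute_rate Per-step acute event probability among carriers
#'   (patient mode).
#' @param surgery_rate Per-step probability of a new surgery; the surgery
#'   column is the running count.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 1000,
                       n_steps = 56,
                       age_start = 40,
                       cm_prevalence = default_cm_prevalence(),
                       lesion_probs = default_lesion_probs(),
                       hfh_count_mixture = c(0.4713, 0.20, 0.10, 0.08, 0.15),
                       hf_base_rate = NULL,
                       planted_effect = 1,
                       recurrence_gap_p = 0.75,
                       trigger_prob = 0.6,
                       age_doubling_years = 10,
                       onset_before_first = 0.8,
                       burden_noise_sd = 1,
                       cm_mode = c("patient", "hazard"),
                       acute_rate = 0.08,
                       surgery_rate = 0.01,
                       seed = 1L) {
  cm_mode <- match.arg(cm_mode)
  if (n_steps < 2) stop_hftraj("n_steps must be >= 2", "contract_error")
  if (n_patients < 1) stop_hftraj("n_patients must be >= 1", "contract_error")
  stopifnot(length(cm_prevalence) == 11, length(lesion_probs) == 4,
            length(hfh_count_mixture) == 5)
  if (any(cm_prevalence < 0 | cm_prevalence > 1) ||
      any(hfh_count_mixture < 0)) {
    stop_hftraj("probabilities must lie in [0, 1]", "contract_error")
  }
  if (!is.null(hf_base_rate) && (hf_base_rate < 0 || hf_base_rate >= 1)) {
    stop_hftraj("hf_base_rate must lie in [0, 1)", "contract_error")
  }
  if (recurrence_gap_p <= 0 || recurrence_gap_p > 1) {
    stop_hftraj("recurrence_gap_p must lie in (0, 1]", "contract_error")
  }
  if (trigger_prob < 0 || trigger_prob > 1) {
    stop_hftraj("trigger_prob must lie in [0, 1]", "contract_error")
  }
  if (onset_before_first < 0 || onset_before_first > 1) {
    stop_hftraj("onset_before_first must lie in [0, 1]", "contract_error")
  }
  if (age_doubling_years <= 0) {
    stop_hftraj("age_doubling_years must be positive", "contract_error")
  }
  if (is.null(names(cm_prevalence))) names(cm_prevalence) <- cm_columns()
  structure(list(
    n_patients = as.integer(n_patients),
    n_steps = as.integer(n_steps),
    age_start = age_start,
    cm_prevalence = cm_prevalence,
    lesion_probs = lesion_probs / sum(lesion_probs),
    hfh_count_mixture = hfh_count_mixture / sum(hfh_count_mixture),
    hf_base_rate = hf_base_rate,
    planted_effect = planted_effect,
    recurrence_gap_p = recurrence_gap_p,
    trigger_prob = trigger_prob,
    age_doubling_years = age_doubling_years,
    onset_before_first = onset_before_first,
    burden_noise_sd = burden_noise_sd,
    cm_mode = cm_mode,
    acute_rate = acute_rate,
    surgery_rate = surgery_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Co-morbidity and lesion marginals of the study cohort
#'
#' Patient-level prevalences among HF+ congenital heart disease patients
#' (acute myocardial infarction 29.7%, coronary artery disease 59.5%,
#' arrhythmia 45.4%, ventricular arrhythmias 10.8%, pulmonary hypertension
#' 30.3%, infective endocarditis 7.0%, diabetes 30.6%, stroke 24.2%, chronic
#' liver disease 6.1%, chronic kidney disease 30.4%, sepsis 10.8%) and the
#' lesion-type distribution of the same arm.
#'
#' @return Named numeric vector.
#' @export
default_cm_prevalence <- function() {
  stats::setNames(
    c(0.297, 0.595, 0.454, 0.108, 0.303, 0.070, 0.306, 0.242, 0.061,
      0.304, 0.108),
    cm_columns()
  )
}

#' @rdname default_cm_prevalence
#' @export
default_lesion_probs <- function() {
  c(lesion_severe = 0.106, lesion_shunt = 0.221, lesion_valve = 0.198,
    lesion_other = 0.475)
}

#' Simulation profile matching the study cohort's published marginals
#'
#' @param n_patients,n_steps,seed Overrides passed to [sim_config()].
#' @param ... Further overrides (e.g. `planted_effect`).
#' @return A `sim_config`.
#' @export
default_paper_profile <- function(n_patients = 1000, n_steps = 56,
                                  seed = 1L, ...) {
  sim_config(n_patients = n_patients, n_steps = n_steps, seed = seed, ...)
}

# draw total HFH counts from the mixture; >=5 tail is truncated-geometric
draw_hfh_counts <- function(n, mixture) {
  bucket <- sample.int(5, n, replace = TRUE, prob = mixture)
  k <- bucket
  tail_idx <- which(bucket == 5)
  if (length(tail_idx) > 0) {
    support <- 5:12
    w <- 0.5^(seq_along(support) - 1)
    k[tail_idx] <- sample(support, length(tail_idx), replace = TRUE,
                          prob = w / sum(w))
  }
  k
}

#' Simulate a synthetic cohort
#'
#' Static covariates are drawn once per patient (sex uniform, lesion type
#' categorical); chronic co-morbidities get a uniform random onset step and
#' stay 1 afterwards; acute co-morbidities recur per step among carriers;
#' surgery counts accumulate. HF hospitalizations follow the configured
#' mode: in mixture mode each patient's total count is drawn from the
#' recurrent-event mixture (all patients HF-positive), coupled to the static
#' co-morbidity burden, with the first event placed with planted-effect
#' weighting, recurrences after short geometric gaps, and (when the planted
#' signal is active) acute precipitant flares in the step before an event.
#' Deterministic given `config$seed`; empirical marginal frequencies
#' converge to the configured values as the cohort grows.
#'
#' @param config A [sim_config()].
#' @return A validated `hf_cohort` tibble.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  N <- config$n_patients
  T_len <- config$n_steps
  acute <- acute_cm_columns()
  chronic <- static_cm_columns()
  pe <- max(config$planted_effect, 1)

  sex_m <- stats::rbinom(N, 1, 0.5)
  lesion_idx <- sample.int(4, N, replace = TRUE, prob = config$lesion_probs)
  lesion <- matrix(0L, N, 4,
                   dimnames = list(NULL, names(default_lesion_probs())))
  lesion[cbind(seq_len(N), lesion_idx)] <- 1L

  # chronic CM carrier flags (onset times are drawn after the HF events so
  # that deterioration can precede the first hospitalization)
  chronic_carrier <- lapply(chronic, function(col) {
    stats::rbinom(N, 1, config$cm_prevalence[[col]])
  })
  names(chronic_carrier) <- chronic
  burden <- Reduce(`+`, chronic_carrier) + lesion[, "lesion_severe"]

  mixture_mode <- is.null(config$hf_base_rate)
  K <- NULL
  if (mixture_mode) {
    K <- draw_hfh_counts(N, config$hfh_count_mixture)
    # couple counts to the observable static burden, preserving the mixture
    noisy <- burden + stats::rnorm(N, 0, config$burden_noise_sd)
    K <- sort(K)[rank(noisy, ties.method = "first")]
  }

  # acute CMs: carriership coupled to event burden (patient mode), events
  # recur per step among carriers
  cm_arrays <- list()
  acute_carrier <- list()
  for (col in acute) {
    prev <- config$cm_prevalence[[col]]
    if (config$cm_mode == "patient") {
      n_c <- stats::rbinom(1, N, prev)
      carrier <- if (mixture_mode) {
        r <- rank(K + stats::rnorm(N, 0, config$burden_noise_sd),
                  ties.method = "random")
        as.integer(r > N - n_c)
      } else {
        as.integer(sample.int(N) <= n_c)
      }
      m <- matrix(stats::rbinom(N * T_len, 1, config$acute_rate), N, T_len) *
        carrier
      # carriers must show at least one event so patient-level prevalence
      # matches the configured marginal
      none <- which(carrier == 1 & rowSums(m) == 0)
      if (length(none) > 0) {
        at <- sample.int(T_len, length(none), replace = TRUE)
        m[cbind(none, at)] <- 1L
      }
    } else {
      hazard <- 1 - (1 - prev)^(1 / T_len)
      m <- matrix(stats::rbinom(N * T_len, 1, hazard), N, T_len)
      carrier <- as.integer(rowSums(m) > 0)
    }
    cm_arrays[[col]] <- m
    acute_carrier[[col]] <- carrier
  }

  surgery_events <- matrix(stats::rbinom(N * T_len, 1, config$surgery_rate),
                           N, T_len)
  surgery <- t(apply(surgery_events, 1, cumsum))

  if (!mixture_mode) {
    hf <- draw_hf_base_rate(config, cm_arrays, N, T_len, pe)
    first_event <- apply(hf == 1, 1, function(z) {
      w <- which(z)
      if (length(w)) w[1] else T_len
    })
  } else {
    res <- draw_hf_mixture(config, cm_arrays, acute_carrier, K, N, T_len, pe)
    cm_arrays <- res$cm_arrays
    hf <- res$hf
    first_event <- res$first_event
  }

  # chronic CM onsets: mostly before the first HFH, absorbing afterwards
  for (col in chronic) {
    before <- stats::runif(N) < config$onset_before_first
    onset <- ifelse(before & first_event > 1,
                    floor(stats::runif(N) * (first_event - 1)),
                    floor(stats::runif(N) * T_len))
    cm_arrays[[col]] <- outer(onset, 0:(T_len - 1), "<=") *
      chronic_carrier[[col]]
  }

  pid <- sprintf("P%05d", seq_len(N))
  sex_m_rep <- rep(sex_m, each = T_len)
  out <- tibble(
    patient_id = rep(pid, each = T_len),
    step = rep(0:(T_len - 1), times = N),
    age = config$age_start + 0.5 * rep(0:(T_len - 1), times = N),
    sex_m = sex_m_rep,
    sex_f = 1L - sex_m_rep
  )
  for (col in colnames(lesion)) out[[col]] <- rep(lesion[, col], each = T_len)
  for (col in cm_columns()) out[[col]] <- as.integer(t(cm_arrays[[col]]))
  out$surgery <- as.integer(t(surgery))
  out$hf <- as.integer(t(hf))
  as_cohort(out)
}

# homogeneous logistic hazard mode
draw_hf_base_rate <- function(config, cm_arrays, N, T_len, pe) {
  if (config$hf_base_rate == 0) return(matrix(0L, N, T_len))
  acute_any <- Reduce(`+`, cm_arrays[acute_cm_columns()])
  b <- stats::qlogis(config$hf_base_rate)
  hf <- matrix(0L, N, T_len)
  hf[, 1] <- as.integer(stats::runif(N) < config$hf_base_rate)
  for (t in 2:T_len) {
    lo <- b + log(pe) * acute_any[, t - 1]
    hf[, t] <- as.integer(stats::runif(N) < stats::plogis(lo))
  }
  hf
}

# recurrent-event mixture mode: the first event is placed with odds tilted
# by age and by preceding acute co-morbidity flags; recurrences follow after
# short geometric gaps; acute precipitant flares are stamped into the step
# before an event for carriers
draw_hf_mixture <- function(config, cm_arrays, acute_carrier, K, N, T_len, pe) {
  acute_any <- Reduce(`+`, cm_arrays[acute_cm_columns()])
  prev_acute <- config$cm_prevalence[acute_cm_columns()]
  planted <- pe > 1
  # placement odds double every age_doubling_years (2 steps per year)
  age_w <- 2^(seq_len(T_len) / (2 * config$age_doubling_years))

  hf <- matrix(0L, N, T_len)
  first_event <- integer(N)
  for (i in seq_len(N)) {
    w <- age_w
    if (planted) w <- w * c(1, pe^acute_any[i, seq_len(T_len - 1)])
    ev <- sample.int(T_len, 1, prob = w)
    while (length(ev) < K[i]) {
      nxt <- ev[length(ev)] + 1L + stats::rgeom(1, config$recurrence_gap_p)
      if (nxt > T_len) break
      ev <- c(ev, nxt)
    }
    hf[i, ev] <- 1L
    first_event[i] <- ev[1]
    if (planted && config$trigger_prob > 0) {
      carried <- names(which(vapply(acute_cm_columns(), function(cc) {
        acute_carrier[[cc]][i] == 1L
      }, logical(1))))
      names(carried) <- NULL
      if (length(carried) > 0) {
        pre <- ev[ev > 1] - 1L
        fl <- pre[stats::runif(length(pre)) < config$trigger_prob]
        if (length(fl) > 0) {
          which_cm <- sample(carried, length(fl), replace = TRUE,
                             prob = prev_acute[carried])
          for (j in seq_along(fl)) {
            cm_arrays[[which_cm[j]]][i, fl[j]] <- 1L
          }
        }
      }
    }
  }
  list(hf = hf, cm_arrays = cm_arrays, first_event = first_event)
}
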