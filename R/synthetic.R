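#' Virtual cohort specification
#'
#' Ranges for the demographic covariates of a simulated elderly surgical
#' cohort. Defaults target the population the model is meant for:
#' ages 65-85 years, weights 50-85 kg, heights 150-180 cm, balanced sex.
#'
#' @param n cohort size.
#' @param age_range,weight_range,height_range length-2 numeric ranges
#'   (years, kg, cm); sampled uniformly.
#' @param sex_ratio probability that a patient is male.
#' @param noise_sd BIS observation noise standard deviation (BIS units).
#' @param seed integer seed for reproducible cohorts.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n, age_range = c(65, 85), weight_range = c(50, 85),
                        height_range = c(150, 180), sex_ratio = 0.5,
                        noise_sd = 3, seed = NULL) {
  stopifnot(n >= 1, length(age_range) == 2L, length(weight_range) == 2L,
            length(height_range) == 2L, sex_ratio >= 0, sex_ratio <= 1,
            noise_sd >= 0)
  structure(list(n = as.integer(n), age_range = age_range,
                 weight_range = weight_range, height_range = height_range,
                 sex_ratio = sex_ratio, noise_sd = noise_sd, seed = seed),
            class = "cohort_spec")
}

# guard: the covariate ranges must keep every PK parameter positive
check_envelope <- function(spec) {
  for (sex in c("male", "female"))
    for (a in spec$age_range)
      for (w in spec$weight_range)
        for (h in spec$height_range) {
          p <- patient("corner", a, w, h, sex)
          tryCatch(pk_params(p), error = function(e)
            stop("cohort spec outside the PK model's valid envelope: ",
                 conditionMessage(e), call. = FALSE))
        }
  invisible(TRUE)
}

#' Generate a cohort of virtual patients with known ground truth
#'
#' Each virtual patient consists of sampled demographic covariates, true
#' Hill PD parameters drawn from sub-boxes of the default identification
#' bounds (E0 in \[85, 95\], Emax in \[60, 85\], EC50 in \[1.5, 4\] ug/mL,
#' gamma in \[1.5, 3.5\]), and a dosing protocol emulating clinical
#' practice: an induction bolus of 1.0-1.5 mg/kg followed by a
#' maintenance infusion titrated (through the patient's own PK/PD model,
#' as a clinician titrates to effect) towards a target BIS drawn
#' uniformly in \[40, 55\], with a 15% higher rate over the first half of
#' maintenance. This yields traces that traverse the full dynamic range
#' from awake to surgical anesthesia, so all four Hill parameters are
#' identifiable.
#'
#' @param spec a [cohort_spec()].
#' @return A list of `"true_patient_model"` objects, each with fields
#'   `patient`, `pd_true`, `protocol`, `noise_sd`, `bis_target`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(3, seed = 1))
#' cohort[[1]]$pd_true
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_envelope(spec)
  with_seed(spec$seed, function() {
    lapply(seq_len(spec$n), function(i) {
      pat <- patient(sprintf("p%02d", i),
                     age = stats::runif(1, spec$age_range[1], spec$age_range[2]),
                     weight = stats::runif(1, spec$weight_range[1],
                                           spec$weight_range[2]),
                     height = stats::runif(1, spec$height_range[1],
                                           spec$height_range[2]),
                     sex = if (stats::runif(1) < spec$sex_ratio)
                       "male" else "female")
      pd_true <- pd_params(e0 = stats::runif(1, 85, 95),
                           emax = stats::runif(1, 60, 85),
                           ec50 = stats::runif(1, 1.5, 4),
                           gamma = stats::runif(1, 1.5, 3.5))
      pk <- pk_params(pat)
      bolus <- stats::runif(1, 1.0, 1.5) * pat$weight
      bis_target <- stats::runif(1, 40, 55)
      effect <- (pd_true$e0 - bis_target) / pd_true$emax
      ce_target <- pd_true$ec50 * (effect / (1 - effect))^(1 / pd_true$gamma)
      rate <- ce_target * pk$Cl1
      protocol <- infusion_protocol(
        boluses = data.frame(time = 0, dose = bolus),
        segments = data.frame(t_start = c(0.5, 30), t_end = c(30, 60),
                              rate = c(1.15 * rate, rate)))
      structure(list(patient = pat, pd_true = pd_true, protocol = protocol,
                     noise_sd = spec$noise_sd, bis_target = bis_target),
                class = "true_patient_model")
    })
  })
}

#' @export
print.true_patient_model <- function(x, ...) {
  cat("Virtual patient with known ground truth\n")
  print(x$patient)
  print(x$pd_true)
  cat(sprintf("  BIS target %.1f, observation noise sd %.1f\n",
              x$bis_target, x$noise_sd))
  invisible(x)
}

#' Observe a noisy BIS trace from a virtual patient
#'
#' Simulates the noiseless BIS trace through the patient's PK/PD model
#' and adds i.i.d. Gaussian observation noise (sd from the model, default
#' 3 BIS units), clipping to the monitor's \[0, 100\] scale.
#'
#' @param model a `"true_patient_model"` from [generate_cohort()].
#' @param times time grid in minutes (default 0-60 min at 0.1 min,
#'   i.e. 6 s, spacing).
#' @param seed optional seed for the noise draw.
#' @param ke0 effect-site equilibration constant (1/min).
#' @return A `"bis_trace"` data.frame with columns `time`, `bis`; the
#'   noiseless trace and concentrations are attached as attributes
#'   `"noiseless"` and `"conc"`.
#' @export
observe_bis <- function(model, times = seq(0, 60, by = 0.1), seed = NULL,
                        ke0 = 0.456) {
  stopifnot(inherits(model, "true_patient_model"))
  clean <- simulate_bis(model$patient, model$protocol, model$pd_true,
                        times, ke0 = ke0)
  noisy <- with_seed(seed, function()
    clean$bis + stats::rnorm(length(times), sd = model$noise_sd))
  res <- data.frame(time = times, bis = pmin(pmax(noisy, 0), 100))
  attr(res, "noiseless") <- clean$bis
  attr(res, "conc") <- attr(clean, "conc")
  class(res) <- c("bis_trace", "data.frame")
  res
}

#' Generate an EEG-derived feature matrix coupled to effect-site
#' concentration
#'
#' Emulates the statistical situation of regressing BIS from processed
#' EEG features: informative columns are smooth monotone transforms of
#' the effect-site concentration Ce(t) — identity, `log(1 + Ce)` and the
#' saturating `Ce^2/(EC50^2 + Ce^2)` — each perturbed with Gaussian noise
#' proportional to its scale, plus pure-noise distractor columns carrying
#' no signal. The aligned target is the (noisy) observed BIS.
#'
#' @param model a `"true_patient_model"`.
#' @param times time grid (min).
#' @param seed seed controlling both feature and observation noise.
#' @param n_informative number of Ce-derived columns (0-3).
#' @param n_distractors number of pure-noise columns.
#' @param feature_noise_sd noise on each informative column, as a
#'   fraction of that column's standard deviation.
#' @param ke0 effect-site equilibration constant (1/min).
#' @return A list of class `"feature_set"`: `features` (numeric matrix,
#'   one row per grid point), `target` (observed BIS), `target_clean`
#'   (noiseless BIS), `time`.
#' @export
generate_eeg_features <- function(model, times = seq(0, 60, by = 0.1),
                                  seed = NULL, n_informative = 3,
                                  n_distractors = 3,
                                  feature_noise_sd = 0.05, ke0 = 0.456) {
  stopifnot(n_informative >= 0, n_informative <= 3, n_distractors >= 0,
            n_informative + n_distractors >= 1)
  obs <- observe_bis(model, times, seed = if (is.null(seed)) NULL
                     else seed + 1L, ke0 = ke0)
  ce <- attr(obs, "conc")$Ce
  ec50 <- model$pd_true$ec50
  base <- cbind(ce_linear = ce,
                ce_log = log1p(ce),
                ce_sigmoid = ce^2 / (ec50^2 + ce^2))[, seq_len(n_informative),
                                                     drop = FALSE]
  with_seed(seed, function() {
    n <- length(times)
    if (n_informative > 0)
      for (j in seq_len(ncol(base)))
        base[, j] <- base[, j] +
          stats::rnorm(n, sd = feature_noise_sd * stats::sd(base[, j]))
    distract <- if (n_distractors > 0) {
      d <- matrix(stats::rnorm(n * n_distractors), n, n_distractors)
      colnames(d) <- sprintf("noise%d", seq_len(n_distractors))
      d
    } else NULL
    features <- cbind(base, distract)
    structure(list(features = features, target = obs$bis,
                   target_clean = attr(obs, "noiseless"), time = times),
              class = "feature_set")
  })
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set: %d epochs x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(colnames(x$features), collapse = ", ")))
  invisible(x)
}
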