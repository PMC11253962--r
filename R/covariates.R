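#' Patient covariate record
#'
#' Bundles the demographic covariates that drive the compartmental
#' pharmacokinetic parameters: age, total body weight, height and sex.
#' Lean body mass is derived on demand by [lean_body_mass()].
#'
#' @param id character identifier.
#' @param age age in years (> 0).
#' @param weight total body weight in kg (> 0).
#' @param height height in cm (> 0).
#' @param sex `"male"` or `"female"`.
#'
#' @return An object of class `"patient"`: a list with fields `id`, `age`,
#'   `weight`, `height`, `sex`.
#' @examples
#' patient("p01", age = 73, weight = 62, height = 165, sex = "female")
#' @export
patient <- function(id, age, weight, height, sex) {
  stopifnot(is.character(id), length(id) == 1L)
  for (nm in c("age", "weight", "height")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  sex <- match_sex(sex)
  structure(list(id = id, age = as.numeric(age), weight = as.numeric(weight),
                 height = as.numeric(height), sex = sex),
            class = "patient")
}

match_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L || !sex %in% c("male", "female"))
    stop("'sex' must be \"male\" or \"female\", got: ",
         deparse(substitute(sex)), " = ", paste(sex, collapse = ","),
         call. = FALSE)
  sex
}

#' @export
print.patient <- function(x, ...) {
  cat(sprintf("Patient %s: %s, %.0f y, %.1f kg, %.1f cm (lbm %.1f kg)\n",
              x$id, x$sex, x$age, x$weight, x$height,
              lean_body_mass(x$weight, x$height, x$sex)))
  invisible(x)
}

#' Lean body mass from weight, height and sex
#'
#' James-type sex-specific lean body mass used as a pharmacokinetic
#' covariate:
#' \deqn{lbm_{female} = 1.07\,w - 148\,w^2/h^2, \qquad
#'       lbm_{male} = 1.1\,w - 128\,w^2/h^2}
#' with weight \eqn{w} in kg and height \eqn{h} in cm.
#'
#' @param weight total body weight in kg (> 0).
#' @param height height in cm (> 0).
#' @param sex `"male"` or `"female"`.
#'
#' @return Lean body mass in kg. Errors if the quadratic term drives the
#'   result non-positive (degenerate covariates far outside the formula's
#'   applicable range).
#' @examples
#' lean_body_mass(60, 160, "female") # 43.3875
#' @export
lean_body_mass <- function(weight, height, sex) {
  stopifnot(is.numeric(weight), length(weight) == 1L, is.finite(weight),
            is.numeric(height), length(height) == 1L, is.finite(height))
  if (weight <= 0) stop("'weight' must be positive", call. = FALSE)
  if (height <= 0) stop("'height' must be positive", call. = FALSE)
  sex <- match_sex(sex)
  lbm <- if (sex == "female") {
    1.07 * weight - 148 * weight^2 / height^2
  } else {
    1.1 * weight - 128 * weight^2 / height^2
  }
  if (lbm <= 0)
    stop("degenerate covariates: lean body mass is non-positive (",
         format(lbm), " kg) for weight = ", weight, " kg, height = ",
         height, " cm", call. = FALSE)
  lbm
}

#' Three-compartment PK parameters from patient covariates
#'
#' Computes compartment volumes, clearances and micro rate constants for
#' the covariate-parameterized three-compartment (central, rapid and slow
#' peripheral) disposition model:
#' \deqn{V_1 = 4.27,\quad V_2 = 18.9 - 0.391\,(age - 53),\quad V_3 = 238}
#' \deqn{Cl_1 = 1.89 + 0.0456\,(w - 77) - 0.0681\,(lbm - 59)
#'             + 0.0264\,(h - 177)}
#' \deqn{Cl_2 = 1.29 - 0.024\,(age - 53), \quad Cl_3 = 0.836}
#' \deqn{k_{10} = Cl_1/V_1,\; k_{12} = Cl_2/V_1,\; k_{13} = Cl_3/V_1,\;
#'       k_{21} = Cl_2/V_2,\; k_{31} = Cl_3/V_3}
#'
#' Units: volumes in L, clearances in L/min, rate constants in 1/min.
#' At the reference covariates (age 53, weight 77 kg, height 177 cm,
#' lbm 59 kg) every correction term vanishes and the intercepts are
#' returned exactly.
#'
#' @param patient a [patient()] object (or a list with fields `age`,
#'   `weight`, `height`, `sex`).
#' @param lbm optional lean body mass override in kg; by default computed
#'   from the patient's weight, height and sex via [lean_body_mass()].
#'
#' @return An object of class `"pk_params"`: a named list with elements
#'   `V1, V2, V3` (L), `Cl1, Cl2, Cl3` (L/min) and
#'   `k10, k12, k13, k21, k31` (1/min).
#' @examples
#' p <- patient("ref", age = 53, weight = 77, height = 177, sex = "male")
#' pk_params(p, lbm = 59)
#' @export
pk_params <- function(patient, lbm = NULL) {
  stopifnot(is.list(patient),
            all(c("age", "weight", "height", "sex") %in% names(patient)))
  if (is.null(lbm))
    lbm <- lean_body_mass(patient$weight, patient$height, patient$sex)
  age <- patient$age
  V1 <- 4.27
  V2 <- 18.9 - 0.391 * (age - 53)
  V3 <- 238
  Cl1 <- 1.89 + 0.0456 * (patient$weight - 77) - 0.0681 * (lbm - 59) +
    0.0264 * (patient$height - 177)
  Cl2 <- 1.29 - 0.024 * (age - 53)
  Cl3 <- 0.836
  vals <- c(V1 = V1, V2 = V2, V3 = V3, Cl1 = Cl1, Cl2 = Cl2, Cl3 = Cl3)
  bad <- names(vals)[vals <= 0]
  if (length(bad))
    stop("covariates outside the model's valid range: ",
         paste(sprintf("%s = %.4g", bad, vals[bad]), collapse = ", "),
         " (must be > 0)", call. = FALSE)
  structure(list(
    V1 = V1, V2 = V2, V3 = V3, Cl1 = Cl1, Cl2 = Cl2, Cl3 = Cl3,
    k10 = Cl1 / V1, k12 = Cl2 / V1, k13 = Cl3 / V1,
    k21 = Cl2 / V2, k31 = Cl3 / V3
  ), class = "pk_params")
}

#' @export
print.pk_params <- function(x, digits = 4, ...) {
  cat("Three-compartment PK parameters\n")
  cat("  Volumes (L):      ",
      paste(sprintf("V%d = %.*g", 1:3, digits,
                    unlist(x[c("V1", "V2", "V3")])), collapse = ", "), "\n")
  cat("  Clearances (L/min):",
      paste(sprintf("Cl%d = %.*g", 1:3, digits,
                    unlist(x[c("Cl1", "Cl2", "Cl3")])), collapse = ", "), "\n")
  k <- unlist(x[c("k10", "k12", "k13", "k21", "k31")])
  cat("  Rate constants (1/min):",
      paste(sprintf("%s = %.*g", names(k), digits, k), collapse = ", "), "\n")
  invisible(x)
}

#' Read a patient cohort from CSV
#'
#' Expects a header row with columns `id,age,weight,height,sex`
#' (sex coded `male`/`female`; age in years, weight in kg, height in cm).
#'
#' @param path path to the CSV file.
#' @return A list of [patient()] objects.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "weight", "height", "sex")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    patient(as.character(df$id[i]), df$age[i], df$weight[i],
            df$height[i], df$sex[i]))
}

#' Write a patient cohort to CSV
#'
#' @param cohort list of [patient()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- do.call(rbind, lapply(cohort, function(p)
    data.frame(id = p$id, age = p$age, weight = p$weight,
               height = p$height, sex = p$sex)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize PK or PD parameters to JSON
#'
#' @param params a `"pk_params"` or `"pd_params"` object (any named list of
#'   scalars).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(lapply(unclass(params), unname), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
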