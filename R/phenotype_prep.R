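#' Prepare analysis blood-pressure values
#'
#' Averages the available (one or two) measurements per trait and, for
#' subjects on antihypertensive medication, optionally imputes the
#' treatment effect by adding 10 mm Hg to SBP and 5 mm Hg to DBP.
#' Turning imputation off gives the measured-BP sensitivity-analysis mode.
#'
#' @param sbp_measurements numeric vector or list of numeric vectors
#'   (one element per subject, each of length 1 or 2), systolic mm Hg.
#' @param dbp_measurements same shape, diastolic mm Hg.
#' @param on_antihypertensive logical vector, medication flag per subject.
#' @param use_imputed logical scalar; add 10/5 mm Hg for medicated subjects.
#' @return data.frame with columns \code{sbp} and \code{dbp} (mm Hg);
#'   subjects with no finite measurement for a trait get \code{NA}.
#' @export
prepare_bp <- function(sbp_measurements, dbp_measurements, on_antihypertensive,
                       use_imputed = TRUE) {
  avg <- function(m) {
    if (!is.list(m)) m <- as.list(m)
    vapply(m, function(x) {
      x <- x[is.finite(x)]
      if (length(x) == 0L) NA_real_ else mean(x)
    }, numeric(1))
  }
  sbp <- avg(sbp_measurements)
  dbp <- avg(dbp_measurements)
  if (length(on_antihypertensive) == 1L)
    on_antihypertensive <- rep(on_antihypertensive, length(sbp))
  stopifnot(length(on_antihypertensive) == length(sbp),
            length(dbp) == length(sbp))
  if (isTRUE(use_imputed)) {
    med <- on_antihypertensive %in% TRUE
    sbp[med] <- sbp[med] + 10
    dbp[med] <- dbp[med] + 5
  }
  data.frame(sbp = sbp, dbp = dbp)
}

#' Classify hypertension status
#'
#' Hypertension is SBP >= 140 mm Hg, DBP >= 90 mm Hg, or current
#' antihypertensive medication.
#'
#' @param sbp,dbp mm Hg (vectors).
#' @param on_antihypertensive logical vector.
#' @return logical vector.
#' @export
classify_hypertension <- function(sbp, dbp, on_antihypertensive) {
  (sbp >= 140) | (dbp >= 90) | (on_antihypertensive %in% TRUE)
}

#' Spot-urine sodium estimator coefficients
#'
#' Coefficient set for the spot-urine estimator of 24-h urinary sodium
#' excretion,
#' \deqn{\hat{Na}_{24h} = scale \cdot (Na_{spot} / (Cr_{spot} \cdot
#'   cr\_unit\_factor) \cdot \hat{Cr}_{24h})^{exponent}}
#' with predicted 24-h creatinine excretion (mg/day) a linear function of
#' age (years), weight (kg) and height (cm). All coefficients are
#' configuration values; \code{tanaka_coefficients()} returns the published
#' defaults of the Tanaka estimator (spot Na in mEq/L, spot Cr in mg/dL,
#' \code{cr_unit_factor = 10} converting mg/dL to mg/L; output mEq/day).
#'
#' @param scale,exponent positive dimensionless coefficients of the power law.
#' @param pr_cr_intercept,pr_cr_age,pr_cr_weight,pr_cr_height coefficients of
#'   the predicted 24-h creatinine excretion (mg/day).
#' @param cr_unit_factor divisor applied to spot creatinine before forming the
#'   Na/Cr ratio (unit harmonisation; 1 = analytes already unit-consistent).
#' @return object of class \code{sodium_formula}.
#' @export
sodium_formula <- function(scale, exponent, pr_cr_intercept, pr_cr_age,
                           pr_cr_weight, pr_cr_height, cr_unit_factor = 1) {
  stopifnot(is.finite(scale), scale > 0, is.finite(exponent), exponent > 0,
            is.finite(cr_unit_factor), cr_unit_factor > 0)
  structure(list(scale = scale, exponent = exponent,
                 pr_cr_intercept = pr_cr_intercept, pr_cr_age = pr_cr_age,
                 pr_cr_weight = pr_cr_weight, pr_cr_height = pr_cr_height,
                 cr_unit_factor = cr_unit_factor),
            class = "sodium_formula")
}

#' @rdname sodium_formula
#' @export
tanaka_coefficients <- function() {
  sodium_formula(scale = 21.98, exponent = 0.392,
                 pr_cr_intercept = -2244.45, pr_cr_age = -2.04,
                 pr_cr_weight = 14.89, pr_cr_height = 16.14,
                 cr_unit_factor = 10)
}

predicted_creatinine <- function(coeffs, age, weight, height) {
  coeffs$pr_cr_intercept + coeffs$pr_cr_age * age +
    coeffs$pr_cr_weight * weight + coeffs$pr_cr_height * height
}

#' Estimate daily sodium excretion from a spot urine sample
#'
#' @param spot_na spot urinary sodium (mEq/L under the default coefficients).
#' @param spot_cr spot urinary creatinine (mg/dL under the defaults); must be
#'   positive.
#' @param age years; \code{height} cm; \code{weight} kg.
#' @param coeffs a [sodium_formula] object; defaults to
#'   [tanaka_coefficients()].
#' @return estimated daily sodium excretion, mEq/day.
#' @export
estimate_daily_sodium <- function(spot_na, spot_cr, age, height, weight,
                                  coeffs = tanaka_coefficients()) {
  stopifnot(inherits(coeffs, "sodium_formula"))
  if (any(!is.finite(spot_cr) | spot_cr <= 0))
    stop("spot_cr must be positive for all subjects")
  pr_cr <- predicted_creatinine(coeffs, age, weight, height)
  bad <- which(!is.finite(pr_cr) | pr_cr <= 0)
  if (length(bad))
    stop("non-positive predicted 24-h creatinine for subject(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  coeffs$scale *
    (spot_na / (spot_cr * coeffs$cr_unit_factor) * pr_cr) ^ coeffs$exponent
}

#' Convert sodium amounts between units
#'
#' 1 mEq = 1 mmol of sodium; mass units use a sodium molar mass of
#' 23.0 mg/mmol, which together with half-up rounding reproduces the usual
#' clinical mg/day figures (e.g. 164.8 mEq/day -> 3,790 mg/day;
#' 2 g/day -> 87 mmol/day). Conversion itself is exact; rounding is left to
#' the presentation layer (see \code{round_half_up}).
#'
#' @param value numeric vector.
#' @param from_unit,to_unit one of \code{"mEq/day"}, \code{"mmol/day"},
#'   \code{"mg/day"}, \code{"g/day"}.
#' @param molar_mass sodium molar mass in mg/mmol.
#' @return converted values.
#' @export
convert_sodium_units <- function(value, from_unit, to_unit,
                                 molar_mass = 23.0) {
  units <- c("mEq/day" = 1, "mmol/day" = 1,
             "mg/day" = NA, "g/day" = NA)
  chk <- function(u) {
    if (!u %in% names(units)) stop("unknown sodium unit: ", u)
    u
  }
  from_unit <- chk(from_unit); to_unit <- chk(to_unit)
  # canonical scale: mmol/day
  to_mmol <- switch(from_unit,
    "mEq/day" = value, "mmol/day" = value,
    "mg/day" = value / molar_mass, "g/day" = value * 1000 / molar_mass)
  switch(to_unit,
    "mEq/day" = to_mmol, "mmol/day" = to_mmol,
    "mg/day" = to_mmol * molar_mass, "g/day" = to_mmol * molar_mass / 1000)
}

#' Half-up rounding for presentation
#'
#' @param x numeric; @param digits decimal places.
#' @return rounded values (ties away from zero has no role here; sodium
#'   amounts are positive so half-up and half-away coincide).
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Exclude subjects with missing core variables
#'
#' Removes subjects missing BMI, SBP, DBP or daily sodium; a subject missing
#' several variables is excluded once but counted under every reason.
#'
#' @param cohort data.frame with (at least) columns \code{bmi}, \code{sbp},
#'   \code{dbp}, \code{daily_sodium}.
#' @return list with \code{cohort} (complete rows) and \code{exclusion_log}
#'   (named integer vector of per-reason counts plus \code{n_excluded}).
#' @export
exclude_incomplete <- function(cohort) {
  req <- c("bmi", "sbp", "dbp", "daily_sodium")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  miss <- vapply(req, function(v) !is.finite(cohort[[v]]),
                 logical(nrow(cohort)))
  miss <- matrix(miss, nrow = nrow(cohort),
                 dimnames = list(NULL, req))
  drop <- rowSums(miss) > 0
  log <- c(colSums(miss), n_excluded = sum(drop))
  list(cohort = cohort[!drop, , drop = FALSE],
       exclusion_log = as.integer(log) |> stats::setNames(names(log)))
}
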