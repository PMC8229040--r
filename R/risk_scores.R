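#' @name risk-scores
#' @title Outcome standardisation and the clustered cardiometabolic risk score
#'
#' @description
#' Outcomes are analysed on the z-score scale so that associations are
#' comparable across markers with different units. The clustered
#' cardiometabolic risk score (CCRS) averages the standardised values of
#' HbA1c, triglycerides, mean blood pressure, inverted HDL cholesterol
#' and, optionally, waist circumference; higher scores indicate higher
#' cardiometabolic risk.
NULL

#' Standardise a numeric vector to mean 0, SD 1
#'
#' Uses the n-1 sample SD. Missing values propagate and are excluded from
#' the mean/SD computation.
#'
#' @param values numeric vector with at least two distinct non-missing
#'   values.
#' @param name optional label used in error messages.
#' @return z-score vector of the same length.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(values, name = deparse(substitute(values))) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    stop("cannot standardise '", name, "': fewer than two observed values",
         call. = FALSE)
  }
  s <- stats::sd(values[ok])
  if (s == 0) {
    stop("cannot standardise '", name, "': all observed values identical",
         call. = FALSE)
  }
  (values - mean(values[ok])) / s
}

#' Body mass index
#'
#' @param mass_kg body mass, kg.
#' @param height_m height, m (> 0.5).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(93, 1.75)
#' @export
compute_bmi <- function(mass_kg, height_m) {
  if (any(height_m <= 0.5, na.rm = TRUE)) {
    stop("height must exceed 0.5 m (check units)", call. = FALSE)
  }
  mass_kg / height_m^2
}

#' Mean of systolic and diastolic blood pressure
#'
#' @param sbp,dbp systolic and diastolic pressure, mmHg.
#' @return `(sbp + dbp) / 2`, mmHg.
#' @export
mean_bp <- function(sbp, dbp) {
  if (any(c(sbp, dbp) <= 0, na.rm = TRUE)) {
    stop("blood pressures must be positive", call. = FALSE)
  }
  (sbp + dbp) / 2
}

.ccrs_components <- function(panel) {
  need <- c("hba1c", "triglycerides", "hdl", "waist", "sbp_mmhg", "dbp_mmhg")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("outcome panel is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    z_hba1c = standardize(panel$hba1c, "hba1c"),
    z_trig = standardize(panel$triglycerides, "triglycerides"),
    z_meanbp = standardize(mean_bp(panel$sbp_mmhg, panel$dbp_mmhg), "mean_bp"),
    z_hdl_inverted = -standardize(panel$hdl, "hdl"),
    z_waist = standardize(panel$waist, "waist"))
}

#' Clustered cardiometabolic risk score
#'
#' Row-wise mean of the standardised components: HbA1c, triglycerides,
#' mean blood pressure, inverted HDL, and (if `include_waist`) waist
#' circumference. Standardisation uses the rows supplied, i.e. the
#' analysis sample after exclusions.
#'
#' @param panel data frame with columns `hba1c`, `triglycerides`, `hdl`,
#'   `waist`, `sbp_mmhg`, `dbp_mmhg` (at least two rows).
#' @param include_waist include the adiposity component (default `TRUE`);
#'   the no-waist score isolates associations from adiposity.
#' @param complete_cases if `TRUE`, rows missing any component get `NA`;
#'   default averages the available components per row.
#' @return Numeric score vector; higher means higher risk. Rows with all
#'   components missing are `NA`.
#' @export
compute_ccrs <- function(panel, include_waist = TRUE, complete_cases = FALSE) {
  if (nrow(panel) < 2L) stop("need at least two rows", call. = FALSE)
  z <- .ccrs_components(panel)
  if (!include_waist) z$z_waist <- NULL
  score <- rowMeans(z, na.rm = !complete_cases)
  score[rowSums(!is.na(z)) == 0L] <- NA_real_
  score
}

#' Attach z-scores and risk scores to a cohort table
#'
#' Adds `z_hba1c`, `z_trig`, `z_meanbp`, `z_hdl_inverted`, `z_waist`,
#' `ccrs` (with waist) and `ccrs_noadiposity` columns.
#'
#' @param cohort participant table containing the CCRS component columns.
#' @inheritParams compute_ccrs
#' @return The cohort with score columns appended.
#' @export
add_risk_scores <- function(cohort, complete_cases = FALSE) {
  z <- .ccrs_components(cohort)
  cohort[names(z)] <- z
  cohort$ccrs <- compute_ccrs(cohort, TRUE, complete_cases)
  cohort$ccrs_noadiposity <- compute_ccrs(cohort, FALSE, complete_cases)
  cohort
}
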