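#' @name substitution-models
#' @title ISM and CISM regression fits and reallocation estimates
#'
#' @description
#' Both models regress a standardised outcome on behaviour information
#' plus covariates (age, sex, ethnicity, deprivation score, blood-pressure
#' and lipid-lowering medication) and express effects per hour of
#' behaviour. ISM enters standing hours, stepping hours and total waking
#' wear hours, omitting sitting, so each behaviour coefficient is the
#' estimated effect of substituting an hour of sitting with that
#' behaviour. CISM enters the ILR coordinates of the (sit, stand, step)
#' composition; a reallocation effect is the fitted-outcome difference
#' between a perturbed and a base composition, with a delta-method CI.
NULL

#' Default covariate set
#' @return Character vector of covariate column names.
#' @export
default_covariates <- function() {
  c("age", "male", "ethnicity", "imd", "bp_med", "lipid_med")
}

#' Convert behaviour minutes to hours
#'
#' @param comp numeric vector or matrix of minutes.
#' @return The same structure divided by 60 (the models' behaviour unit).
#' @export
behaviours_to_hours <- function(comp) comp / 60

# Assemble the analysis frame shared by both fits: complete cases on the
# outcome, behaviours and covariates; outcome standardised on that sample;
# ethnicity reference-coded with White European first when present.
.analysis_frame <- function(cohort, outcome, covariates, extra = character()) {
  need <- c(outcome, .behaviour_parts_cols(cohort), covariates, extra)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(cohort[need])
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < length(covariates) + 5L) {
    stop("too few complete rows to fit '", outcome, "'", call. = FALSE)
  }
  if ("ethnicity" %in% names(df)) {
    df$ethnicity <- factor(df$ethnicity)
    if ("White European" %in% levels(df$ethnicity)) {
      df$ethnicity <- stats::relevel(df$ethnicity, "White European")
    }
  }
  df$.z_outcome <- standardize(df[[outcome]], outcome)
  df
}

.behaviour_parts_cols <- function(cohort) {
  cols <- paste0(.behaviour_parts, "_min")
  if (all(cols %in% names(cohort))) cols else .behaviour_parts
}

.parts_matrix <- function(df) {
  m <- as.matrix(df[.behaviour_parts_cols(df)])
  colnames(m) <- .behaviour_parts
  m
}

.check_full_rank <- function(fit) {
  bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(bad)) {
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Fit an isotemporal substitution model
#'
#' Ordinary least squares of the standardised outcome on standing hours,
#' stepping hours and total waking wear hours plus covariates. Sitting is
#' the omitted behaviour, so `stand_h` and `step_h` coefficients estimate
#' the effect of substituting one hour of sitting with standing or
#' stepping while waking time is held fixed.
#'
#' @param cohort participant table with behaviour minutes (`sit_min`,
#'   `stand_min`, `step_min`, and `wear_min` or `total_min`), the outcome
#'   column, and the covariates.
#' @param outcome outcome column name; standardised internally on the
#'   analysis sample (complete cases).
#' @param covariates covariate column names (default [default_covariates()]).
#' @return An object of class `c("ism_fit", "substitution_fit")` with
#'   elements `method`, `outcome`, `coefficients`, `covariance`, `n`,
#'   `parts` (analysis-sample behaviour minutes) and the underlying `lm`.
#' @export
fit_ism <- function(cohort, outcome, covariates = default_covariates()) {
  wear_col <- intersect(c("wear_min", "total_min"), names(cohort))[1]
  df <- .analysis_frame(cohort, outcome, covariates,
                        extra = wear_col[!is.na(wear_col)])
  parts <- .parts_matrix(df)
  wear_min <- if (!is.na(wear_col)) df[[wear_col]] else rowSums(parts)
  df$stand_h <- behaviours_to_hours(parts[, "stand"])
  df$step_h <- behaviours_to_hours(parts[, "step"])
  df$wear_h <- behaviours_to_hours(wear_min)
  fml <- stats::reformulate(c("stand_h", "step_h", "wear_h", covariates),
                            response = ".z_outcome")
  fit <- stats::lm(fml, data = df)
  .check_full_rank(fit)
  structure(list(method = "ISM", outcome = outcome,
                 coefficients = stats::coef(fit),
                 covariance = stats::vcov(fit),
                 n = nrow(df), parts = parts,
                 behaviour_unit = "hour", lm = fit),
            class = c("ism_fit", "substitution_fit"))
}

#' Fit a compositional isotemporal substitution model
#'
#' Ordinary least squares of the standardised outcome on the ILR
#' coordinates of the behaviour composition plus covariates. The
#' coordinate coefficient vector (gamma) and its covariance block drive
#' reallocation predictions; fitted values and reallocation estimates are
#' invariant to the choice of SBP basis.
#'
#' @inheritParams fit_ism
#' @param basis [ilr_basis][build_ilr_basis] (default [default_ilr_basis()]).
#' @param zero_policy `"error"` (default) refuses zero behaviour minutes;
#'   `"replace"` applies multiplicative replacement with `delta`.
#' @param delta replacement minutes when `zero_policy = "replace"`.
#' @return An object of class `c("cism_fit", "substitution_fit")` with
#'   `gamma`, `gamma_covariance`, `basis`, `parts`, `n` and the `lm`.
#' @export
fit_cism <- function(cohort, outcome, basis = default_ilr_basis(),
                     covariates = default_covariates(),
                     zero_policy = c("error", "replace"), delta = 1) {
  zero_policy <- match.arg(zero_policy)
  df <- .analysis_frame(cohort, outcome, covariates)
  parts <- .parts_matrix(df)
  if (any(parts == 0)) {
    if (zero_policy == "error") {
      stop("zero behaviour minutes present; set zero_policy = \"replace\" ",
           "to apply multiplicative replacement", call. = FALSE)
    }
    parts <- t(apply(parts, 1L, replace_zeros, delta = delta))
  }
  z <- ilr_transform(parts, basis)
  zn <- colnames(z)
  df[zn] <- as.data.frame(z)
  fml <- stats::reformulate(c(zn, covariates), response = ".z_outcome")
  fit <- stats::lm(fml, data = df)
  .check_full_rank(fit)
  structure(list(method = "CISM", outcome = outcome,
                 coefficients = stats::coef(fit),
                 covariance = stats::vcov(fit),
                 gamma = stats::coef(fit)[zn],
                 gamma_covariance = stats::vcov(fit)[zn, zn, drop = FALSE],
                 basis = basis, n = nrow(df), parts = parts,
                 behaviour_unit = "hour", lm = fit),
            class = c("cism_fit", "substitution_fit"))
}

#' @export
print.substitution_fit <- function(x, ...) {
  cat(x$method, "fit for standardised", x$outcome, "(n =", x$n, ")\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

.realloc_row <- function(method, outcome, from, to, minutes,
                         estimate, se, n, delta_z = NULL) {
  tibble::tibble(
    method = method, outcome = outcome, from = from, to = to,
    minutes = minutes, estimate = estimate, se = se,
    ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
    n = n,
    delta_z = if (is.null(delta_z)) list(NULL) else list(delta_z))
}

#' ISM reallocation estimate
#'
#' Scales the fitted per-hour substitution coefficient to `minutes`.
#' Reallocations towards sitting are the exact sign negation of the
#' corresponding sitting-to-behaviour estimate, so ISM estimates are
#' symmetric in direction and linear in minutes by construction.
#'
#' @param fit an [ism_fit][fit_ism].
#' @param from_part,to_part behaviour names; exactly one must be `"sit"`.
#' @param minutes minutes reallocated (nonnegative).
#' @return One-row tibble: `method, outcome, from, to, minutes, estimate,
#'   se, ci_low, ci_high, n, delta_z` (the CI uses the normal 1.96
#'   critical value).
#' @export
ism_reallocation <- function(fit, from_part = "sit", to_part, minutes = 60) {
  stopifnot(inherits(fit, "ism_fit"))
  if (minutes < 0) stop("minutes must be nonnegative", call. = FALSE)
  if (sum(c(from_part, to_part) == "sit") != 1L) {
    stop("ISM reallocations must involve sitting on exactly one side",
         call. = FALSE)
  }
  other <- if (from_part == "sit") to_part else from_part
  coef_name <- paste0(other, "_h")
  if (!coef_name %in% names(fit$coefficients)) {
    stop("unknown behaviour '", other, "'", call. = FALSE)
  }
  sign <- if (from_part == "sit") 1 else -1
  scale <- minutes / 60
  est <- sign * fit$coefficients[[coef_name]] * scale
  se <- sqrt(fit$covariance[coef_name, coef_name]) * scale
  .realloc_row("ISM", fit$outcome, from_part, to_part, minutes, est, se, fit$n)
}

# ILR coordinate shift induced by moving `minutes` from one part to
# another, starting from `base`.
.cism_delta_z <- function(base, from_part, to_part, minutes, basis) {
  z0 <- ilr_transform(base, basis)
  z1 <- ilr_transform(reallocate(base, from_part, to_part, minutes), basis)
  z1 - z0
}

#' CISM reallocation estimate
#'
#' Perturbs a base composition by moving `minutes` from one behaviour to
#' another, takes the ILR coordinate shift `delta_z`, and predicts the
#' standardised-outcome difference `gamma %*% delta_z` with a delta-method
#' standard error `sqrt(delta_z' Sigma delta_z)`. Because the perturbation
#' acts on the simplex, estimates are non-linear in `minutes` and
#' asymmetric in direction.
#'
#' @param fit a [cism_fit][fit_cism].
#' @param from_part,to_part distinct behaviour names.
#' @param minutes minutes reallocated; must be feasible on the base.
#' @param base base composition (named minutes vector); default is the
#'   mean composition of the fit's analysis sample.
#' @param mean_method how the default base is computed: `"geometric"`
#'   (compositional convention, default) or `"arithmetic"`.
#' @return One-row tibble as in [ism_reallocation()], with `delta_z`
#'   carrying the coordinate shift.
#' @export
cism_reallocation <- function(fit, from_part = "sit", to_part, minutes = 60,
                              base = NULL,
                              mean_method = c("geometric", "arithmetic")) {
  stopifnot(inherits(fit, "cism_fit"))
  if (is.null(base)) {
    base <- mean_composition(fit$parts, match.arg(mean_method))
  }
  dz <- .cism_delta_z(base, from_part, to_part, minutes, fit$basis)
  est <- sum(fit$gamma * dz)
  se <- sqrt(drop(t(dz) %*% fit$gamma_covariance %*% dz))
  .realloc_row("CISM", fit$outcome, from_part, to_part, minutes, est, se,
               fit$n, delta_z = dz)
}

#' Solve CISM coordinate coefficients from known reallocation estimates
#'
#' Given D-1 reallocation estimates around a common base composition,
#' recovers the unique ILR coefficient vector gamma satisfying
#' `gamma %*% delta_z = estimate` for each. Useful for reconstructing a
#' fitted model's reallocation surface from published effect estimates.
#'
#' @param base base composition, named minutes vector.
#' @param estimates data frame with columns `from`, `to`, `minutes`,
#'   `estimate`; one row per equation (D-1 rows).
#' @param basis [ilr_basis][build_ilr_basis].
#' @return Named numeric vector of ILR coefficients.
#' @examples
#' base <- c(sit = 548, stand = 286, step = 107)
#' printed <- data.frame(from = c("sit", "step"), to = c("step", "sit"),
#'                       minutes = 60, estimate = c(-0.230, 0.315))
#' solve_cism_gamma(base, printed)
#' @export
solve_cism_gamma <- function(base, estimates, basis = default_ilr_basis()) {
  k <- nrow(basis$contrast)
  if (nrow(estimates) != k) {
    stop("need exactly ", k, " estimates to identify gamma", call. = FALSE)
  }
  A <- t(vapply(seq_len(k), function(i) {
    .cism_delta_z(base, estimates$from[i], estimates$to[i],
                  estimates$minutes[i], basis)
  }, numeric(k)))
  gamma <- solve(A, estimates$estimate)
  stats::setNames(gamma, paste0("z", seq_len(k)))
}

#' Predict a reallocation effect from a known gamma
#'
#' @param gamma ILR coefficient vector (length D-1).
#' @param base base composition, named minutes vector.
#' @param from_part,to_part behaviour names.
#' @param minutes minutes reallocated.
#' @param basis [ilr_basis][build_ilr_basis]; must match the basis gamma
#'   is expressed in.
#' @return Predicted standardised-outcome difference (a number).
#' @export
cism_predict <- function(gamma, base, from_part, to_part, minutes,
                         basis = default_ilr_basis()) {
  dz <- .cism_delta_z(base, from_part, to_part, minutes, basis)
  sum(gamma * dz)
}
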