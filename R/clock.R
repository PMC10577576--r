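#' Construct an epigenetic clock model
#'
#' A clock is a named linear combination of probe beta values plus an
#' intercept, with an age-calibration transform. The piecewise log-linear
#' calibration (`horvath_log_linear`) maps age a to
#' log(a+1) - log(adult_age+1) below `adult_age` and to
#' (a - adult_age)/(adult_age+1) above it; `identity` leaves ages untouched.
#'
#' @param name label for the clock.
#' @param intercept intercept on the transformed-age scale.
#' @param coefficients named numeric vector, probe id -> weight.
#' @param adult_age calibration knot in years (default 20).
#' @param transform `"horvath_log_linear"` or `"identity"`.
#' @return list of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients, adult_age = 20,
                        transform = c("horvath_log_linear", "identity")) {
  transform <- match.arg(transform)
  stopifnot(length(coefficients) >= 1, !is.null(names(coefficients)),
            adult_age > 0)
  m <- list(name = name, intercept = intercept,
            coefficients = coefficients, adult_age = adult_age,
            transform = transform)
  class(m) <- "clock_model"
  m
}

#' Read a clock coefficient table from CSV
#'
#' Expected format: header `probe_id,weight`; the reserved probe id
#' `(Intercept)` carries the intercept.
#'
#' @param path CSV file.
#' @param name clock label (default: file name).
#' @param ... passed to [clock_model()] (`adult_age`, `transform`).
#' @return a `clock_model`.
#' @export
read_clock_csv <- function(path, name = basename(path), ...) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "weight") %in% names(tab)))
  ic <- tab$probe_id == "(Intercept)"
  intercept <- if (any(ic)) tab$weight[ic][1] else 0
  coefs <- stats::setNames(tab$weight[!ic], tab$probe_id[!ic])
  clock_model(name, intercept, coefs, ...)
}

#' Piecewise log-linear age calibration and its inverse
#'
#' @param age chronological age in years (vectorised).
#' @param adult_age calibration knot.
#' @return transformed value; strictly increasing and continuous in age.
#' @export
age_transform <- function(age, adult_age = 20) {
  ifelse(age < adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname age_transform
#' @param x transformed value.
#' @export
age_inverse <- function(x, adult_age = 20) {
  ifelse(x < 0,
         exp(x + log(adult_age + 1)) - 1,
         x * (adult_age + 1) + adult_age)
}

#' Predict epigenetic (DNAm) age
#'
#' Computes intercept + sum(coef * beta) per sample and back-transforms to
#' years. Missing values within a model probe's row are imputed by that
#' probe's cohort mean. Model probes entirely absent from the matrix are
#' dropped with a message; more than 20% absent is an error (the prediction
#' would not be trustworthy).
#'
#' @param beta probes x samples matrix.
#' @param model a [clock_model()].
#' @return named numeric vector of DNAm ages (years).
#' @export
predict_age <- function(beta, model) {
  stopifnot(inherits(model, "clock_model"))
  probes <- names(model$coefficients)
  present <- probes %in% rownames(beta)
  if (!any(present)) stop("no clock probes present in the beta matrix")
  if (mean(!present) > 0.20)
    stop(sprintf("%.0f%% of clock probes absent; prediction untrustworthy",
                 100 * mean(!present)))
  if (any(!present))
    message(sum(!present), " clock probe(s) absent; dropped from the model")
  x <- beta[probes[present], , drop = FALSE]
  if (anyNA(x)) {
    rm_ <- rowMeans(x, na.rm = TRUE)
    for (i in which(apply(x, 1, anyNA))) x[i, is.na(x[i, ])] <- rm_[i]
  }
  raw <- model$intercept + drop(crossprod(x, model$coefficients[present]))
  if (model$transform == "identity") return(raw)
  age_inverse(raw, model$adult_age)
}

#' Age acceleration: residuals of DNAm age on chronological age
#'
#' Fits OLS of DNAm age on chronological age across all included samples (the
#' pooled regression), takes per-sample residuals as the age-acceleration
#' measure, and compares the Progeroid vs NonProgeroid groups by Welch
#' t-test. With `adjust_sex`, the phenotype p-value comes from the phenotype
#' coefficient of OLS residual ~ phenotype + sex. Samples whose chronological
#' age is censored (taken from the latest report/death rather than biopsy) are
#' included by default with a warning.
#'
#' @param dnam_age named per-sample DNAm age (years).
#' @param sheet sample sheet with `phenotype`, `age_years`,
#'   `age_is_censored`, `sex`.
#' @param adjust_sex also report a sex-adjusted phenotype p-value.
#' @param include_censored include censored-age samples (default TRUE).
#' @return list: `residuals` (named), `fit` (the lm), `mean_residual`
#'   (per phenotype), `difference` (Progeroid - NonProgeroid, years), `p`
#'   (Welch), `sex_adjusted_p` (or `NA`).
#' @export
age_acceleration <- function(dnam_age, sheet, adjust_sex = FALSE,
                             include_censored = TRUE) {
  sheet <- sheet[match(names(dnam_age), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) stop("samples missing from the sample sheet")
  keep <- !is.na(sheet$age_years)
  if (!include_censored) keep <- keep & !sheet$age_is_censored
  else if (any(sheet$age_is_censored[keep]))
    warning(sum(sheet$age_is_censored[keep]),
            " sample(s) with censored chronological age included; ",
            "their age is likely overestimated")
  if (sum(keep) < 3) stop("need at least 3 samples with chronological age")
  da <- dnam_age[keep]; ca <- sheet$age_years[keep]
  fit <- stats::lm(da ~ ca)
  res <- stats::setNames(stats::residuals(fit), names(da))
  phen <- sheet$phenotype[keep]
  mr <- tapply(res, phen, mean)
  diff <- unname(mr["Progeroid"] - mr["NonProgeroid"])
  p <- stats::t.test(res[phen == "Progeroid"], res[phen == "NonProgeroid"])$p.value
  sex_p <- NA_real_
  if (adjust_sex) {
    f2 <- stats::lm(res ~ factor(phen, levels = c("NonProgeroid", "Progeroid")) +
                      factor(sheet$sex[keep]))
    sex_p <- summary(f2)$coefficients[2, 4]
  }
  list(residuals = res, fit = fit, mean_residual = mr, difference = diff,
       p = p, sex_adjusted_p = sex_p)
}
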