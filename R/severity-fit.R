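# nlme emits "Singular precision matrix" warnings while its optimizer
# probes near-zero variance components (routine on low-noise data);
# the simplification fallback already handles genuinely singular fits,
# so these are muffled.
quiet_lme <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("Singular precision matrix", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Longitudinal severity model: outcome (% vacuolated lymphocytes or
# per-subset % LAMP-1 single-positive cells) ~ age + severity class,
# with a per-patient random intercept and, when AIC prefers it, a
# per-patient random age slope. Random-structure selection is done
# under maximum likelihood; final coefficients are re-estimated under
# REML. Fixed-effect tests are Wald t tests with nlme's between-within
# degrees of freedom.

#' Fit the longitudinal severity model
#'
#' Fits `outcome ~ age_years + class` by linear mixed model with a
#' random intercept per patient, compares (by ML AIC) the
#' intercept-only random structure against intercept + random age
#' slope, and reports REML estimates under the preferred structure.
#' The severity class enters as a factor with `control` as reference
#' (treatment contrasts), so each class coefficient is that class's
#' contrast versus controls. The outcome is modelled on the raw
#' percentage (0-100) scale by default; `logit = TRUE` models
#' `qlogis(outcome/100)` instead (clamped away from 0/1).
#'
#' @param data Data frame with columns `patient_id`, `age_years`,
#'   `class`, and the outcome column.
#' @param outcome Name of the outcome column (default
#'   `"pct_vacuolated"`).
#' @param logit Model on the logit scale instead of raw percentages
#'   (default `FALSE`).
#' @param alpha Significance level used in reporting (default 0.05).
#' @return Object of class `severity_fit`: `fixed_effects` (data frame
#'   with estimate, SE, df, t, p per term), `class_test` (marginal
#'   Wald F test for the class term), `variance_components`
#'   (intercept_sd, slope_sd, residual_sd), `aic_with_slope`,
#'   `aic_without_slope` (ML scale), `chosen_random_structure`,
#'   `fit_method = "REML"`, `model` (the underlying `nlme::lme` fit),
#'   `outcome`, `n_patients`, `n_obs`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_patients_per_class = c(control = 8, protracted = 8, classical = 8),
#'   samples_per_patient = c(2, 4), seed = 11))
#' scores <- score_cohort(cohort$observations)
#' fit <- fit_severity(scores)
#' summary(fit)
fit_severity <- function(data, outcome = "pct_vacuolated", logit = FALSE,
                         alpha = 0.05) {
  need <- c("patient_id", "age_years", "class", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[need]), need]
  d$class <- severity_factor(d$class, drop = TRUE)
  if (nlevels(d$class) < 2L) stop("need >= 2 severity classes")
  if (length(unique(d$patient_id)) < 2L) stop("need >= 2 patients")
  y <- d[[outcome]]
  if (any(y < 0 | y > 100)) stop("outcome must lie in [0, 100]")
  d$.y <- if (logit) stats::qlogis(pmin(pmax(y / 100, 1e-4), 1 - 1e-4)) else y
  d$patient_id <- factor(d$patient_id)

  repeated <- any(table(d$patient_id) > 1L)
  fixed <- stats::as.formula(".y ~ age_years + class")
  # generous optimizer budget: random-slope fits on small-variance data
  # need more BFGS iterations than the nlme default allows
  ctrl <- nlme::lmeControl(opt = "optim", returnObject = TRUE,
                           maxIter = 100, msMaxIter = 300)

  fit_ml_int <- quiet_lme(nlme::lme(fixed, random = ~ 1 | patient_id,
                                    data = d, method = "ML", control = ctrl))
  aic_without <- stats::AIC(fit_ml_int)
  aic_with <- NA_real_
  slope_ok <- FALSE
  if (repeated) {
    fit_ml_slope <- tryCatch(
      quiet_lme(nlme::lme(fixed, random = ~ age_years | patient_id, data = d,
                          method = "ML", control = ctrl)),
      error = function(e) NULL)
    if (!is.null(fit_ml_slope)) {
      aic_with <- stats::AIC(fit_ml_slope)
      slope_ok <- TRUE
    }
  } else {
    warning("no patient has repeated measures; falling back to the ",
            "random-intercept-only structure")
  }

  use_slope <- slope_ok && !is.na(aic_with) && aic_with < aic_without
  structure_label <- if (!repeated) {
    "random intercept (fallback: no repeated measures)"
  } else if (use_slope) {
    "random intercept + random age slope (AIC-preferred)"
  } else if (!slope_ok) {
    "random intercept (random-slope fit failed; simplified)"
  } else {
    "random intercept (AIC-preferred)"
  }

  random <- if (use_slope) ~ age_years | patient_id else ~ 1 | patient_id
  fit <- tryCatch(
    quiet_lme(nlme::lme(fixed, random = random, data = d, method = "REML",
                        control = ctrl)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- quiet_lme(nlme::lme(fixed, random = ~ 1 | patient_id, data = d,
                               method = "REML", control = ctrl))
    structure_label <- "random intercept (REML random-slope refit failed; simplified)"
    use_slope <- FALSE
  }

  tt <- summary(fit)$tTable
  fixed_effects <- data.frame(
    term = rownames(tt), estimate = tt[, "Value"],
    se = tt[, "Std.Error"], df = tt[, "DF"],
    t = tt[, "t-value"], p = tt[, "p-value"],
    row.names = NULL, stringsAsFactors = FALSE)

  an <- stats::anova(fit, type = "marginal")
  class_test <- list(F = an["class", "F-value"],
                     df_num = an["class", "numDF"],
                     df_den = an["class", "denDF"],
                     p = an["class", "p-value"])

  vc <- nlme::VarCorr(fit)
  intercept_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  slope_sd <- if (use_slope)
    suppressWarnings(as.numeric(vc["age_years", "StdDev"])) else 0
  residual_sd <- fit$sigma

  structure(list(
    fixed_effects = fixed_effects,
    class_test = class_test,
    variance_components = c(intercept_sd = intercept_sd,
                            slope_sd = slope_sd,
                            residual_sd = residual_sd),
    aic_with_slope = aic_with, aic_without_slope = aic_without,
    chosen_random_structure = structure_label,
    fit_method = "REML", model = fit, outcome = outcome,
    logit = logit, alpha = alpha,
    n_patients = length(unique(d$patient_id)), n_obs = nrow(d)
  ), class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, ...) {
  cat(sprintf("Longitudinal severity model (REML): %s ~ age + class\n",
              x$outcome))
  cat(sprintf("  %d observations, %d patients; %s\n",
              x$n_obs, x$n_patients, x$chosen_random_structure))
  age <- x$fixed_effects[x$fixed_effects$term == "age_years", ]
  cat(sprintf("  age slope: %.4g (SE %.3g, p = %.3g)\n",
              age$estimate, age$se, age$p))
  cat(sprintf("  class effect: F(%d, %d) = %.3g, p = %.3g\n",
              x$class_test$df_num, x$class_test$df_den,
              x$class_test$F, x$class_test$p))
  invisible(x)
}

#' @export
summary.severity_fit <- function(object, ...) {
  print(object)
  cat("\nFixed effects (contrasts vs control):\n")
  print(object$fixed_effects, row.names = FALSE, digits = 4)
  cat("\nVariance components (SD):\n")
  print(round(object$variance_components, 4))
  cat(sprintf("\nAIC (ML): with random slope %.2f, without %.2f\n",
              object$aic_with_slope, object$aic_without_slope))
  invisible(object)
}

#' @export
coef.severity_fit <- function(object, ...) {
  stats::setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' @export
predict.severity_fit <- function(object, newdata = NULL, level = 0, ...) {
  if (is.null(newdata)) return(stats::predict(object$model, level = level))
  newdata$class <- severity_factor(newdata$class)
  stats::predict(object$model, newdata = newdata, level = level, ...)
}

#' @export
residuals.severity_fit <- function(object, ...) {
  stats::residuals(object$model, ...)
}

#' Tabulate severity fits across outcomes
#'
#' Collects per-outcome class contrasts, age slopes with confidence
#' intervals, and a stability verdict: an outcome is "stable" over age
#' when the age-slope confidence interval contains zero (no evidence
#' of progression with age), "changing" otherwise.
#'
#' @param fits Named list of `severity_fit` objects (name = outcome).
#' @param level Confidence level for the age-slope interval
#'   (default 0.95).
#' @return Data frame of class `severity_trend_report`: one row per
#'   outcome with age slope, CI, verdict, class-effect F/p, and the
#'   per-class contrast estimates.
#' @export
severity_trend_report <- function(fits, level = 0.95) {
  if (!length(fits)) stop("no fits to report")
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$outcome, "")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    age <- f$fixed_effects[f$fixed_effects$term == "age_years", ]
    lo <- age$estimate - z * age$se
    hi <- age$estimate + z * age$se
    row <- data.frame(
      outcome = nm, age_slope = age$estimate, age_slope_lo = lo,
      age_slope_hi = hi,
      verdict = if (lo <= 0 && hi >= 0) "stable" else "changing",
      class_F = f$class_test$F, class_p = f$class_test$p,
      stringsAsFactors = FALSE)
    contr <- f$fixed_effects[grepl("^class", f$fixed_effects$term), ]
    for (i in seq_len(nrow(contr))) {
      row[[sub("^class", "contrast_", contr$term[i])]] <- contr$estimate[i]
    }
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA_real_
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("severity_trend_report", "data.frame")
  out
}

#' @export
print.severity_trend_report <- function(x, ...) {
  cat("Severity trends per outcome (age slope CI and class effect):\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
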