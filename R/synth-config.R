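#' Configuration for synthetic CLN3 cohort generation
#'
#' Bundles every parameter of the synthetic cohort, flow-sample and
#' cell-image generators. Defaults emulate the published CLN3 cohort:
#' classical disease with a median 30% of lymphocytes vacuolated
#' (range roughly 11-69%) and a median of 10 vacuoles per affected
#' cell (6-18); protracted disease with a median 8% vacuolated
#' (5-30%) and a median of 8 vacuoles (3-12); controls at 1-3% with
#' 1-5 small vacuoles; no true age trend (the cohort study found
#' none). The per-sample true vacuolated fraction is
#' `plogis(qlogis(class_mean) + b0 + b1 * age)` with per-patient
#' random intercept `b0` and random age slope `b1`.
#'
#' LAMP-1 elevation per lymphocyte subset is parameterized by
#' `lamp_shift_by_class_and_subset`, a class x subset (T4, T8, B)
#' matrix of log-fluorescence shifts. The per-subset fraction of
#' "affected" (LAMP-1-positive, perforin-negative) cells is
#' `plogis(qlogis(baseline_affected_rate) + 2 * shift)`, so a zero
#' shift reproduces the baseline false-positive rate exactly. The
#' retina-only class places its largest shift in the B-cell
#' compartment; all other affected classes shift T cells most.
#'
#' @param n_patients_per_class Named integer vector: patients per
#'   severity class. Classes with 0 may be omitted.
#' @param samples_per_patient Integer length-2 vector: inclusive range
#'   of longitudinal samples drawn per patient.
#' @param age_range_years Numeric length-2 vector: sampling-age window.
#' @param vac_fraction_by_class Named numeric vector of per-class mean
#'   vacuolated fractions (probability scale).
#' @param vacuoles_per_cell_dist_by_class Named list; each entry a list
#'   with `median`, `min`, `max` describing the discrete per-cell
#'   vacuole-count distribution of that class.
#' @param lamp_shift_by_class_and_subset Numeric matrix, rows = severity
#'   classes, columns = `T4`, `T8`, `B`: log-fluorescence LAMP-1 shifts.
#' @param baseline_affected_rate Affected-cell false-positive rate in a
#'   zero-shift subset.
#' @param subset_proportions Named numeric vector of event proportions
#'   for subsets `T4`, `T8`, `B`, `NK`, `other`; must sum to 1.
#' @param random_intercept_sd SD of the per-patient random intercept on
#'   the logit scale.
#' @param random_slope_sd SD of the per-patient random age slope
#'   (logit units per year).
#' @param observer_sd SD of the per-observer, per-sample additive logit
#'   shift modelling inter-observer counting differences.
#' @param age_slope_true Population age slope (logit units per year);
#'   default 0: vacuolization does not progress with age.
#' @param seed Integer seed recorded in the config and used by the
#'   generators.
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$vac_fraction_by_class
cohort_config <- function(n_patients_per_class = c(control = 10, carrier = 3,
                                                   retina_only = 1,
                                                   protracted = 2,
                                                   delayed_classical = 1,
                                                   classical = 15),
                          samples_per_patient = c(1L, 4L),
                          age_range_years = c(5, 25),
                          vac_fraction_by_class = c(control = 0.02,
                                                    carrier = 0.025,
                                                    retina_only = 0.03,
                                                    protracted = 0.08,
                                                    delayed_classical = 0.15,
                                                    classical = 0.30),
                          vacuoles_per_cell_dist_by_class = NULL,
                          lamp_shift_by_class_and_subset = NULL,
                          baseline_affected_rate = 0.02,
                          subset_proportions = c(T4 = 0.35, T8 = 0.20,
                                                 B = 0.15, NK = 0.15,
                                                 other = 0.15),
                          random_intercept_sd = 0.4,
                          random_slope_sd = 0.02,
                          observer_sd = 0.15,
                          age_slope_true = 0,
                          seed = 1L) {
  if (is.null(vacuoles_per_cell_dist_by_class)) {
    vacuoles_per_cell_dist_by_class <- list(
      control           = list(median = 2L,  min = 1L, max = 5L),
      carrier           = list(median = 2L,  min = 1L, max = 5L),
      retina_only       = list(median = 2L,  min = 1L, max = 5L),
      protracted        = list(median = 8L,  min = 3L, max = 12L),
      delayed_classical = list(median = 9L,  min = 4L, max = 15L),
      classical         = list(median = 10L, min = 6L, max = 18L)
    )
  }
  if (is.null(lamp_shift_by_class_and_subset)) {
    lamp_shift_by_class_and_subset <- rbind(
      control           = c(T4 = 0.0,  T8 = 0.0,  B = 0.0),
      carrier           = c(T4 = 0.05, T8 = 0.05, B = 0.05),
      retina_only       = c(T4 = 0.1,  T8 = 0.1,  B = 1.8),
      protracted        = c(T4 = 0.8,  T8 = 0.8,  B = 0.5),
      delayed_classical = c(T4 = 1.2,  T8 = 1.2,  B = 0.8),
      classical         = c(T4 = 1.5,  T8 = 1.5,  B = 1.0)
    )
  }

  if (length(n_patients_per_class) == 0L) {
    stop("n_patients_per_class must name at least one severity class")
  }
  severity_rank(names(n_patients_per_class))  # validates labels
  if (any(n_patients_per_class < 0)) stop("patient counts must be >= 0")
  sds <- c(random_intercept_sd = random_intercept_sd,
           random_slope_sd = random_slope_sd, observer_sd = observer_sd)
  if (any(sds < 0)) {
    stop("negative SD: ", paste(names(sds)[sds < 0], collapse = ", "))
  }
  if (any(vac_fraction_by_class < 0 | vac_fraction_by_class > 1)) {
    stop("vac_fraction_by_class entries must lie in [0, 1]")
  }
  if (baseline_affected_rate <= 0 || baseline_affected_rate >= 1) {
    stop("baseline_affected_rate must lie in (0, 1)")
  }
  if (abs(sum(subset_proportions) - 1) > 1e-8) {
    stop("subset_proportions must sum to 1")
  }
  if (length(samples_per_patient) != 2L ||
      samples_per_patient[1] < 1L ||
      samples_per_patient[2] < samples_per_patient[1]) {
    stop("samples_per_patient must be an increasing range with min >= 1")
  }

  structure(list(
    n_patients_per_class = n_patients_per_class,
    samples_per_patient = as.integer(samples_per_patient),
    age_range_years = age_range_years,
    vac_fraction_by_class = vac_fraction_by_class,
    vacuoles_per_cell_dist_by_class = vacuoles_per_cell_dist_by_class,
    lamp_shift_by_class_and_subset = lamp_shift_by_class_and_subset,
    baseline_affected_rate = baseline_affected_rate,
    subset_proportions = subset_proportions,
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd,
    observer_sd = observer_sd,
    age_slope_true = age_slope_true,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic CLN3 cohort configuration\n")
  cat("  patients/class:",
      paste(sprintf("%s=%d", names(x$n_patients_per_class),
                    x$n_patients_per_class), collapse = " "), "\n")
  cat(sprintf("  samples/patient: %d-%d over ages %.4g-%.4g y\n",
              x$samples_per_patient[1], x$samples_per_patient[2],
              x$age_range_years[1], x$age_range_years[2]))
  cat("  vacuolated fraction:",
      paste(sprintf("%s=%.3g", names(x$vac_fraction_by_class),
                    x$vac_fraction_by_class), collapse = " "), "\n")
  cat(sprintf("  random effects: intercept SD %.3g, slope SD %.3g/y, observer SD %.3g (logit)\n",
              x$random_intercept_sd, x$random_slope_sd, x$observer_sd))
  cat(sprintf("  true age slope: %.3g/y, seed %d\n",
              x$age_slope_true, x$seed))
  invisible(x)
}

# Affected-cell probability for one class/subset from its LAMP shift.
affected_prob <- function(config, class_label, subset) {
  shift <- config$lamp_shift_by_class_and_subset[class_label, subset]
  stats::plogis(stats::qlogis(config$baseline_affected_rate) + 2 * shift)
}
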