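# Cohort-level synthetic data: patients with random effects and
# per-sample smear observations by three independent observers.

# Draw one vacuole count from a class's discrete distribution:
# 1 + Poisson(median - 1) clamped to [min, max]. The clamp keeps the
# printed per-class ranges hard bounds; the Poisson spread approximates
# the within-class heterogeneity of vacuole numbers.
draw_vacuole_counts <- function(n, dist, exact = FALSE) {
  if (n == 0L) return(integer(0))
  if (exact) return(rep(as.integer(dist$median), n))
  x <- 1L + stats::rpois(n, lambda = max(dist$median - 1L, 0L))
  pmin(pmax(x, dist$min), dist$max)
}

#' Generate a synthetic longitudinal CLN3 cohort with smear counts
#'
#' Draws a patient set (per-class sizes, per-patient random intercept
#' and random age slope on the logit scale, sorted sampling ages) and,
#' for every sample, smear observations by three independent observers.
#' Each observer counts `n_counted` = 100 lymphocytes; the number of
#' vacuolated cells is binomial with per-observer probability
#' `plogis(qlogis(class_mean) + b0 + (b1 + age_slope_true) * age +
#' observer_shift)`, and vacuole counts per affected cell are recorded
#' for at most the first 20 vacuolated cells, mirroring the manual
#' counting protocol.
#'
#' @param config A [cohort_config()] object.
#' @param seed Optional integer overriding `config$seed`.
#' @return A list of class `synthetic_cohort` with elements
#'   `patients` (data frame: patient_id, class, genotype, random
#'   intercept/slope) and `observations` (data frame: one row per
#'   sample x observer with `n_counted`, `n_vacuolated`,
#'   `vacuole_counts` as a semicolon-joined string, and the latent
#'   `true_fraction`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_patients_per_class = c(control = 2, classical = 2), seed = 7))
#' head(cohort$observations)
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))

  genotype_for_class <- c(
    control = "wild type", carrier = "1 kb deletion heterozygous",
    retina_only = "c.1213C>T homozygous",
    protracted = "c.139T>C / c.1000C>T",
    delayed_classical = "1 kb deletion / c.1000C>T",
    classical = "1 kb deletion homozygous")

  # With every noise SD at zero the generator collapses to its analytic
  # expectation: counts become round(100 * p) and per-cell vacuole
  # numbers the class median, so downstream recovery is exact.
  zero_noise <- config$random_intercept_sd == 0 &&
    config$random_slope_sd == 0 && config$observer_sd == 0

  classes <- names(config$n_patients_per_class)
  pat <- list(); obs <- list(); pid <- 0L
  for (cl in classes) {
    if (!cl %in% names(config$vac_fraction_by_class)) {
      stop("no vac_fraction_by_class entry for class ", cl)
    }
    for (i in seq_len(config$n_patients_per_class[[cl]])) {
      pid <- pid + 1L
      patient_id <- sprintf("P%03d", pid)
      b0 <- stats::rnorm(1, 0, config$random_intercept_sd)
      b1 <- stats::rnorm(1, 0, config$random_slope_sd)
      samp_range <- seq(config$samples_per_patient[1],
                        config$samples_per_patient[2])
      n_samp <- if (length(samp_range) == 1L) samp_range else
        sample(samp_range, 1L)
      ages <- sort(stats::runif(n_samp, config$age_range_years[1],
                                config$age_range_years[2]))
      pat[[pid]] <- data.frame(
        patient_id = patient_id, class = cl,
        genotype = genotype_for_class[[cl]],
        random_intercept = b0, random_slope = b1,
        stringsAsFactors = FALSE)

      base_logit <- stats::qlogis(config$vac_fraction_by_class[[cl]])
      vdist <- config$vacuoles_per_cell_dist_by_class[[cl]]
      for (s in seq_along(ages)) {
        age <- ages[s]
        p_true <- stats::plogis(base_logit + b0 +
                                  (b1 + config$age_slope_true) * age)
        sample_id <- sprintf("%s_S%02d", patient_id, s)
        for (o in 1:3) {
          p_obs <- stats::plogis(stats::qlogis(p_true) +
                                   stats::rnorm(1, 0, config$observer_sd))
          n_vac <- if (zero_noise) as.integer(round(100 * p_obs)) else
            stats::rbinom(1, 100L, p_obs)
          counts <- draw_vacuole_counts(min(n_vac, 20L), vdist,
                                        exact = zero_noise)
          obs[[length(obs) + 1L]] <- data.frame(
            sample_id = sample_id, patient_id = patient_id, class = cl,
            genotype = genotype_for_class[[cl]],
            age_years = age, observer_id = o,
            n_counted = 100L, n_vacuolated = n_vac,
            vacuole_counts = paste(counts, collapse = ";"),
            true_fraction = p_true, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (pid == 0L) stop("configuration yields zero patients")
  structure(list(patients = do.call(rbind, pat),
                 observations = do.call(rbind, obs),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d samples, %d observer rows\n",
              nrow(x$patients),
              length(unique(x$observations$sample_id)),
              nrow(x$observations)))
  print(table(x$patients$class)[names(x$config$n_patients_per_class)])
  invisible(x)
}
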