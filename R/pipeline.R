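# End-to-end pipeline: simulate a cohort, score smears, gate flow
# samples, quantify cell images, and fit the longitudinal severity
# model for each outcome. Every stage writes its outputs under the run
# directory and is logged in a manifest; a fixed seed makes the whole
# run deterministic.

#' Pipeline configuration
#'
#' @param synth A [cohort_config()] for the synthetic stages.
#' @param n_flow_events Events per simulated flow sample.
#' @param n_cells_per_class Cells per class imaged in the
#'   ImageStream-style stage.
#' @param image_classes Severity classes imaged (default control and
#'   classical, the two conditions of the per-cell imaging comparison).
#' @param nk_quantile,min_nk NK-anchored gating options.
#' @param outcomes Severity-model outcomes to fit.
#' @param alpha Significance level for reporting.
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = cohort_config(),
                            n_flow_events = 2000L,
                            n_cells_per_class = 25L,
                            image_classes = c("control", "classical"),
                            nk_quantile = 0.05, min_nk = 50L,
                            outcomes = c("pct_vacuolated",
                                         "pct_affected_T4",
                                         "pct_affected_T8",
                                         "pct_affected_B"),
                            alpha = 0.05,
                            seed = 1L) {
  severity_rank(image_classes)
  structure(list(synth = synth, n_flow_events = as.integer(n_flow_events),
                 n_cells_per_class = as.integer(n_cells_per_class),
                 image_classes = image_classes,
                 nk_quantile = nk_quantile, min_nk = as.integer(min_nk),
                 outcomes = outcomes, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `synth`
#' mapping mirrors [cohort_config()] arguments (its
#' `lamp_shift_by_class_and_subset` may be given as a nested mapping
#' class -> subset -> shift).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (!is.null(synth_args$n_patients_per_class)) {
    synth_args$n_patients_per_class <- unlist(synth_args$n_patients_per_class)
  }
  if (!is.null(synth_args$vac_fraction_by_class)) {
    synth_args$vac_fraction_by_class <- unlist(synth_args$vac_fraction_by_class)
  }
  if (!is.null(synth_args$subset_proportions)) {
    synth_args$subset_proportions <- unlist(synth_args$subset_proportions)
  }
  if (!is.null(synth_args$lamp_shift_by_class_and_subset)) {
    sh <- synth_args$lamp_shift_by_class_and_subset
    synth_args$lamp_shift_by_class_and_subset <-
      do.call(rbind, lapply(sh, function(r) unlist(r)[c("T4", "T8", "B")]))
  }
  args <- y[setdiff(names(y), "synth")]
  args$synth <- do.call(cohort_config, synth_args)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full vacuolization-quantification pipeline
#'
#' Stage order: (1) simulate the cohort and write smear observations;
#' (2) score smears per sample and summarize along the two axes;
#' (3) simulate and gate one flow sample per cohort sample, reporting
#' per-subset affected fractions; (4) simulate and quantify per-cell
#' images for the configured classes, with population bands and the
#' per-class comparison; (5) fit the longitudinal severity model for
#' every configured outcome. Outputs are CSV/JSON files under
#' `out_dir`; `manifest.json` records the stages that completed, their
#' outputs, and the full parameter set. A stage failure stops the run
#' but leaves completed stage outputs and the manifest intact.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; must not require parents).
#' @param seed Optional integer overriding `config$seed`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`, `scores`, `two_axis`, `gating_reports`, `quants`,
#'   `bands`, `class_comparison`, `fits`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  manifest <- list(package = "lymphovac", version = pkg_version_string(),
                   seed = config$seed, stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, outputs, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok", outputs = outputs)
    write_manifest()
    res
  }

  # stage seeds derived from the master seed (kept below 2^31)
  seed_of <- function(offset) (config$seed + offset) %% .Machine$integer.max

  cohort <- run_stage("simulate_cohort", "cohort.csv", function() {
    co <- generate_cohort(config$synth, seed = seed_of(101L))
    write_cohort_csv(co, file.path(out_dir, "cohort.csv"))
    co
  })

  scores <- run_stage("smear_score", c("smear_scores.csv", "two_axis_summary.csv"),
                      function() {
    sc <- score_cohort(cohort$observations)
    write_csv_with_header(sc, file.path(out_dir, "smear_scores.csv"),
                          list(seed = config$seed))
    ta <- two_axis_summary(sc)
    write_csv_with_header(ta$per_class,
                          file.path(out_dir, "two_axis_summary.csv"),
                          list(log_floor_pct = ta$log_floor_pct))
    sc
  })

  gating <- run_stage("flow_gating", "gating_reports.csv", function() {
    samples <- unique(scores[c("sample_id", "patient_id", "class", "age_years")])
    reports <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
      ev <- generate_flow_sample(samples$class[i], config$n_flow_events,
                                 config$synth, seed = seed_of(1000L + i))
      g <- gate_sample(ev, quantile = config$nk_quantile,
                       min_nk = config$min_nk,
                       sample_id = samples$sample_id[i])
      rep_i <- g$report
      rep_i$patient_id <- samples$patient_id[i]
      rep_i$class <- samples$class[i]
      rep_i$age_years <- samples$age_years[i]
      reports[[i]] <- rep_i
    }
    all_reports <- do.call(rbind, reports)
    write_csv_with_header(all_reports, file.path(out_dir, "gating_reports.csv"),
                          list(n_events = config$n_flow_events,
                               nk_quantile = config$nk_quantile,
                               min_nk = config$min_nk))
    all_reports
  })

  imaging <- run_stage(
    "image_quant",
    c("cell_quants.csv", "population_bands.csv", "class_comparison.csv"),
    function() {
      quants_by_class <- list(); bands_by_class <- list(); rows <- list()
      for (j in seq_along(config$image_classes)) {
        cl <- config$image_classes[j]
        imgs <- generate_cell_images(cl, config$n_cells_per_class,
                                     config$synth,
                                     seed = seed_of(5000L + j))
        qs <- quantify_cells(imgs)
        quants_by_class[[cl]] <- qs
        b <- population_bands(qs)
        b$class <- cl
        bands_by_class[[cl]] <- b
        rows[[cl]] <- data.frame(
          cell_id = vapply(qs, `[[`, "", "cell_id"), class = cl,
          mean_lamp1 = vapply(qs, `[[`, 0, "mean_lamp1"),
          area_px = vapply(qs, function(q) as.numeric(q$area_px), 0))
      }
      write_csv_with_header(do.call(rbind, rows),
                            file.path(out_dir, "cell_quants.csv"),
                            list(n_cells_per_class = config$n_cells_per_class))
      write_csv_with_header(do.call(rbind, bands_by_class),
                            file.path(out_dir, "population_bands.csv"))
      cmp <- compare_classes(quants_by_class)
      write_csv_with_header(cmp, file.path(out_dir, "class_comparison.csv"))
      list(quants = quants_by_class, bands = bands_by_class,
           comparison = cmp)
    })

  fits <- run_stage("fit_severity",
                    paste0("severity_fit_", config$outcomes, ".json"),
                    function() {
    # wide per-sample outcome table: smear % + per-subset affected %
    wide <- scores
    for (sub in c("T4", "T8", "B")) {
      col <- paste0("pct_affected_", sub)
      sub_rows <- gating[gating$subset == sub, ]
      wide[[col]] <- sub_rows$pct_affected[match(wide$sample_id,
                                                 sub_rows$sample_id)]
    }
    out <- list()
    for (oc in config$outcomes) {
      if (!oc %in% names(wide)) stop("unknown outcome: ", oc)
      f <- fit_severity(wide, outcome = oc, alpha = config$alpha)
      write_severity_fit_json(f, file.path(out_dir,
                                           paste0("severity_fit_", oc, ".json")))
      out[[oc]] <- f
    }
    trend <- severity_trend_report(out)
    write_csv_with_header(as.data.frame(trend),
                          file.path(out_dir, "severity_trends.csv"))
    out
  })

  invisible(list(cohort = cohort, scores = scores,
                 two_axis = two_axis_summary(scores),
                 gating_reports = gating,
                 quants = imaging$quants, bands = imaging$bands,
                 class_comparison = imaging$comparison,
                 fits = fits, manifest = manifest))
}
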