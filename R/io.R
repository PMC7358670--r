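# Shared readers and writers. All tabular outputs are UTF-8 CSV with
# '.' decimal separator and a mandatory header row; every file starts
# with a '#' comment line embedding the package version and the
# parameters that produced it, which readers skip.

pkg_version_string <- function() {
  as.character(utils::packageVersion("lymphovac"))
}

csv_header_comment <- function(params = NULL) {
  meta <- sprintf("# lymphovac %s", pkg_version_string())
  if (!is.null(params) && length(params)) {
    meta <- paste0(meta, "; ",
                   paste(sprintf("%s=%s", names(params),
                                 vapply(params, function(p)
                                   paste(format(p), collapse = "|"), "")),
                         collapse = "; "))
  }
  meta
}

write_csv_with_header <- function(df, path, params = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(csv_header_comment(params), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_with_header <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a cohort smear-observation table
#'
#' Columns: `sample_id`, `patient_id`, `class`, `genotype`,
#' `age_years`, `observer_id`, `n_counted`, `n_vacuolated`,
#' `vacuole_counts` (semicolon-joined per-cell counts).
#'
#' @param cohort A `synthetic_cohort` or its `observations` data frame.
#' @param path Output CSV path.
#' @return `write_cohort_csv` returns the path invisibly;
#'   `read_cohort_csv` returns the observation data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  obs <- if (inherits(cohort, "synthetic_cohort")) cohort$observations else cohort
  params <- if (inherits(cohort, "synthetic_cohort")) {
    cfg <- cohort$config
    list(seed = cfg$seed,
         classes = paste(names(cfg$n_patients_per_class), collapse = "|"),
         observer_sd = cfg$observer_sd)
  }
  write_csv_with_header(obs, path, params)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  obs <- read_csv_with_header(path)
  need <- c("sample_id", "patient_id", "class", "age_years",
            "observer_id", "n_counted", "n_vacuolated", "vacuole_counts")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("cohort CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  obs$vacuole_counts <- as.character(obs$vacuole_counts)
  obs$vacuole_counts[is.na(obs$vacuole_counts)] <- ""
  obs
}

#' Write / read a flow-cytometry event table
#'
#' One row per event; channel columns are named exactly
#' `CD3,CD4,CD8,CD20,CD56,LAMP1,PERFORIN`. Ground-truth columns
#' (`true_subset`, `true_affected`) and gate-derived labels (`subset`)
#' are preserved when present.
#'
#' @param events Event data frame.
#' @param path CSV path.
#' @param params Optional named list recorded in the header comment.
#' @export
write_flow_csv <- function(events, path, params = NULL) {
  miss <- setdiff(FLOW_CHANNELS, names(events))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  write_csv_with_header(events, path, params)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path) {
  ev <- read_csv_with_header(path)
  miss <- setdiff(FLOW_CHANNELS, names(ev))
  if (length(miss)) stop("flow CSV missing channel(s): ",
                         paste(miss, collapse = ", "))
  ev
}

#' Write / read channel-separated single-cell TIFF images
#'
#' Each cell is stored as 8-bit grayscale TIFFs `<cell_id>_CD4.tif` and
#' `<cell_id>_LAMP1.tif`; the ground-truth mask, when present, as a
#' 0/255 TIFF `<cell_id>_MASK.tif`.
#'
#' @param images List of `cell_image_pair` objects.
#' @param dir Output directory (created if missing).
#' @return `write_cell_images` returns the directory invisibly;
#'   `read_cell_images` returns a list of `cell_image_pair` objects
#'   (with `true_mask`/`true_mean_lamp1` only if mask files exist).
#' @export
write_cell_images <- function(images, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (img in images) {
    tiff::writeTIFF(img$cd4_channel / 255,
                    file.path(dir, paste0(img$cell_id, "_CD4.tif")),
                    bits.per.sample = 8L)
    tiff::writeTIFF(img$lamp1_channel / 255,
                    file.path(dir, paste0(img$cell_id, "_LAMP1.tif")),
                    bits.per.sample = 8L)
    if (!is.null(img$true_mask)) {
      tiff::writeTIFF((img$true_mask * 255) / 255,
                      file.path(dir, paste0(img$cell_id, "_MASK.tif")),
                      bits.per.sample = 8L)
    }
  }
  invisible(dir)
}

#' @rdname write_cell_images
#' @export
read_cell_images <- function(dir) {
  cd4_files <- sort(list.files(dir, pattern = "_CD4\\.tif$", full.names = TRUE))
  if (!length(cd4_files)) stop("no *_CD4.tif images found in ", dir)
  lapply(cd4_files, function(f) {
    cell_id <- sub("_CD4\\.tif$", "", basename(f))
    lampf <- file.path(dir, paste0(cell_id, "_LAMP1.tif"))
    if (!file.exists(lampf)) stop("missing LAMP1 channel for cell ", cell_id)
    to8 <- function(p) clamp8(tiff::readTIFF(p) * 255)
    img <- list(cd4_channel = to8(f), lamp1_channel = to8(lampf),
                cell_id = cell_id, class_label = NA_character_,
                true_mask = NULL, true_mean_lamp1 = NA_real_)
    maskf <- file.path(dir, paste0(cell_id, "_MASK.tif"))
    if (file.exists(maskf)) img$true_mask <- to8(maskf) > 127
    structure(img, class = "cell_image_pair")
  })
}

#' Write a subset report (and gates) as JSON
#'
#' @param report A `subset_report` data frame.
#' @param gates Optional `gate_set` stored alongside.
#' @param path Output JSON path.
#' @export
write_subset_report_json <- function(report, path, gates = NULL) {
  payload <- list(package = "lymphovac", version = pkg_version_string(),
                  report = as.data.frame(report))
  if (!is.null(gates)) payload$gates <- unclass(gates)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a severity fit to JSON (without the model object)
#'
#' @param fit A `severity_fit`.
#' @param path Output JSON path.
#' @export
write_severity_fit_json <- function(fit, path) {
  payload <- list(
    package = "lymphovac", version = pkg_version_string(),
    outcome = fit$outcome, fit_method = fit$fit_method,
    chosen_random_structure = fit$chosen_random_structure,
    fixed_effects = fit$fixed_effects,
    class_test = fit$class_test,
    variance_components = as.list(fit$variance_components),
    aic_with_slope = fit$aic_with_slope,
    aic_without_slope = fit$aic_without_slope,
    n_patients = fit$n_patients, n_obs = fit$n_obs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
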