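# Blood-smear vacuolization scoring. Each of (typically) three
# technicians counts the percentage of vacuolated lymphocytes among
# 100 cells and the number of vacuoles per cell in at most 20
# vacuolated cells; observer percentages are averaged and per-cell
# vacuole counts pooled.

parse_vacuole_counts <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Score one sample's smear observations
#'
#' Aggregates independent observer counts on a single sample:
#' `pct_vacuolated` is the arithmetic mean over observers of
#' `100 * n_vacuolated / n_counted`; per-cell vacuole statistics
#' (median and min-max range) are pooled across all observers'
#' vacuole-count lists.
#'
#' @param observations Data frame with columns `sample_id`,
#'   `observer_id`, `n_counted`, `n_vacuolated`, `vacuole_counts`
#'   (semicolon-joined integers, possibly empty).
#' @return One-row data frame: `sample_id`, `pct_vacuolated`,
#'   `vacuoles_per_cell_median`, `vacuoles_per_cell_min`,
#'   `vacuoles_per_cell_max`, `n_observers`. Per-cell statistics are
#'   `NA` when no vacuolated cells were characterized.
#' @export
#' @examples
#' obs <- data.frame(sample_id = "s1", observer_id = 1:3,
#'                   n_counted = 100, n_vacuolated = c(10, 20, 30),
#'                   vacuole_counts = c("8;9", "10;12", "10"))
#' score_sample(obs)  # pct_vacuolated 20
score_sample <- function(observations) {
  if (nrow(observations) < 1L) stop("need at least one observation")
  sid <- unique(observations$sample_id)
  if (length(sid) != 1L) {
    stop("observations mix sample_ids: ", paste(sid, collapse = ", "))
  }
  if (any(observations$n_vacuolated < 0 |
          observations$n_vacuolated > observations$n_counted)) {
    stop("n_vacuolated outside [0, n_counted] for sample ", sid)
  }
  pct <- mean(100 * observations$n_vacuolated / observations$n_counted)
  pooled <- unlist(lapply(observations$vacuole_counts, parse_vacuole_counts))
  if (length(pooled) && any(pooled < 1)) {
    stop("vacuole counts must be >= 1 (sample ", sid, ")")
  }
  if (!length(pooled) && any(observations$n_vacuolated > 0)) {
    warning("sample ", sid, ": vacuolated cells counted but no per-cell ",
            "vacuole counts recorded; per-cell statistics reported missing")
  }
  data.frame(
    sample_id = sid,
    pct_vacuolated = pct,
    vacuoles_per_cell_median = if (length(pooled)) stats::median(pooled) else NA_real_,
    vacuoles_per_cell_min = if (length(pooled)) min(pooled) else NA_integer_,
    vacuoles_per_cell_max = if (length(pooled)) max(pooled) else NA_integer_,
    n_observers = length(unique(observations$observer_id)),
    stringsAsFactors = FALSE)
}

#' Score every sample of a cohort
#'
#' Applies [score_sample()] per sample and joins patient metadata
#' (severity class, genotype, age), preserving the repeated-measures
#' structure required by the longitudinal severity model.
#'
#' @param observations Cohort observation table (one row per sample x
#'   observer), e.g. `generate_cohort(...)$observations` or a table
#'   read with [read_cohort_csv()]. Must carry `patient_id`, `class`,
#'   `age_years` metadata columns (a separate `metadata` table keyed by
#'   `sample_id` may supply them instead).
#' @param metadata Optional data frame keyed by `sample_id` with
#'   columns `patient_id`, `class`, `age_years` (and optionally
#'   `genotype`) when `observations` lacks them.
#' @return Data frame, one row per sample, with scores and metadata.
#' @export
score_cohort <- function(observations, metadata = NULL) {
  meta_cols <- c("patient_id", "class", "age_years")
  if (!is.null(metadata)) {
    missing_ids <- setdiff(unique(observations$sample_id),
                           metadata$sample_id)
    if (length(missing_ids)) {
      stop("samples without metadata: ", paste(missing_ids, collapse = ", "))
    }
    keep <- intersect(c("sample_id", meta_cols, "genotype"), names(metadata))
    observations <- merge(observations[setdiff(names(observations),
                                               setdiff(keep, "sample_id"))],
                          metadata[keep], by = "sample_id")
  }
  if (!all(meta_cols %in% names(observations))) {
    stop("missing metadata columns: ",
         paste(setdiff(meta_cols, names(observations)), collapse = ", "))
  }
  parts <- lapply(split(observations, observations$sample_id), function(d) {
    sc <- score_sample(d)
    sc$patient_id <- d$patient_id[1]
    sc$class <- d$class[1]
    sc$age_years <- d$age_years[1]
    if ("genotype" %in% names(d)) sc$genotype <- d$genotype[1]
    sc
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Two-axis per-class vacuolization summary
#'
#' Summarizes scored samples along the two discriminative axes used to
#' separate disease phenotypes: percentage of vacuolated lymphocytes
#' (displayed on a log10 axis) and vacuoles per affected cell
#' (linear). Zero percentages are floored at 0.5% for the log display
#' and flagged.
#'
#' @param scores Output of [score_cohort()].
#' @param log_floor_pct Display floor substituted for 0% on the log
#'   axis (default 0.5).
#' @return List of class `two_axis_summary`: `per_class` data frame
#'   (class, n, centroid and range on both axes) and `per_sample`
#'   data frame with `log10_pct` and `floored` flag.
#' @export
two_axis_summary <- function(scores, log_floor_pct = 0.5) {
  if (nrow(scores) < 1L) stop("no scores to summarize")
  pct_disp <- pmax(scores$pct_vacuolated, log_floor_pct)
  per_sample <- data.frame(
    sample_id = scores$sample_id, class = scores$class,
    pct_vacuolated = scores$pct_vacuolated,
    log10_pct = log10(pct_disp),
    floored = scores$pct_vacuolated < log_floor_pct,
    vacuoles_per_cell_median = scores$vacuoles_per_cell_median,
    stringsAsFactors = FALSE)
  per_class <- do.call(rbind, lapply(split(scores, scores$class), function(d) {
    vpc <- d$vacuoles_per_cell_median
    data.frame(class = d$class[1], n_samples = nrow(d),
               pct_median = stats::median(d$pct_vacuolated),
               pct_min = min(d$pct_vacuolated),
               pct_max = max(d$pct_vacuolated),
               vpc_median = stats::median(vpc, na.rm = TRUE),
               vpc_min = suppressWarnings(min(vpc, na.rm = TRUE)),
               vpc_max = suppressWarnings(max(vpc, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  per_class <- per_class[order(severity_rank(per_class$class)), ]
  rownames(per_class) <- NULL
  structure(list(per_class = per_class, per_sample = per_sample,
                 log_floor_pct = log_floor_pct),
            class = "two_axis_summary")
}

#' @export
print.two_axis_summary <- function(x, ...) {
  cat("Two-axis vacuolization summary (% vacuolated / vacuoles per cell)\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  if (any(x$per_sample$floored)) {
    cat(sprintf("(%d zero-%% samples plotted at the %.2g%% log floor)\n",
                sum(x$per_sample$floored), x$log_floor_pct))
  }
  invisible(x)
}
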