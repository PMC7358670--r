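# Lymphocyte subset gating and "affected"-cell quantification.
# Subsets are assigned with 1-D thresholds (B if CD20+, else T split
# into T4/T8, else NK if CD56+, else other); the LAMP-1 and perforin
# positivity gates are anchored on the NK population, the internal
# positive control that expresses both markers in every sample.

GATED_SUBSETS <- c("B", "T4", "T8", "NK")

#' Construct a gate set
#'
#' @param cd3,cd4,cd8,cd20,cd56 Marker positivity thresholds
#'   (log-intensity units); events at/above the threshold are positive.
#' @param lamp1_gate,perforin_gate LAMP-1 and perforin gates (may be
#'   `NA` until derived with [derive_lamp1_gate()]).
#' @param lamp1_gate_source `"nk_anchored"` or `"manual"`.
#' @return List of class `gate_set`.
#' @export
gate_set <- function(cd3, cd4, cd8, cd20, cd56,
                     lamp1_gate = NA_real_, perforin_gate = NA_real_,
                     lamp1_gate_source = "manual") {
  thr <- c(cd3 = cd3, cd4 = cd4, cd8 = cd8, cd20 = cd20, cd56 = cd56)
  if (any(!is.finite(thr))) stop("marker thresholds must be finite")
  stopifnot(lamp1_gate_source %in% c("nk_anchored", "manual"))
  structure(list(cd3_threshold = cd3, cd4_threshold = cd4,
                 cd8_threshold = cd8, cd20_threshold = cd20,
                 cd56_threshold = cd56,
                 lamp1_gate = lamp1_gate, perforin_gate = perforin_gate,
                 lamp1_gate_source = lamp1_gate_source),
            class = "gate_set")
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf("gate_set: CD3 %.3g, CD4 %.3g, CD8 %.3g, CD20 %.3g, CD56 %.3g\n",
              x$cd3_threshold, x$cd4_threshold, x$cd8_threshold,
              x$cd20_threshold, x$cd56_threshold))
  cat(sprintf("  LAMP-1 gate %.3g, perforin gate %.3g (%s)\n",
              x$lamp1_gate, x$perforin_gate, x$lamp1_gate_source))
  invisible(x)
}

# One marker's positivity threshold: 2-class Otsu on the (log-scale)
# intensities discretized into 256 bins over their observed range —
# the same thresholding primitive the imaging stage uses.
marker_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) <= 0) stop("cannot threshold a constant marker")
  bins <- pmin(floor((values - rng[1]) / diff(rng) * 256), 255)
  t_bin <- otsu_threshold(bins)
  rng[1] + t_bin / 256 * diff(rng)
}

#' Derive marker positivity thresholds from the data
#'
#' Applies the shared Otsu primitive to each surface marker's
#' log-intensity histogram, placing the positive/negative threshold
#' between the two modes.
#'
#' @param events Flow event data frame with columns CD3, CD4, CD8,
#'   CD20, CD56 (plus LAMP1/PERFORIN, unused here).
#' @return A `gate_set` with marker thresholds set and LAMP-1/perforin
#'   gates unset.
#' @export
derive_marker_gates <- function(events) {
  need <- c("CD3", "CD4", "CD8", "CD20", "CD56")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  gate_set(cd3 = marker_threshold(events$CD3),
           cd4 = marker_threshold(events$CD4),
           cd8 = marker_threshold(events$CD8),
           cd20 = marker_threshold(events$CD20),
           cd56 = marker_threshold(events$CD56))
}

#' Assign lymphocyte subsets from marker intensities
#'
#' Label precedence: CD20+ events are B cells; otherwise CD3+ events
#' are T cells, split into T4 (CD4+) and T8 (CD8+); otherwise CD56+
#' events are NK cells; everything else is `other`. CD4+CD8+
#' double-positive T cells are assigned to the marker with the larger
#' standardized excess above its threshold (ties to T4); CD4-CD8-
#' T cells are labelled `other`.
#'
#' @param events Flow event data frame with the seven named channels.
#' @param gates A `gate_set` with marker thresholds.
#' @return `events` with a `subset` column added.
#' @export
assign_subsets <- function(events, gates) {
  need <- c("CD3", "CD4", "CD8", "CD20", "CD56", "LAMP1", "PERFORIN")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))

  cd4_sd <- stats::sd(events$CD4); cd8_sd <- stats::sd(events$CD8)
  if (!is.finite(cd4_sd) || cd4_sd == 0) cd4_sd <- 1
  if (!is.finite(cd8_sd) || cd8_sd == 0) cd8_sd <- 1

  b <- events$CD20 >= gates$cd20_threshold
  t <- !b & events$CD3 >= gates$cd3_threshold
  cd4p <- events$CD4 >= gates$cd4_threshold
  cd8p <- events$CD8 >= gates$cd8_threshold
  nk <- !b & !t & events$CD56 >= gates$cd56_threshold

  subset <- rep("other", nrow(events))
  subset[b] <- "B"
  subset[t & cd4p & !cd8p] <- "T4"
  subset[t & !cd4p & cd8p] <- "T8"
  dp <- t & cd4p & cd8p
  if (any(dp)) {
    exc4 <- (events$CD4[dp] - gates$cd4_threshold) / cd4_sd
    exc8 <- (events$CD8[dp] - gates$cd8_threshold) / cd8_sd
    subset[dp] <- ifelse(exc8 > exc4, "T8", "T4")
  }
  subset[nk] <- "NK"
  events$subset <- subset
  events
}

#' Anchor LAMP-1 and perforin gates on the NK internal positive control
#'
#' NK cells express both LAMP-1 and perforin in every sample, so the
#' positivity gates are placed at a lower quantile (default the 5th
#' percentile) of the NK population's LAMP-1 and perforin
#' distributions: essentially all NK events then sit above both gates,
#' and the gates transfer to the other subsets of the same sample.
#'
#' @param events Labelled events (from [assign_subsets()]).
#' @param gates A `gate_set` to update.
#' @param quantile Lower NK quantile used as the gate (default 0.05).
#'   The lower empirical quantile (inverse ECDF) is used, so at least
#'   `1 - quantile` of NK events are at/above each gate by construction.
#' @param min_nk Minimum number of NK events required (default 50).
#' @return The updated `gate_set` with `lamp1_gate_source =
#'   "nk_anchored"`.
#' @export
derive_lamp1_gate <- function(events, gates, quantile = 0.05, min_nk = 50L) {
  if (is.null(events$subset)) stop("events are not labelled; run assign_subsets first")
  nk <- events[events$subset == "NK", ]
  if (nrow(nk) < min_nk) {
    stop("only ", nrow(nk), " NK events (minimum ", min_nk,
         "); supply manual LAMP-1/perforin gates instead")
  }
  # lower empirical quantile (inverse ECDF, type 1): guarantees that at
  # least a (1 - quantile) share of NK events sits at/above the gate
  gates$lamp1_gate <- unname(stats::quantile(nk$LAMP1, quantile, type = 1))
  gates$perforin_gate <- unname(stats::quantile(nk$PERFORIN, quantile, type = 1))
  gates$lamp1_gate_source <- "nk_anchored"
  gates
}

#' Per-subset fractions of affected (LAMP-1+ perforin-) cells
#'
#' An event is "affected" (lysosomal storage) when its LAMP-1 is at or
#' above the LAMP-1 gate AND its perforin is below the perforin gate;
#' LAMP-1-high perforin-high events indicate cytotoxic activation, not
#' storage, and are excluded. The NK row is reported but flagged: it
#' is the positive-control population, not a readout.
#'
#' @param events Labelled events.
#' @param gates A `gate_set` with finalized LAMP-1/perforin gates.
#' @param sample_id Optional identifier carried into the report.
#' @return Data frame of class `subset_report`: one row per subset
#'   (B, T4, T8, NK) with `n_events`, `n_affected`, `pct_affected`
#'   (`NA` for empty subsets) and `is_control_population`.
#' @export
affected_fractions <- function(events, gates, sample_id = NA_character_) {
  if (is.null(events$subset)) stop("events are not labelled; run assign_subsets first")
  if (!is.finite(gates$lamp1_gate) || !is.finite(gates$perforin_gate)) {
    stop("LAMP-1/perforin gates not set; run derive_lamp1_gate or set manually")
  }
  affected <- events$LAMP1 >= gates$lamp1_gate &
    events$PERFORIN < gates$perforin_gate
  out <- do.call(rbind, lapply(GATED_SUBSETS, function(sub) {
    idx <- events$subset == sub
    n <- sum(idx)
    n_aff <- sum(affected & idx)
    data.frame(sample_id = sample_id, subset = sub, n_events = n,
               n_affected = n_aff,
               pct_affected = if (n > 0) 100 * n_aff / n else NA_real_,
               is_control_population = sub == "NK",
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("subset_report", "data.frame")
  out
}

#' Gate one flow sample end to end
#'
#' Convenience wrapper: derives marker gates, assigns subsets, anchors
#' the LAMP-1/perforin gates on NK cells, and reports per-subset
#' affected fractions.
#'
#' @inheritParams derive_lamp1_gate
#' @inheritParams affected_fractions
#' @param events Flow event data frame (seven named channels).
#' @return List: `report` (`subset_report`), `gates` (`gate_set`),
#'   `events` (labelled).
#' @export
gate_sample <- function(events, quantile = 0.05, min_nk = 50L,
                        sample_id = NA_character_) {
  gates <- derive_marker_gates(events)
  labelled <- assign_subsets(events, gates)
  gates <- derive_lamp1_gate(labelled, gates, quantile = quantile,
                             min_nk = min_nk)
  list(report = affected_fractions(labelled, gates, sample_id = sample_id),
       gates = gates, events = labelled)
}
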