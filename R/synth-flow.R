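# Synthetic flow-cytometry events for the seven-marker lymphocyte
# panel (CD3, CD4, CD8, CD20, CD56, LAMP1, PERFORIN).
#
# Fluorescence is modelled on a log scale with Gaussian
# class-conditional components: marker-negative events around 1.0
# (SD 0.3), marker-positive events around 4.5 (SD 0.35). LAMP-1 has
# three components: unaffected cytoplasmic background (1.5, SD 0.3),
# the NK lysosomal/cytotoxic compartment (3.5, SD 0.4) and the storage
# ("affected") compartment (4.0, SD 0.4). NK cells are always drawn
# LAMP-1-high AND perforin-high: they are the internal positive
# control the gating stage anchors its thresholds on.

FLOW_CHANNELS <- c("CD3", "CD4", "CD8", "CD20", "CD56", "LAMP1", "PERFORIN")

flow_intensity_model <- function() {
  list(neg = c(mean = 1.0, sd = 0.30),
       pos = c(mean = 4.5, sd = 0.35),
       lamp_unaffected = c(mean = 1.5, sd = 0.30),
       lamp_nk = c(mean = 3.5, sd = 0.40),
       lamp_affected = c(mean = 4.0, sd = 0.40),
       perforin_nk = c(mean = 4.0, sd = 0.40))
}

#' Generate a synthetic flow-cytometry sample
#'
#' Draws `n_events` events from the seven-marker lymphocyte panel with
#' the subset mixture and per-subset affected fractions implied by the
#' configuration and severity class. Ground-truth subset labels and
#' affected flags are carried along so gating recovery can be measured.
#'
#' @param class_label Severity class of the sample donor.
#' @param n_events Number of events (>= 1).
#' @param config A [cohort_config()]; supplies subset proportions, LAMP
#'   shifts and the baseline affected rate.
#' @param seed Integer seed.
#' @return Data frame with one row per event: the seven marker channels
#'   (log-scale intensities), `true_subset` in
#'   `{B, T4, T8, NK, other}` and logical `true_affected`.
#' @export
#' @examples
#' ev <- generate_flow_sample("classical", 1000, cohort_config(), seed = 3)
#' table(ev$true_subset)
generate_flow_sample <- function(class_label, n_events, config = cohort_config(),
                                 seed = NULL) {
  severity_rank(class_label)  # validates
  if (length(class_label) != 1L) stop("class_label must be a single class")
  if (n_events < 1) stop("n_events must be >= 1")
  if (!class_label %in% rownames(config$lamp_shift_by_class_and_subset)) {
    stop("no LAMP shift row for class ", class_label)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  m <- flow_intensity_model()
  props <- config$subset_proportions
  subsets <- sample(names(props), n_events, replace = TRUE, prob = props)

  draw <- function(n, comp) stats::rnorm(n, m[[comp]]["mean"], m[[comp]]["sd"])
  n <- n_events
  ev <- data.frame(
    CD3 = draw(n, "neg"), CD4 = draw(n, "neg"), CD8 = draw(n, "neg"),
    CD20 = draw(n, "neg"), CD56 = draw(n, "neg"),
    LAMP1 = draw(n, "lamp_unaffected"), PERFORIN = draw(n, "neg"),
    true_subset = subsets, true_affected = FALSE,
    stringsAsFactors = FALSE)

  is_t <- subsets %in% c("T4", "T8")
  ev$CD3[is_t] <- draw(sum(is_t), "pos")
  ev$CD4[subsets == "T4"] <- draw(sum(subsets == "T4"), "pos")
  ev$CD8[subsets == "T8"] <- draw(sum(subsets == "T8"), "pos")
  ev$CD20[subsets == "B"] <- draw(sum(subsets == "B"), "pos")
  ev$CD56[subsets == "NK"] <- draw(sum(subsets == "NK"), "pos")

  # NK internal positive control: elevated LAMP-1 and perforin, never
  # counted as "affected" (storage) truth.
  nk <- subsets == "NK"
  ev$LAMP1[nk] <- draw(sum(nk), "lamp_nk")
  ev$PERFORIN[nk] <- draw(sum(nk), "perforin_nk")

  # Storage-affected cells in the gated subsets: LAMP-1 from the
  # affected compartment, perforin stays negative.
  for (sub in c("T4", "T8", "B")) {
    idx <- which(subsets == sub)
    if (!length(idx)) next
    p_aff <- affected_prob(config, class_label, sub)
    aff <- idx[stats::runif(length(idx)) < p_aff]
    ev$true_affected[aff] <- TRUE
    ev$LAMP1[aff] <- draw(length(aff), "lamp_affected")
  }
  ev
}
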