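# Synthetic single-cell image pairs mimicking channel-separated 8-bit
# ImageStream exports: a surface CD4 channel (bright disk on dark
# background) used for segmentation, and an intracellular LAMP-1
# channel. In affected cells LAMP-1 concentrates at vacuole membranes,
# rendered as bright rings around the (dark) vacuole lumina scattered
# through the cytoplasm; control cells show only diffuse low signal.

clamp8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0; x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Generate a synthetic two-channel single-cell image
#'
#' Renders an 8-bit CD4/LAMP-1 image pair with known ground truth: the
#' cell is a disk of radius `cell_radius` centred in the frame; the
#' LAMP-1 channel carries a uniform cytoplasmic baseline plus
#' `n_vacuoles` bright membrane rings at random non-overlapping
#' positions inside the cytoplasm. Gaussian read noise is added to
#' both channels and clipped to 0..255.
#'
#' @param class_label Severity class; controls the default cytoplasmic
#'   LAMP-1 baseline (elevated in affected classes, reflecting the
#'   globally enlarged lysosomal compartment).
#' @param n_vacuoles Number of vacuole rings (>= 0). Vacuoles that
#'   cannot be placed inside the cell disk raise an error.
#' @param image_size Side length in pixels (square frame, >= 32).
#' @param seed Integer seed.
#' @param cell_radius Cell disk radius in px (default 40% of frame).
#' @param noise_sd Gaussian read-noise SD in intensity levels
#'   (default 8); 0 gives a noiseless image.
#' @param cd4_intensity,background_intensity CD4 disk and background
#'   levels.
#' @param cytoplasm_intensity LAMP-1 cytoplasm baseline; `NULL` picks
#'   the class default (40 for control/carrier, 90 otherwise — the
#'   lysosomal compartment is globally enlarged in every affected-class
#'   cell, not only in vacuolated ones).
#' @param texture_sd Per-pixel SD of the granular cytoplasmic LAMP-1
#'   signal (punctate lysosomal staining); `NULL` picks the class
#'   default (10 for control/carrier, 30 otherwise). Texture is part of
#'   the rendered signal and enters `true_mean_lamp1`; set 0 for a
#'   uniform cytoplasm.
#' @param ring_intensity LAMP-1 level at vacuole membranes (default 220).
#' @param vacuole_radius Vacuole lumen radius in px (default 3).
#' @return A list of class `cell_image_pair`: `cd4_channel` and
#'   `lamp1_channel` (integer matrices 0..255), `true_mask` (logical
#'   matrix), `true_mean_lamp1` (mean of the noiseless LAMP-1 signal
#'   over the true mask), `cell_id`, `class_label`, `n_vacuoles`.
#' @export
#' @examples
#' img <- generate_cell_image("classical", n_vacuoles = 10, seed = 1)
#' img$true_mean_lamp1
generate_cell_image <- function(class_label, n_vacuoles,
                                image_size = 64L, seed = NULL,
                                cell_radius = round(0.4 * image_size),
                                noise_sd = 8,
                                cd4_intensity = 180,
                                background_intensity = 20,
                                cytoplasm_intensity = NULL,
                                texture_sd = NULL,
                                ring_intensity = 220,
                                vacuole_radius = 3) {
  severity_rank(class_label)
  if (n_vacuoles < 0) stop("n_vacuoles must be >= 0")
  if (image_size < 32) stop("image_size must be >= 32")
  if (!is.null(seed)) set.seed(as.integer(seed))
  unaffected <- class_label %in% c("control", "carrier")
  if (is.null(cytoplasm_intensity)) {
    cytoplasm_intensity <- if (unaffected) 40 else 90
  }
  if (is.null(texture_sd)) texture_sd <- if (unaffected) 10 else 30

  n <- as.integer(image_size)
  cx <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)         # row index
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d2 <- (rr - cx)^2 + (cc - cx)^2
  mask <- d2 <= cell_radius^2

  cd4 <- matrix(background_intensity, n, n)
  cd4[mask] <- cd4_intensity
  lamp <- matrix(0, n, n)
  lamp[mask] <- pmax(cytoplasm_intensity +
                       stats::rnorm(sum(mask), 0, texture_sd), 0)

  # place vacuoles: centres inside the cytoplasm, rings must fit inside
  # the cell disk and not overlap an already-placed vacuole
  max_c <- cell_radius - vacuole_radius - 2
  if (n_vacuoles > 0 && max_c <= 0) {
    stop("vacuoles of radius ", vacuole_radius,
         " cannot fit inside a cell of radius ", cell_radius)
  }
  centres <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centres) < n_vacuoles) {
    tries <- tries + 1L
    if (tries > 200L * max(n_vacuoles, 1L)) {
      stop(n_vacuoles, " vacuoles of radius ", vacuole_radius,
           " cannot be placed without overlap inside a cell of radius ",
           cell_radius)
    }
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * max_c
    cand <- c(cx + rad * cos(ang), cx + rad * sin(ang))
    if (nrow(centres) == 0 ||
        all(sqrt(rowSums(sweep(centres, 2, cand)^2)) > 2 * vacuole_radius + 1)) {
      centres <- rbind(centres, cand)
      vd2 <- (rr - cand[1])^2 + (cc - cand[2])^2
      lumen <- vd2 <= (vacuole_radius - 1)^2
      ring <- vd2 <= (vacuole_radius + 1)^2 & !lumen
      lamp[ring & mask] <- ring_intensity
      lamp[lumen & mask] <- 0.3 * cytoplasm_intensity  # dark lumen
    }
  }

  true_mean <- mean(lamp[mask])
  if (noise_sd > 0) {
    cd4 <- cd4 + stats::rnorm(n * n, 0, noise_sd)
    lamp <- lamp + stats::rnorm(n * n, 0, noise_sd)
  }
  structure(list(
    cd4_channel = clamp8(cd4), lamp1_channel = clamp8(lamp),
    true_mask = mask, true_mean_lamp1 = true_mean,
    cell_id = sprintf("cell_%08x",
                      as.integer(stats::runif(1, 0, 2^30))),
    class_label = class_label, n_vacuoles = as.integer(n_vacuoles)
  ), class = "cell_image_pair")
}

#' Generate a batch of synthetic cell images for one severity class
#'
#' Vacuole numbers are drawn from the class's configured per-cell
#' distribution for vacuolated cells; a `1 - vac_fraction` share of
#' cells carries no vacuoles (class-level heterogeneity: only a
#' proportion of lymphocytes is vacuolated even in classical disease).
#'
#' @param class_label Severity class.
#' @param n_cells Number of cells.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param ... Passed to [generate_cell_image()].
#' @return List of `cell_image_pair` objects.
#' @export
generate_cell_images <- function(class_label, n_cells,
                                 config = cohort_config(), seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p_vac <- config$vac_fraction_by_class[[class_label]]
  vdist <- config$vacuoles_per_cell_dist_by_class[[class_label]]
  lapply(seq_len(n_cells), function(i) {
    nv <- if (stats::runif(1) < p_vac) draw_vacuole_counts(1L, vdist) else 0L
    img <- generate_cell_image(class_label, n_vacuoles = nv, ...)
    img$cell_id <- sprintf("%s_%04d", class_label, i)
    img
  })
}

#' @export
print.cell_image_pair <- function(x, ...) {
  cat(sprintf("cell_image_pair %s (%s): %dx%d px, %d vacuoles, true mean LAMP-1 %.2f\n",
              x$cell_id, x$class_label, nrow(x$cd4_channel),
              ncol(x$cd4_channel), x$n_vacuoles, x$true_mean_lamp1))
  invisible(x)
}
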