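# Per-cell LAMP-1 image quantification: Otsu whole-cell masks from the
# surface CD4 channel, mean LAMP-1 per cell, and the per-cell
# "sliding threshold" curve giving, for each 8-bit level k, the
# percentage of masked cell area with LAMP-1 intensity >= k.

#' Otsu threshold of an 8-bit intensity sample
#'
#' Returns the intensity level maximizing the between-class variance of
#' the 256-bin histogram (Otsu's method). Pixels `< t` form the
#' background class and pixels `>= t` the foreground, for candidate
#' thresholds t = 1..255. Ties are broken toward the lowest maximizing
#' level, making the result deterministic.
#'
#' @param pixels Integer vector/matrix of intensities in 0..255 with at
#'   least two distinct values (a constant image has no threshold).
#' @return Integer threshold in 1..255; pixels `>= t` are foreground.
#' @export
#' @examples
#' otsu_threshold(c(0, 0, 0, 255, 255, 255))  # 1: any split works
otsu_threshold <- function(pixels) {
  v <- as.integer(pixels)
  if (any(v < 0 | v > 255, na.rm = TRUE) || anyNA(v)) {
    stop("pixels must be integers in 0..255")
  }
  if (length(unique(v)) < 2L) stop("constant image: no Otsu threshold exists")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  levels <- 0:255
  w0 <- cumsum(h)                     # background count for t = level+1
  s0 <- cumsum(h * levels)            # background intensity sum
  total <- s0[256]
  # candidate thresholds t = 1..255 split at level t: bg = {0..t-1}
  w0 <- w0[1:255]; s0 <- s0[1:255]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0 / w0
  mu1 <- (total - s0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2      # between-class variance * n^2
  bcv[!valid] <- -Inf
  which.max(bcv)                      # lowest argmax; threshold t in 1..255
}

#' Segment a whole-cell mask from the CD4 channel
#'
#' Thresholds the surface CD4 channel with [otsu_threshold()], keeps
#' the largest 8-connected foreground component and fills interior
#' holes. The LAMP-1 channel never influences segmentation, so LAMP-1
#' statistics cannot be circular.
#'
#' @param image A `cell_image_pair` (or any list with a `cd4_channel`
#'   integer matrix).
#' @return List of class `cell_mask`: `mask` (logical matrix),
#'   `area_px`, `otsu_threshold`, `source_channel = "CD4"`.
#' @export
segment_cell <- function(image) {
  cd4 <- image$cd4_channel
  if (is.null(cd4)) stop("image has no cd4_channel")
  thr <- otsu_threshold(cd4)
  fg <- cd4 >= thr
  if (!any(fg)) stop("empty foreground after thresholding")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  comp <- lab == keep
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
  structure(list(mask = filled, area_px = sum(filled),
                 otsu_threshold = as.integer(thr),
                 source_channel = "CD4"),
            class = "cell_mask")
}

#' Quantify per-cell LAMP-1 inside a whole-cell mask
#'
#' Computes the mean LAMP-1 intensity over masked pixels and the
#' sliding-threshold curve: for every 8-bit level k = 0..255, the
#' percentage of masked cell area with LAMP-1 intensity equal to or
#' above k. By construction `pct_at_level[k = 0] = 100`, the curve is
#' monotone non-increasing, and
#' `sum(pct_at_level[k], k = 1..255) / 100 = mean_lamp1` exactly
#' (each pixel of intensity v contributes to exactly v levels >= 1).
#'
#' @param image A `cell_image_pair`.
#' @param mask A `cell_mask` from [segment_cell()] (or any list with a
#'   logical `mask` matching the image shape).
#' @return List of class `cell_quant`: `cell_id`, `class_label`,
#'   `mean_lamp1`, `area_px`, and `pct_at_level` (numeric length 256,
#'   index k+1 = level k).
#' @export
#' @examples
#' img <- generate_cell_image("control", 0, seed = 1, noise_sd = 0)
#' q <- quantify_cell(img, segment_cell(img))
#' q$mean_lamp1
quantify_cell <- function(image, mask) {
  m <- mask$mask
  if (is.null(m)) m <- mask
  if (!identical(dim(m), dim(image$lamp1_channel))) {
    stop("mask and LAMP-1 channel shapes differ: ",
         paste(dim(m), collapse = "x"), " vs ",
         paste(dim(image$lamp1_channel), collapse = "x"))
  }
  px <- as.integer(image$lamp1_channel[m])
  area <- length(px)
  if (area == 0L) stop("empty mask")
  # pct_at_level[k+1] = 100 * #{px >= k} / area via the intensity histogram
  h <- tabulate(px + 1L, nbins = 256L)
  n_ge <- rev(cumsum(rev(h)))        # n_ge[k+1] = #{px >= k}
  structure(list(cell_id = image$cell_id,
                 class_label = image$class_label,
                 mean_lamp1 = mean(px), area_px = area,
                 pct_at_level = 100 * n_ge / area),
            class = "cell_quant")
}

#' Segment and quantify a batch of cell images
#'
#' @param images List of `cell_image_pair` objects.
#' @return List of `cell_quant` objects.
#' @export
quantify_cells <- function(images) {
  lapply(images, function(img) quantify_cell(img, segment_cell(img)))
}

#' Population percentile bands of sliding-threshold curves
#'
#' At every intensity level, computes the median, interquartile range
#' (25th-75th percentile) and the 2.5th-97.5th percentile range of the
#' per-cell sliding-threshold curves, i.e. the banded population
#' distribution of LAMP-1 expression. Quantiles use the
#' linear-interpolation definition (R type 7).
#'
#' @param quants List of `cell_quant` objects (or a list of numeric
#'   length-256 curves).
#' @return Data frame of class `population_bands`: `level` (0..255),
#'   `p2_5`, `q25`, `median`, `q75`, `p97_5`, attribute `n_cells`.
#' @export
population_bands <- function(quants) {
  if (length(quants) < 1L) stop("need at least one curve")
  curves <- lapply(quants, function(q) if (is.list(q)) q$pct_at_level else q)
  mat <- do.call(rbind, curves)       # cells x 256
  qs <- apply(mat, 2, stats::quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7)
  out <- data.frame(level = 0:255, p2_5 = qs[1, ], q25 = qs[2, ],
                    median = qs[3, ], q75 = qs[4, ], p97_5 = qs[5, ])
  attr(out, "n_cells") <- nrow(mat)
  class(out) <- c("population_bands", "data.frame")
  out
}

#' Per-class summary of per-cell mean LAMP-1
#'
#' Reports, per severity class, the number of cells, the mean of
#' per-cell mean LAMP-1 ("mean of means") and the 10th-90th deciles of
#' the per-cell means (linear-interpolation quantiles).
#'
#' @param quants_by_class Named list (class label -> list of
#'   `cell_quant`).
#' @return Data frame: one row per class with `n_cells`,
#'   `mean_of_means`, and decile columns `d10`..`d90`.
#' @export
compare_classes <- function(quants_by_class) {
  if (!length(quants_by_class)) stop("no classes to compare")
  out <- do.call(rbind, lapply(names(quants_by_class), function(cl) {
    means <- vapply(quants_by_class[[cl]], function(q) q$mean_lamp1, 0)
    if (!length(means)) stop("class ", cl, " has no cells")
    dec <- stats::quantile(means, probs = seq(0.1, 0.9, 0.1), type = 7)
    row <- data.frame(class = cl, n_cells = length(means),
                      mean_of_means = mean(means))
    row[paste0("d", seq(10, 90, 10))] <- as.list(unname(dec))
    row
  }))
  rownames(out) <- NULL
  out
}
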