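test_that("Otsu threshold matches its definition on canonical inputs", {
  # perfectly bimodal: every split separates; tie broken to lowest level
  expect_identical(otsu_threshold(c(0, 0, 0, 255, 255, 255)), 1L)
  # two tight modes: threshold falls in the valley
  thr <- otsu_threshold(c(rep(10, 50), rep(200, 50)))
  expect_gt(thr, 10)
  expect_lte(thr, 200)
  expect_error(otsu_threshold(rep(7, 100)), "constant image")
  expect_error(otsu_threshold(c(-1, 5)), "0\\.\\.255")
})

test_that("Otsu equals the exhaustive between-class-variance argmax", {
  set.seed(424)
  for (i in 1:100) {
    n <- sample(20:400, 1)
    v <- switch(sample(3, 1),
                sample(0:255, n, replace = TRUE),
                pmin(pmax(round(c(rnorm(n / 2, 60, 20),
                                  rnorm(n / 2, 180, 25))), 0), 255),
                sample(c(0:10, 250:255), n, replace = TRUE))
    if (length(unique(v)) < 2) next
    expect_identical(otsu_threshold(v), otsu_brute_force(v),
                     info = paste("case", i))
  }
})

test_that("segmentation recovers the true mask and keeps the largest component", {
  img <- generate_cell_image("classical", 8, seed = 4, noise_sd = 0)
  m <- segment_cell(img)
  expect_identical(m$mask, img$true_mask)
  expect_equal(m$area_px, sum(img$true_mask))
  expect_identical(m$source_channel, "CD4")

  # two disks: only the larger is kept
  two <- matrix(10L, 64, 64)
  rr <- row(two); cc <- col(two)
  big <- (rr - 20)^2 + (cc - 20)^2 <= 12^2
  small <- (rr - 50)^2 + (cc - 50)^2 <= 5^2
  two[big | small] <- 200L
  m2 <- segment_cell(list(cd4_channel = two))
  expect_true(all(m2$mask[big]))
  expect_false(any(m2$mask[small]))

  # Otsu segmentation is invariant to a constant shift below saturation
  img_shift <- img
  img_shift$cd4_channel <- clamp8(img$cd4_channel + 40L)
  expect_identical(segment_cell(img_shift)$mask, m$mask)
})

test_that("noisy segmentation stays close to the true mask", {
  cfg <- cohort_config()
  imgs <- generate_cell_images("classical", 40, cfg, seed = 31)
  jac <- vapply(imgs, function(im) jaccard(segment_cell(im)$mask,
                                           im$true_mask), 0)
  expect_gte(mean(jac >= 0.9), 0.95)
})

test_that("per-cell quantification matches hand-computed values", {
  # uniform LAMP-1 = 100 inside the mask: step-function curve
  img <- generate_cell_image("control", 0, seed = 1, noise_sd = 0,
                             cytoplasm_intensity = 100, texture_sd = 0)
  q <- quantify_cell(img, segment_cell(img))
  expect_equal(q$mean_lamp1, 100)
  expect_true(all(q$pct_at_level[1:101] == 100))   # levels 0..100
  expect_true(all(q$pct_at_level[102:256] == 0))   # levels 101..255

  # 4-pixel mask with LAMP-1 {0, 50, 100, 150}
  tiny <- list(cd4_channel = matrix(0L, 2, 2),
               lamp1_channel = matrix(c(0L, 50L, 100L, 150L), 2, 2),
               cell_id = "tiny", class_label = "control")
  mask <- list(mask = matrix(TRUE, 2, 2))
  qt <- quantify_cell(tiny, mask)
  expect_equal(qt$mean_lamp1, 75)
  expect_equal(qt$pct_at_level[51], 75)    # level 50
  expect_equal(qt$pct_at_level[102], 25)   # level 101

  expect_error(quantify_cell(tiny, list(mask = matrix(FALSE, 2, 2))),
               "empty mask")
  expect_error(quantify_cell(tiny, list(mask = matrix(TRUE, 3, 3))),
               "shapes differ")
})

test_that("sliding-threshold curves satisfy their invariants on generated cells", {
  cfg <- cohort_config()
  imgs <- c(generate_cell_images("control", 15, cfg, seed = 51),
            generate_cell_images("classical", 15, cfg, seed = 52))
  for (im in imgs) {
    q <- quantify_cell(im, segment_cell(im))
    expect_equal(q$pct_at_level[1], 100)
    expect_true(all(diff(q$pct_at_level) <= 0))
    expect_true(all(q$pct_at_level >= 0 & q$pct_at_level <= 100))
    # self-consistency: the curve integrates to the mean intensity
    expect_equal(sum(q$pct_at_level[2:256]) / 100, q$mean_lamp1,
                 tolerance = 1e-12)
  }
})

test_that("population bands are ordered and degenerate correctly", {
  cfg <- cohort_config()
  qs <- quantify_cells(generate_cell_images("classical", 12, cfg, seed = 61))
  b <- population_bands(qs)
  expect_true(all(b$p2_5 <= b$q25 & b$q25 <= b$median &
                    b$median <= b$q75 & b$q75 <= b$p97_5))
  # one curve: every band equals that curve
  b1 <- population_bands(qs[1])
  expect_equal(b1$median, qs[[1]]$pct_at_level)
  expect_equal(b1$p2_5, qs[[1]]$pct_at_level)
  # identical curves: zero-width bands
  bN <- population_bands(rep(qs[1], 8))
  expect_equal(bN$p97_5 - bN$p2_5, rep(0, 256))
  expect_error(population_bands(list()), "at least one curve")

  # classical median band dominates control at mid-range levels
  qc <- quantify_cells(generate_cell_images("control", 12, cfg, seed = 62))
  bc <- population_bands(qc)
  lev <- 51:151  # levels 50..150
  expect_true(all(b$median[lev] > bc$median[lev]))
})

test_that("class comparison reports deciles of per-cell means", {
  mk <- function(m) list(cell_id = "x", class_label = "y",
                         mean_lamp1 = m, area_px = 1L)
  cmp <- compare_classes(list(a = lapply(1:10, mk)))
  # linear-interpolation deciles of 1..10: 1 + 9 p
  expect_equal(unlist(cmp[paste0("d", seq(10, 90, 10))], use.names = FALSE),
               1 + 9 * seq(0.1, 0.9, 0.1))
  expect_equal(cmp$mean_of_means, 5.5)
  one <- compare_classes(list(a = list(mk(42))))
  expect_true(all(one[paste0("d", seq(10, 90, 10))] == 42))

  cfg <- cohort_config()
  qa <- quantify_cells(generate_cell_images("classical", 10, cfg, seed = 71))
  qb <- quantify_cells(generate_cell_images("control", 10, cfg, seed = 72))
  both <- compare_classes(list(classical = qa, control = qb))
  expect_gt(both$mean_of_means[both$class == "classical"],
            both$mean_of_means[both$class == "control"])
  expect_error(compare_classes(list()), "no classes")
})
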