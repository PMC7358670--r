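test_that("zero-noise cohort collapses to exact analytic counts", {
  cfg <- cohort_config(
    n_patients_per_class = c(classical = 5),
    vac_fraction_by_class = c(classical = 0.30),
    samples_per_patient = c(2L, 2L),
    random_intercept_sd = 0, random_slope_sd = 0, observer_sd = 0,
    seed = 42L)
  co <- generate_cohort(cfg)
  expect_true(all(co$observations$n_vacuolated == 30L))
  expect_true(all(co$observations$n_counted == 100L))
  # every characterized cell at the class median of 10 vacuoles
  pooled <- unlist(lapply(co$observations$vacuole_counts,
                          function(x) as.integer(strsplit(x, ";")[[1]])))
  expect_true(all(pooled == 10L))
})

test_that("default classical vacuolization is consistent with 11-69% (median 30%)", {
  cfg <- cohort_config(n_patients_per_class = c(classical = 30),
                       samples_per_patient = c(1L, 2L), seed = 7L)
  co <- generate_cohort(cfg)
  pct <- 100 * co$observations$n_vacuolated / co$observations$n_counted
  expect_gt(median(pct), 11)
  expect_lt(median(pct), 69)
  # central mass near the configured 30% class mean
  expect_lt(abs(median(pct) - 30), 8)
  expect_gt(mean(pct >= 11 & pct <= 69), 0.9)
})

test_that("between-patient variance of logit fractions matches the random-intercept SD", {
  cfg <- cohort_config(n_patients_per_class = c(classical = 200),
                       samples_per_patient = c(1L, 1L),
                       random_slope_sd = 0, age_slope_true = 0,
                       seed = 99L)
  co <- generate_cohort(cfg)
  one_per_patient <- co$observations[!duplicated(co$observations$patient_id), ]
  lg <- qlogis(one_per_patient$true_fraction)
  expect_lt(abs(var(lg) - cfg$random_intercept_sd^2),
            0.15 * cfg$random_intercept_sd^2)
})

test_that("cohort configuration rejects invalid inputs", {
  expect_error(cohort_config(n_patients_per_class = integer(0)),
               "at least one severity class")
  expect_error(cohort_config(observer_sd = -1), "negative SD")
  expect_error(cohort_config(random_intercept_sd = -0.1), "negative SD")
  expect_error(cohort_config(vac_fraction_by_class = c(classical = 1.2)),
               "\\[0, 1\\]")
})

test_that("flow generator enforces bounds and class structure", {
  cfg <- cohort_config()
  expect_error(generate_flow_sample("classical", 0, cfg), "n_events")
  expect_error(generate_flow_sample("narnia", 10, cfg), "unknown severity class")

  ev <- generate_flow_sample("classical", 4000, cfg, seed = 3)
  expect_true(all(table(ev$true_subset) > 0))
  expect_false(any(ev$true_affected[ev$true_subset %in% c("NK", "other")]))
  # NK internal positive control: elevated LAMP-1 AND perforin
  nk <- ev$true_subset == "NK"
  expect_gt(mean(ev$LAMP1[nk]), mean(ev$LAMP1[!nk & !ev$true_affected]) + 1)
  expect_gt(mean(ev$PERFORIN[nk]), mean(ev$PERFORIN[!nk]) + 1)
  # classical shifts LAMP-1 up among non-NK events relative to control
  ctrl <- generate_flow_sample("control", 4000, cfg, seed = 3)
  expect_gt(mean(ev$LAMP1[!nk]), mean(ctrl$LAMP1[ctrl$true_subset != "NK"]))
})

test_that("zero LAMP shift reproduces the baseline affected rate", {
  cfg <- cohort_config(baseline_affected_rate = 0.02)
  ev <- generate_flow_sample("control", 30000, cfg, seed = 11)
  for (sub in c("T4", "T8", "B")) {
    idx <- ev$true_subset == sub
    p_hat <- mean(ev$true_affected[idx])
    se <- sqrt(0.02 * 0.98 / sum(idx))
    expect_lt(abs(p_hat - 0.02), 4 * se)
  }
})

test_that("retina-only class shifts the B compartment most", {
  cfg <- cohort_config()
  sh <- cfg$lamp_shift_by_class_and_subset
  expect_gt(sh["retina_only", "B"], sh["retina_only", "T4"])
  expect_gt(sh["retina_only", "B"], max(sh[, c("T4", "T8")]))
  # class-ordered monotonicity of the T-cell affected probability
  # (retina_only excepted: its T shift is ~0 by design)
  classes <- c("control", "carrier", "protracted", "delayed_classical",
               "classical")
  p_t4 <- vapply(classes, function(cl)
    lymphovac:::affected_prob(cfg, cl, "T4"), 0)
  expect_true(all(diff(p_t4) > 0))
  vf <- cfg$vac_fraction_by_class[severity_levels()]
  expect_true(all(diff(vf) > 0))
})

test_that("cell image generator honours its ground-truth contract", {
  img0 <- generate_cell_image("control", 0, seed = 1, noise_sd = 0,
                              cytoplasm_intensity = 57, texture_sd = 0)
  expect_equal(img0$true_mean_lamp1, 57)
  expect_true(all(img0$lamp1_channel[img0$true_mask] == 57))
  expect_identical(dim(img0$cd4_channel), dim(img0$lamp1_channel))
  expect_true(all(img0$cd4_channel >= 0 & img0$cd4_channel <= 255))

  img10 <- generate_cell_image("classical", 10, seed = 2, noise_sd = 0,
                               cytoplasm_intensity = 57, texture_sd = 0)
  expect_gt(img10$true_mean_lamp1, img0$true_mean_lamp1)
  expect_error(generate_cell_image("classical", -1), "n_vacuoles")
  expect_error(generate_cell_image("classical", 5, image_size = 16),
               "image_size")
  # vacuoles that cannot fit inside the cell disk
  expect_error(generate_cell_image("classical", 5, image_size = 32,
                                   cell_radius = 4, vacuole_radius = 3),
               "cannot")
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_config(seed = 17L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_identical(generate_flow_sample("classical", 500, cfg, seed = 5),
                   generate_flow_sample("classical", 500, cfg, seed = 5))
  a <- generate_cell_images("classical", 10, cfg, seed = 9)
  b <- generate_cell_images("classical", 10, cfg, seed = 9)
  expect_identical(a, b)
})
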