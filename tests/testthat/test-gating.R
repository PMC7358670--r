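# Hand-set gates used by the rule tests: positive above 2.5 on every
# marker.
manual_gates <- function() gate_set(cd3 = 2.5, cd4 = 2.5, cd8 = 2.5,
                                    cd20 = 2.5, cd56 = 2.5)

one_event <- function(CD3 = 1, CD4 = 1, CD8 = 1, CD20 = 1, CD56 = 1,
                      LAMP1 = 1, PERFORIN = 1) {
  data.frame(CD3 = CD3, CD4 = CD4, CD8 = CD8, CD20 = CD20, CD56 = CD56,
             LAMP1 = LAMP1, PERFORIN = PERFORIN)
}

test_that("subset precedence follows the marker rules", {
  g <- manual_gates()
  expect_identical(assign_subsets(one_event(CD20 = 4), g)$subset, "B")
  expect_identical(assign_subsets(one_event(CD3 = 4, CD4 = 4), g)$subset, "T4")
  expect_identical(assign_subsets(one_event(CD3 = 4, CD8 = 4), g)$subset, "T8")
  expect_identical(assign_subsets(one_event(CD56 = 4), g)$subset, "NK")
  expect_identical(assign_subsets(one_event(), g)$subset, "other")
  # B takes precedence over T and NK markers
  expect_identical(assign_subsets(one_event(CD20 = 4, CD3 = 4, CD56 = 4),
                                  g)$subset, "B")
  # CD3+ CD56+ is a T cell, not NK
  expect_identical(assign_subsets(one_event(CD3 = 4, CD4 = 4, CD56 = 4),
                                  g)$subset, "T4")
  expect_error(assign_subsets(one_event()[-1], g), "missing channel")
})

test_that("CD4+CD8+ double positives go to the larger standardized excess, ties to T4", {
  g <- manual_gates()
  ev <- rbind(one_event(CD3 = 4, CD4 = 5.0, CD8 = 3.0),
              one_event(CD3 = 4, CD4 = 3.0, CD8 = 5.0),
              one_event(CD3 = 4, CD4 = 4.0, CD8 = 4.0))
  # several events so marker SDs are defined; equal spread on CD4/CD8
  lab <- assign_subsets(ev, g)$subset
  expect_identical(lab, c("T4", "T8", "T4"))
})

test_that("labels partition the events", {
  cfg <- cohort_config()
  ev <- generate_flow_sample("protracted", 3000, cfg, seed = 5)
  lab <- assign_subsets(ev, derive_marker_gates(ev))
  expect_equal(nrow(lab), 3000)
  expect_true(all(lab$subset %in% c("B", "T4", "T8", "NK", "other")))
})

test_that("well-separated synthetic populations are assigned perfectly", {
  cfg <- cohort_config()
  for (cl in c("control", "classical", "retina_only")) {
    ev <- generate_flow_sample(cl, 10000, cfg, seed = 13)
    lab <- assign_subsets(ev, derive_marker_gates(ev))
    expect_identical(lab$subset, lab$true_subset)
  }
})

test_that("NK-anchored gates sit at the stated NK quantile", {
  cfg <- cohort_config()
  ev <- generate_flow_sample("classical", 8000, cfg, seed = 23)
  lab <- assign_subsets(ev, derive_marker_gates(ev))
  g <- derive_lamp1_gate(lab, derive_marker_gates(ev), quantile = 0.05)
  expect_identical(g$lamp1_gate_source, "nk_anchored")
  nk <- lab[lab$subset == "NK", ]
  expect_gte(mean(nk$LAMP1 >= g$lamp1_gate), 0.95)
  expect_gte(mean(nk$PERFORIN >= g$perforin_gate), 0.95)

  # quantile 0 is the NK minimum
  g0 <- derive_lamp1_gate(lab, derive_marker_gates(ev), quantile = 0)
  expect_equal(g0$lamp1_gate, min(nk$LAMP1))

  # too few NK events: instructive error
  few <- lab[c(which(lab$subset == "NK")[1:10],
               which(lab$subset != "NK")), ]
  expect_error(derive_lamp1_gate(few[few$subset == "NK" |
                                       few$subset == "B", ],
                                 derive_marker_gates(ev), min_nk = 50),
               "manual")
})

test_that("affected = LAMP-1 positive AND perforin negative", {
  g <- manual_gates()
  g$lamp1_gate <- 3; g$perforin_gate <- 3
  ev <- rbind(one_event(CD3 = 4, CD4 = 4, LAMP1 = 4, PERFORIN = 1),  # affected
              one_event(CD3 = 4, CD4 = 4, LAMP1 = 4, PERFORIN = 4),  # cytotoxic
              one_event(CD3 = 4, CD4 = 4, LAMP1 = 1, PERFORIN = 1))  # negative
  lab <- assign_subsets(ev, g)
  rep <- affected_fractions(lab, g)
  t4 <- rep[rep$subset == "T4", ]
  expect_equal(t4$n_events, 3L)
  expect_equal(t4$n_affected, 1L)   # the perforin-high cell is excluded
  expect_equal(t4$pct_affected, 100 / 3)
  # empty subsets report NA, not 0
  expect_true(is.na(rep$pct_affected[rep$subset == "B"]))
  expect_true(rep$is_control_population[rep$subset == "NK"])
  # all events below the LAMP-1 gate: all zero
  g_hi <- g; g_hi$lamp1_gate <- 99
  expect_equal(affected_fractions(lab, g_hi)$pct_affected[
    rep$subset == "T4"], 0)
})

test_that("affected fractions are order-invariant and monotone in the gate", {
  cfg <- cohort_config()
  ev <- generate_flow_sample("classical", 6000, cfg, seed = 31)
  g <- gate_sample(ev)
  shuffled <- ev[sample(nrow(ev)), ]
  g2 <- gate_sample(shuffled)
  expect_equal(g2$report$pct_affected, g$report$pct_affected)

  raised <- g$gates; raised$lamp1_gate <- raised$lamp1_gate + 0.5
  rep_hi <- affected_fractions(g$events, raised)
  expect_true(all(rep_hi$pct_affected <= g$report$pct_affected + 1e-12))
})

test_that("affected fractions recover generator truth within binomial error", {
  cfg <- cohort_config()
  ev <- generate_flow_sample("classical", 10000, cfg, seed = 37)
  g <- gate_sample(ev)
  for (sub in c("T4", "T8", "B")) {
    idx <- ev$true_subset == sub
    p_true <- mean(ev$true_affected[idx])
    row <- g$report[g$report$subset == sub, ]
    se <- sqrt(p_true * (1 - p_true) / row$n_events)
    expect_lt(abs(row$pct_affected / 100 - p_true), 3 * se + 1e-9)
  }
})

test_that("class contrast reproduces the expected subset signature", {
  cfg <- cohort_config()
  pct <- function(cl, sub) {
    ev <- generate_flow_sample(cl, 8000, cfg, seed = 41)
    r <- gate_sample(ev)$report
    r$pct_affected[r$subset == sub]
  }
  # T-cell storage tracks severity: classical > protracted > control
  expect_gt(pct("classical", "T4"), pct("protracted", "T4"))
  expect_gt(pct("protracted", "T4"), pct("control", "T4"))
  # retina-only is maximal in the B compartment
  b_by_class <- vapply(c("control", "protracted", "classical",
                         "retina_only"), pct, 0, sub = "B")
  expect_identical(names(which.max(b_by_class)), "retina_only")
})
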