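# Sweeps and PSA runs use shortened horizons / small cohorts; the science
# is scale-free in cohort size and the checks are structural.

test_that("zero-width ranges reproduce base-case ICERs bit-for-bit", {
  pset <- fixture_pset()
  meta <- pset$uncertainty$meta
  meta$low <- meta$base
  meta$high <- meta$base
  pset$uncertainty$meta <- meta
  base <- comparison_table(
    run_strategies(pset, 62, cohort_size = 10000), digits = NA)
  sw <- one_way_sweep(c("compliance_screening", "u_gc_adv"), pset, 62,
                      cohort_size = 10000)
  vs_none <- sw[sw$comparator == "no_screening", ]
  expect_identical(
    vs_none$icer_low[match(base$strategy[-1], vs_none$strategy)],
    base$icer_vs_none[-1])
  expect_identical(vs_none$icer_low, vs_none$icer_high)
})

test_that("grouped sweep moves members together and shifts the ICER", {
  pset <- fixture_pset()
  groups <- parameter_groups(pset)
  expect_true(all(lengths(groups) >= 1))
  expect_setequal(
    groups$utility_scores,
    c("u_ec_mild", "u_ec_mod", "u_ec_sev", "u_ec_early", "u_ec_adv",
      "u_gc_lgin", "u_gc_hgin", "u_gc_early", "u_gc_adv"))
  sw <- one_way_sweep(groups$utility_scores, pset, 62,
                      strategies = fast_menu(), cohort_size = 10000)
  expect_true(all(c("icer_low", "icer_high", "upper_limit",
                    "gdp_flag") %in% names(sw)))
  expect_true(all(sw$upper_limit >= pmin(sw$icer_low, sw$icer_high)))
  expect_false(any(is.na(sw$upper_limit)))
})

test_that("a parameter outside the comparison leaves ICERs unchanged", {
  pset <- fixture_pset()
  base <- comparison_table(
    run_strategies(pset, 62, fast_menu(), cohort_size = 10000), digits = NA)
  # complication treatment cost has a vanishing footprint only if the
  # complication rate is zero; use reexamination compliance with no
  # surveillance-tier detections instead: sweep the GC-specificity with a
  # perfect test already at 1.0 (low = high = 1 after forcing the range)
  meta <- pset$uncertainty$meta
  meta[meta$id == "spec_gc", c("low", "high")] <- 1
  pset$uncertainty$meta <- meta
  sw <- one_way_sweep("spec_gc", pset, 62, fast_menu(), cohort_size = 10000)
  vs_none <- sw[sw$comparator == "no_screening", ]
  expect_equal(vs_none$icer_low, vs_none$icer_high)
  expect_equal(vs_none$icer_low[match("every_2y", vs_none$strategy)],
               base$icer_vs_none[match("every_2y", base$strategy)])
})

test_that("PSA is reproducible given a seed and joint across strategies", {
  pset <- fixture_pset()
  ps1 <- run_psa(pset, 67, fast_menu(), n_draws = 5, seed = 42,
                 cohort_size = 5000)
  ps2 <- run_psa(pset, 67, fast_menu(), n_draws = 5, seed = 42,
                 cohort_size = 5000)
  expect_identical(ps1$cost, ps2$cost)
  expect_identical(ps1$qalys, ps2$qalys)
  expect_identical(ps1$params, ps2$params)
  ps3 <- run_psa(pset, 67, fast_menu(), n_draws = 5, seed = 43,
                 cohort_size = 5000)
  expect_false(identical(ps1$cost, ps3$cost))
  expect_equal(dim(ps1$cost), c(5, 2))
})

test_that("CEAC probabilities are bounded and behave at WTP extremes", {
  pset <- fixture_pset()
  ps <- run_psa(pset, 67, fast_menu(), n_draws = 20, seed = 7,
                cohort_size = 5000)
  ce <- ceac_vs_comparator(ps, "no_screening", wtp = wtp_grid(steps = 20))
  expect_true(all(ce$probability >= 0 & ce$probability <= 1))
  # screening is always costlier here, so at WTP 0 it is never preferred
  expect_equal(ce$probability[ce$wtp == 0], 0)
  # draws all gain QALYs, so the curve is non-decreasing in WTP
  if (all(ps$qalys[, "every_2y"] > ps$qalys[, "no_screening"]))
    expect_true(all(diff(ce$probability) >= -1e-12))
  expect_error(ceac_vs_comparator(ps, "no_screening", wtp = numeric(0)),
               "empty")
  expect_error(ceac_vs_comparator(ps, "bogus"), "comparator")
})

test_that("probability-optimal curves partition the draws", {
  pset <- fixture_pset()
  ps <- run_psa(pset, 62, strategy_menu()[c("no_screening", "every_5y",
                                            "every_2y")],
                n_draws = 15, seed = 3, cohort_size = 5000)
  po <- prob_optimal(ps, wtp = wtp_grid(steps = 10))
  sums <- tapply(po$probability, po$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(po$probability >= 0 & po$probability <= 1))
})

test_that("degenerate single-strategy input gives probability one everywhere", {
  pset <- fixture_pset()
  ps <- run_psa(pset, 67, strategy_menu()["every_2y"], n_draws = 4,
                seed = 5, cohort_size = 2000)
  po <- prob_optimal(ps, wtp = c(0, 10276))
  expect_true(all(po$probability == 1))
})
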