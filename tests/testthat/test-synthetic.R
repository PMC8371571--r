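test_that("published parameter table carries the base cases and ranges", {
  tab <- default_table1_params()
  get <- function(id, col) tab$meta[tab$meta$id == id, col]
  expect_equal(get("c_endoscopy", "base"), 47.87)
  expect_equal(get("u_ec_early", "base"), 0.70)
  expect_equal(get("compliance_screening", "base"), 0.49)
  expect_equal(get("discount_rate", "low"), 0)
  expect_equal(get("discount_rate", "high"), 0.08)
  expect_equal(get("ctx_gc_early", "base"), 7548)
  # cost ranges are +/-50%
  expect_equal(get("c_endoscopy", "low"), 47.87 * 0.5)
  expect_equal(get("c_endoscopy", "high"), 47.87 * 1.5)
  expect_equal(nrow(tab$meta), 41)
})

test_that("synthetic matrices are valid, deterministic, and configurable", {
  s <- fixture_space()
  for (seed in c(1, 5, 99)) {
    m <- synth_transition_matrix(seed)
    expect_true(validate_matrix(m, s)$ok)
  }
  expect_identical(synth_transition_matrix(4), synth_transition_matrix(4))
  expect_false(identical(synth_transition_matrix(4),
                         synth_transition_matrix(5)))

  # progression_scale 0 freezes dynamics apart from cancer mortality
  m0 <- synth_transition_matrix(1, synthetic_config(1, progression_scale = 0))
  living <- setdiff(s$id, "death")
  nonadv <- living[!grepl("adv", living)]
  expect_equal(unname(diag(m0[nonadv, nonadv])), rep(1, length(nonadv)))
})

test_that("synthetic prevalence is undetected-only and sums to the cohort", {
  s <- fixture_space()
  occ <- synth_initial_prevalence(2, space = s, size = 100000)
  expect_equal(sum(occ), 100000)
  expect_true(all(occ >= 0))
  expect_equal(sum(occ[detected_states(s)]), 0)
  expect_equal(sum(occ[posttreatment_states(s)]), 0)
  expect_equal(occ[["death"]], 0)

  occ0 <- synth_initial_prevalence(
    2, synthetic_config(2, prevalence_scale = 0), s, size = 1000)
  expect_equal(occ0[["normal"]], 1000)
})

test_that("synthetic life table is monotone in age and doubles with the level", {
  lt <- synth_life_table()
  expect_equal(lt$age, 40:90)
  expect_true(all(diff(lt$qx) > 0))
  expect_true(all(lt$qx > 0 & lt$qx < 1))
  lt2 <- synth_life_table(synthetic_config(life_table_level = 0.004))
  expect_equal(lt2$qx[1] / lt$qx[1], 2, tolerance = 0.01)
})

test_that("a full synthetic set drives the pipeline end to end", {
  pset <- synthetic_parameter_set(11)
  out <- run_strategies(pset, 67, cohort_size = 20000)
  expect_equal(nrow(out), 6)
  expect_true(all(is.finite(out$qalys)), all(is.finite(out$cost)))
  tab <- comparison_table(out)
  expect_true(all(tab$icer_vs_none[-1] > 0))
})

test_that("screening gains QALYs over no screening on the synthetic set", {
  pset <- fixture_pset()
  for (age in c(42, 57, 67)) {
    out <- run_strategies(pset, age, cohort_size = 50000)
    none <- out$qalys[out$strategy == "no_screening"]
    expect_true(all(out$qalys >= none))
    # and more frequent screening gains more
    expect_true(out$qalys[out$strategy == "every_2y"] >
                  out$qalys[out$strategy == "once_per_lifetime"])
  }
})

test_that("parameter bundles round-trip through the text schema", {
  pset <- fixture_pset()
  dir <- tempfile("bundle")
  write_parameter_set(pset, dir)
  expect_true(file.exists(file.path(dir, "parameters.yaml")))
  p2 <- read_parameter_set(dir)
  expect_equal(p2$tmat, pset$tmat, tolerance = 1e-12)
  expect_equal(unname(p2$init_prev), unname(pset$init_prev),
               tolerance = 1e-12)
  expect_equal(p2$screening$treatment_compliance,
               pset$screening$treatment_compliance)
  # the reloaded bundle produces the same outcomes
  a <- run_strategies(pset, 67, fast_menu(), cohort_size = 5000)
  b <- run_strategies(p2, 67, fast_menu(), cohort_size = 5000)
  expect_equal(a$qalys, b$qalys, tolerance = 1e-9)
  expect_equal(a$cost, b$cost, tolerance = 1e-9)
})
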