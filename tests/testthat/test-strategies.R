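test_that("screening_cycles honors interval and the 40-69 eligibility window", {
  expect_equal(screening_cycles(strategy(2), 67, 23), c(0L, 2L))
  expect_equal(screening_cycles(strategy("none"), 52, 38), integer(0))
  expect_equal(screening_cycles(strategy("once"), 52, 38), 0L)
  # at mean age 62 every-10-years collapses onto once per lifetime
  expect_equal(screening_cycles(strategy(10), 62, 28),
               screening_cycles(strategy("once"), 62, 28))
  expect_equal(screening_cycles(strategy(5), 42, 48),
               seq(0L, 25L, by = 5L))
  expect_error(strategy(7), "interval")
})

test_that("strategy rows per age band match the published layout", {
  # distinct schedules per band: 40-59 all six, 60-64 five (no every-10y),
  # 65-69 three (none, once, every-2y)
  menu <- strategy_menu()
  n_distinct <- function(age) {
    keys <- vapply(menu, function(st)
      paste(screening_cycles(st, age, 90 - age), collapse = ","), "")
    length(unique(keys))
  }
  expect_equal(n_distinct(42), 6)
  expect_equal(n_distinct(47), 6)
  expect_equal(n_distinct(52), 6)
  expect_equal(n_distinct(57), 6)
  expect_equal(n_distinct(62), 5)
  expect_equal(n_distinct(67), 3)
})

test_that("shorter intervals give nested, larger cycle sets", {
  for (age in c(42, 47, 52, 57, 62, 67)) {
    c2 <- screening_cycles(strategy(2), age, 90 - age)
    c3 <- screening_cycles(strategy(3), age, 90 - age)
    c5 <- screening_cycles(strategy(5), age, 90 - age)
    c10 <- screening_cycles(strategy(10), age, 90 - age)
    expect_gte(length(c2), length(c3))
    expect_gte(length(c3), length(c5))
    expect_gte(length(c5), length(c10))
    expect_gte(length(c10), 1)
    expect_true(all(c10 %in% c5))
  }
})

test_that("a perfect test detects all undetected mass with no false positives", {
  space <- fixture_space()
  params <- screening_params(compliance_screening = 1, sens_ec = 1,
                             spec_ec = 1, sens_gc = 1, spec_gc = 1)
  econ <- econ_params()
  occ <- unit_occ(space, "normal", 500)
  occ[undetected_states(space)] <- 100
  res <- apply_screening_event(occ, params, econ, space)
  expect_equal(sum(res$occupancy[undetected_states(space)]), 0)
  expect_equal(res$tally[["false_positives"]], 0)
  expect_equal(sum(res$newly_detected), 9 * 100)
  expect_equal(sum(res$occupancy), sum(occ))
})

test_that("zero compliance leaves occupancy unchanged except mobilization", {
  space <- fixture_space()
  params <- screening_params(compliance_screening = 0)
  econ <- econ_params()
  occ <- unit_occ(space, "normal", 1000)
  occ[["ec_adv_u"]] <- 50
  res <- apply_screening_event(occ, params, econ, space)
  expect_equal(res$occupancy, occ)
  expect_equal(res$tally[["cost"]], 1050 * econ$screening_mobilization_cost)
})

test_that("100000 attendees yield 9 expected complications at rate 0.00009", {
  space <- fixture_space()
  params <- screening_params(compliance_screening = 1)
  res <- apply_screening_event(unit_occ(space, "normal", 100000),
                               params, econ_params(), space)
  expect_equal(res$tally[["complications"]], 9, tolerance = 1e-12)
})

test_that("self-detection moves stage-specific fractions and spares mild lesions", {
  space <- fixture_space()
  params <- screening_params()
  occ <- unit_occ(space, "ec_adv_u", 1000)
  res <- apply_self_detection(occ, params, space)
  expect_equal(res$occupancy[["ec_adv_d"]], 700)
  expect_equal(res$occupancy[["ec_adv_u"]], 300)

  occ2 <- unit_occ(space, "ec_mild_u", 1000)
  res2 <- apply_self_detection(occ2, params, space)
  expect_equal(res2$occupancy, occ2)

  params0 <- screening_params(self_exam_probs = c(severe = 0, early = 0,
                                                  advanced = 0))
  res3 <- apply_self_detection(occ, params0, space)
  expect_equal(res3$occupancy, occ)
})

test_that("treatment moves the compliant fraction and charges initial costs", {
  space <- fixture_space()
  params <- screening_params()
  econ <- econ_params()
  occ <- unit_occ(space, "gc_early_d", 1000)
  newly <- unit_occ(space, "gc_early_d", 1000)
  res <- apply_treatment(occ, newly, params, econ, space)
  expect_equal(res$occupancy[["gc_early_pt"]], 900)
  expect_equal(res$occupancy[["gc_early_d"]], 100)
  expect_equal(res$cost, 900 * 7548)

  occ2 <- unit_occ(space, "gc_hgin_d", 1000)
  res2 <- apply_treatment(occ2, occ2, params, econ, space)
  expect_equal(res2$occupancy[["gc_hgin_pt"]], 545.5)

  params1 <- screening_params(treatment_compliance = c(ec_sev = 1, ec_early = 1,
                                                       ec_adv = 1, gc_hgin = 1,
                                                       gc_early = 1, gc_adv = 1))
  res3 <- apply_treatment(occ, newly, params1, econ, space)
  expect_equal(res3$occupancy[["gc_early_d"]], 0)
})

test_that("event operators conserve total mass", {
  space <- fixture_space()
  params <- screening_params()
  econ <- econ_params()
  set.seed(42)
  for (rep in 1:5) {
    occ <- stats::setNames(stats::runif(nrow(space), 0, 1000), space$id)
    r1 <- apply_screening_event(occ, params, econ, space)
    expect_equal(sum(r1$occupancy), sum(occ), tolerance = 1e-9)
    r2 <- apply_self_detection(r1$occupancy, params, space)
    expect_equal(sum(r2$occupancy), sum(occ), tolerance = 1e-9)
    r3 <- apply_treatment(r2$occupancy, r2$newly_detected, params, econ, space)
    expect_equal(sum(r3$occupancy), sum(occ), tolerance = 1e-9)
  }
})

test_that("zero sensitivity reproduces the no-screening trajectory apart from costs", {
  pset <- fixture_pset()
  pset$screening <- screening_params(sens_ec = 0, sens_gc = 0)
  cs <- cohort_spec(100000, 62, 75)
  init <- pset$init_prev * 100000
  blind <- run_cohort(pset$space, pset$tmat, strategy(2), pset$screening,
                      pset$econ, cs, 0.05, pset$life_table, init)
  none <- run_cohort(pset$space, pset$tmat, strategy("none"), pset$screening,
                     pset$econ, cs, 0.05, pset$life_table, init)
  occ_cols <- pset$space$id
  expect_equal(blind$trace[, occ_cols], none$trace[, occ_cols],
               tolerance = 1e-12)
  expect_gt(blind$outcome$cost, none$outcome$cost)      # fp + mobilization
  expect_lt(blind$outcome$qalys, none$outcome$qalys)    # fp disutility
})
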