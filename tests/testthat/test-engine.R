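test_that("annual mortality from 5-year survival matches the closed form", {
  expect_equal(annual_prob_from_survival(1), 0)
  expect_equal(annual_prob_from_survival(0.303), 1 - 0.303^0.2)
  expect_equal(round(annual_prob_from_survival(0.303), 4), 0.2124)
  expect_equal(round(annual_prob_from_survival(0.351), 4), 0.1889)
  expect_error(annual_prob_from_survival(0), "survival")
  expect_error(annual_prob_from_survival(-0.1), "survival")
})

test_that("background mortality overlay rescales rows proportionally", {
  s <- fixture_space()
  m <- synth_transition_matrix(1)
  lt0 <- data.frame(age = 50, qx = 0)
  expect_equal(overlay_background_mortality(m, lt0, 50), m)

  lt1 <- data.frame(age = 50, qx = 1)
  m1 <- overlay_background_mortality(m, lt1, 50)
  expect_true(all(m1[setdiff(s$id, "death"), "death"] == 1))

  # hand arithmetic: (0.9 stay, 0.1 progress) with qx 0.01
  lt <- data.frame(age = 50, qx = 0.01)
  m2 <- m
  m2["ec_early_u", ] <- 0
  m2["ec_early_u", "ec_early_u"] <- 0.9
  m2["ec_early_u", "ec_adv_u"] <- 0.1
  out <- overlay_background_mortality(m2, lt, 50)
  expect_equal(out["ec_early_u", "ec_early_u"], 0.891)
  expect_equal(out["ec_early_u", "ec_adv_u"], 0.099)
  expect_equal(out["ec_early_u", "death"], 0.01)
  expect_equal(rowSums(out), stats::setNames(rep(1, nrow(s)), s$id))

  expect_error(overlay_background_mortality(m, lt, 99), "life-table")
})

test_that("constant occupancy with no mortality gives exactly size x cycles QALYs", {
  s <- fixture_space()
  m <- diag(nrow(s))
  dimnames(m) <- list(s$id, s$id)
  lt <- data.frame(age = 40:90, qx = 0)
  cs <- cohort_spec(100000, 42, 52)
  run <- run_cohort(s, m, strategy("none"), screening_params(
    self_exam_probs = c(severe = 0, early = 0, advanced = 0)),
    econ_params(), cs, discount_rate = 0, life_table = lt,
    init_occupancy = unit_occ(s, "normal", 100000))
  expect_equal(run$outcome$qalys, 10 * 100000)
  expect_equal(run$outcome$cost, 0)
})

test_that("one-time event costs are discounted at mid-cycle", {
  s <- fixture_space()
  m <- diag(nrow(s))
  dimnames(m) <- list(s$id, s$id)
  lt <- data.frame(age = 40:90, qx = 0)
  r <- 0.05
  # screening only at cycle 0; mobilization is the only cost since nobody
  # attends
  sc <- screening_params(compliance_screening = 0,
                         self_exam_probs = c(severe = 0, early = 0,
                                             advanced = 0))
  cs <- cohort_spec(1000, 42, 47)
  run <- run_cohort(s, m, strategy("once"), sc, econ_params(), cs,
                    discount_rate = r, life_table = lt,
                    init_occupancy = unit_occ(s, "normal", 1000))
  expected <- 1000 * 1.05 / (1 + r)^0.5
  expect_equal(run$outcome$cost, expected, tolerance = 1e-12)
  # start-of-cycle timing as the configurable alternative
  run2 <- run_cohort(s, m, strategy("once"), sc, econ_params(), cs,
                     discount_rate = r, life_table = lt,
                     init_occupancy = unit_occ(s, "normal", 1000),
                     event_timing = "start")
  expect_equal(run2$outcome$cost, 1000 * 1.05, tolerance = 1e-12)
})

test_that("no-screening occupancy equals the matrix-power closed form", {
  pset <- fixture_pset()
  s <- pset$space
  lt <- data.frame(age = 40:90, qx = 0.005)  # time-homogeneous overlay
  m <- overlay_background_mortality(pset$tmat, lt, 50)
  sc <- screening_params(self_exam_probs = c(severe = 0, early = 0,
                                             advanced = 0))
  cs <- cohort_spec(100000, 42, 52)
  init <- pset$init_prev * 100000
  run <- run_cohort(s, pset$tmat, strategy("none"), sc, pset$econ, cs,
                    0.05, lt, init)
  occ <- init
  for (t in 1:10) occ <- drop(occ %*% m)
  final <- unlist(run$trace[10, s$id])
  expect_equal(final, occ, tolerance = 1e-9)
})

test_that("discounted totals are non-increasing in the discount rate", {
  pset <- fixture_pset()
  cs <- cohort_spec(10000, 57, 80)
  init <- pset$init_prev * 10000
  res <- lapply(c(0, 0.03, 0.05, 0.08), function(r) {
    run_cohort(pset$space, pset$tmat, strategy(5), pset$screening,
               pset$econ, cs, r, pset$life_table, init,
               keep_trace = FALSE)$outcome
  })
  q <- vapply(res, `[[`, 0, "qalys")
  co <- vapply(res, `[[`, 0, "cost")
  expect_true(all(diff(q) < 0))
  expect_true(all(diff(co) < 0))
  # discounted never exceeds undiscounted
  expect_lte(res[[2]]$qalys, res[[2]]$qalys_undiscounted)
  expect_lte(res[[2]]$cost, res[[2]]$cost_undiscounted)
})

test_that("zero-cycle run returns zero accumulations", {
  pset <- fixture_pset()
  cs <- cohort_spec(1000, 67, 67)
  run <- run_cohort(pset$space, pset$tmat, strategy("once"), pset$screening,
                    pset$econ, cs, 0.05, pset$life_table,
                    pset$init_prev * 1000)
  expect_equal(run$outcome$qalys, 0)
  expect_equal(run$outcome$cost, 0)
  expect_equal(nrow(run$trace), 0)
})

test_that("mass is conserved each cycle and death is monotone in a full run", {
  pset <- fixture_pset()
  cs <- cohort_spec(100000, 42, 90)
  run <- run_cohort(pset$space, pset$tmat, strategy(2), pset$screening,
                    pset$econ, cs, 0.05, pset$life_table,
                    pset$init_prev * 100000)
  occ_mat <- as.matrix(run$trace[, pset$space$id])
  expect_true(all(abs(rowSums(occ_mat) - 100000) < 1e-6))
  expect_true(all(diff(run$trace$death) > -1e-9))
})

test_that("tidy trace is long-format and consistent with the wide trace", {
  pset <- fixture_pset()
  cs <- cohort_spec(1000, 62, 70)
  run <- run_cohort(pset$space, pset$tmat, strategy("once"), pset$screening,
                    pset$econ, cs, 0.05, pset$life_table,
                    pset$init_prev * 1000)
  td <- tidy_trace(run, pset$space)
  expect_equal(nrow(td), 8 * 26)
  expect_equal(sum(td$occupancy[td$cycle == 3]), 1000, tolerance = 1e-6)
})
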