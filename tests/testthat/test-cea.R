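test_that("icer reproduces published arithmetic and flags dominance", {
  expect_equal(icer(3299000, 1087)$icer, 3035)
  expect_equal(icer(5643000, 1251)$icer, 4511)
  expect_equal(icer(0, 100)$flag, "dominant")
  expect_equal(icer(0, 100)$icer, 0)
  expect_equal(icer(-500, 100)$flag, "dominant")
  expect_equal(icer(500, -10)$flag, "dominated")
  expect_equal(icer(0, 0)$flag, "equivalent")
})

test_that("sequential comparison reproduces the published 40-44 ICER column", {
  ref <- reference_basecase()
  blk <- ref[ref$age_band == "40-44", ]
  out <- data.frame(strategy = blk$strategy, qalys = blk$qalys,
                    cost = blk$cost_thousand * 1000)
  seqc <- frontier_sequence(out, "sequential")
  expect_equal(seqc$strategy,
               c("no_screening", "once_per_lifetime", "every_10y",
                 "every_5y", "every_3y", "every_2y"))
  expect_equal(seqc$icer[-1], c(3035, 1087, 1781, 2720, 4511))
})

test_that("frontier_sequence is invariant to input ordering", {
  ref <- reference_basecase()
  blk <- ref[ref$age_band == "50-54", ]
  out <- data.frame(strategy = blk$strategy, qalys = blk$qalys,
                    cost = blk$cost_thousand * 1000)
  set.seed(9)
  for (rep in 1:3) {
    shuf <- out[sample(nrow(out)), ]
    expect_equal(frontier_sequence(shuf, "sequential"),
                 frontier_sequence(out, "sequential"),
                 ignore_attr = TRUE)
  }
})

test_that("frontier mode eliminates once-per-lifetime by extended dominance", {
  ref <- reference_basecase()
  blk <- ref[ref$age_band == "40-44", ]
  out <- data.frame(strategy = blk$strategy, qalys = blk$qalys,
                    cost = blk$cost_thousand * 1000)
  fr <- frontier_sequence(out, "frontier")
  expect_true("once_per_lifetime" %in% attr(fr, "eliminated"))
  expect_false("once_per_lifetime" %in% fr$strategy)
  # surviving ICERs strictly increase along the frontier
  expect_true(all(diff(fr$icer[-1]) > 0))
})

test_that("QALY ties are flagged", {
  out <- data.frame(strategy = c("a", "b"), qalys = c(10, 10),
                    cost = c(5, 7))
  seqc <- frontier_sequence(out, "sequential")
  expect_equal(seqc$flag[2], "tie")
})

test_that("WHO GDP-multiple categories use the 1x and 3x boundaries", {
  expect_equal(who_category(3035), "highly cost-effective")
  expect_equal(who_category(15000), "cost-effective")
  expect_equal(who_category(30829), "not cost-effective")
  expect_equal(who_category(30828), "cost-effective")  # exactly 3x GDP
  expect_equal(who_category(c(500, 20000, 50000)),
               c("highly cost-effective", "cost-effective",
                 "not cost-effective"))
})

test_that("published ICER columns are consistent with their increments", {
  ref <- reference_basecase()
  scr <- ref[ref$strategy != "no_screening", ]
  # vs no screening: 26 comparisons (5+5+5+5+4+2 screening rows)
  expect_equal(nrow(scr), 26)
  re_none <- vapply(seq_len(nrow(scr)), function(i)
    icer(scr$inc_cost_thousand_vs_none[i] * 1000,
         scr$inc_qalys_vs_none[i])$icer, 0)
  expect_equal(re_none, scr$icer_vs_none)
  re_next <- vapply(seq_len(nrow(scr)), function(i)
    icer(scr$inc_cost_thousand_vs_next[i] * 1000,
         scr$inc_qalys_vs_next[i])$icer, 0)
  expect_equal(re_next, scr$icer_vs_next)
})

test_that("comparison_table matches direct frontier arithmetic on model output", {
  pset <- fixture_pset()
  out <- run_strategies(pset, 67, cohort_size = 10000)
  tab <- comparison_table(out)
  expect_equal(tab$strategy[1], "no_screening")
  expect_true(all(is.na(tab[1, c("inc_qalys_vs_none", "icer_vs_none")])))
  i2 <- 2
  expect_equal(tab$icer_vs_none[i2],
               round((tab$cost_thousand[i2] - tab$cost_thousand[1]) * 1000 /
                       (tab$qalys[i2] - tab$qalys[1])))
})
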