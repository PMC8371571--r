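#' Incremental cost-effectiveness ratio
#'
#' Computes incremental cost per QALY gained, with dominance flags: a
#' comparison gaining QALYs at no extra cost (or saving cost) is
#' `"dominant"`; one losing QALYs at extra cost is `"dominated"`; equal
#' cost and QALYs is `"equivalent"`.
#'
#' @param incremental_cost Incremental cost (US$).
#' @param incremental_qalys Incremental QALYs.
#' @param digits Rounding applied to the reported ratio; the default 0
#'   reports whole dollars per QALY. Use `NA` for no rounding.
#' @return A list with `icer` (numeric or `NA` when flagged) and `flag`
#'   (`"ok"`, `"dominant"`, `"dominated"`, `"equivalent"`).
#' @examples
#' icer(3299000, 1087)$icer  # 3035
#' @export
icer <- function(incremental_cost, incremental_qalys, digits = 0) {
  if (incremental_qalys == 0 && incremental_cost == 0)
    return(list(icer = NA_real_, flag = "equivalent"))
  if (incremental_qalys > 0 && incremental_cost <= 0)
    return(list(icer = if (incremental_cost == 0) 0 else NA_real_,
                flag = "dominant"))
  if (incremental_qalys <= 0 && incremental_cost >= 0)
    return(list(icer = NA_real_, flag = "dominated"))
  val <- incremental_cost / incremental_qalys
  if (!is.na(digits)) val <- round(val, digits)
  list(icer = val, flag = "ok")
}

#' Sequential next-most-effective comparison and efficiency frontier
#'
#' Sorts strategies by effectiveness (QALYs ascending) and compares each
#' with its predecessor. The default `"sequential"` mode keeps every
#' strategy, reproducing the published presentation in which the ICER
#' sequence need not be monotone; `"frontier"` mode first removes strongly
#' dominated strategies (less effective and at least as costly) and then
#' extendedly dominated ones (ICER above that of a more effective
#' successor), leaving strictly increasing frontier ICERs.
#'
#' @param outcomes `data.frame` with columns `strategy`, `qalys`, `cost`.
#' @param mode `"sequential"` or `"frontier"`.
#' @param digits ICER rounding, passed to [icer()].
#' @return `data.frame` with columns `strategy`, `comparator`,
#'   `incremental_qalys`, `incremental_cost`, `icer`, `flag` (the least
#'   effective strategy has no comparator and `NA` increments). In
#'   frontier mode an attribute `"eliminated"` lists dropped strategies.
#' @export
frontier_sequence <- function(outcomes, mode = c("sequential", "frontier"),
                              digits = 0) {
  mode <- match.arg(mode)
  stopifnot(all(c("strategy", "qalys", "cost") %in% names(outcomes)),
            nrow(outcomes) >= 2)
  # order by QALYs, ties broken by cost (flagged below)
  ord <- order(outcomes$qalys, outcomes$cost)
  out <- outcomes[ord, , drop = FALSE]
  eliminated <- character(0)
  if (mode == "frontier") {
    # strong dominance: more (or equally) costly and no more effective
    repeat {
      n <- nrow(out)
      dom <- rep(FALSE, n)
      for (i in seq_len(n)) {
        dom[i] <- any(out$qalys > out$qalys[i] & out$cost <= out$cost[i]) ||
          any(out$qalys >= out$qalys[i] & out$cost < out$cost[i])
      }
      if (!any(dom)) break
      eliminated <- c(eliminated, out$strategy[dom])
      out <- out[!dom, , drop = FALSE]
    }
    # extended dominance: drop strategies whose sequential ICER exceeds
    # the next one's, until ICERs increase along the frontier
    repeat {
      n <- nrow(out)
      if (n < 3) break
      ic <- vapply(2:n, function(i) {
        (out$cost[i] - out$cost[i - 1]) / (out$qalys[i] - out$qalys[i - 1])
      }, 0)
      drop_i <- which(diff(ic) < 0)
      if (!length(drop_i)) break
      # the strategy between the decreasing pair is extendedly dominated
      i <- drop_i[1] + 1L
      eliminated <- c(eliminated, out$strategy[i])
      out <- out[-i, , drop = FALSE]
    }
  }
  n <- nrow(out)
  res <- data.frame(strategy = out$strategy,
                    comparator = c(NA_character_, out$strategy[-n]),
                    incremental_qalys = c(NA, diff(out$qalys)),
                    incremental_cost = c(NA, diff(out$cost)),
                    icer = NA_real_, flag = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)[-1]) {
    r <- icer(res$incremental_cost[i], res$incremental_qalys[i], digits)
    res$icer[i] <- r$icer
    res$flag[i] <- r$flag
    if (res$incremental_qalys[i] == 0) res$flag[i] <- "tie"
  }
  attr(res, "eliminated") <- eliminated
  res
}

#' WHO GDP-multiple cost-effectiveness category
#'
#' Classifies an ICER against the per-capita GDP: below 1 time GDP is
#' highly cost-effective, 1 to 3 times GDP cost-effective, above 3 times
#' GDP not cost-effective. The 2019 Chinese per-capita GDP of US$10276 is
#' the default threshold.
#'
#' @param icer_value ICER in US$/QALY (finite).
#' @param gdp_per_capita Per-capita GDP, default 10276.
#' @return One of `"highly cost-effective"`, `"cost-effective"`,
#'   `"not cost-effective"` (vectorized).
#' @examples
#' who_category(3035)   # highly cost-effective
#' who_category(30829)  # not cost-effective
#' @export
who_category <- function(icer_value, gdp_per_capita = 10276) {
  if (gdp_per_capita <= 0) stop("GDP threshold must be positive", call. = FALSE)
  stopifnot(all(is.finite(icer_value)))
  ifelse(icer_value < gdp_per_capita, "highly cost-effective",
         ifelse(icer_value <= 3 * gdp_per_capita, "cost-effective",
                "not cost-effective"))
}

#' Published base-case cost-effectiveness results (reference data)
#'
#' The published per-100000-cohort base-case results for combined
#' endoscopic EC/GC screening in high-risk areas of China, by initial
#' screening age band and strategy: total discounted QALYs, total
#' discounted cost (US$ thousand, 2019), the printed incremental columns
#' and ICERs versus no screening and versus the next most effective
#' strategy. These published values serve as reference inputs for ICER
#' and frontier arithmetic; they are not produced by this package's
#' synthetic parameterization.
#'
#' @return `data.frame` with columns `age_band`, `strategy`, `qalys`,
#'   `cost_thousand`, `inc_qalys_vs_none`, `inc_qalys_vs_next`,
#'   `inc_cost_thousand_vs_none`, `inc_cost_thousand_vs_next`,
#'   `icer_vs_none`, `icer_vs_next`.
#' @export
reference_basecase <- function() {
  rows <- rbind(
    c("40-44", "no_screening",      1659260, 25035, NA,    NA,   NA,    NA,   NA,   NA),
    c("40-44", "once_per_lifetime", 1660347, 28334, 1087,  1087, 3299,  3299, 3035, 3035),
    c("40-44", "every_10y",         1663677, 31954, 4417,  3330, 6919,  3620, 1566, 1087),
    c("40-44", "every_5y",          1666345, 36707, 7085,  2668, 11672, 4753, 1647, 1781),
    c("40-44", "every_3y",          1668371, 42218, 9111,  2026, 17183, 5511, 1886, 2720),
    c("40-44", "every_2y",          1669622, 47861, 10362, 1251, 22826, 5643, 2203, 4511),
    c("45-49", "no_screening",      1572532, 26817, NA,    NA,   NA,    NA,   NA,   NA),
    c("45-49", "once_per_lifetime", 1574161, 30347, 1629,  1629, 3530,  3530, 2167, 2167),
    c("45-49", "every_10y",         1576941, 33961, 4409,  2780, 7144,  3614, 1620, 1300),
    c("45-49", "every_5y",          1579145, 37745, 6613,  2204, 10928, 3784, 1653, 1717),
    c("45-49", "every_3y",          1580974, 42531, 8442,  1829, 15714, 4786, 1861, 2617),
    c("45-49", "every_2y",          1582334, 48190, 9802,  1360, 21373, 5659, 2180, 4161),
    c("50-54", "no_screening",      1468506, 30229, NA,    NA,   NA,    NA,   NA,   NA),
    c("50-54", "once_per_lifetime", 1470890, 34142, 2384,  2384, 3913,  3913, 1641, 1641),
    c("50-54", "every_10y",         1472583, 36373, 4077,  1693, 6144,  2231, 1507, 1318),
    c("50-54", "every_5y",          1474773, 40356, 6267,  2190, 10127, 3983, 1616, 1819),
    c("50-54", "every_3y",          1476325, 44120, 7819,  1552, 13891, 3764, 1777, 2425),
    c("50-54", "every_2y",          1477651, 49010, 9145,  1326, 18781, 4890, 2054, 3688),
    c("55-59", "no_screening",      1342830, 36095, NA,    NA,   NA,    NA,   NA,   NA),
    c("55-59", "once_per_lifetime", 1346031, 40491, 3201,  3201, 4396,  4396, 1373, 1373),
    c("55-59", "every_10y",         1347264, 42811, 4434,  1233, 6716,  2320, 1515, 1882),
    c("55-59", "every_5y",          1348747, 45240, 5917,  1483, 9145,  2429, 1546, 1638),
    c("55-59", "every_3y",          1350365, 49171, 7535,  1618, 13076, 3931, 1735, 2430),
    c("55-59", "every_2y",          1351491, 52843, 8661,  1126, 16748, 3672, 1934, 3261),
    c("60-64", "no_screening",      1195742, 45876, NA,    NA,   NA,    NA,   NA,   NA),
    c("60-64", "once_per_lifetime", 1199618, 51081, 3876,  3876, 5205,  5205, 1343, 1343),
    c("60-64", "every_5y",          1201091, 53970, 5349,  1473, 8094,  2889, 1513, 1961),
    c("60-64", "every_3y",          1202293, 56498, 6551,  1202, 10622, 2528, 1621, 2103),
    c("60-64", "every_2y",          1203210, 58779, 7468,  917,  12903, 2281, 1728, 2487),
    c("65-69", "no_screening",      1025119, 60442, NA,    NA,   NA,    NA,   NA,   NA),
    c("65-69", "once_per_lifetime", 1029058, 67233, 3939,  3939, 6791,  6791, 1724, 1724),
    c("65-69", "every_2y",          1030594, 70810, 5475,  1536, 10368, 3577, 1894, 2329))
  out <- data.frame(age_band = rows[, 1], strategy = rows[, 2],
                    stringsAsFactors = FALSE)
  num <- apply(rows[, 3:10], 2, as.numeric)
  colnames(num) <- c("qalys", "cost_thousand", "inc_qalys_vs_none",
                     "inc_qalys_vs_next", "inc_cost_thousand_vs_none",
                     "inc_cost_thousand_vs_next", "icer_vs_none",
                     "icer_vs_next")
  cbind(out, as.data.frame(num))
}

#' Build a publication-layout comparison table from strategy outcomes
#'
#' Given total (discounted) QALYs and costs per strategy for one cohort,
#' computes both comparison columns: versus no screening, and versus the
#' next most effective strategy (sequential mode).
#'
#' @param outcomes `data.frame` with `strategy`, `qalys`, `cost` (US$);
#'   must contain a `no_screening` row.
#' @param digits ICER rounding.
#' @return `data.frame` in the published column layout, costs in US$
#'   thousand.
#' @export
comparison_table <- function(outcomes, digits = 0) {
  stopifnot("no_screening" %in% outcomes$strategy)
  seqc <- frontier_sequence(outcomes, "sequential", digits = NA)
  base <- outcomes[outcomes$strategy == "no_screening", ]
  out <- data.frame(strategy = seqc$strategy,
                    qalys = outcomes$qalys[match(seqc$strategy, outcomes$strategy)],
                    cost_thousand = outcomes$cost[
                      match(seqc$strategy, outcomes$strategy)] / 1000)
  out$inc_qalys_vs_none <- out$qalys - base$qalys
  out$inc_qalys_vs_next <- seqc$incremental_qalys
  out$inc_cost_thousand_vs_none <- out$cost_thousand - base$cost / 1000
  out$inc_cost_thousand_vs_next <- seqc$incremental_cost / 1000
  out$icer_vs_none <- vapply(seq_len(nrow(out)), function(i) {
    if (out$strategy[i] == "no_screening") return(NA_real_)
    icer(out$inc_cost_thousand_vs_none[i] * 1000,
         out$inc_qalys_vs_none[i], digits)$icer
  }, 0)
  out$icer_vs_next <- vapply(seq_len(nrow(out)), function(i) {
    if (is.na(seqc$comparator[i])) return(NA_real_)
    icer(seqc$incremental_cost[i], seqc$incremental_qalys[i], digits)$icer
  }, 0)
  na_base <- out$strategy == "no_screening"
  out$inc_qalys_vs_none[na_base] <- NA
  out$inc_cost_thousand_vs_none[na_base] <- NA
  out
}
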