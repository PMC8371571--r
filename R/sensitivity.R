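#' Parameter groups for grouped one-way sweeps
#'
#' Members of a group move together (all to their low limits or all to
#' their high limits — a common quantile, realizing positive
#' correlation). Returns the groups of the published univariate analysis:
#' the utility-score set, screening compliance, discount rate, the
#' baseline-prevalence set, the three screening-cost components, and the
#' severe-dysplasia-to-early-EC progression probability.
#'
#' @param pset A `ugic_params` (groups are read from its uncertainty
#'   table).
#' @return Named list of character vectors of parameter ids.
#' @export
parameter_groups <- function(pset) {
  meta <- pset$uncertainty$meta
  split(meta$id, meta$group)
}

#' Grouped one-way (univariate) sensitivity sweep
#'
#' Re-runs the model with every member of a parameter group set to its
#' low limit, then to its high limit, and reports the ICERs versus no
#' screening and versus the next most effective strategy at both limits
#' together with the per-comparison maximum (the tornado "upper limit")
#' and its GDP-multiple flag.
#'
#' @param group Character vector of parameter ids moved together.
#' @param pset A `ugic_params`.
#' @param initial_mean_age Cohort entry age.
#' @param strategies Strategy list, default full menu.
#' @param gdp_per_capita WHO threshold base, default 10276.
#' @param ... Passed to [run_strategies()] (e.g. `cohort_size`).
#' @return `data.frame` with one row per (strategy, comparator):
#'   `strategy`, `comparator` (`"no_screening"` or `"next"`), `icer_low`,
#'   `icer_high`, `upper_limit`, `gdp_flag`.
#' @export
one_way_sweep <- function(group, pset, initial_mean_age,
                          strategies = strategy_menu(),
                          gdp_per_capita = 10276, ...) {
  meta <- pset$uncertainty$meta
  missing <- setdiff(group, meta$id)
  if (length(missing))
    stop("no range for parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  limits <- lapply(c(low = "low", high = "high"), function(side) {
    vals <- stats::setNames(meta[[side]][match(group, meta$id)], group)
    ps <- apply_overrides(pset, vals)
    out <- tryCatch(run_strategies(ps, initial_mean_age, strategies, ...),
                    error = function(e) e)
    out
  })
  icer_tab <- function(out) {
    if (inherits(out, "error"))
      return(NULL)
    vs_none <- comparison_table(out, digits = NA)
    data.frame(strategy = rep(vs_none$strategy, 2),
               comparator = rep(c("no_screening", "next"),
                                each = nrow(vs_none)),
               icer = c(vs_none$icer_vs_none, vs_none$icer_vs_next),
               stringsAsFactors = FALSE)
  }
  lo <- icer_tab(limits$low)
  hi <- icer_tab(limits$high)
  if (is.null(lo) || is.null(hi)) {
    diag_msg <- paste(vapply(limits[vapply(limits, inherits, TRUE, "error")],
                             conditionMessage, ""), collapse = "; ")
    return(structure(data.frame(), missing_reason = diag_msg))
  }
  res <- merge(lo, hi, by = c("strategy", "comparator"),
               suffixes = c("_low", "_high"))
  res <- res[!is.na(res$icer_low) | !is.na(res$icer_high), , drop = FALSE]
  res$upper_limit <- pmax(res$icer_low, res$icer_high, na.rm = TRUE)
  res$gdp_flag <- who_category(res$upper_limit, gdp_per_capita)
  res[order(res$comparator, res$strategy), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Per draw, all uncertain parameters are sampled jointly from their
#' distributions (the discount rate and any `fixed` specs stay at base),
#' and every strategy is evaluated on that common parameter draw. Draws
#' producing an invalid transition matrix are resampled and counted.
#'
#' @param pset A `ugic_params`.
#' @param initial_mean_age Cohort entry age.
#' @param strategies Strategy list.
#' @param n_draws Number of PSA draws (>= 1).
#' @param seed Integer seed; the sample set is reproducible given it.
#' @param ... Passed to [run_strategies()].
#' @return An object of class `ugic_psa`: list with `cost` and `qalys`
#'   (`n_draws` x strategies matrices), `params` (draws of each sampled
#'   parameter), `seed`, `n`, `resampled`.
#' @export
run_psa <- function(pset, initial_mean_age, strategies = strategy_menu(),
                    n_draws = 100, seed = 1L, ...) {
  stopifnot(n_draws >= 1)
  meta <- pset$uncertainty$meta
  dists <- pset$uncertainty$dists
  sampled_ids <- meta$id[vapply(dists[meta$id], function(d)
    d$kind != "fixed", TRUE)]
  snames <- vapply(strategies, `[[`, "", "name")
  cost <- qal <- matrix(NA_real_, n_draws, length(strategies),
                        dimnames = list(NULL, snames))
  pdraws <- matrix(NA_real_, n_draws, length(sampled_ids),
                   dimnames = list(NULL, sampled_ids))
  resampled <- 0L
  with_private_seed(seed, {
    for (i in seq_len(n_draws)) {
      repeat {
        vals <- vapply(sampled_ids, function(id)
          sample_parameter(dists[[id]]), 0)
        ps <- tryCatch(apply_overrides(pset, vals), error = function(e) NULL)
        if (!is.null(ps)) break
        resampled <- resampled + 1L
      }
      pdraws[i, ] <- vals
      out <- run_strategies(ps, initial_mean_age, strategies, ...)
      cost[i, ] <- out$cost[match(snames, out$strategy)]
      qal[i, ] <- out$qalys[match(snames, out$strategy)]
    }
  })
  structure(list(cost = cost, qalys = qal, params = pdraws,
                 seed = seed, n = n_draws, resampled = resampled),
            class = "ugic_psa")
}

#' Default willingness-to-pay grid
#'
#' 0 to 3 times the per-capita GDP in 100 steps.
#'
#' @param gdp_per_capita Default 10276.
#' @param steps Number of intervals, default 100.
#' @return Numeric vector of WTP values (US$/QALY).
#' @export
wtp_grid <- function(gdp_per_capita = 10276, steps = 100) {
  seq(0, 3 * gdp_per_capita, length.out = steps + 1)
}

#' Cost-effectiveness acceptability curve versus a comparator
#'
#' For each strategy and willingness-to-pay value, the fraction of PSA
#' draws in which the strategy's net monetary benefit
#' (`WTP x QALYs - cost`) exceeds the comparator's.
#'
#' @param samples A `ugic_psa`.
#' @param comparator Strategy label, default `"no_screening"`.
#' @param wtp Numeric WTP grid (non-empty).
#' @return Long `data.frame(strategy, wtp, probability)`.
#' @export
ceac_vs_comparator <- function(samples, comparator = "no_screening",
                               wtp = wtp_grid()) {
  stopifnot(inherits(samples, "ugic_psa"))
  if (length(wtp) == 0) stop("empty WTP grid", call. = FALSE)
  snames <- colnames(samples$cost)
  if (!comparator %in% snames)
    stop("comparator '", comparator, "' not in sample set", call. = FALSE)
  others <- setdiff(snames, comparator)
  out <- lapply(others, function(s) {
    prob <- vapply(wtp, function(w) {
      nmb_s <- w * samples$qalys[, s] - samples$cost[, s]
      nmb_c <- w * samples$qalys[, comparator] - samples$cost[, comparator]
      mean(nmb_s > nmb_c)
    }, 0)
    data.frame(strategy = s, wtp = wtp, probability = prob,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Probability each strategy is optimal (all strategies competing)
#'
#' Per draw and WTP, the strategy maximizing net monetary benefit wins;
#' exact ties split the win equally. Probabilities across strategies sum
#' to 1 at every WTP.
#'
#' @inheritParams ceac_vs_comparator
#' @return Long `data.frame(strategy, wtp, probability)`.
#' @export
prob_optimal <- function(samples, wtp = wtp_grid()) {
  stopifnot(inherits(samples, "ugic_psa"))
  snames <- colnames(samples$cost)
  rows <- lapply(wtp, function(w) {
    nmb <- w * samples$qalys - samples$cost
    wins <- stats::setNames(numeric(length(snames)), snames)
    mx <- apply(nmb, 1, max)
    for (i in seq_len(nrow(nmb))) {
      best <- snames[nmb[i, ] >= mx[i] - 1e-12]
      wins[best] <- wins[best] + 1 / length(best)
    }
    data.frame(strategy = snames, wtp = w,
               probability = unname(wins) / nrow(nmb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
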