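# Initial-age bands and their cohort mean ages.
.age_bands <- c("40-44" = 42, "45-49" = 47, "50-54" = 52,
                "55-59" = 57, "60-64" = 62, "65-69" = 67)

.band_of <- function(mean_age) names(.age_bands)[match(mean_age, .age_bands)]

#' Run configuration for the reporting commands
#'
#' @param pset A `ugic_params` (or a directory readable by
#'   [read_parameter_set()]).
#' @param ages Mean ages to run; subset of 42, 47, 52, 57, 62, 67.
#' @param strategies Strategy list, default full menu.
#' @param discount_rate Optional override of the set's discount rate.
#' @param out_dir Output directory for CSVs.
#' @param seed Seed for stochastic commands.
#' @param n_psa PSA draw count.
#' @param wtp WTP grid.
#' @param cohort_size Persons per cohort.
#' @return A list of class `ugic_run_config`.
#' @export
run_config <- function(pset, ages = unname(.age_bands),
                       strategies = strategy_menu(), discount_rate = NULL,
                       out_dir = tempdir(), seed = 1L, n_psa = 100,
                       wtp = wtp_grid(), cohort_size = 100000) {
  if (is.character(pset)) pset <- read_parameter_set(pset)
  stopifnot(inherits(pset, "ugic_params"))
  if (!all(ages %in% .age_bands))
    stop("ages must be a subset of ", paste(.age_bands, collapse = ", "),
         call. = FALSE)
  if (length(strategies) == 0) stop("empty strategy list", call. = FALSE)
  if (!is.null(discount_rate)) pset$discount_rate <- discount_rate
  structure(list(pset = pset, ages = ages, strategies = strategies,
                 out_dir = out_dir, seed = as.integer(seed), n_psa = n_psa,
                 wtp = wtp, cohort_size = cohort_size),
            class = "ugic_run_config")
}

# Drop strategies whose screening schedules coincide at this entry age
# (e.g. every-10-years equals once-per-lifetime at mean age 62), keeping
# the least intensive label — this reproduces which strategy rows appear
# per age band in the published layout.
distinct_strategies <- function(strategies, initial_mean_age,
                                horizon_cycles = 48) {
  keys <- vapply(strategies, function(st)
    paste(screening_cycles(st, initial_mean_age, horizon_cycles),
          collapse = ","), "")
  strategies[!duplicated(keys)]
}

.write_output <- function(df, config, name) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, name)
  con <- file(path, "w")
  prov <- paste(names(config$pset$provenance), config$pset$provenance,
                sep = "=", collapse = "; ")
  writeLines(paste0("# provenance: ", prov, "; currency: 2019 US$"), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  message("wrote ", path, " [", prov, "]")
  invisible(path)
}

#' Base-case cost-effectiveness table
#'
#' Runs every (age, strategy) cohort and assembles the publication-layout
#' table: QALYs, incremental QALYs (vs no screening and vs next most
#' effective), costs in US$ thousand, incremental costs, and both ICER
#' columns rounded to whole dollars. Strategy rows indistinguishable
#' under the eligibility window are trimmed.
#'
#' @param config A `ugic_run_config`.
#' @param write Write `basecase.csv` to the config's output directory?
#' @return The table, invisibly written as CSV when `write = TRUE`.
#' @export
cmd_run <- function(config, write = TRUE) {
  blocks <- lapply(config$ages, function(age) {
    menu <- distinct_strategies(config$strategies, age)
    out <- run_strategies(config$pset, age, menu,
                          cohort_size = config$cohort_size)
    tab <- comparison_table(out)
    cbind(age_band = .band_of(age), tab)
  })
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  if (write) .write_output(res, config, "basecase.csv")
  res
}

#' Grouped one-way sensitivity (tornado) table
#'
#' @param config A `ugic_run_config`.
#' @param groups Named list of parameter-id groups; default
#'   [parameter_groups()] of the set.
#' @param write Write `oneway.csv`?
#' @return Long `data.frame(age_band, group, strategy, comparator,
#'   icer_low, icer_high, upper_limit, gdp_flag)`.
#' @export
cmd_oneway <- function(config, groups = parameter_groups(config$pset),
                       write = TRUE) {
  rows <- list()
  for (age in config$ages) {
    menu <- distinct_strategies(config$strategies, age)
    for (g in names(groups)) {
      sw <- one_way_sweep(groups[[g]], config$pset, age, menu,
                          cohort_size = config$cohort_size)
      if (nrow(sw) == 0) next
      rows[[length(rows) + 1L]] <- cbind(age_band = .band_of(age),
                                         group = g, sw)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (write) .write_output(res, config, "oneway.csv")
  res
}

#' Probabilistic sensitivity analysis and CEAC tables
#'
#' Runs the PSA per initial age and writes two long-format CSVs: the
#' acceptability curves versus no screening and the all-competing
#' probability-optimal curves.
#'
#' @param config A `ugic_run_config`.
#' @param write Write `ceac_vs_none.csv` and `ceac_optimal.csv`?
#' @return List with `vs_none`, `optimal` (long data.frames, with an
#'   `age_band` column) and `samples` (list of `ugic_psa` per age).
#' @export
cmd_psa <- function(config, write = TRUE) {
  vs_none <- list(); optimal <- list(); samples <- list()
  for (age in config$ages) {
    menu <- distinct_strategies(config$strategies, age)
    ps <- run_psa(config$pset, age, menu, n_draws = config$n_psa,
                  seed = config$seed + match(age, .age_bands),
                  cohort_size = config$cohort_size)
    samples[[.band_of(age)]] <- ps
    vs_none[[length(vs_none) + 1L]] <-
      cbind(age_band = .band_of(age),
            ceac_vs_comparator(ps, "no_screening", config$wtp))
    optimal[[length(optimal) + 1L]] <-
      cbind(age_band = .band_of(age), prob_optimal(ps, config$wtp))
  }
  vs_none <- do.call(rbind, vs_none)
  optimal <- do.call(rbind, optimal)
  if (write) {
    .write_output(vs_none, config, "ceac_vs_none.csv")
    .write_output(optimal, config, "ceac_optimal.csv")
  }
  list(vs_none = vs_none, optimal = optimal, samples = samples)
}

#' Efficiency-frontier table
#'
#' Frontier-mode comparison (dominated and extendedly dominated
#' strategies eliminated) per initial age.
#'
#' @param config A `ugic_run_config`.
#' @param write Write `frontier.csv`?
#' @return `data.frame` of frontier comparisons with eliminated
#'   strategies flagged in the `eliminated` attribute per block.
#' @export
cmd_frontier <- function(config, write = TRUE) {
  blocks <- lapply(config$ages, function(age) {
    menu <- distinct_strategies(config$strategies, age)
    out <- run_strategies(config$pset, age, menu,
                          cohort_size = config$cohort_size)
    fr <- frontier_sequence(out, "frontier")
    fr$eliminated <- paste(attr(fr, "eliminated"), collapse = ";")
    cbind(age_band = .band_of(age), fr)
  })
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  if (write) .write_output(res, config, "frontier.csv")
  res
}

#' Generate and write a synthetic parameter bundle
#'
#' @param seed Integer seed.
#' @param out_dir Directory for the bundle.
#' @param config A `ugic_synth_config`.
#' @return The `ugic_params`, after writing the bundle.
#' @export
cmd_synth <- function(seed = 1L, out_dir = tempdir(),
                      config = synthetic_config(seed)) {
  pset <- synthetic_parameter_set(seed, config)
  write_parameter_set(pset, out_dir)
  message("wrote synthetic parameter bundle to ", out_dir,
          " [transitions/prevalence/life_table are synthetic stand-ins]")
  pset
}
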