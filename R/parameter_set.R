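#' The published base-case parameter table
#'
#' Returns every published model parameter with its base-case value,
#' sensitivity range, uncertainty distribution and sweep group:
#' compliances, endoscopy test characteristics, complication rate, annual
#' self-initiated examination probabilities, treatment compliances, all
#' costs (ranges +/-50% of base) and utility scores, and the discount
#' rate (0.05, range 0-0.08, held fixed in probabilistic analysis).
#'
#' @return A list with `meta` (`data.frame`: id, base, low, high, group)
#'   and `dists` (named list of [dist_spec()] objects).
#' @examples
#' p <- default_table1_params()
#' p$meta[p$meta$id == "c_endoscopy", "base"]  # 47.87
#' @export
default_table1_params <- function() {
  tri <- function(a, c, b) list(kind = "triangular", p = c(a, c, b))
  bet <- function(s1, s2) list(kind = "beta", p = c(s1, s2))
  gam <- function(sh, ra) list(kind = "gamma", p = c(sh, ra))
  fx <- function(v) list(kind = "fixed", p = v)
  # id, base, low, high, dist, group
  rows <- list(
    list("compliance_screening", 0.49, 0.30, 0.80, tri(0.30, 0.49, 0.80), "compliance_screening"),
    list("compliance_reexamination", 0.67, 0.40, 0.90, tri(0.40, 0.67, 0.90), "compliance_reexamination"),
    list("sens_ec", 0.96, 0.88, 0.99, tri(0.88, 0.96, 0.99), "test_characteristics"),
    list("spec_ec", 0.90, 0.59, 1.00, tri(0.59, 0.90, 1.00), "test_characteristics"),
    list("sens_gc", 0.89, 0.70, 0.98, tri(0.70, 0.89, 0.98), "test_characteristics"),
    list("spec_gc", 1.00, 0.90, 1.00, tri(0.90, 1.00, 1.00), "test_characteristics"),
    list("complication_rate", 0.00009, 0, 0.002, tri(0, 0.00009, 0.002), "complications"),
    list("selfexam_severe", 0.01, 0.005, 0.02, tri(0.005, 0.01, 0.02), "self_examination"),
    list("selfexam_early", 0.20, 0.10, 0.40, tri(0.10, 0.20, 0.40), "self_examination"),
    list("selfexam_advanced", 0.70, 0.56, 0.90, tri(0.56, 0.70, 0.90), "self_examination"),
    list("tc_ec_sev", 0.7458, 0.5625, 0.9654, bet(31.72, 10.81), "treatment_compliance"),
    list("tc_ec_early", 0.9405, 0.7149, 1.0000, bet(8.17, 0.52), "treatment_compliance"),
    list("tc_ec_adv", 0.9643, 0.8393, 1.0000, bet(16.99, 0.63), "treatment_compliance"),
    list("tc_gc_hgin", 0.5455, 0.4425, 0.7746, bet(92.43, 77.01), "treatment_compliance"),
    list("tc_gc_early", 0.9000, 0.6792, 1.0000, bet(12.41, 1.38), "treatment_compliance"),
    list("tc_gc_adv", 0.9643, 0.8393, 1.0000, bet(16.99, 0.63), "treatment_compliance"),
    list("c_mobilization", 1.05, NA, NA, gam(0.16, 0.15), "costs_screening"),
    list("c_endoscopy", 47.87, NA, NA, gam(46.57, 0.97), "costs_screening"),
    list("c_complication", 113.68, NA, NA, gam(5.82, 0.05), "costs_screening"),
    list("ctx_ec_sev", 1604, NA, NA, gam(3.33, 0.002), "costs_treatment"),
    list("ctx_ec_early", 7732, NA, NA, gam(2.33, 3.01), "costs_treatment"),
    list("ctx_ec_adv", 7320, NA, NA, gam(3.33, 4.55), "costs_treatment"),
    list("ctx_gc_hgin", 1423, NA, NA, gam(1.41, 9.88), "costs_treatment"),
    list("ctx_gc_early", 7548, NA, NA, gam(4.61, 6.11), "costs_treatment"),
    list("ctx_gc_adv", 7086, NA, NA, gam(5.96, 8.41), "costs_treatment"),
    list("ca_ec_sev", 216, NA, NA, gam(1.22, 0.006), "costs_annual"),
    list("ca_ec_early", 367, NA, NA, gam(1.23, 0.003), "costs_annual"),
    list("ca_ec_adv", 342, NA, NA, gam(2.05, 0.006), "costs_annual"),
    list("ca_gc_hgin", 243, NA, NA, gam(1.24, 0.005), "costs_annual"),
    list("ca_gc_early", 409, NA, NA, gam(1.18, 0.003), "costs_annual"),
    list("ca_gc_adv", 435, NA, NA, gam(1.19, 0.003), "costs_annual"),
    list("u_ec_mild", 1.00, 0.98, 1.00, tri(0.98, 1.00, 1.00), "utility_scores"),
    list("u_ec_mod", 1.00, 0.98, 1.00, tri(0.98, 1.00, 1.00), "utility_scores"),
    list("u_ec_sev", 0.84, 0.79, 0.89, bet(3.57, 0.68), "utility_scores"),
    list("u_ec_early", 0.70, 0.66, 0.74, bet(2.63, 1.13), "utility_scores"),
    list("u_ec_adv", 0.61, 0.56, 0.66, bet(1.12, 0.71), "utility_scores"),
    list("u_gc_lgin", 1.00, 0.98, 1.00, tri(0.98, 1.00, 1.00), "utility_scores"),
    list("u_gc_hgin", 0.92, 0.86, 0.99, bet(2.53, 0.22), "utility_scores"),
    list("u_gc_early", 0.75, 0.71, 0.78, bet(3.15, 1.05), "utility_scores"),
    list("u_gc_adv", 0.57, 0.53, 0.62, bet(1.35, 1.02), "utility_scores"),
    list("discount_rate", 0.05, 0, 0.08, fx(0.05), "discount_rate")
  )
  meta <- data.frame(
    id = vapply(rows, `[[`, "", 1),
    base = vapply(rows, `[[`, 0, 2),
    low = vapply(rows, `[[`, 0, 3),
    high = vapply(rows, `[[`, 0, 4),
    group = vapply(rows, `[[`, "", 6),
    stringsAsFactors = FALSE)
  # cost ranges are +/-50% of base
  cost_rows <- grepl("^c", meta$id)
  meta$low[cost_rows & is.na(meta$low)] <- meta$base[cost_rows & is.na(meta$low)] * 0.5
  meta$high[cost_rows & is.na(meta$high)] <- meta$base[cost_rows & is.na(meta$high)] * 1.5
  dists <- stats::setNames(lapply(seq_along(rows), function(i) {
    d <- rows[[i]][[5]]
    domain <- if (grepl("^(compliance|sens|spec|selfexam|tc_|u_|complication|discount)",
                        meta$id[i])) c(0, 1) else c(0, Inf)
    dist_spec(d$kind, d$p, range = c(meta$low[i], meta$high[i]),
              base = meta$base[i], domain = domain)
  }), meta$id)
  list(meta = meta, dists = dists)
}

# Uncertain synthetic (supplement stand-in) parameters swept/sampled in
# addition to the published table: baseline prevalence scale and the
# severe-dysplasia-to-early-EC progression probability.
.synth_param_meta <- function(rates) {
  base_prog <- rates[["r_ec_sev_early"]]
  meta <- data.frame(
    id = c("prev_scale", "r_ec_sev_early"),
    base = c(1, base_prog),
    low = c(0.5, base_prog * 0.5),
    high = c(1.5, base_prog * 1.5),
    group = c("prevalences", "r_ec_sev_early"),
    stringsAsFactors = FALSE)
  dists <- list(
    prev_scale = dist_spec("triangular", c(0.5, 1, 1.5), range = c(0.5, 1.5),
                           base = 1, domain = c(0, Inf)),
    r_ec_sev_early = dist_spec("triangular",
                               base_prog * c(0.5, 1, 1.5),
                               range = base_prog * c(0.5, 1.5),
                               base = base_prog, domain = c(0, 1)))
  list(meta = meta, dists = dists)
}

#' Assemble a complete synthetic parameter set
#'
#' Combines the published base-case parameters with synthetic stand-ins
#' for the supplement-only inputs (transition matrix, initial prevalence,
#' background life table) into the single validated container every other
#' module consumes. Provenance of each block is recorded.
#'
#' @param seed Integer seed for the synthetic pieces.
#' @param config A `ugic_synth_config`.
#' @return An object of class `ugic_params` with elements `space`,
#'   `rates`, `tmat`, `init_prev` (proportions summing to 1),
#'   `life_table`, `screening`, `econ`, `discount_rate`, `uncertainty`
#'   (meta + dists), `provenance`, `config`.
#' @export
synthetic_parameter_set <- function(seed = 1L, config = synthetic_config(seed)) {
  config$seed <- as.integer(seed)
  space <- build_state_space()
  rates <- synth_rates(config)
  tmat <- build_transition_matrix(rates, space)
  prev <- synth_initial_prevalence(seed, config, space, size = 1)
  tab <- default_table1_params()
  synth <- .synth_param_meta(rates)
  # keep the realized (possibly jittered) progression rate as the base
  uncertainty <- list(meta = rbind(tab$meta, synth$meta),
                      dists = c(tab$dists, synth$dists))
  structure(list(space = space, rates = rates, tmat = tmat,
                 init_prev = prev, life_table = synth_life_table(config),
                 screening = screening_params(), econ = econ_params(),
                 discount_rate = 0.05,
                 uncertainty = uncertainty,
                 provenance = c(parameters = "published_base_case",
                                transitions = "synthetic",
                                prevalence = "synthetic",
                                life_table = "synthetic"),
                 config = config),
            class = "ugic_params")
}

#' @export
print.ugic_params <- function(x, ...) {
  cat("<ugic_params> ", nrow(x$space), " states; discount ",
      x$discount_rate, "\n provenance: ",
      paste(names(x$provenance), x$provenance, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Override parameter values in a parameter set
#'
#' Applies named value overrides and rebuilds the dependent pieces
#' (transition matrix when a natural-history rate changes, prevalence
#' when `prev_scale` changes). Recognized ids are those in the parameter
#' set's `uncertainty$meta` table.
#'
#' @param pset A `ugic_params`.
#' @param values Named numeric vector of overrides.
#' @return The modified `ugic_params`.
#' @export
apply_overrides <- function(pset, values) {
  if (length(values) == 0) return(pset)
  stopifnot(!is.null(names(values)))
  sc <- pset$screening
  ec <- pset$econ
  rebuild_tmat <- FALSE
  tckey <- c(tc_ec_sev = "ec_sev", tc_ec_early = "ec_early",
             tc_ec_adv = "ec_adv", tc_gc_hgin = "gc_hgin",
             tc_gc_early = "gc_early", tc_gc_adv = "gc_adv")
  for (id in names(values)) {
    v <- values[[id]]
    if (id %in% c("compliance_screening", "sens_ec", "spec_ec", "sens_gc",
                  "spec_gc", "complication_rate")) {
      slot <- if (id == "complication_rate") "complication_rate" else id
      sc[[slot]] <- v
    } else if (id == "compliance_reexamination") {
      sc$compliance_reexamination <- v
    } else if (grepl("^selfexam_", id)) {
      sc$self_exam_probs[[sub("selfexam_", "", id)]] <- v
    } else if (id %in% names(tckey)) {
      sc$treatment_compliance[[tckey[[id]]]] <- v
    } else if (id == "c_mobilization") {
      ec$screening_mobilization_cost <- v
    } else if (id == "c_endoscopy") {
      ec$endoscopy_cost <- v
    } else if (id == "c_complication") {
      ec$complication_treatment_cost <- v
    } else if (grepl("^ctx_", id)) {
      ec$initial_treatment_cost[[sub("ctx_", "", id)]] <- v
    } else if (grepl("^ca_", id)) {
      ec$annual_healthcare_cost[[sub("ca_", "", id)]] <- v
    } else if (grepl("^u_", id)) {
      ec$utilities[[sub("u_", "", id)]] <- min(max(v, 0), 1)
    } else if (id == "discount_rate") {
      pset$discount_rate <- v
    } else if (id == "prev_scale") {
      cfg <- pset$config
      cfg$prevalence_scale <- cfg$prevalence_scale * v
      pset$init_prev <- synth_initial_prevalence(cfg$seed, cfg, pset$space,
                                                 size = 1)
    } else if (id %in% names(pset$rates)) {
      pset$rates[[id]] <- v
      rebuild_tmat <- TRUE
    } else {
      stop("unknown parameter id '", id, "'", call. = FALSE)
    }
  }
  pset$screening <- do.call(screening_params, sc[setdiff(names(sc), NULL)])
  pset$econ <- do.call(econ_params, list(
    screening_mobilization_cost = ec$screening_mobilization_cost,
    endoscopy_cost = ec$endoscopy_cost,
    complication_treatment_cost = ec$complication_treatment_cost,
    initial_treatment_cost = ec$initial_treatment_cost,
    annual_healthcare_cost = ec$annual_healthcare_cost,
    utilities = ec$utilities,
    exchange_rate = ec$exchange_rate))
  if (rebuild_tmat)
    pset$tmat <- build_transition_matrix(pset$rates, pset$space)
  pset
}

#' Run the cohort model for several strategies on one parameter set
#'
#' The common model runner behind the base-case table, the one-way sweeps
#' and the probabilistic analysis.
#'
#' @param pset A `ugic_params`.
#' @param initial_mean_age Cohort entry mean age.
#' @param strategies List of `ugic_strategy` (default full menu).
#' @param cohort_size Persons, default 100000.
#' @param terminal_mean_age Default 90.
#' @param keep_trace Passed to [run_cohort()]; default `FALSE`.
#' @return `data.frame(strategy, qalys, cost)` of discounted totals.
#' @export
run_strategies <- function(pset, initial_mean_age,
                           strategies = strategy_menu(),
                           cohort_size = 100000, terminal_mean_age = 90,
                           keep_trace = FALSE) {
  cs <- cohort_spec(cohort_size, initial_mean_age, terminal_mean_age)
  init <- pset$init_prev * cohort_size
  out <- lapply(strategies, function(st) {
    run_cohort(pset$space, pset$tmat, st, pset$screening, pset$econ, cs,
               discount_rate = pset$discount_rate,
               life_table = pset$life_table,
               init_occupancy = init, keep_trace = keep_trace)$outcome
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("strategy", "qalys", "cost")]
}

#' Write / read a parameter set as structured text files
#'
#' `write_parameter_set` emits the schema the model consumes: a YAML file
#' with the scalar parameters, provenance and rates, plus CSVs for the
#' transition matrix, initial prevalence and life table. A directory in
#' the same schema holding supplement-derived values (a verbatim
#' transition matrix, baseline prevalence and yearbook life table) can be
#' read back with `read_parameter_set` and drops into every analysis
#' unchanged.
#'
#' @param pset A `ugic_params`.
#' @param dir Directory to write to / read from.
#' @return `read_parameter_set` returns a `ugic_params`.
#' @export
write_parameter_set <- function(pset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- pset$screening
  ec <- pset$econ
  yaml::write_yaml(list(
    provenance = as.list(pset$provenance),
    discount_rate = pset$discount_rate,
    screening = list(
      compliance_screening = sc$compliance_screening,
      compliance_reexamination = sc$compliance_reexamination,
      sens_ec = sc$sens_ec, spec_ec = sc$spec_ec,
      sens_gc = sc$sens_gc, spec_gc = sc$spec_gc,
      complication_rate = sc$complication_rate,
      self_exam_probs = as.list(sc$self_exam_probs),
      treatment_compliance = as.list(sc$treatment_compliance),
      fp_disutility = sc$fp_disutility),
    econ = list(
      screening_mobilization_cost = ec$screening_mobilization_cost,
      endoscopy_cost = ec$endoscopy_cost,
      complication_treatment_cost = ec$complication_treatment_cost,
      initial_treatment_cost = as.list(ec$initial_treatment_cost),
      annual_healthcare_cost = as.list(ec$annual_healthcare_cost),
      utilities = as.list(ec$utilities),
      exchange_rate = ec$exchange_rate),
    rates = as.list(pset$rates)),
    file.path(dir, "parameters.yaml"))
  write_transition_csv(pset$tmat, file.path(dir, "transition_matrix.csv"))
  utils::write.csv(data.frame(state = names(pset$init_prev),
                              proportion = unname(pset$init_prev)),
                   file.path(dir, "initial_prevalence.csv"),
                   row.names = FALSE)
  utils::write.csv(pset$life_table, file.path(dir, "life_table.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "parameters.yaml"))
  space <- build_state_space()
  tmat <- read_transition_csv(file.path(dir, "transition_matrix.csv"))
  chk <- validate_matrix(tmat, space)
  if (!chk$ok)
    stop("transition matrix in '", dir, "' invalid: ",
         paste(chk$problems, collapse = "; "), call. = FALSE)
  prev_df <- utils::read.csv(file.path(dir, "initial_prevalence.csv"))
  prev <- stats::setNames(prev_df$proportion, prev_df$state)[space$id]
  names(prev) <- space$id
  lt <- utils::read.csv(file.path(dir, "life_table.csv"))
  sc <- y$screening
  ec <- y$econ
  rates <- unlist(y$rates)
  tab <- default_table1_params()
  synth <- .synth_param_meta(rates)
  structure(list(
    space = space, rates = rates, tmat = tmat, init_prev = prev,
    life_table = lt,
    screening = screening_params(
      compliance_screening = sc$compliance_screening,
      compliance_reexamination = sc$compliance_reexamination,
      sens_ec = sc$sens_ec, spec_ec = sc$spec_ec,
      sens_gc = sc$sens_gc, spec_gc = sc$spec_gc,
      complication_rate = sc$complication_rate,
      self_exam_probs = unlist(sc$self_exam_probs),
      treatment_compliance = unlist(sc$treatment_compliance),
      fp_disutility = sc$fp_disutility),
    econ = econ_params(
      screening_mobilization_cost = ec$screening_mobilization_cost,
      endoscopy_cost = ec$endoscopy_cost,
      complication_treatment_cost = ec$complication_treatment_cost,
      initial_treatment_cost = unlist(ec$initial_treatment_cost),
      annual_healthcare_cost = unlist(ec$annual_healthcare_cost),
      utilities = unlist(ec$utilities),
      exchange_rate = ec$exchange_rate),
    discount_rate = y$discount_rate,
    uncertainty = list(meta = rbind(tab$meta, synth$meta),
                       dists = c(tab$dists, synth$dists)),
    provenance = unlist(y$provenance),
    config = synthetic_config()),
    class = "ugic_params")
}
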