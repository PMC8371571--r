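#' Cost and utility parameters
#'
#' Holds every economic input of the model in 2019 US dollars: per-event
#' screening costs, one-time initial treatment costs and annual health-care
#' costs by stage, and utility scores by stage. Defaults are the published
#' base-case values (endoscopic examination $47.87, early-EC initial
#' treatment $7732, advanced-GC utility 0.57, ...). Stage keys are
#' `ec_sev`, `ec_early`, `ec_adv`, `gc_hgin`, `gc_early`, `gc_adv`;
#' utilities additionally carry `ec_mild`, `ec_mod` and `gc_lgin`.
#'
#' @param screening_mobilization_cost US$ per invited person per round.
#' @param endoscopy_cost US$ per examination (also the reexamination cost).
#' @param complication_treatment_cost US$ per complication event.
#' @param initial_treatment_cost Named US$ per newly treated case.
#' @param annual_healthcare_cost Named US$ per person-year in a detected
#'   or posttreatment stage.
#' @param utilities Named utility scores in `[0, 1]`; normal is 1 and
#'   death 0 by construction.
#' @param exchange_rate CNY per USD used for currency conversion
#'   (2019 average, 6.8968).
#' @return An object of class `ugic_econ_params`.
#' @export
econ_params <- function(screening_mobilization_cost = 1.05,
                        endoscopy_cost = 47.87,
                        complication_treatment_cost = 113.68,
                        initial_treatment_cost = c(ec_sev = 1604,
                                                   ec_early = 7732,
                                                   ec_adv = 7320,
                                                   gc_hgin = 1423,
                                                   gc_early = 7548,
                                                   gc_adv = 7086),
                        annual_healthcare_cost = c(ec_sev = 216,
                                                   ec_early = 367,
                                                   ec_adv = 342,
                                                   gc_hgin = 243,
                                                   gc_early = 409,
                                                   gc_adv = 435),
                        utilities = c(ec_mild = 1.00, ec_mod = 1.00,
                                      ec_sev = 0.84, ec_early = 0.70,
                                      ec_adv = 0.61, gc_lgin = 1.00,
                                      gc_hgin = 0.92, gc_early = 0.75,
                                      gc_adv = 0.57),
                        exchange_rate = 6.8968) {
  costs <- c(screening_mobilization_cost, endoscopy_cost,
             complication_treatment_cost, initial_treatment_cost,
             annual_healthcare_cost)
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  if (any(utilities < 0 | utilities > 1))
    stop("utilities must lie in [0, 1]", call. = FALSE)
  if (exchange_rate <= 0)
    stop("exchange rate must be positive", call. = FALSE)
  structure(list(screening_mobilization_cost = screening_mobilization_cost,
                 endoscopy_cost = endoscopy_cost,
                 complication_treatment_cost = complication_treatment_cost,
                 initial_treatment_cost = initial_treatment_cost,
                 annual_healthcare_cost = annual_healthcare_cost,
                 utilities = utilities,
                 exchange_rate = exchange_rate),
            class = "ugic_econ_params")
}

# Stage key of a state for utility / annual-cost lookup, or NA.
.stage_key <- function(space, i) {
  org <- c(esophagus = "ec", stomach = "gc")[space$organ[i]]
  stg <- c(mild_dysplasia = "mild", moderate_dysplasia = "mod",
           severe_dysplasia_cis = "sev", early_cancer = "early",
           advanced_cancer = "adv", lgin = "lgin", hgin_cis = "hgin")[space$stage[i]]
  ifelse(is.na(org) | is.na(stg), NA_character_, paste(org, stg, sep = "_"))
}

#' Utility score per state
#'
#' Utilities are stage-level: normal 1, death 0, and the stage's score for
#' every detection/treatment status of that stage (a treated patient keeps
#' the stage's utility).
#'
#' @param econ A `ugic_econ_params`.
#' @param space A `ugic_space`.
#' @return Named numeric vector aligned to the space.
#' @export
state_utilities <- function(econ, space) {
  u <- numeric(nrow(space))
  for (i in seq_len(nrow(space))) {
    u[i] <- switch(space$stage[i], normal = 1, death = 0, {
      key <- .stage_key(space, i)
      if (!key %in% names(econ$utilities))
        stop("missing utility for stage key '", key, "'", call. = FALSE)
      econ$utilities[[key]]
    })
  }
  stats::setNames(u, space$id)
}

#' Annual health-care cost per state
#'
#' Accrues for detected cancer/precancer states of treatable stages and
#' for posttreatment states; undetected disease, surveillance-tier
#' precancer, normal and death cost nothing per year.
#'
#' @inheritParams state_utilities
#' @return Named numeric vector (US$/person-year) aligned to the space.
#' @export
state_annual_costs <- function(econ, space) {
  cost <- numeric(nrow(space))
  for (i in seq_len(nrow(space))) {
    if (space$detection[i] == "detected") {
      key <- .stage_key(space, i)
      if (key %in% names(econ$annual_healthcare_cost))
        cost[i] <- econ$annual_healthcare_cost[[key]]
    }
  }
  stats::setNames(cost, space$id)
}

#' Per-cycle rewards from half-cycle-corrected occupancy
#'
#' QALYs are occupancy-weighted utilities over the cycle minus event
#' disutilities; cost is occupancy-weighted annual health-care cost plus
#' event costs (screening round, initial treatment, complications).
#'
#' @param occupancy_halfcycle Named occupancy vector (average of start- and
#'   end-of-cycle occupancy).
#' @param event_tally Named vector with at least `cost` and `disutility`
#'   entries (0 if absent).
#' @param econ A `ugic_econ_params`.
#' @param space A `ugic_space`.
#' @param cycle_length Years per cycle, default 1.
#' @return List with `qalys`, `cost`, and the split into `state_qalys`,
#'   `event_disutility`, `state_cost`, `event_cost`.
#' @export
cycle_rewards <- function(occupancy_halfcycle, event_tally = c(), econ, space,
                          cycle_length = 1) {
  .check_occupancy(occupancy_halfcycle, space)
  u <- state_utilities(econ, space)
  ac <- state_annual_costs(econ, space)
  ev_cost <- if ("cost" %in% names(event_tally)) event_tally[["cost"]] else 0
  ev_dis <- if ("disutility" %in% names(event_tally)) event_tally[["disutility"]] else 0
  state_qalys <- sum(occupancy_halfcycle * u) * cycle_length
  state_cost <- sum(occupancy_halfcycle * ac) * cycle_length
  list(qalys = state_qalys - ev_dis,
       cost = state_cost + ev_cost,
       state_qalys = state_qalys, event_disutility = ev_dis,
       state_cost = state_cost, event_cost = ev_cost)
}

#' Convert 2019 Chinese yuan to US dollars
#'
#' @param amount_cny Amount in CNY.
#' @param rate CNY per USD; default 6.8968 (2019 average).
#' @return Amount in US$.
#' @examples
#' convert_currency(6.8968)  # 1
#' @export
convert_currency <- function(amount_cny, rate = 6.8968) {
  if (rate <= 0) stop("exchange rate must be positive", call. = FALSE)
  if (any(amount_cny < 0)) stop("amount must be non-negative", call. = FALSE)
  amount_cny / rate
}
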