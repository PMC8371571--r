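#' Define a screening strategy
#'
#' A strategy is a screening frequency plus an eligibility window. The
#' menu considered for population screening is: no screening, once per
#' lifetime, and every 10, 5, 3 or 2 years, offered to people aged 40-69.
#'
#' @param interval `"none"`, `"once"`, or a positive integer number of
#'   years between screening rounds (one of 2, 3, 5, 10).
#' @param name Optional label; defaults to a descriptive one.
#' @param eligible_ages Inclusive age bounds for screening eligibility,
#'   default `c(40, 69)`.
#' @return An object of class `ugic_strategy`.
#' @export
strategy <- function(interval, name = NULL, eligible_ages = c(40, 69)) {
  if (is.character(interval)) {
    interval <- match.arg(interval, c("none", "once"))
  } else {
    if (!is.numeric(interval) || length(interval) != 1 ||
        !(interval %in% c(2, 3, 5, 10)))
      stop("interval must be 'none', 'once', or one of 2, 3, 5, 10 years",
           call. = FALSE)
    interval <- as.integer(interval)
  }
  if (length(eligible_ages) != 2 || eligible_ages[1] > eligible_ages[2])
    stop("eligible_ages must be ordered bounds", call. = FALSE)
  if (is.null(name)) {
    name <- switch(as.character(interval),
                   none = "no_screening",
                   once = "once_per_lifetime",
                   paste0("every_", interval, "y"))
  }
  structure(list(name = name, interval = interval,
                 eligible_ages = eligible_ages),
            class = "ugic_strategy")
}

#' The default strategy menu
#'
#' @param eligible_ages Eligibility window passed to every strategy.
#' @return Named list of the six `ugic_strategy` objects, least to most
#'   intensive.
#' @export
strategy_menu <- function(eligible_ages = c(40, 69)) {
  ints <- list("none", "once", 10L, 5L, 3L, 2L)
  out <- lapply(ints, strategy, eligible_ages = eligible_ages)
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Cycles at which screening is offered
#'
#' Screening rounds fall at cycles `0, k, 2k, ...` while the cohort's mean
#' age stays within the eligibility window; `"once"` gives cycle 0 only and
#' `"none"` gives no rounds. With a 40-69 window this reproduces which
#' strategies remain distinguishable at older initial ages (e.g. at mean
#' age 62 the every-10-years schedule collapses onto once per lifetime).
#'
#' @param strategy A `ugic_strategy`.
#' @param initial_mean_age Cohort mean age at entry (years).
#' @param horizon_cycles Number of model cycles available.
#' @return Integer vector of 0-based cycle indices.
#' @examples
#' screening_cycles(strategy(2), 67, 23)  # 0 and 2
#' @export
screening_cycles <- function(strategy, initial_mean_age, horizon_cycles) {
  stopifnot(inherits(strategy, "ugic_strategy"))
  upper <- strategy$eligible_ages[2]
  if (identical(strategy$interval, "none")) return(integer(0))
  if (initial_mean_age > upper || initial_mean_age < strategy$eligible_ages[1])
    return(integer(0))
  if (identical(strategy$interval, "once")) return(0L)
  k <- strategy$interval
  t <- seq.int(0L, max(0L, horizon_cycles - 1L), by = k)
  t[initial_mean_age + t <= upper]
}

#' Screening, detection and treatment parameters
#'
#' Base-case values follow the published estimates for combined endoscopic
#' EC/GC screening in high-risk areas of China: 49% screening compliance,
#' endoscopy sensitivity/specificity 0.96/0.90 for esophageal and
#' 0.89/1.00 for gastric lesions, a 0.009% complication rate, annual
#' self-initiated examination probabilities of 0.01 (severe dysplasia/CIS
#' and HGIN/CIS), 0.20 (early cancer) and 0.70 (advanced cancer), and
#' stage-specific treatment compliance.
#'
#' @param compliance_screening Probability an invited person attends a round.
#' @param compliance_reexamination Annual reexamination compliance for
#'   screen-detected mild/moderate dysplasia and LGIN under surveillance.
#' @param sens_ec,spec_ec,sens_gc,spec_gc Endoscopy test characteristics.
#' @param complication_rate Per-examination probability of a clinically
#'   significant complication.
#' @param self_exam_probs Named annual self-detection probabilities for
#'   tiers `severe`, `early`, `advanced`.
#' @param treatment_compliance Named probabilities of completing treatment,
#'   by `ec_sev`, `ec_early`, `ec_adv`, `gc_hgin`, `gc_early`, `gc_adv`.
#' @param fp_disutility QALY decrement per false-positive result.
#' @return An object of class `ugic_screening_params`.
#' @export
screening_params <- function(compliance_screening = 0.49,
                             compliance_reexamination = 0.67,
                             sens_ec = 0.96, spec_ec = 0.90,
                             sens_gc = 0.89, spec_gc = 1.00,
                             complication_rate = 0.00009,
                             self_exam_probs = c(severe = 0.01,
                                                 early = 0.20,
                                                 advanced = 0.70),
                             treatment_compliance = c(ec_sev = 0.7458,
                                                      ec_early = 0.9405,
                                                      ec_adv = 0.9643,
                                                      gc_hgin = 0.5455,
                                                      gc_early = 0.9000,
                                                      gc_adv = 0.9643),
                             fp_disutility = 0.001) {
  probs <- c(compliance_screening, compliance_reexamination, sens_ec, spec_ec,
             sens_gc, spec_gc, complication_rate, self_exam_probs,
             treatment_compliance)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (!all(c("severe", "early", "advanced") %in% names(self_exam_probs)))
    stop("self_exam_probs needs entries severe, early, advanced", call. = FALSE)
  structure(list(compliance_screening = compliance_screening,
                 compliance_reexamination = compliance_reexamination,
                 sens_ec = sens_ec, spec_ec = spec_ec,
                 sens_gc = sens_gc, spec_gc = spec_gc,
                 complication_rate = complication_rate,
                 self_exam_probs = self_exam_probs,
                 treatment_compliance = treatment_compliance,
                 fp_disutility = fp_disutility),
            class = "ugic_screening_params")
}

.check_occupancy <- function(occupancy, space) {
  if (is.null(names(occupancy)) || !identical(names(occupancy), space$id))
    stop("occupancy must be a named vector aligned to the state space",
         call. = FALSE)
  if (any(occupancy < 0))
    stop("negative occupancy", call. = FALSE)
  invisible(TRUE)
}

# Self-detection tier of a stage, or NA if not self-detectable.
.self_tier <- function(stage) {
  switch(stage,
         severe_dysplasia_cis = , hgin_cis = "severe",
         early_cancer = "early",
         advanced_cancer = "advanced",
         NA_character_)
}

#' Apply one screening round to a cohort occupancy vector
#'
#' A fraction `compliance_screening` of the invited pool (normal plus all
#' undetected lesion/cancer states; people already diagnosed or treated
#' are not re-invited) attends. Attendees with an undetected lesion are
#' detected with the organ-specific sensitivity; attendees free of a
#' lesion in one organ yield a false positive for that organ at one minus
#' its specificity, each triggering one reexamination at the endoscopy
#' cost and a small QALY loss; complications accrue per attendee.
#' Mobilization cost is charged per invited person, examination cost per
#' attendee. Mass is conserved.
#'
#' @param occupancy Named non-negative vector over the state space.
#' @param params A `ugic_screening_params`.
#' @param econ A `ugic_econ_params` (for event costs).
#' @param space A `ugic_space`.
#' @return List with `occupancy` (updated), `newly_detected` (vector of
#'   mass moved undetected to detected, named by the detected state), and
#'   `tally` (true_positives, false_positives, complications,
#'   reexaminations, cost, disutility).
#' @export
apply_screening_event <- function(occupancy, params, econ, space) {
  .check_occupancy(occupancy, space)
  invited_ids <- c("normal", undetected_states(space))
  invited_ids <- setdiff(invited_ids, "death")
  n_invited <- sum(occupancy[invited_ids])
  attend <- occupancy[invited_ids] * params$compliance_screening
  n_attend <- sum(attend)

  newly <- stats::setNames(numeric(nrow(space)), space$id)
  tp <- 0
  for (id in undetected_states(space)) {
    i <- match(id, space$id)
    sens <- if (space$organ[i] == "esophagus") params$sens_ec else params$sens_gc
    det <- attend[[id]] * sens
    if (det > 0) {
      did <- space$id[space$organ == space$organ[i] &
                        space$stage == space$stage[i] &
                        space$detection == "detected" &
                        space$treatment == "untreated"]
      occupancy[[id]] <- occupancy[[id]] - det
      occupancy[[did]] <- occupancy[[did]] + det
      newly[[did]] <- newly[[did]] + det
      tp <- tp + det
    }
  }
  # False positives: per attendee and organ without a lesion in that organ.
  att_normal <- attend[["normal"]]
  att_ec <- sum(attend[names(attend) %in%
                         space$id[space$organ == "esophagus"]])
  att_gc <- sum(attend[names(attend) %in%
                         space$id[space$organ == "stomach"]])
  fp <- (att_normal + att_gc) * (1 - params$spec_ec) +
    (att_normal + att_ec) * (1 - params$spec_gc)
  complications <- n_attend * params$complication_rate
  cost <- n_invited * econ$screening_mobilization_cost +
    n_attend * econ$endoscopy_cost +
    fp * econ$endoscopy_cost +
    complications * econ$complication_treatment_cost
  tally <- c(true_positives = tp, false_positives = fp,
             complications = complications, reexaminations = fp,
             cost = cost, disutility = fp * params$fp_disutility)
  list(occupancy = occupancy, newly_detected = newly, tally = tally)
}

#' Apply annual self-initiated examination
#'
#' Every cycle, undetected severe dysplasia/CIS or HGIN/CIS, early cancer
#' and advanced cancer come to clinical attention at their stage-specific
#' annual probabilities; milder lesions are asymptomatic and never
#' self-detected.
#'
#' @inheritParams apply_screening_event
#' @return List with `occupancy` and `newly_detected` as in
#'   [apply_screening_event()].
#' @export
apply_self_detection <- function(occupancy, params, space) {
  .check_occupancy(occupancy, space)
  newly <- stats::setNames(numeric(nrow(space)), space$id)
  for (id in undetected_states(space)) {
    i <- match(id, space$id)
    tier <- .self_tier(space$stage[i])
    if (is.na(tier)) next
    p <- params$self_exam_probs[[tier]]
    det <- occupancy[[id]] * p
    if (det > 0) {
      did <- space$id[space$organ == space$organ[i] &
                        space$stage == space$stage[i] &
                        space$detection == "detected" &
                        space$treatment == "untreated"]
      occupancy[[id]] <- occupancy[[id]] - det
      occupancy[[did]] <- occupancy[[did]] + det
      newly[[did]] <- newly[[did]] + det
    }
  }
  list(occupancy = occupancy, newly_detected = newly)
}

# Map a treatable detected state id to its treatment-compliance key and
# posttreatment state id.
.treat_key <- function(space, id) {
  i <- match(id, space$id)
  org <- c(esophagus = "ec", stomach = "gc")[[space$organ[i]]]
  stg <- c(severe_dysplasia_cis = "sev", hgin_cis = "hgin",
           early_cancer = "early", advanced_cancer = "adv")[[space$stage[i]]]
  paste(org, stg, sep = "_")
}

#' Offer treatment to newly diagnosed patients
#'
#' The stage-specific compliant fraction of mass newly arrived in a
#' detected treatable state (severe dysplasia/CIS, HGIN/CIS, early or
#' advanced cancer) moves to the matching posttreatment state and incurs
#' the stage's initial treatment cost; the rest remains detected but
#' untreated and follows natural history.
#'
#' @param occupancy Named occupancy vector.
#' @param newly_detected Vector of mass newly arrived in detected states
#'   this cycle (same alignment).
#' @param params A `ugic_screening_params` (for treatment compliance).
#' @param econ A `ugic_econ_params` (for initial treatment costs).
#' @param space A `ugic_space`.
#' @return List with `occupancy`, `treated` (named vector of treated mass
#'   per stage key) and `cost` (initial-treatment spend).
#' @export
apply_treatment <- function(occupancy, newly_detected, params, econ, space) {
  .check_occupancy(occupancy, space)
  cost <- 0
  treated <- c()
  for (id in treatable_detected_states(space)) {
    key <- .treat_key(space, id)
    if (!key %in% names(params$treatment_compliance))
      stop("no treatment compliance entry for stage '", key, "'",
           call. = FALSE)
    mass <- min(newly_detected[[id]], occupancy[[id]])
    tx <- mass * params$treatment_compliance[[key]]
    if (tx > 0) {
      pt <- sub("_d$", "_pt", id)
      occupancy[[id]] <- occupancy[[id]] - tx
      occupancy[[pt]] <- occupancy[[pt]] + tx
      cost <- cost + tx * econ$initial_treatment_cost[[key]]
    }
    treated[key] <- tx
  }
  list(occupancy = occupancy, treated = treated, cost = cost)
}
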