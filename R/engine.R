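#' Cohort specification
#'
#' A closed cohort of `size` persons entering at one of the six band mean
#' ages and followed with 1-year cycles until the mean age reaches the
#' terminal age (90 years).
#'
#' @param size Cohort size, default 100000.
#' @param initial_mean_age One of 42, 47, 52, 57, 62, 67 years.
#' @param terminal_mean_age Mean age at termination, default 90.
#' @param cycle_length Years per cycle, default 1.
#' @return An object of class `ugic_cohort`.
#' @export
cohort_spec <- function(size = 100000, initial_mean_age = 42,
                        terminal_mean_age = 90, cycle_length = 1) {
  if (size <= 0) stop("cohort size must be positive", call. = FALSE)
  if (terminal_mean_age < initial_mean_age)
    stop("terminal age before initial age", call. = FALSE)
  structure(list(size = size, initial_mean_age = initial_mean_age,
                 terminal_mean_age = terminal_mean_age,
                 cycle_length = cycle_length,
                 horizon_cycles = as.integer(
                   (terminal_mean_age - initial_mean_age) / cycle_length)),
            class = "ugic_cohort")
}

#' Annual mortality probability from a 5-year survival rate
#'
#' Converts a 5-year survival proportion `S` into the constant annual
#' death probability consistent with it, `1 - S^(1/5)`. Used to derive
#' cancer-specific mortality of advanced disease from published survival.
#'
#' @param five_year_survival Proportion in `(0, 1]`.
#' @return Annual mortality probability.
#' @examples
#' annual_prob_from_survival(0.303)  # ~0.2124
#' @export
annual_prob_from_survival <- function(five_year_survival) {
  if (any(five_year_survival <= 0) || any(five_year_survival > 1))
    stop("five-year survival must lie in (0, 1]", call. = FALSE)
  1 - five_year_survival^(1 / 5)
}

#' Overlay age-specific background mortality on a transition matrix
#'
#' Adds the life-table death probability at the cohort's current mean age
#' to every living state's row, rescaling the row's other entries
#' proportionally so rows stay stochastic (competing risks by proportional
#' hazards at the probability scale).
#'
#' @param m Validated transition matrix.
#' @param life_table `data.frame` with columns `age` and `qx` (annual
#'   death probability).
#' @param current_mean_age Cohort mean age this cycle.
#' @return Age-adjusted matrix.
#' @examples
#' # a background qx of 0.01 turns a row (0.9 stay, 0.1 progress)
#' # into (0.891, 0.099, 0.010 death)
#' @export
overlay_background_mortality <- function(m, life_table, current_mean_age) {
  row <- match(current_mean_age, life_table$age)
  if (is.na(row))
    stop("age ", current_mean_age, " outside life-table support", call. = FALSE)
  q <- life_table$qx[row]
  out <- m
  living <- setdiff(rownames(m), "death")
  out[living, ] <- m[living, ] * (1 - q)
  out[living, "death"] <- m[living, "death"] * (1 - q) + q
  out
}

#' Run the closed-cohort Markov simulation for one strategy
#'
#' Iterates annual cycles from the cohort's initial mean age to the
#' terminal age. Each cycle applies, in order: the screening round (if
#' offered), self-initiated examination, the treatment offer to newly
#' diagnosed mass, surveillance reexamination costs, then the
#' natural-history transition with age-specific background mortality
#' overlaid. State rewards (utilities, annual health-care costs) use the
#' trapezoidal half-cycle correction (mean of start- and end-of-cycle
#' occupancy); one-time event costs and disutilities are discounted at
#' mid-cycle by default.
#'
#' @param space A `ugic_space`.
#' @param tmat Validated annual transition matrix (without background
#'   mortality).
#' @param strategy A `ugic_strategy`.
#' @param screening A `ugic_screening_params`.
#' @param econ A `ugic_econ_params`.
#' @param cohort A `ugic_cohort`.
#' @param discount_rate Annual discount rate for QALYs and costs,
#'   default 0.05 (a value outside the 0-0.08 range is accepted with a
#'   warning).
#' @param life_table `data.frame(age, qx)` covering the model ages.
#' @param init_occupancy Named initial occupancy (all detected and
#'   posttreatment mass zero); must sum to the cohort size.
#' @param event_timing Discounting of one-time event costs: `"midcycle"`
#'   (default) or `"start"`.
#' @param keep_trace Keep the per-cycle trace (set `FALSE` for bulk
#'   re-runs such as probabilistic sensitivity analysis).
#' @return List of class `ugic_run` with `outcome` (`strategy`,
#'   `qalys`, `cost`, discounted, plus undiscounted totals) and `trace`
#'   (per-cycle `data.frame`: cycle, age, occupancy columns, event
#'   tallies, undiscounted and discounted rewards).
#' @export
run_cohort <- function(space, tmat, strategy, screening, econ, cohort,
                       discount_rate = 0.05, life_table, init_occupancy,
                       event_timing = c("midcycle", "start"),
                       keep_trace = TRUE) {
  event_timing <- match.arg(event_timing)
  chk <- validate_matrix(tmat, space)
  if (!chk$ok)
    stop("invalid transition matrix: ", paste(chk$problems, collapse = "; "),
         call. = FALSE)
  if (discount_rate < 0 || discount_rate > 0.08)
    warning("discount rate ", discount_rate, " outside the 0-0.08 range")
  .check_occupancy(init_occupancy, space)
  if (abs(sum(init_occupancy) - cohort$size) > 1e-6 * cohort$size)
    stop("initial occupancy must sum to the cohort size", call. = FALSE)

  H <- cohort$horizon_cycles
  occ <- init_occupancy
  pending <- stats::setNames(numeric(nrow(space)), space$id)
  scycles <- screening_cycles(strategy, cohort$initial_mean_age, H)
  surv_ids <- surveillance_states(space)
  treatable_ids <- treatable_detected_states(space)
  det_untreated <- detected_states(space)
  pt_ids <- posttreatment_states(space)

  trace <- vector("list", H)
  tot <- c(qalys = 0, cost = 0, qalys_disc = 0, cost_disc = 0)
  for (t in seq_len(H) - 1L) {
    age <- cohort$initial_mean_age + t * cohort$cycle_length
    tally <- c(true_positives = 0, false_positives = 0, complications = 0,
               reexaminations = 0, cost = 0, disutility = 0)
    newly <- pending
    if (t %in% scycles) {
      scr <- apply_screening_event(occ, screening, econ, space)
      occ <- scr$occupancy
      newly <- newly + scr$newly_detected
      tally <- tally + scr$tally
    }
    sd <- apply_self_detection(occ, screening, space)
    occ <- sd$occupancy
    newly <- newly + sd$newly_detected
    tx <- apply_treatment(occ, newly, screening, econ, space)
    occ <- tx$occupancy
    tally[["cost"]] <- tally[["cost"]] + tx$cost
    # annual surveillance endoscopy for compliant screen-detected
    # mild/moderate dysplasia and LGIN
    surv_cost <- screening$compliance_reexamination *
      sum(occ[surv_ids]) * econ$endoscopy_cost
    tally[["cost"]] <- tally[["cost"]] + surv_cost
    tally[["reexaminations"]] <- tally[["reexaminations"]] +
      screening$compliance_reexamination * sum(occ[surv_ids])

    m_age <- overlay_background_mortality(tmat, life_table, age)
    occ_end <- drop(occ %*% m_age)
    # mass newly arriving in a detected treatable state by progression
    # under surveillance/observation or by recurrence: offered treatment
    # next cycle
    src <- c(det_untreated, pt_ids)
    pending <- stats::setNames(numeric(nrow(space)), space$id)
    for (j in treatable_ids) {
      from <- setdiff(src, j)
      pending[[j]] <- sum(occ[from] * m_age[from, j])
    }

    occ_half <- (occ + occ_end) / 2
    rw <- cycle_rewards(occ_half, tally, econ, space, cohort$cycle_length)
    d_mid <- (1 + discount_rate)^-(t + 0.5)
    d_ev <- if (event_timing == "midcycle") d_mid else (1 + discount_rate)^-t
    q_disc <- rw$state_qalys * d_mid - rw$event_disutility * d_ev
    c_disc <- rw$state_cost * d_mid + rw$event_cost * d_ev
    tot <- tot + c(rw$qalys, rw$cost, q_disc, c_disc)

    if (keep_trace) trace[[t + 1L]] <- data.frame(
      cycle = t, age = age, t(occ_end),
      true_positives = tally[["true_positives"]],
      false_positives = tally[["false_positives"]],
      complications = tally[["complications"]],
      reexaminations = tally[["reexaminations"]],
      event_cost = rw$event_cost, state_cost = rw$state_cost,
      qalys = rw$qalys, cost = rw$cost,
      qalys_disc = q_disc, cost_disc = c_disc,
      check.names = FALSE)
    occ <- occ_end
  }
  trace_df <- if (H > 0 && keep_trace) do.call(rbind, trace) else data.frame()
  structure(list(
    outcome = data.frame(strategy = strategy$name,
                         qalys = tot[["qalys_disc"]],
                         cost = tot[["cost_disc"]],
                         qalys_undiscounted = tot[["qalys"]],
                         cost_undiscounted = tot[["cost"]],
                         stringsAsFactors = FALSE),
    trace = trace_df,
    final_occupancy = occ),
    class = "ugic_run")
}

#' Export a cohort trace in tidy long format
#'
#' @param run A `ugic_run`.
#' @param space The `ugic_space` the run used.
#' @return `data.frame` with columns cycle, age, state, occupancy.
#' @export
tidy_trace <- function(run, space) {
  tr <- run$trace
  if (nrow(tr) == 0) return(data.frame())
  out <- do.call(rbind, lapply(space$id, function(id) {
    data.frame(cycle = tr$cycle, age = tr$age, state = id,
               occupancy = tr[[id]], stringsAsFactors = FALSE)
  }))
  out[order(out$cycle, match(out$state, space$id)), , drop = FALSE]
}
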