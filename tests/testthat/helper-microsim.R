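# Independent individual-level Monte-Carlo microsimulation of the same
# screening model. Re-implements the event rules by per-person Bernoulli /
# multinomial sampling; shares only the parameter containers with the
# cohort engine, never its operators. Used as the oracle for the
# cohort-engine equivalence check.

microsim_run <- function(pset, strategy, n = 20000, initial_age = 42,
                         terminal_age = 90, seed = 1) {
  set.seed(seed)
  space <- pset$space
  ids <- space$id
  ns <- nrow(space)
  sc <- pset$screening
  ec <- pset$econ
  r <- pset$discount_rate
  H <- terminal_age - initial_age

  u <- state_utilities(ec, space)
  ac <- state_annual_costs(ec, space)
  is_undet <- space$detection == "undetected"
  is_det_untx <- space$detection == "detected" & space$treatment == "untreated"
  is_pt <- space$treatment == "posttreatment"
  is_surv <- is_det_untx & space$stage %in%
    c("mild_dysplasia", "moderate_dysplasia", "lgin")
  organ <- space$organ
  i_death <- match("death", ids)
  i_normal <- match("normal", ids)
  # detected counterpart / posttreatment target / treatment key per state
  det_of <- vapply(seq_len(ns), function(i) {
    if (!is_undet[i]) return(NA_integer_)
    which(space$organ == organ[i] & space$stage == space$stage[i] &
            is_det_untx)
  }, 0L)
  treatable <- is_det_untx & ((organ == "esophagus" &
      space$stage %in% c("severe_dysplasia_cis", "early_cancer", "advanced_cancer")) |
    (organ == "stomach" &
      space$stage %in% c("hgin_cis", "early_cancer", "advanced_cancer")))
  org_key <- c(esophagus = "ec", stomach = "gc")
  stg_key <- c(severe_dysplasia_cis = "sev", hgin_cis = "hgin",
               early_cancer = "early", advanced_cancer = "adv")
  tkey <- ifelse(treatable,
                 paste(org_key[organ], stg_key[space$stage], sep = "_"), NA)
  pt_of <- match(sub("_d$", "_pt", ids), ids)

  # initial states sampled from the initial prevalence proportions
  state <- sample.int(ns, n, replace = TRUE, prob = pset$init_prev)
  pending <- logical(n)   # newly arrived in a treatable detected state
  qalys <- numeric(n)
  cost <- numeric(n)
  sched <- screening_cycles(strategy, initial_age, H)

  for (t in seq_len(H) - 1L) {
    age <- initial_age + t
    newly <- pending
    pending <- logical(n)
    ev_cost <- numeric(n)
    ev_dis <- numeric(n)
    if (t %in% sched) {
      invited <- state == i_normal | is_undet[state]
      ev_cost[invited] <- ev_cost[invited] + ec$screening_mobilization_cost
      attend <- invited & stats::runif(n) < sc$compliance_screening
      ev_cost[attend] <- ev_cost[attend] + ec$endoscopy_cost
      # true positives
      sens <- ifelse(organ[state] == "esophagus", sc$sens_ec, sc$sens_gc)
      hit <- attend & is_undet[state] & stats::runif(n) < sens
      newly <- newly | hit
      state[hit] <- det_of[state[hit]]
      # false positives per organ without a lesion there
      fp_ec <- attend & organ[state] != "esophagus" &
        stats::runif(n) < (1 - sc$spec_ec)
      fp_gc <- attend & organ[state] != "stomach" &
        stats::runif(n) < (1 - sc$spec_gc)
      nfp <- fp_ec + fp_gc
      ev_cost <- ev_cost + nfp * ec$endoscopy_cost
      ev_dis <- ev_dis + nfp * sc$fp_disutility
      compl <- attend & stats::runif(n) < sc$complication_rate
      ev_cost[compl] <- ev_cost[compl] + ec$complication_treatment_cost
    }
    # self-initiated examination
    tier <- rep(NA_character_, n)
    und <- is_undet[state]
    stg <- space$stage[state]
    tier[und & stg %in% c("severe_dysplasia_cis", "hgin_cis")] <- "severe"
    tier[und & stg == "early_cancer"] <- "early"
    tier[und & stg == "advanced_cancer"] <- "advanced"
    p_self <- ifelse(is.na(tier), 0, sc$self_exam_probs[tier])
    selfdet <- stats::runif(n) < p_self
    newly <- newly | selfdet
    state[selfdet] <- det_of[state[selfdet]]
    # treatment offer to the newly diagnosed in treatable states
    offer <- newly & treatable[state]
    comply <- offer &
      stats::runif(n) < ifelse(is.na(tkey[state]), 0,
                               sc$treatment_compliance[tkey[state]])
    ev_cost[comply] <- ev_cost[comply] +
      ec$initial_treatment_cost[tkey[state[comply]]]
    state[comply] <- pt_of[state[comply]]
    # annual surveillance endoscopy
    re <- is_surv[state] & stats::runif(n) < sc$compliance_reexamination
    ev_cost[re] <- ev_cost[re] + ec$endoscopy_cost
    # natural-history transition with background mortality
    m_age <- overlay_background_mortality(pset$tmat, pset$life_table, age)
    prev_state <- state
    new_state <- state
    for (s in unique(state)) {
      idx <- which(prev_state == s)
      new_state[idx] <- sample.int(ns, length(idx), replace = TRUE,
                                   prob = m_age[s, ])
    }
    state <- new_state
    moved <- state != prev_state
    pending <- moved & treatable[state] &
      (is_det_untx[prev_state] | is_pt[prev_state])
    # rewards: trapezoidal half-cycle correction, mid-cycle discounting
    d_mid <- (1 + r)^-(t + 0.5)
    qalys <- qalys + ((u[prev_state] + u[state]) / 2) * d_mid - ev_dis * d_mid
    cost <- cost + ((ac[prev_state] + ac[state]) / 2) * d_mid + ev_cost * d_mid
  }
  list(qalys = qalys, cost = cost,
       mean_qalys = mean(qalys), mean_cost = mean(cost),
       se_qalys = stats::sd(qalys) / sqrt(n),
       se_cost = stats::sd(cost) / sqrt(n))
}
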