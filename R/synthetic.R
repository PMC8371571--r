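# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's stream afterwards.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for synthetic parameter generation
#'
#' @param seed Integer seed; generation is deterministic given it.
#' @param prevalence_scale Multiplier on the default baseline lesion
#'   prevalences.
#' @param progression_scale Multiplier on the default annual progression
#'   probabilities (0 freezes disease dynamics).
#' @param jitter_sd Log-normal jitter SD applied once to each generated
#'   rate/prevalence (0 for the plain defaults).
#' @param life_table_level,life_table_slope Gompertz-type background
#'   mortality: annual hazard `level * exp(slope * (age - 40))`.
#' @return A list of class `ugic_synth_config`.
#' @export
synthetic_config <- function(seed = 1L, prevalence_scale = 1,
                             progression_scale = 1, jitter_sd = 0.05,
                             life_table_level = 0.002,
                             life_table_slope = 0.085) {
  if (prevalence_scale < 0 || progression_scale < 0)
    stop("scales must be non-negative", call. = FALSE)
  if (life_table_level <= 0 || life_table_slope <= 0)
    stop("life-table shape parameters must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 prevalence_scale = prevalence_scale,
                 progression_scale = progression_scale,
                 jitter_sd = jitter_sd,
                 life_table_level = life_table_level,
                 life_table_slope = life_table_slope),
            class = "ugic_synth_config")
}

# Default annual natural-history rates (SYNTHETIC: stand-ins for the
# supplement-only observational estimates; see the methods vignette for
# the ranges they were drawn from).
.default_rates <- c(
  r_normal_ec_mild = 0.008,   # incidence of mild esophageal dysplasia
  r_ec_mild_mod    = 0.060,
  r_ec_mild_normal = 0.050,   # regression
  r_ec_mod_sev     = 0.070,
  r_ec_mod_mild    = 0.040,
  r_ec_sev_early   = 0.070,
  r_ec_sev_mod     = 0.020,
  r_ec_early_adv   = 0.300,
  r_normal_gc_lgin = 0.010,
  r_gc_lgin_hgin   = 0.050,
  r_gc_lgin_normal = 0.050,
  r_gc_hgin_early  = 0.060,
  r_gc_hgin_lgin   = 0.020,
  r_gc_early_adv   = 0.250,
  r_rec_ec_sev     = 0.020,   # recurrence, posttreatment -> detected
  r_rec_ec_early   = 0.050,
  r_rec_ec_adv     = 0.100,
  r_rec_gc_hgin    = 0.020,
  r_rec_gc_early   = 0.050,
  r_rec_gc_adv     = 0.100,
  surv5_ec_adv     = 0.150,   # 5-year survival, untreated advanced EC
  surv5_gc_adv     = 0.200,
  surv5_ec_adv_pt  = 0.350,   # 5-year survival after treatment
  surv5_gc_adv_pt  = 0.400
)

# Default baseline per-100000 undetected prevalence (SYNTHETIC stand-in
# for baseline endoscopic screening yields in high-risk areas).
.default_prevalence <- c(
  ec_mild_u = 6000, ec_mod_u = 1500, ec_sev_u = 500,
  ec_early_u = 150, ec_adv_u = 50,
  gc_lgin_u = 8000, gc_hgin_u = 300, gc_early_u = 200, gc_adv_u = 50
)

#' Generate the synthetic natural-history rate vector
#'
#' Progression/regression/recurrence rates are the package defaults,
#' scaled by `progression_scale` and jittered once by a seeded log-normal
#' factor; the 5-year survival entries are left unjittered.
#'
#' @param config A `ugic_synth_config`.
#' @return Named rate vector.
#' @export
synth_rates <- function(config = synthetic_config()) {
  r <- .default_rates
  prog <- grep("^r_", names(r))
  with_private_seed(config$seed, {
    if (config$jitter_sd > 0) {
      r[prog] <- r[prog] * exp(stats::rnorm(length(prog), 0, config$jitter_sd))
    }
  })
  r[prog] <- pmin(r[prog] * config$progression_scale, 0.95)
  r
}

#' Build the transition matrix from a natural-history rate vector
#'
#' Structural rules: entry from normal into mild dysplasia / LGIN;
#' stepwise progression along each organ chain with regression between
#' adjacent precancer states; detection status is preserved by natural
#' history (a detected lesion progresses within the detected tier);
#' cancer-specific mortality only from advanced states, derived from
#' 5-year survival via [annual_prob_from_survival()]; recurrence from
#' posttreatment to the corresponding detected state; death absorbing.
#' Background mortality is overlaid per cycle, not stored here.
#'
#' @param rates Named vector as from [synth_rates()].
#' @param space A `ugic_space` (default canonical 26 states).
#' @return Validated transition matrix.
#' @export
build_transition_matrix <- function(rates, space = build_state_space()) {
  n <- nrow(space)
  m <- matrix(0, n, n, dimnames = list(space$id, space$id))
  mort_ec <- annual_prob_from_survival(rates[["surv5_ec_adv"]])
  mort_gc <- annual_prob_from_survival(rates[["surv5_gc_adv"]])
  mort_ec_pt <- annual_prob_from_survival(rates[["surv5_ec_adv_pt"]])
  mort_gc_pt <- annual_prob_from_survival(rates[["surv5_gc_adv_pt"]])

  put <- function(from, to, p) m[from, to] <<- m[from, to] + p
  put("normal", "ec_mild_u", rates[["r_normal_ec_mild"]])
  put("normal", "gc_lgin_u", rates[["r_normal_gc_lgin"]])
  for (sfx in c("u", "d")) {
    s <- function(stub) paste0(stub, "_", sfx)
    # esophageal chain
    put(s("ec_mild"), s("ec_mod"), rates[["r_ec_mild_mod"]])
    put(s("ec_mild"), "normal", rates[["r_ec_mild_normal"]])
    put(s("ec_mod"), s("ec_sev"), rates[["r_ec_mod_sev"]])
    put(s("ec_mod"), s("ec_mild"), rates[["r_ec_mod_mild"]])
    put(s("ec_sev"), s("ec_early"), rates[["r_ec_sev_early"]])
    put(s("ec_sev"), s("ec_mod"), rates[["r_ec_sev_mod"]])
    put(s("ec_early"), s("ec_adv"), rates[["r_ec_early_adv"]])
    put(s("ec_adv"), "death", mort_ec)
    # gastric chain
    put(s("gc_lgin"), s("gc_hgin"), rates[["r_gc_lgin_hgin"]])
    put(s("gc_lgin"), "normal", rates[["r_gc_lgin_normal"]])
    put(s("gc_hgin"), s("gc_early"), rates[["r_gc_hgin_early"]])
    put(s("gc_hgin"), s("gc_lgin"), rates[["r_gc_hgin_lgin"]])
    put(s("gc_early"), s("gc_adv"), rates[["r_gc_early_adv"]])
    put(s("gc_adv"), "death", mort_gc)
  }
  # regression from detected precancer back to normal is allowed above
  # (normal carries no detection flag); recurrence after treatment
  put("ec_sev_pt", "ec_sev_d", rates[["r_rec_ec_sev"]])
  put("ec_early_pt", "ec_early_d", rates[["r_rec_ec_early"]])
  put("ec_adv_pt", "ec_adv_d", rates[["r_rec_ec_adv"]])
  put("ec_adv_pt", "death", mort_ec_pt)
  put("gc_hgin_pt", "gc_hgin_d", rates[["r_rec_gc_hgin"]])
  put("gc_early_pt", "gc_early_d", rates[["r_rec_gc_early"]])
  put("gc_adv_pt", "gc_adv_d", rates[["r_rec_gc_adv"]])
  put("gc_adv_pt", "death", mort_gc_pt)
  m["death", "death"] <- 1
  rs <- rowSums(m)
  if (any(rs > 1 + 1e-12))
    stop("generated rates exceed unit row mass in row(s): ",
         paste(rownames(m)[rs > 1 + 1e-12], collapse = ", "), call. = FALSE)
  diag(m) <- diag(m) + (1 - rs)
  chk <- validate_matrix(m, space)
  if (!chk$ok)
    stop("generated matrix invalid: ", paste(chk$problems, collapse = "; "),
         call. = FALSE)
  m
}

#' Synthetic transition matrix
#'
#' Convenience wrapper: [synth_rates()] then [build_transition_matrix()].
#'
#' @param seed Integer seed (overrides the config's).
#' @param config A `ugic_synth_config`.
#' @param space A `ugic_space`.
#' @return Validated transition matrix, deterministic given the seed.
#' @export
synth_transition_matrix <- function(seed = 1L, config = synthetic_config(seed),
                                    space = build_state_space()) {
  config$seed <- as.integer(seed)
  build_transition_matrix(synth_rates(config), space)
}

#' Synthetic baseline occupancy (initial prevalence)
#'
#' All lesion/cancer mass starts undetected; detected, posttreatment and
#' death states start empty. Prevalences emulate baseline endoscopic
#' screening yields in high-risk areas and are scaled by
#' `prevalence_scale` with a seeded jitter.
#'
#' @param seed Integer seed.
#' @param config A `ugic_synth_config`.
#' @param space A `ugic_space`.
#' @param size Cohort size the vector should sum to, default 100000.
#' @return Named non-negative occupancy vector summing to `size`.
#' @export
synth_initial_prevalence <- function(seed = 1L, config = synthetic_config(seed),
                                     space = build_state_space(),
                                     size = 100000) {
  config$seed <- as.integer(seed)
  prev <- .default_prevalence
  with_private_seed(config$seed + 1L, {
    if (config$jitter_sd > 0)
      prev <- prev * exp(stats::rnorm(length(prev), 0, config$jitter_sd))
  })
  prev <- prev * config$prevalence_scale
  if (sum(prev) >= 100000)
    stop("prevalence_scale too large: lesion mass exceeds the cohort",
         call. = FALSE)
  occ <- stats::setNames(numeric(nrow(space)), space$id)
  keep <- intersect(names(prev), space$id)
  occ[keep] <- prev[keep] * size / 100000
  occ[["normal"]] <- size - sum(occ)
  occ
}

#' Synthetic background life table
#'
#' Gompertz-type adult mortality: annual hazard
#' `level * exp(slope * (age - 40))`, converted to a probability
#' `1 - exp(-hazard)`; increasing in age and bounded in (0, 1). Stands in
#' for a national yearbook life table.
#'
#' @param config A `ugic_synth_config` (uses its two life-table shape
#'   parameters).
#' @param ages Age grid, default 40-90.
#' @return `data.frame(age, qx)`.
#' @export
synth_life_table <- function(config = synthetic_config(), ages = 40:90) {
  h <- config$life_table_level * exp(config$life_table_slope * (ages - 40))
  data.frame(age = ages, qx = 1 - exp(-h))
}
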