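# Canonical stage labels per organ chain. The esophageal (EC) chain runs
# mild dysplasia -> moderate dysplasia -> severe dysplasia/CIS -> early
# cancer -> advanced cancer; the gastric (GC) chain runs LGIN -> HGIN/CIS ->
# early cancer -> advanced cancer.
.ec_stages <- c("mild_dysplasia", "moderate_dysplasia", "severe_dysplasia_cis",
                "early_cancer", "advanced_cancer")
.gc_stages <- c("lgin", "hgin_cis", "early_cancer", "advanced_cancer")

# Stages with a dedicated posttreatment state (endoscopic/surgical therapy).
.default_treatable <- list(
  esophagus = c("severe_dysplasia_cis", "early_cancer", "advanced_cancer"),
  stomach   = c("hgin_cis", "early_cancer", "advanced_cancer")
)

.state_id <- function(organ, stage, suffix) {
  org <- c(esophagus = "ec", stomach = "gc")[[organ]]
  stg <- c(mild_dysplasia = "mild", moderate_dysplasia = "mod",
           severe_dysplasia_cis = "sev", early_cancer = "early",
           advanced_cancer = "adv", lgin = "lgin", hgin_cis = "hgin")[[stage]]
  paste(org, stg, suffix, sep = "_")
}

#' Construct a single health state
#'
#' A health state couples an organ-specific disease stage with a detection
#' flag (was the lesion found by screening or self-initiated examination?)
#' and a treatment flag (has the patient completed the stage's treatment?).
#' `normal` and `death` carry neither organ nor flags.
#'
#' @param id Short unique key.
#' @param organ `"none"`, `"esophagus"` or `"stomach"`.
#' @param stage Disease stage label.
#' @param detection `"undetected"`, `"detected"` or `"not_applicable"`.
#' @param treatment `"untreated"`, `"posttreatment"` or `"not_applicable"`.
#' @return A one-row `data.frame` with the five fields.
#' @export
health_state <- function(id, organ, stage, detection, treatment) {
  organ <- match.arg(organ, c("none", "esophagus", "stomach"))
  stage <- match.arg(stage, c("normal", "death", .ec_stages, .gc_stages))
  detection <- match.arg(detection, c("undetected", "detected", "not_applicable"))
  treatment <- match.arg(treatment, c("untreated", "posttreatment", "not_applicable"))
  if (stage %in% c("normal", "death")) {
    if (organ != "none" || detection != "not_applicable" ||
        treatment != "not_applicable") {
      stop("'", stage, "' must have organ = none and flags not_applicable",
           call. = FALSE)
    }
  } else {
    if (organ == "none")
      stop("lesion/cancer stage '", stage, "' needs an organ", call. = FALSE)
    if (detection == "not_applicable")
      stop("lesion/cancer stage '", stage, "' needs a detection flag",
           call. = FALSE)
  }
  data.frame(id = id, organ = organ, stage = stage,
             detection = detection, treatment = treatment,
             stringsAsFactors = FALSE)
}

#' Build the canonical Markov state space
#'
#' The default space has 26 states: `normal` and `death`, nine
#' organ-specific lesion/cancer stages each split into undetected and
#' detected (18 states), and one posttreatment state per treatable stage
#' and organ (6 states). The decomposition is configurable: chains can be
#' dropped (e.g. an esophagus-only model) and the treatable set changed.
#'
#' @param organs Organ chains to include; default both.
#' @param treatable Named list (by organ) of stages with a posttreatment
#'   state; defaults to severe dysplasia/CIS or HGIN/CIS plus early and
#'   advanced cancer.
#' @return An object of class `ugic_space`: a `data.frame` of states in
#'   canonical order with an `index` attribute mapping id to position.
#' @examples
#' s <- build_state_space()
#' nrow(s)  # 26
#' @export
build_state_space <- function(organs = c("esophagus", "stomach"),
                              treatable = .default_treatable) {
  organs <- match.arg(organs, c("esophagus", "stomach"), several.ok = TRUE)
  stages_of <- list(esophagus = .ec_stages, stomach = .gc_stages)
  rows <- list(health_state("normal", "none", "normal",
                            "not_applicable", "not_applicable"))
  for (organ in organs) {
    for (stage in stages_of[[organ]]) {
      rows[[length(rows) + 1L]] <- health_state(
        .state_id(organ, stage, "u"), organ, stage, "undetected", "untreated")
      rows[[length(rows) + 1L]] <- health_state(
        .state_id(organ, stage, "d"), organ, stage, "detected", "untreated")
    }
  }
  allowed_pt <- c("severe_dysplasia_cis", "early_cancer", "advanced_cancer",
                  "hgin_cis")
  for (organ in organs) {
    tr <- treatable[[organ]]
    bad <- setdiff(tr, intersect(stages_of[[organ]], allowed_pt))
    if (length(bad))
      stop("posttreatment requested for non-treatable stage(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (stage in tr) {
      rows[[length(rows) + 1L]] <- health_state(
        .state_id(organ, stage, "pt"), organ, stage, "detected", "posttreatment")
    }
  }
  rows[[length(rows) + 1L]] <- health_state("death", "none", "death",
                                            "not_applicable", "not_applicable")
  states <- do.call(rbind, rows)
  if (anyDuplicated(states$id))
    stop("duplicate state ids", call. = FALSE)
  structure(states,
            index = stats::setNames(seq_len(nrow(states)), states$id),
            class = c("ugic_space", "data.frame"))
}

#' @export
print.ugic_space <- function(x, ...) {
  cat("<ugic_space> ", nrow(x), " health states (",
      sum(x$detection == "undetected"), " undetected, ",
      sum(x$detection == "detected" & x$treatment == "untreated"),
      " detected, ", sum(x$treatment == "posttreatment"),
      " posttreatment)\n", sep = "")
  invisible(x)
}

state_ids <- function(space) attr(space, "index")

#' Helper selectors over a state space
#'
#' @param space A `ugic_space`.
#' @return Character vector of state ids.
#' @name state-selectors
NULL

#' @rdname state-selectors
#' @export
living_states <- function(space) space$id[space$stage != "death"]

#' @rdname state-selectors
#' @export
undetected_states <- function(space) space$id[space$detection == "undetected"]

#' @rdname state-selectors
#' @export
detected_states <- function(space) {
  space$id[space$detection == "detected" & space$treatment == "untreated"]
}

#' @rdname state-selectors
#' @export
posttreatment_states <- function(space) space$id[space$treatment == "posttreatment"]

# Detected precancer states kept under endoscopic surveillance rather than
# immediate treatment: mild/moderate esophageal dysplasia and LGIN.
surveillance_states <- function(space) {
  space$id[space$detection == "detected" & space$treatment == "untreated" &
             space$stage %in% c("mild_dysplasia", "moderate_dysplasia", "lgin")]
}

# Detected untreated states of treatable stages (the treatment offer pool).
treatable_detected_states <- function(space, treatable = .default_treatable) {
  keep <- logical(nrow(space))
  for (organ in names(treatable)) {
    keep <- keep | (space$organ == organ &
                      space$stage %in% treatable[[organ]] &
                      space$detection == "detected" &
                      space$treatment == "untreated")
  }
  space$id[keep]
}

#' Validate a transition matrix against a state space
#'
#' Checks that the matrix is aligned with the space, non-negative,
#' row-stochastic (rows sum to 1 within `tol`), that death is absorbing,
#' and that no mass flows from a detected or posttreatment state back to an
#' undetected state (detection is irreversible).
#'
#' @param m Square numeric matrix with state ids as dimnames.
#' @param space A `ugic_space`.
#' @param tol Row-sum tolerance, default `1e-9`.
#' @return A list with `ok` (logical) and `problems` (character vector,
#'   one entry per offending row/check).
#' @export
validate_matrix <- function(m, space, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("transition matrix must be square", call. = FALSE)
  if (nrow(m) != nrow(space) ||
      !identical(rownames(m), space$id) || !identical(colnames(m), space$id))
    stop("matrix not aligned to state space (dimnames must equal state ids ",
         "in canonical order)", call. = FALSE)
  problems <- character(0)
  if (any(m < 0 | m > 1)) {
    bad <- unique(rownames(m)[which(m < 0 | m > 1, arr.ind = TRUE)[, 1]])
    problems <- c(problems, paste0("entries outside [0,1] in row(s): ",
                                   paste(bad, collapse = ", ")))
  }
  rs <- rowSums(m)
  off <- abs(rs - 1) > tol
  if (any(off)) {
    problems <- c(problems, paste0("row '", rownames(m)[off],
                                   "' sums to ", format(rs[off])))
  }
  death <- m["death", ]
  if (death[["death"]] != 1 || any(death[setdiff(colnames(m), "death")] != 0))
    problems <- c(problems, "death row is not an absorbing unit vector")
  from_locked <- c(detected_states(space), posttreatment_states(space))
  undet <- undetected_states(space)
  if (length(from_locked) && length(undet)) {
    leak <- m[from_locked, undet, drop = FALSE]
    if (any(leak > 0)) {
      bad <- rownames(leak)[rowSums(leak) > 0]
      problems <- c(problems,
                    paste0("detected/posttreatment row(s) flow back to an ",
                           "undetected state: ", paste(bad, collapse = ", ")))
    }
  }
  list(ok = length(problems) == 0L, problems = problems)
}

#' Read or write a transition matrix as CSV
#'
#' The CSV carries state ids as a header row and a leading id column, in
#' the canonical order of the space it belongs to.
#'
#' @param m Matrix to write.
#' @param path File path.
#' @return `read_transition_csv` returns the matrix.
#' @export
write_transition_csv <- function(m, path) {
  df <- data.frame(state = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Serialize a state space to / from a YAML config
#'
#' @param space A `ugic_space`.
#' @param path File path.
#' @export
write_state_space <- function(space, path) {
  yaml::write_yaml(lapply(seq_len(nrow(space)), function(i) as.list(space[i, ])),
                   path)
  invisible(path)
}

#' @rdname write_state_space
#' @export
read_state_space <- function(path) {
  rows <- yaml::read_yaml(path)
  states <- do.call(rbind, lapply(rows, function(r) {
    do.call(health_state, r[c("id", "organ", "stage", "detection", "treatment")])
  }))
  structure(states,
            index = stats::setNames(seq_len(nrow(states)), states$id),
            class = c("ugic_space", "data.frame"))
}
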