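# Six-state Markov cohort engine: labelled transition matrices, discounted
# cohort trace, costs and QALYs.

#' Discount factor for a model cycle
#'
#' Returns `(1 + r)^-(k - 1)`: the first cycle is undiscounted and each
#' subsequent cycle is discounted by one further year.
#'
#' @param cycle_index cycle number `k` (1-based, >= 1).
#' @param discount_rate annual discount rate `r` in \[0, 1).
#' @return discount factor in (0, 1\].
#' @export
discount_factor <- function(cycle_index, discount_rate) {
  if (any(cycle_index < 1) || any(cycle_index != round(cycle_index)))
    stop("cycle_index must be a positive integer", call. = FALSE)
  if (!is.numeric(discount_rate) ||
      any(discount_rate < 0 | discount_rate >= 1))
    stop("discount_rate must lie in [0, 1)", call. = FALSE)
  (1 + discount_rate)^(-(cycle_index - 1))
}

#' Build the six-state transition matrix for one arm
#'
#' Assembles the labelled row-stochastic matrix over
#' `well, stroke, post_stroke, mi, post_mi, dead` from per-cycle event
#' probabilities. Residual mass closes each row: `well -> well`,
#' `stroke -> post_stroke`, `mi -> post_mi`, and self-loops in the
#' post-event states. Death is absorbing; structurally impossible moves
#' (e.g. `post_stroke -> mi`, `well -> post_stroke`, crossing between the
#' stroke and MI families) are exactly zero.
#'
#' @param event_probs named numeric vector with `p_well_stroke`,
#'   `p_well_mi`, `p_stroke_stroke`, `p_stroke_death`,
#'   `p_post_stroke_death`, `p_mi_mi`, `p_mi_death`, `p_post_mi_death`,
#'   all per-cycle probabilities in \[0, 1\].
#' @return a `transition_model`: a 6x6 matrix with state dimnames.
#' @export
#' @examples
#' ev <- derive_all_event_probabilities(paper_default_bundle())
#' build_transition_matrix(ev$nifedipine)
build_transition_matrix <- function(event_probs) {
  need <- c("p_well_stroke", "p_well_mi", "p_stroke_stroke",
            "p_stroke_death", "p_post_stroke_death", "p_mi_mi",
            "p_mi_death", "p_post_mi_death")
  missing <- setdiff(need, names(event_probs))
  if (length(missing))
    stop("missing event probability: ", missing[1], call. = FALSE)
  ev <- as.numeric(event_probs[need])
  names(ev) <- need
  if (any(ev < 0 | ev > 1))
    stop("event probabilities must lie in [0, 1]", call. = FALSE)
  chk <- c(well = unname(ev["p_well_stroke"] + ev["p_well_mi"]),
           stroke = unname(ev["p_stroke_stroke"] + ev["p_stroke_death"]),
           mi = unname(ev["p_mi_mi"] + ev["p_mi_death"]))
  over <- names(chk)[chk > 1 + 1e-12]
  if (length(over))
    stop("incoherent transitions: exits from state '", over[1],
         "' sum above 1", call. = FALSE)
  m <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  m["well", "stroke"] <- ev["p_well_stroke"]
  m["well", "mi"] <- ev["p_well_mi"]
  m["well", "well"] <- 1 - ev["p_well_stroke"] - ev["p_well_mi"]
  m["stroke", "stroke"] <- ev["p_stroke_stroke"]
  m["stroke", "dead"] <- ev["p_stroke_death"]
  m["stroke", "post_stroke"] <- 1 - ev["p_stroke_stroke"] - ev["p_stroke_death"]
  m["post_stroke", "dead"] <- ev["p_post_stroke_death"]
  m["post_stroke", "post_stroke"] <- 1 - ev["p_post_stroke_death"]
  m["mi", "mi"] <- ev["p_mi_mi"]
  m["mi", "dead"] <- ev["p_mi_death"]
  m["mi", "post_mi"] <- 1 - ev["p_mi_mi"] - ev["p_mi_death"]
  m["post_mi", "dead"] <- ev["p_post_mi_death"]
  m["post_mi", "post_mi"] <- 1 - ev["p_post_mi_death"]
  m["dead", "dead"] <- 1
  validate_transition_model(m)
}

#' Validate a transition matrix
#'
#' Checks row-stochasticity (rows sum to 1 within 1e-9), entries in
#' \[0, 1\], and that the last state is absorbing.
#'
#' @param m a square numeric matrix with identical row/column state labels;
#'   the last state is the absorbing one.
#' @return the matrix, classed `transition_model`, invisibly valid.
#' @export
validate_transition_model <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("transition model must be a square matrix", call. = FALSE)
  if (any(m < -1e-12 | m > 1 + 1e-12))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9))
    stop("row ", which(abs(rs - 1) > 1e-9)[1],
         " of the transition matrix does not sum to 1", call. = FALSE)
  n <- nrow(m)
  if (abs(m[n, n] - 1) > 1e-12)
    stop("last state must be absorbing", call. = FALSE)
  structure(m, class = c("transition_model", "matrix", "array"))
}

#' Run the discounted Markov cohort simulation for one arm
#'
#' Starts the full cohort in the first state, propagates the occupancy
#' vector through the transition matrix for `n_cycles` cycles, and
#' accumulates discounted costs and QALYs. Cycle `k` is discounted by
#' `(1 + r)^-(k - 1)` (first cycle undiscounted). The occupancy credited
#' with cycle-`k` rewards follows `reward_timing`:
#' * `"start"` (default): state membership at the start of the cycle;
#' * `"end"`: membership after the cycle's transition;
#' * `"half"`: the mean of the two (half-cycle correction).
#'
#' Cycle cost is the occupancy-weighted sum of annual state costs plus the
#' annual drug cost accrued over the alive mass (all alive states by
#' default, or the event-free state only when
#' `drug_cost_states = "well_only"`); cycle QALYs are the
#' occupancy-weighted utilities.
#'
#' @param tm a `transition_model` (see [build_transition_matrix()]); the
#'   states must match the rows of `states`.
#' @param states data frame with columns `name`, `utility`, `annual_cost`
#'   in the matrix's state order; the last (absorbing) state must have
#'   utility 0 and cost 0.
#' @param strategy list or one-row data frame with `name` and
#'   `annual_drug_cost`.
#' @param settings list with `n_cycles`, `discount_rate` and optionally
#'   `reward_timing`, `drug_cost_states` (e.g. from [cea_settings()]).
#' @return a `cohort_result`: list with `trace`
#'   ((n_cycles + 1) x n_states occupancy matrix, row 1 the initial
#'   distribution), `per_cycle_cost`, `per_cycle_qalys` (discounted),
#'   `total_cost`, `total_qalys`, and the effective `settings`.
#' @export
#' @examples
#' b <- paper_default_bundle()
#' ev <- derive_all_event_probabilities(b)
#' tm <- build_transition_matrix(ev$combined)
#' res <- run_cohort(tm, health_states(b),
#'                   list(name = "combined", annual_drug_cost = 102.42),
#'                   cea_settings(b))
#' c(res$total_cost, res$total_qalys)
run_cohort <- function(tm, states, strategy, settings) {
  tm <- validate_transition_model(unclass(tm))
  n_states <- nrow(tm)
  if (nrow(states) != n_states)
    stop("states table does not match transition matrix", call. = FALSE)
  if (!is.null(rownames(tm)) && !identical(states$name, rownames(tm)))
    stop("state order mismatch between matrix and state table",
         call. = FALSE)
  last <- n_states
  if (states$utility[last] != 0 || states$annual_cost[last] != 0)
    stop("absorbing state must have utility 0 and cost 0", call. = FALSE)
  n_cycles <- as.integer(settings$n_cycles)
  if (is.na(n_cycles) || n_cycles < 1)
    stop("n_cycles must be >= 1", call. = FALSE)
  r <- settings$discount_rate
  timing <- settings$reward_timing
  if (is.null(timing)) timing <- "start"
  timing <- match.arg(timing, c("start", "end", "half"))
  drug_states <- settings$drug_cost_states
  if (is.null(drug_states)) drug_states <- "alive"
  drug_states <- match.arg(drug_states, c("alive", "well_only"))
  drug <- as.numeric(strategy$annual_drug_cost)
  if (is.na(drug) || drug < 0)
    stop("annual_drug_cost must be >= 0", call. = FALSE)

  u <- states$utility
  cost <- states$annual_cost
  drug_mask <- if (drug_states == "alive") {
    x <- rep(1, n_states); x[last] <- 0; x
  } else {
    x <- rep(0, n_states); x[1] <- 1; x
  }

  trace <- matrix(NA_real_, n_cycles + 1, n_states,
                  dimnames = list(cycle = 0:n_cycles, state = states$name))
  occ <- c(1, rep(0, n_states - 1))
  trace[1, ] <- occ
  per_cost <- per_qaly <- numeric(n_cycles)
  dead_prev <- occ[last]
  for (k in seq_len(n_cycles)) {
    occ_next <- as.vector(occ %*% tm)
    if (abs(sum(occ_next) - 1) > 1e-9)
      stop("cohort mass not conserved at cycle ", k, call. = FALSE)
    if (occ_next[last] < dead_prev - 1e-12)
      stop("absorbing-state occupancy decreased at cycle ", k,
           call. = FALSE)
    dead_prev <- occ_next[last]
    w <- switch(timing, start = occ, end = occ_next,
                half = (occ + occ_next) / 2)
    d <- discount_factor(k, r)
    per_cost[k] <- d * (sum(w * cost) + sum(w * drug_mask) * drug)
    per_qaly[k] <- d * sum(w * u)
    occ <- occ_next
    trace[k + 1, ] <- occ
  }
  structure(list(trace = trace,
                 per_cycle_cost = per_cost,
                 per_cycle_qalys = per_qaly,
                 total_cost = sum(per_cost),
                 total_qalys = sum(per_qaly),
                 strategy = as.character(strategy$name),
                 settings = list(n_cycles = n_cycles, discount_rate = r,
                                 reward_timing = timing,
                                 drug_cost_states = drug_states)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", x$strategy, ": ",
      x$settings$n_cycles, " cycles, r = ", x$settings$discount_rate,
      ", timing = ", x$settings$reward_timing, "\n", sep = "")
  cat(sprintf("  total cost  %10.2f USD\n  total QALYs %10.4f\n",
              x$total_cost, x$total_qalys))
  invisible(x)
}

#' Run both arms of the base-case model
#'
#' Convenience wrapper: derives per-arm event probabilities, builds both
#' transition matrices, runs the cohort engine for each arm and returns the
#' paired results.
#'
#' @param bundle a validated `cea_bundle`.
#' @param mode event-probability mode passed to
#'   [derive_all_event_probabilities()].
#' @return named list of `cohort_result` objects, one per arm.
#' @export
run_base_case <- function(bundle, mode = NULL) {
  ev <- derive_all_event_probabilities(bundle, mode = mode)
  states <- health_states(bundle)
  arms <- strategy_table(bundle)
  settings <- cea_settings(bundle)
  out <- lapply(seq_len(nrow(arms)), function(i)
    run_cohort(build_transition_matrix(ev[[arms$name[i]]]), states,
               list(name = arms$name[i],
                    annual_drug_cost = arms$annual_drug_cost[i]),
               settings))
  names(out) <- arms$name
  out
}
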