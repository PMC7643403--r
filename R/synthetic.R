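# Synthetic model generation for property tests and an individual-level
# microsimulation oracle for the cohort engine. The oracle shares no
# implementation with run_cohort: it accrues rewards per simulated patient
# trajectory and only agrees with the cohort engine through the model's
# public contract.

#' Generate a random valid Markov cost-effectiveness model
#'
#' Draws a row-stochastic transition matrix with one absorbing state (the
#' last), random utilities in \[0, 1\] and non-negative annual costs, plus
#' run settings. Every non-absorbing row keeps strictly positive mass on
#' itself and on the absorbing state, so death is reachable from
#' everywhere; an optional sparsity knob zeroes a fraction of the remaining
#' transitions.
#'
#' @param seed integer seed; generation is deterministic given the seed.
#' @param n_states number of states (>= 2), the last one absorbing.
#' @param sparsity fraction of off-diagonal, non-absorbing transitions
#'   forced to zero (in \[0, 1\)).
#' @param utility_range,cost_range ranges for the alive states' utilities
#'   and annual costs.
#' @param n_cycles,discount_rate run settings.
#' @param reward_timing cycle-reward convention for the generated settings.
#' @return a list with `tm` (a `transition_model`), `states` (data frame
#'   `name`, `utility`, `annual_cost`), `strategy` (`name`,
#'   `annual_drug_cost`), and `settings`.
#' @export
generate_random_model <- function(seed, n_states = 6, sparsity = 0.3,
                                  utility_range = c(0, 1),
                                  cost_range = c(0, 3000),
                                  n_cycles = 20, discount_rate = 0.05,
                                  reward_timing = "start") {
  stopifnot(n_states >= 2, sparsity >= 0, sparsity < 1)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  m <- matrix(0, n_states, n_states)
  for (s in seq_len(n_states - 1)) {
    w <- stats::rexp(n_states)
    keep <- stats::runif(n_states) >= sparsity
    keep[s] <- TRUE          # self-transition stays
    keep[n_states] <- TRUE   # absorbing state always reachable
    w[!keep] <- 0
    m[s, ] <- w / sum(w)
  }
  m[n_states, n_states] <- 1
  dimnames(m) <- list(paste0("s", seq_len(n_states)),
                      paste0("s", seq_len(n_states)))
  states <- data.frame(
    name = rownames(m),
    utility = c(stats::runif(n_states - 1, utility_range[1],
                             utility_range[2]), 0),
    annual_cost = c(stats::runif(n_states - 1, cost_range[1],
                                 cost_range[2]), 0),
    stringsAsFactors = FALSE)
  list(tm = validate_transition_model(m),
       states = states,
       strategy = list(name = "synthetic",
                       annual_drug_cost = stats::runif(1, 0, 200)),
       settings = list(n_cycles = n_cycles, discount_rate = discount_rate,
                       reward_timing = reward_timing,
                       drug_cost_states = "alive"))
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` independent patient trajectories through the
#' transition matrix, accruing each patient's discounted costs and QALYs
#' cycle by cycle under the same reward-timing and drug-cost conventions
#' as the cohort engine, and returns the sample means with their standard
#' errors. This is an independent estimate of what [run_cohort()] computes
#' exactly: for a valid engine the cohort totals lie within a few standard
#' errors of the microsimulation means.
#'
#' @param model a list as returned by [generate_random_model()] (`tm`,
#'   `states`, `strategy`, `settings`); any compatible hand-built list
#'   works.
#' @param n_patients number of simulated patients.
#' @param seed integer seed.
#' @param settings optional settings overriding `model$settings`.
#' @return a list with `total_cost`, `total_qalys` (means per patient),
#'   `se_cost`, `se_qalys`, `occupancy` (empirical
#'   (n_cycles + 1) x n_states state-occupancy fractions), `n_patients`,
#'   `seed`.
#' @export
microsimulate <- function(model, n_patients, seed, settings = NULL) {
  tm <- validate_transition_model(unclass(model$tm))
  states <- model$states
  if (is.null(settings)) settings <- model$settings
  n_states <- nrow(tm)
  n_cycles <- as.integer(settings$n_cycles)
  r <- settings$discount_rate
  timing <- settings$reward_timing
  if (is.null(timing)) timing <- "start"
  timing <- match.arg(timing, c("start", "end", "half"))
  drug_states <- settings$drug_cost_states
  if (is.null(drug_states)) drug_states <- "alive"
  drug <- as.numeric(model$strategy$annual_drug_cost)
  u <- states$utility
  cost_s <- states$annual_cost
  drug_mask <- if (drug_states == "alive") {
    x <- rep(1, n_states); x[n_states] <- 0; x
  } else {
    x <- rep(0, n_states); x[1] <- 1; x
  }
  cost_vec <- cost_s + drug * drug_mask

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  state <- rep.int(1L, n_patients)
  tot_cost <- tot_qaly <- numeric(n_patients)
  occupancy <- matrix(0, n_cycles + 1, n_states,
                      dimnames = list(cycle = 0:n_cycles,
                                      state = states$name))
  occupancy[1, ] <- tabulate(state, n_states) / n_patients
  for (k in seq_len(n_cycles)) {
    nxt <- integer(n_patients)
    for (s in seq_len(n_states)) {
      idx <- which(state == s)
      if (!length(idx)) next
      nxt[idx] <- sample.int(n_states, length(idx), replace = TRUE,
                             prob = tm[s, ])
    }
    d <- (1 + r)^(-(k - 1))
    w_cost <- switch(timing,
                     start = cost_vec[state],
                     end = cost_vec[nxt],
                     half = (cost_vec[state] + cost_vec[nxt]) / 2)
    w_qaly <- switch(timing,
                     start = u[state],
                     end = u[nxt],
                     half = (u[state] + u[nxt]) / 2)
    tot_cost <- tot_cost + d * w_cost
    tot_qaly <- tot_qaly + d * w_qaly
    state <- nxt
    occupancy[k + 1, ] <- tabulate(state, n_states) / n_patients
  }
  list(total_cost = mean(tot_cost), total_qalys = mean(tot_qaly),
       se_cost = stats::sd(tot_cost) / sqrt(n_patients),
       se_qalys = stats::sd(tot_qaly) / sqrt(n_patients),
       occupancy = occupancy,
       n_patients = n_patients, seed = as.integer(seed))
}
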