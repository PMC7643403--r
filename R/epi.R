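# Rate-to-probability annualization and BPV-based derivation of per-arm
# annual stroke/MI incidence.

#' Convert a multi-year event rate to a per-cycle transition probability
#'
#' Applies the constant-rate conversion `tP = 1 - (1 - P)^(t/T)`: the
#' probability `P` of an event over a horizon of `T` years is converted to
#' the probability per cycle of length `t` years under the assumption that
#' the per-cycle risk is constant over the horizon.
#'
#' @param rate event probability over the full horizon, in \[0, 1\].
#' @param horizon_years horizon `T` over which `rate` is expressed (> 0).
#' @param cycle_length_years cycle length `t` in years (default 1).
#' @return the per-cycle probability, in \[0, 1\]. Equal to `rate` when the
#'   horizon equals the cycle length; 0 when `rate` is 0.
#' @export
#' @examples
#' annualize_probability(0.417, 5)    # 5-year stroke recurrence -> annual
#' annualize_probability(0.0569, 5.5) # 5.5-year baseline stroke rate
annualize_probability <- function(rate, horizon_years,
                                  cycle_length_years = 1) {
  if (!is.numeric(rate) || any(rate < 0 | rate > 1))
    stop("rate must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(horizon_years) || any(horizon_years <= 0))
    stop("horizon_years must be > 0", call. = FALSE)
  if (!is.numeric(cycle_length_years) || any(cycle_length_years <= 0))
    stop("cycle_length_years must be > 0", call. = FALSE)
  1 - (1 - rate)^(cycle_length_years / horizon_years)
}

#' Derive an arm's annual event incidence from its BPV effect
#'
#' The annual incidence under treatment is the annualized baseline incidence
#' minus the product of the achieved reduction in the blood-pressure
#' variability index (SD in mmHg for stroke, CV as a fraction for MI) and
#' the incidence increment attributable to one unit of that index, floored
#' at zero:
#' `incidence = max(0, baseline_annual - delta_index * increment_per_unit)`.
#'
#' @param baseline_annual annualized baseline incidence, in \[0, 1\].
#' @param delta_index achieved reduction in the BPV index (>= 0).
#' @param increment_per_unit incidence increase per unit of the index (>= 0).
#' @return annual incidence in \[0, `baseline_annual`\]; monotone
#'   non-increasing in `delta_index`.
#' @export
#' @examples
#' b <- annualize_probability(0.0569, 5.5)
#' derive_arm_incidence(b, 1.87, 0.0032) # nifedipine arm, stroke
#' derive_arm_incidence(b, 2.99, 0.0032) # combined arm, stroke
derive_arm_incidence <- function(baseline_annual, delta_index,
                                 increment_per_unit) {
  if (!is.numeric(baseline_annual) ||
      any(baseline_annual < 0 | baseline_annual > 1))
    stop("baseline_annual must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(delta_index) || any(delta_index < 0))
    stop("delta_index must be >= 0", call. = FALSE)
  if (!is.numeric(increment_per_unit) || any(increment_per_unit < 0))
    stop("increment_per_unit must be >= 0", call. = FALSE)
  pmax(0, baseline_annual - delta_index * increment_per_unit)
}

#' Per-cycle event probabilities for both arms
#'
#' Assembles, for each treatment arm, the full set of per-cycle transition
#' probabilities the Markov engine needs. Probabilities stored on a
#' multi-year horizon are annualized with [annualize_probability()];
#' one-year entries pass through. The well-state stroke/MI incidences come
#' either from the bundle's per-arm parameters (`mode = "direct"`, the
#' default) or are re-derived from the baseline rates and BPV effects via
#' [derive_arm_incidence()] (`mode = "derived"`).
#'
#' @param bundle a validated `cea_bundle`.
#' @param mode `"direct"` or `"derived"`; defaults to the bundle convention.
#' @return a named list, one element per arm, each a named numeric vector
#'   with entries `p_well_stroke`, `p_well_mi`, `p_stroke_stroke`,
#'   `p_stroke_death`, `p_post_stroke_death`, `p_mi_mi`, `p_mi_death`,
#'   `p_post_mi_death`, all per cycle in \[0, 1\].
#' @export
derive_all_event_probabilities <- function(bundle, mode = NULL) {
  validate_bundle(bundle)
  if (is.null(mode)) mode <- bundle$conventions$sample_mode
  mode <- match.arg(mode, c("direct", "derived"))
  p <- bundle$parameters
  cyc <- param_value(bundle, "cycle_length_years")
  ann <- function(nm) {
    i <- match(nm, p$name)
    h <- p$horizon_years[i]
    if (is.na(h)) h <- cyc
    out <- tryCatch(annualize_probability(p$base[i], h, cyc),
                    error = function(e)
                      stop("parameter '", nm, "': ", conditionMessage(e),
                           call. = FALSE))
    out
  }
  downstream <- c(p_stroke_stroke = ann("p_stroke_stroke"),
                  p_stroke_death = ann("p_stroke_death"),
                  p_post_stroke_death = ann("p_post_stroke_death"),
                  p_mi_mi = ann("p_mi_mi"),
                  p_mi_death = ann("p_mi_death"),
                  p_post_mi_death = ann("p_post_mi_death"))
  arms <- strategy_table(bundle)
  out <- lapply(seq_len(nrow(arms)), function(i) {
    arm <- arms$name[i]
    if (mode == "direct") {
      pws <- ann(paste0("p_well_stroke_", arm))
      pwm <- ann(paste0("p_well_mi_", arm))
    } else {
      pws <- derive_arm_incidence(ann("stroke_baseline_rate"),
                                  arms$delta_sd[i],
                                  param_value(bundle, "stroke_increment_per_sd"))
      pwm <- derive_arm_incidence(ann("mi_baseline_rate"),
                                  arms$delta_cv[i],
                                  param_value(bundle, "mi_increment_per_cv"))
    }
    c(p_well_stroke = pws, p_well_mi = pwm, downstream)
  })
  names(out) <- arms$name
  out
}
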