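# Shared test fixtures, built in code.

# default bundle with all well-state event probabilities set to zero: the
# cohort never leaves the event-free state
no_event_bundle <- function(utility_well = 0.98, drug_cost = 0) {
  b <- paper_default_bundle()
  set0 <- c("p_well_stroke_nifedipine", "p_well_stroke_combined",
            "p_well_mi_nifedipine", "p_well_mi_combined")
  i <- match(set0, b$parameters$name)
  b$parameters$base[i] <- b$parameters$low[i] <- b$parameters$high[i] <- 0
  j <- match("utility_well", b$parameters$name)
  b$parameters$base[j] <- utility_well
  b$parameters$low[j] <- min(b$parameters$low[j], utility_well)
  b$parameters$high[j] <- max(b$parameters$high[j], utility_well)
  k <- match(c("drug_cost_nifedipine", "drug_cost_combined"),
             b$parameters$name)
  b$parameters$base[k] <- b$parameters$low[k] <- b$parameters$high[k] <-
    drug_cost
  b
}

set_param <- function(bundle, name, value) {
  i <- match(name, bundle$parameters$name)
  stopifnot(!is.na(i))
  bundle$parameters$base[i] <- value
  bundle$parameters$low[i] <- min(bundle$parameters$low[i], value)
  bundle$parameters$high[i] <- max(bundle$parameters$high[i], value)
  bundle
}
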