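# Parameter bundle: one flat table keyed by parameter name (base/low/high/
# family/horizon), plus reward-convention switches. YAML, JSON and CSV readers
# share a single validator.

#' @keywords internal
.state_names <- c("well", "stroke", "post_stroke", "mi", "post_mi", "dead")

#' @keywords internal
.strategy_names <- c("nifedipine", "combined")

# Registry of every recognised parameter: its sampling family, the horizon (in
# years) over which a probability is expressed, and its role in the model.
# Unknown names are rejected by the validator; missing names are reported.
#' @keywords internal
.param_registry <- function() {
  reg <- rbind(
    # --- model settings ------------------------------------------------------
    c("n_cycles",                  "fixed", NA, "cycles",        "setting"),
    c("cycle_length_years",        "fixed", NA, "years",         "setting"),
    c("discount_rate",             "fixed", NA, "fraction/year", "setting"),
    c("wtp_threshold",             "fixed", NA, "USD/QALY",      "setting"),
    c("exchange_rate_rmb_per_usd", "fixed", NA, "RMB/USD",       "setting"),
    c("baseline_age",              "fixed", NA, "years",         "setting"),
    # --- utilities (QALY weights, Beta) -------------------------------------
    c("utility_well",        "beta", NA, "utility", "utility"),
    c("utility_stroke",      "beta", NA, "utility", "utility"),
    c("utility_post_stroke", "beta", NA, "utility", "utility"),
    c("utility_mi",          "beta", NA, "utility", "utility"),
    c("utility_post_mi",     "beta", NA, "utility", "utility"),
    # --- annual state costs and drug costs (Gamma) --------------------------
    c("cost_stroke",          "gamma", NA, "USD/year", "cost"),
    c("cost_post_stroke",     "gamma", NA, "USD/year", "cost"),
    c("cost_mi",              "gamma", NA, "USD/year", "cost"),
    c("cost_post_mi",         "gamma", NA, "USD/year", "cost"),
    c("drug_cost_nifedipine", "gamma", NA, "USD/year", "cost"),
    c("drug_cost_combined",   "gamma", NA, "USD/year", "cost"),
    # --- transition probabilities on their native horizon (Beta) ------------
    c("p_well_stroke_nifedipine", "beta", 1, "probability", "probability"),
    c("p_well_stroke_combined",   "beta", 1, "probability", "probability"),
    c("p_well_mi_nifedipine",     "beta", 1, "probability", "probability"),
    c("p_well_mi_combined",       "beta", 1, "probability", "probability"),
    c("p_stroke_stroke",          "beta", 5, "probability", "probability"),
    c("p_stroke_death",           "beta", 5, "probability", "probability"),
    c("p_post_stroke_death",      "beta", 4, "probability", "probability"),
    c("p_mi_mi",                  "beta", 1, "probability", "probability"),
    c("p_mi_death",               "beta", 1, "probability", "probability"),
    c("p_post_mi_death",          "beta", 1, "probability", "probability"),
    # --- blood-pressure-variability effects and risk-derivation inputs ------
    c("bpv_delta_sd_nifedipine", "gamma", NA,  "mmHg",        "bpv"),
    c("bpv_delta_sd_combined",   "gamma", NA,  "mmHg",        "bpv"),
    c("bpv_delta_cv_nifedipine", "fixed", NA,  "fraction",    "bpv"),
    c("bpv_delta_cv_combined",   "beta",  NA,  "fraction",    "bpv"),
    c("stroke_baseline_rate",    "beta",  5.5, "probability", "derivation"),
    c("mi_baseline_rate",        "beta",  5.5, "probability", "derivation"),
    c("stroke_increment_per_sd", "beta",  NA,  "probability/mmHg", "derivation"),
    c("mi_increment_per_cv",     "beta",  NA,  "probability/CV",   "derivation")
  )
  data.frame(name = reg[, 1], family = reg[, 2],
             horizon_years = as.numeric(reg[, 3]),
             units = reg[, 4], role = reg[, 5],
             stringsAsFactors = FALSE)
}

#' Default parameter bundle for the hypertension BPV model
#'
#' Returns the base-case parameter set of the six-state hypertension model:
#' per-arm annual stroke/MI incidences derived from nocturnal
#' blood-pressure-variability effects, downstream recurrence and mortality
#' probabilities on their native horizons, utilities, annual state costs and
#' drug costs in USD, the 5% discount rate, the 20-year horizon and the
#' willingness-to-pay threshold of one GDP per capita (9764.95 USD).
#'
#' Every range is the base value +/- 10% except where the source reports a
#' different interval (e.g. the well-state utility is capped at 1, baseline
#' age spans 60--75, the discount rate is varied over 1--8% in one-way
#' analysis). The post-MI annual cost is 2041.84 USD, the value both
#' endpoints of its +/-10% range back-solve to.
#'
#' @param reward_timing cycle-reward convention: `"start"` (default, rewards
#'   on start-of-cycle state membership), `"end"`, or `"half"` (half-cycle
#'   correction).
#' @param drug_cost_states whether the annual drug cost accrues in all alive
#'   states (`"alive"`, default) or only while event-free (`"well_only"`).
#' @param sample_mode how the PSA samples the per-arm event probabilities:
#'   `"direct"` (default, from their own ranges) or `"derived"` (sample the
#'   BPV effects and re-derive the incidences).
#' @return an object of class `cea_bundle`: a list with a `parameters`
#'   data frame (`name`, `base`, `low`, `high`, `family`, `horizon_years`,
#'   `units`) and a `conventions` list.
#' @export
#' @examples
#' b <- paper_default_bundle()
#' subset(b$parameters, name == "utility_well")
paper_default_bundle <- function(reward_timing = c("start", "end", "half"),
                                 drug_cost_states = c("alive", "well_only"),
                                 sample_mode = c("direct", "derived")) {
  v <- list(
    n_cycles                  = c(20, 20, 20),
    cycle_length_years        = c(1, 1, 1),
    discount_rate             = c(0.05, 0.01, 0.08),
    wtp_threshold             = c(9764.95, 9764.95, 9764.95),
    exchange_rate_rmb_per_usd = c(6.62, 6.62, 6.62),
    baseline_age              = c(67.5, 60, 75),
    utility_well        = c(0.98, 0.882, 1),
    utility_stroke      = c(0.5, 0.45, 0.55),
    utility_post_stroke = c(0.63, 0.567, 0.693),
    utility_mi          = c(0.70, 0.63, 0.77),
    utility_post_mi     = c(0.8, 0.72, 0.88),
    cost_stroke          = c(1843.86, 1659.56, 2028.35),
    cost_post_stroke     = c(1692.15, 1522.93, 1861.36),
    cost_mi              = c(2538.01, 2284.26, 2791.87),
    cost_post_mi         = c(2041.84, 1837.66, 2246.03),
    drug_cost_nifedipine = c(16.31, 14.68, 17.95),
    drug_cost_combined   = c(102.42, 92.18, 112.66),
    p_well_stroke_nifedipine = c(0.0046, 0.0041, 0.0051),
    p_well_stroke_combined   = c(0.00102, 0.0009, 0.0011),
    p_well_mi_nifedipine     = c(0.00199, 0.0018, 0.0022),
    p_well_mi_combined       = c(0.00193, 0.0017, 0.0021),
    p_stroke_stroke          = c(0.417, 0.3753, 0.4587),
    p_stroke_death           = c(0.1303, 0.1172, 0.1433),
    p_post_stroke_death      = c(0.256, 0.2304, 0.2816),
    p_mi_mi                  = c(0.125, 0.1125, 0.1375),
    p_mi_death               = c(0.097, 0.0873, 0.1067),
    p_post_mi_death          = c(0.061, 0.0549, 0.0671),
    bpv_delta_sd_nifedipine = c(1.87, 1.683, 2.057),
    bpv_delta_sd_combined   = c(2.99, 2.691, 3.289),
    bpv_delta_cv_nifedipine = c(0, 0, 0),
    bpv_delta_cv_combined   = c(0.01, 0.009, 0.011),
    stroke_baseline_rate    = c(0.0569, 0.05121, 0.06259),
    mi_baseline_rate        = c(0.0109, 0.00981, 0.01199),
    stroke_increment_per_sd = c(0.0032, 0.003, 0.004),
    mi_increment_per_cv     = c(0.00811, 0.0073, 0.0089)
  )
  reg <- .param_registry()
  stopifnot(identical(names(v), reg$name))
  m <- do.call(rbind, v)
  params <- data.frame(name = reg$name, base = m[, 1], low = m[, 2],
                       high = m[, 3], family = reg$family,
                       horizon_years = reg$horizon_years, units = reg$units,
                       stringsAsFactors = FALSE)
  rownames(params) <- NULL
  bundle <- structure(
    list(parameters = params,
         conventions = list(reward_timing = match.arg(reward_timing),
                            drug_cost_states = match.arg(drug_cost_states),
                            sample_mode = match.arg(sample_mode))),
    class = "cea_bundle")
  validate_bundle(bundle)
}

#' Validate a parameter bundle
#'
#' Checks the full set of bundle invariants: all registry parameters present,
#' no unknown names, `low <= base <= high`, probabilities and utilities in
#' \[0, 1\], costs non-negative, Beta families restricted to \[0, 1\]
#' quantities, a valid discount rate in \[0, 1) and at least one model cycle.
#'
#' @param bundle a `cea_bundle`.
#' @return the bundle, invisibly unchanged, if valid; otherwise an error of
#'   class `cea_missing_parameter` or `cea_invalid_parameter` naming the
#'   offending field.
#' @export
validate_bundle <- function(bundle) {
  if (!inherits(bundle, "cea_bundle"))
    stop("expected a 'cea_bundle' object", call. = FALSE)
  p <- bundle$parameters
  reg <- .param_registry()

  unknown <- setdiff(p$name, reg$name)
  if (length(unknown))
    .invalid(unknown[1], "unknown parameter name")
  missing <- setdiff(reg$name, p$name)
  if (length(missing))
    stop(structure(class = c("cea_missing_parameter", "error", "condition"),
                   list(message = paste0("missing parameter: ", missing[1]),
                        call = NULL)))
  if (anyDuplicated(p$name))
    .invalid(p$name[duplicated(p$name)][1], "duplicated parameter name")

  for (col in c("base", "low", "high"))
    if (!is.numeric(p[[col]]) || anyNA(p[[col]]))
      .invalid(p$name[which(is.na(p[[col]]))[1]],
               paste0("non-numeric or missing '", col, "'"))
  bad <- which(p$low > p$base | p$base > p$high)
  if (length(bad))
    .invalid(p$name[bad[1]], "requires low <= base <= high")
  bad <- which(p$family == "beta" & (p$low < 0 | p$high > 1))
  if (length(bad))
    .invalid(p$name[bad[1]], "beta family requires values in [0, 1]")
  bad <- which(!p$family %in% c("gamma", "beta", "fixed"))
  if (length(bad))
    .invalid(p$name[bad[1]], "family must be gamma, beta or fixed")

  get <- function(nm) p$base[p$name == nm]
  probs <- p[grepl("^(p_|.*_rate$)", p$name) & p$name != "discount_rate" &
               p$name != "exchange_rate_rmb_per_usd", ]
  bad <- which(probs$low < 0 | probs$high > 1)
  if (length(bad))
    .invalid(probs$name[bad[1]], "probability must lie in [0, 1]")
  util <- p[startsWith(p$name, "utility_"), ]
  bad <- which(util$low < 0 | util$high > 1)
  if (length(bad))
    .invalid(util$name[bad[1]], "utility must lie in [0, 1]")
  costs <- p[grepl("^(cost_|drug_cost_)", p$name), ]
  if (any(costs$low < 0))
    .invalid(costs$name[which(costs$low < 0)[1]], "cost must be >= 0")
  if (get("n_cycles") < 1 || get("n_cycles") != round(get("n_cycles")))
    .invalid("n_cycles", "must be a positive integer")
  if (get("cycle_length_years") <= 0)
    .invalid("cycle_length_years", "must be > 0")
  if (get("discount_rate") < 0 || get("discount_rate") >= 1)
    .invalid("discount_rate", "must lie in [0, 1)")
  if (any(p$base[startsWith(p$name, "bpv_delta_")] < 0))
    .invalid("bpv_delta", "BPV reductions must be >= 0")
  hz <- p$horizon_years
  if (any(!is.na(hz) & hz <= 0))
    .invalid(p$name[which(!is.na(hz) & hz <= 0)[1]], "horizon_years must be > 0")

  cv <- bundle$conventions
  if (!is.list(cv) ||
      !cv$reward_timing %in% c("start", "end", "half") ||
      !cv$drug_cost_states %in% c("alive", "well_only") ||
      !cv$sample_mode %in% c("direct", "derived"))
    .invalid("conventions", "unrecognised convention value")
  invisible(bundle)
}

#' @keywords internal
.invalid <- function(name, why) {
  stop(structure(class = c("cea_invalid_parameter", "error", "condition"),
                 list(message = paste0("invalid parameter '", name, "': ", why),
                      call = NULL)))
}

#' Read a parameter bundle from YAML, JSON or CSV
#'
#' The three dialects carry the same flat parameter table and are validated
#' identically. YAML/JSON files hold a `parameters` map keyed by parameter
#' name with `base`/`low`/`high`/`family` (and optional `horizon_years`,
#' `units`) fields plus an optional `conventions` map; a CSV holds the
#' columns `name,base,low,high,family,horizon_years,units` and uses the
#' default conventions.
#'
#' @param path path to a `.yaml`/`.yml`, `.json` or `.csv` file.
#' @return a validated `cea_bundle`.
#' @seealso [write_parameters()], [paper_default_bundle()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  defaults <- list(reward_timing = "start", drug_cost_states = "alive",
                   sample_mode = "direct")
  reg <- .param_registry()
  if (ext %in% c("yaml", "yml", "json")) {
    doc <- if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
           else yaml::read_yaml(path)
    if (is.null(doc$parameters))
      stop(structure(class = c("cea_missing_parameter", "error", "condition"),
                     list(message = "missing parameter: 'parameters' section",
                          call = NULL)))
    rows <- lapply(names(doc$parameters), function(nm) {
      rec <- doc$parameters[[nm]]
      for (k in c("base", "low", "high", "family"))
        if (is.null(rec[[k]]))
          stop(structure(class = c("cea_missing_parameter", "error",
                                   "condition"),
                         list(message = paste0("missing parameter: '", nm,
                                               "' field '", k, "'"),
                              call = NULL)))
      extra <- setdiff(names(rec),
                       c("base", "low", "high", "family", "horizon_years",
                         "units"))
      if (length(extra))
        .invalid(nm, paste0("unknown field '", extra[1], "'"))
      data.frame(name = nm, base = as.numeric(rec$base),
                 low = as.numeric(rec$low), high = as.numeric(rec$high),
                 family = as.character(rec$family),
                 horizon_years = if (is.null(rec$horizon_years)) NA_real_
                                 else as.numeric(rec$horizon_years),
                 units = if (is.null(rec$units)) NA_character_
                         else as.character(rec$units),
                 stringsAsFactors = FALSE)
    })
    params <- do.call(rbind, rows)
    conv <- utils::modifyList(defaults,
                              if (is.null(doc$conventions)) list()
                              else doc$conventions)
    extra_top <- setdiff(names(doc), c("parameters", "conventions"))
    if (length(extra_top))
      .invalid(extra_top[1], "unknown top-level section")
  } else if (ext == "csv") {
    params <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "base", "low", "high", "family")
    for (k in need)
      if (!k %in% names(params))
        stop(structure(class = c("cea_missing_parameter", "error",
                                 "condition"),
                       list(message = paste0("missing parameter: column '",
                                             k, "'"), call = NULL)))
    if (!"horizon_years" %in% names(params)) params$horizon_years <- NA_real_
    if (!"units" %in% names(params)) params$units <- NA_character_
    params <- params[c("name", "base", "low", "high", "family",
                       "horizon_years", "units")]
    conv <- defaults
  } else {
    stop("unsupported parameter file extension: .", ext, call. = FALSE)
  }
  # fill registry horizons/units where the file omitted them
  idx <- match(params$name, reg$name)
  fill <- is.na(params$horizon_years) & !is.na(idx)
  params$horizon_years[fill] <- reg$horizon_years[idx[fill]]
  fill <- is.na(params$units) & !is.na(idx)
  params$units[fill] <- reg$units[idx[fill]]
  bundle <- structure(list(parameters = params, conventions = conv),
                      class = "cea_bundle")
  validate_bundle(bundle)
}

#' Write a parameter bundle to YAML, JSON or CSV
#'
#' Inverse of [load_parameters()]: a written bundle reloads with every field
#' identical (conventions are carried by the YAML/JSON dialects only).
#'
#' @param bundle a validated `cea_bundle`.
#' @param path destination file; the extension selects the dialect.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(bundle, path) {
  validate_bundle(bundle)
  p <- bundle$parameters
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml", "json")) {
    recs <- lapply(seq_len(nrow(p)), function(i) {
      r <- list(base = p$base[i], low = p$low[i], high = p$high[i],
                family = p$family[i])
      if (!is.na(p$horizon_years[i])) r$horizon_years <- p$horizon_years[i]
      if (!is.na(p$units[i])) r$units <- p$units[i]
      r
    })
    names(recs) <- p$name
    doc <- list(conventions = bundle$conventions, parameters = recs)
    if (ext == "json")
      jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    else
      yaml::write_yaml(doc, path, precision = 15)
  } else if (ext == "csv") {
    utils::write.csv(p, path, row.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported parameter file extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Look up a parameter's base value
#' @param bundle a `cea_bundle`.
#' @param name parameter name.
#' @return the base value (numeric scalar).
#' @export
param_value <- function(bundle, name) {
  i <- match(name, bundle$parameters$name)
  if (is.na(i)) stop("no such parameter: ", name, call. = FALSE)
  bundle$parameters$base[i]
}

#' Model settings from a bundle
#'
#' @param bundle a `cea_bundle`.
#' @return a list with `n_cycles`, `cycle_length_years`, `discount_rate`,
#'   `wtp_threshold`, `exchange_rate_rmb_per_usd`, `baseline_age` and the
#'   reward conventions.
#' @export
cea_settings <- function(bundle) {
  g <- function(nm) param_value(bundle, nm)
  c(list(n_cycles = as.integer(g("n_cycles")),
         cycle_length_years = g("cycle_length_years"),
         discount_rate = g("discount_rate"),
         wtp_threshold = g("wtp_threshold"),
         exchange_rate_rmb_per_usd = g("exchange_rate_rmb_per_usd"),
         baseline_age = g("baseline_age")),
    bundle$conventions)
}

#' Health-state table from a bundle
#'
#' @param bundle a `cea_bundle`.
#' @return a data frame with one row per state (`well`, `stroke`,
#'   `post_stroke`, `mi`, `post_mi`, `dead`) and columns `utility` and
#'   `annual_cost` (USD/year, excluding drug cost). The absorbing `dead`
#'   state carries utility 0 and cost 0.
#' @export
health_states <- function(bundle) {
  g <- function(nm) param_value(bundle, nm)
  data.frame(
    name = .state_names,
    utility = c(g("utility_well"), g("utility_stroke"),
                g("utility_post_stroke"), g("utility_mi"),
                g("utility_post_mi"), 0),
    annual_cost = c(0, g("cost_stroke"), g("cost_post_stroke"),
                    g("cost_mi"), g("cost_post_mi"), 0),
    stringsAsFactors = FALSE)
}

#' Treatment-strategy table from a bundle
#'
#' @param bundle a `cea_bundle`.
#' @return a data frame with one row per arm (`nifedipine`, `combined`) and
#'   columns `annual_drug_cost` (USD/year), `delta_sd` (mmHg reduction in
#'   the SD of nocturnal systolic BP) and `delta_cv` (absolute reduction in
#'   its coefficient of variation).
#' @export
strategy_table <- function(bundle) {
  g <- function(nm) param_value(bundle, nm)
  data.frame(
    name = .strategy_names,
    annual_drug_cost = c(g("drug_cost_nifedipine"), g("drug_cost_combined")),
    delta_sd = c(g("bpv_delta_sd_nifedipine"), g("bpv_delta_sd_combined")),
    delta_cv = c(g("bpv_delta_cv_nifedipine"), g("bpv_delta_cv_combined")),
    stringsAsFactors = FALSE)
}

#' @export
print.cea_bundle <- function(x, ...) {
  cat("<cea_bundle> ", nrow(x$parameters), " parameters\n", sep = "")
  cat("  conventions: reward_timing=", x$conventions$reward_timing,
      ", drug_cost_states=", x$conventions$drug_cost_states,
      ", sample_mode=", x$conventions$sample_mode, "\n", sep = "")
  invisible(x)
}

#' Write result tables to CSV
#'
#' Writes each table of a named list as `<name>.csv` under `out_dir` with a
#' deterministic column order (as supplied) and full numeric precision; an
#' empty table yields a header-only file. For tables with a `spread` column
#' (tornado tables) rows are written sorted by spread, descending.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory, created if absent.
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    if (nrow(tab) && "spread" %in% names(tab))
      tab <- tab[order(-tab$spread), , drop = FALSE]
    path <- file.path(out_dir, paste0(nm, ".csv"))
    ok <- tryCatch({
      utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                       path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed writing ", path, ": ", conditionMessage(ok), call. = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
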