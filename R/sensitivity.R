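# Deterministic (tornado) and probabilistic sensitivity analysis.

# run with one parameter replaced, returning the ICER of combined vs
# nifedipine
#' @keywords internal
.icer_with <- function(bundle, name, value) {
  i <- match(name, bundle$parameters$name)
  bundle$parameters$base[i] <- value
  bundle$parameters$low[i] <- min(bundle$parameters$low[i], value)
  bundle$parameters$high[i] <- max(bundle$parameters$high[i], value)
  res <- run_base_case(bundle)
  compute_icer(res$combined, res$nifedipine,
               wtp = param_value(bundle, "wtp_threshold"))$icer
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Reruns the full two-arm base case with each eligible parameter in turn
#' set to `base * (1 - perturbation)` and `base * (1 + perturbation)`
#' (all others at base) and records the resulting ICERs. Eligible
#' parameters are every cost, utility and transition probability, plus the
#' discount rate, which is varied over `discount_range` instead of
#' multiplicatively. Perturbed values that would leave a parameter's legal
#' domain (a utility or probability above 1) are clamped to the bound and
#' flagged.
#'
#' @param bundle a validated `cea_bundle`.
#' @param perturbation relative perturbation applied to each parameter
#'   (default 0.10 = +/-10%).
#' @param discount_range length-2 numeric, the low/high discount rates
#'   (default `c(0.01, 0.08)`).
#' @return a data frame of tornado rows sorted by `spread` descending:
#'   `parameter`, `low`, `high` (the perturbed input values),
#'   `icer_at_low`, `icer_at_high`, `spread`
#'   (`|icer_at_high - icer_at_low|`), `clamped`.
#' @export
one_way_sensitivity <- function(bundle, perturbation = 0.10,
                                discount_range = c(0.01, 0.08)) {
  validate_bundle(bundle)
  if (perturbation < 0) stop("perturbation must be >= 0", call. = FALSE)
  reg <- .param_registry()
  eligible <- reg$name[reg$role %in% c("cost", "utility", "probability")]
  p <- bundle$parameters
  rows <- lapply(eligible, function(nm) {
    base <- param_value(bundle, nm)
    lo <- base * (1 - perturbation)
    hi <- base * (1 + perturbation)
    clamped <- FALSE
    bounded <- reg$role[reg$name == nm] %in% c("utility", "probability")
    if (bounded && hi > 1) { hi <- 1; clamped <- TRUE }
    if (lo < 0) { lo <- 0; clamped <- TRUE }
    data.frame(parameter = nm, low = lo, high = hi,
               icer_at_low = .icer_with(bundle, nm, lo),
               icer_at_high = .icer_with(bundle, nm, hi),
               clamped = clamped, stringsAsFactors = FALSE)
  })
  rows <- c(rows, list(data.frame(
    parameter = "discount_rate",
    low = discount_range[1], high = discount_range[2],
    icer_at_low = .icer_with(bundle, "discount_rate", discount_range[1]),
    icer_at_high = .icer_with(bundle, "discount_rate", discount_range[2]),
    clamped = FALSE, stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  out$spread <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$spread), c("parameter", "low", "high",
                                   "icer_at_low", "icer_at_high", "spread",
                                   "clamped")]
  rownames(out) <- NULL
  out
}

#' Fit a sampling distribution to a parameter range
#'
#' Treats the `[low, high]` range as a 95% interval
#' (`sd = (high - low) / (2 * 1.96)`) and fits by the method of moments
#' with `mean = base`:
#' * gamma (costs): `shape = mean^2 / sd^2`, `scale = sd^2 / mean`;
#' * beta (utilities, probabilities): `nu = mean * (1 - mean) / sd^2 - 1`,
#'   `alpha = mean * nu`, `beta = (1 - mean) * nu`;
#' * fixed (or a zero-width range): a degenerate point sampler.
#'
#' @param p a list or one-row data frame with `base`, `low`, `high`,
#'   `family`.
#' @return a `param_sampler`: list with `family`, the fitted parameters,
#'   `mean`, `sd`, and a sampling function `r(n)`.
#' @export
#' @examples
#' fit_distribution(list(base = 16.31, low = 14.68, high = 17.95,
#'                       family = "gamma"))
fit_distribution <- function(p) {
  base <- as.numeric(p$base)
  sd <- (as.numeric(p$high) - as.numeric(p$low)) / (2 * 1.96)
  if (sd < 0) stop("range requires high >= low", call. = FALSE)
  family <- as.character(p$family)
  if (family == "fixed" || sd == 0) {
    return(structure(list(family = "fixed", value = base, mean = base,
                          sd = 0, r = function(n) rep(base, n)),
                     class = "param_sampler"))
  }
  if (family == "gamma") {
    if (base <= 0)
      stop("gamma fit requires base > 0", call. = FALSE)
    shape <- base^2 / sd^2
    scale <- sd^2 / base
    return(structure(list(family = "gamma", shape = shape, scale = scale,
                          mean = base, sd = sd,
                          r = function(n) stats::rgamma(n, shape = shape,
                                                        scale = scale)),
                     class = "param_sampler"))
  }
  if (family == "beta") {
    if (base <= 0 || base >= 1)
      stop("beta fit requires mean in (0, 1)", call. = FALSE)
    nu <- base * (1 - base) / sd^2 - 1
    if (nu <= 0)
      stop("beta fit impossible: sd too large for mean ", base,
           call. = FALSE)
    alpha <- base * nu
    beta <- (1 - base) * nu
    return(structure(list(family = "beta", alpha = alpha, beta = beta,
                          mean = base, sd = sd,
                          r = function(n) stats::rbeta(n, alpha, beta)),
                     class = "param_sampler"))
  }
  stop("unknown distribution family: ", family, call. = FALSE)
}

# names of the parameters that are sampled in the PSA under each mode
#' @keywords internal
.psa_sampled_names <- function(mode) {
  reg <- .param_registry()
  if (mode == "direct") {
    reg$name[reg$role %in% c("cost", "utility", "probability")]
  } else {
    c(reg$name[reg$role %in% c("cost", "utility")],
      reg$name[reg$role == "probability" &
                 !grepl("^p_well_", reg$name)],
      reg$name[reg$role %in% c("bpv", "derivation")])
  }
}

# fast two-arm evaluation from a named vector of drawn parameter values
# (native scale); everything not in `draw` stays at the bundle base
#' @keywords internal
.eval_arms <- function(bundle, draw = NULL, mode = NULL) {
  if (!is.null(draw)) {
    i <- match(names(draw), bundle$parameters$name)
    bundle$parameters$base[i] <- as.numeric(draw)
    bundle$parameters$low[i] <- pmin(bundle$parameters$low[i],
                                     as.numeric(draw))
    bundle$parameters$high[i] <- pmax(bundle$parameters$high[i],
                                      as.numeric(draw))
  }
  res <- run_base_case(bundle, mode = mode)
  c(delta_cost = res$combined$total_cost - res$nifedipine$total_cost,
    delta_qalys = res$combined$total_qalys - res$nifedipine$total_qalys)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter independently from its fitted
#' distribution (see [fit_distribution()]), reruns both arms per draw, and
#' records the incremental cost and QALYs of the combined arm over
#' nifedipine. Probabilities are sampled on their native (multi-year)
#' scale and annualized inside the model; transition-matrix rows are
#' re-closed by their residual each draw, and draws producing incoherent
#' transitions (state exits summing above 1) are rejected and redrawn.
#'
#' @param bundle a validated `cea_bundle`.
#' @param n_iterations number of PSA iterations.
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param wtp_grid willingness-to-pay grid for the acceptability curve;
#'   default: 50 equally spaced points from 0 to the bundle's
#'   `wtp_threshold` inclusive.
#' @param mode event-probability mode (`"direct"`/`"derived"`); defaults
#'   to the bundle convention. In direct mode the per-arm event
#'   probabilities are sampled from their own ranges; in derived mode the
#'   BPV effects and baseline rates are sampled and the incidences
#'   re-derived.
#' @return a `psa_result`: list with `n_iterations`, `seed`, `pairs`
#'   (data frame `iteration`, `delta_cost`, `delta_qalys`), `ceac`
#'   (data frame `wtp`, `probability` where
#'   `probability = P(wtp * dE - dC >= 0)`), `p_ce_at_threshold`,
#'   `wtp_threshold`, `n_rejected`.
#' @export
run_psa <- function(bundle, n_iterations, seed, wtp_grid = NULL,
                    mode = NULL) {
  validate_bundle(bundle)
  stopifnot(n_iterations >= 1)
  if (is.null(mode)) mode <- bundle$conventions$sample_mode
  mode <- match.arg(mode, c("direct", "derived"))
  wtp_threshold <- param_value(bundle, "wtp_threshold")
  if (is.null(wtp_grid))
    wtp_grid <- seq(0, wtp_threshold, length.out = 50)
  sampled <- .psa_sampled_names(mode)
  p <- bundle$parameters
  samplers <- lapply(sampled, function(nm)
    fit_distribution(p[p$name == nm, ]))
  names(samplers) <- sampled

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  dc <- dq <- numeric(n_iterations)
  n_rejected <- 0L
  for (it in seq_len(n_iterations)) {
    repeat {
      draw <- vapply(samplers, function(s) s$r(1), numeric(1))
      pair <- tryCatch(.eval_arms(bundle, draw, mode = mode),
                       error = function(e) e)
      if (!inherits(pair, "error")) break
      n_rejected <- n_rejected + 1L
      if (n_rejected > 100L * n_iterations)
        stop("PSA rejection rate implausibly high: ",
             conditionMessage(pair), call. = FALSE)
    }
    dc[it] <- pair["delta_cost"]
    dq[it] <- pair["delta_qalys"]
  }
  ceac <- data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid,
                         function(w) mean(w * dq - dc >= 0), numeric(1)))
  structure(list(n_iterations = n_iterations, seed = as.integer(seed),
                 pairs = data.frame(iteration = seq_len(n_iterations),
                                    delta_cost = dc, delta_qalys = dq),
                 ceac = ceac,
                 p_ce_at_threshold = mean(wtp_threshold * dq - dc >= 0),
                 wtp_threshold = wtp_threshold,
                 n_rejected = n_rejected,
                 mode = mode),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  ci <- stats::binom.test(round(x$p_ce_at_threshold * x$n_iterations),
                          x$n_iterations)$conf.int
  cat("<psa_result> ", x$n_iterations, " iterations (seed ", x$seed,
      ", mode ", x$mode, ", ", x$n_rejected, " rejected draws)\n", sep = "")
  cat(sprintf("  mean dC %.2f USD, mean dE %.4f QALYs\n",
              mean(x$pairs$delta_cost), mean(x$pairs$delta_qalys)))
  cat(sprintf(
    "  P(cost-effective at WTP %.2f) = %.3f (95%% CI %.3f-%.3f)\n",
    x$wtp_threshold, x$p_ce_at_threshold, ci[1], ci[2]))
  invisible(x)
}
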