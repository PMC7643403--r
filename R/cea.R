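# Cost-effectiveness metrics: CER, ICER with dominance labels, net monetary
# benefit, and the base-case comparison table.

#' Average cost-effectiveness ratio
#'
#' @param cost total (discounted) cost.
#' @param qalys total (discounted) QALYs; must be > 0.
#' @return `cost / qalys`, in money per QALY.
#' @export
compute_cer <- function(cost, qalys) {
  if (!is.numeric(qalys) || any(qalys <= 0))
    stop("qalys must be > 0", call. = FALSE)
  cost / qalys
}

#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes per-strategy CERs, the incremental cost and effect of the
#' intervention over the comparator, the ICER (or a dominance label), the
#' net monetary benefit `NMB = wtp * dE - dC`, and whether the intervention
#' is cost-effective at the willingness-to-pay threshold.
#'
#' The ICER is the ratio `dC / dE` only when `dE != 0`. When the
#' intervention is cheaper and more effective it is labelled `"dominant"`;
#' costlier and less effective, `"dominated"`; identical on both axes,
#' `"equivalent"`; `dE == 0` with `dC != 0` yields an undefined ICER
#' (`NA`) labelled `"undefined"`, never a division result.
#'
#' @param intervention,comparator lists (or `cohort_result` objects) with
#'   elements `cost`/`total_cost` and `qalys`/`total_qalys`.
#' @param wtp willingness-to-pay threshold, money per QALY.
#' @return a `ce_comparison`: list with `intervention`, `comparator`
#'   (each `cost`, `qalys`, `cer`), `delta_cost`, `delta_qalys`, `icer`,
#'   `label` (`"icer"`, `"dominant"`, `"dominated"`, `"equivalent"`,
#'   `"undefined"`), `nmb`, `wtp`, `cost_effective`.
#' @export
#' @examples
#' compute_icer(list(cost = 1739.87, qalys = 12.69),
#'              list(cost = 1095.73, qalys = 12.50), wtp = 9764.95)
compute_icer <- function(intervention, comparator, wtp) {
  pick <- function(x, a, b) {
    v <- if (!is.null(x[[a]])) x[[a]] else x[[b]]
    as.numeric(v)
  }
  ci <- pick(intervention, "cost", "total_cost")
  qi <- pick(intervention, "qalys", "total_qalys")
  cc <- pick(comparator, "cost", "total_cost")
  qc <- pick(comparator, "qalys", "total_qalys")
  if (anyNA(c(ci, qi, cc, qc)))
    stop("intervention/comparator need cost and qalys", call. = FALSE)
  dc <- ci - cc
  dq <- qi - qc
  if (dq != 0) {
    icer <- dc / dq
    label <- if (dc < 0 && dq > 0) "dominant"
             else if (dc > 0 && dq < 0) "dominated"
             else "icer"
  } else if (dc == 0) {
    icer <- NA_real_; label <- "equivalent"
  } else {
    icer <- NA_real_; label <- "undefined"
  }
  nmb <- wtp * dq - dc
  ce <- label == "dominant" ||
    (label == "icer" && dq > 0 && icer >= 0 && icer <= wtp) ||
    (label == "equivalent" ) ||
    (label == "icer" && dq > 0 && icer < 0)
  structure(list(
    intervention = list(cost = ci, qalys = qi,
                        cer = if (qi > 0) compute_cer(ci, qi) else NA_real_),
    comparator = list(cost = cc, qalys = qc,
                      cer = if (qc > 0) compute_cer(cc, qc) else NA_real_),
    delta_cost = dc, delta_qalys = dq, icer = icer, label = label,
    nmb = nmb, wtp = wtp, cost_effective = ce),
    class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat("<ce_comparison>\n")
  cat(sprintf("  intervention: cost %.2f, QALYs %.4f, CER %.2f\n",
              x$intervention$cost, x$intervention$qalys, x$intervention$cer))
  cat(sprintf("  comparator:   cost %.2f, QALYs %.4f, CER %.2f\n",
              x$comparator$cost, x$comparator$qalys, x$comparator$cer))
  icer_txt <- if (x$label == "icer") sprintf("%.2f per QALY", x$icer)
              else x$label
  cat(sprintf("  dC %.2f, dE %.4f, ICER %s\n", x$delta_cost, x$delta_qalys,
              icer_txt))
  cat(sprintf("  NMB at WTP %.2f: %.2f (%scost-effective)\n", x$wtp, x$nmb,
              if (x$cost_effective) "" else "not "))
  invisible(x)
}

#' Base-case results table
#'
#' Runs both arms and tabulates the Table-of-results surface: discounted
#' cost (USD and RMB via the bundle's exchange rate), QALYs, CER, and the
#' ICER of the combined arm over nifedipine.
#'
#' @param bundle a validated `cea_bundle`.
#' @param results optional precomputed output of [run_base_case()].
#' @return a data frame with columns `strategy`, `cost_usd`, `cost_rmb`,
#'   `qalys`, `cer`, `icer` (ICER on the intervention row, `NA` on the
#'   comparator row), plus a rounded `display` column.
#' @export
base_case_table <- function(bundle, results = NULL) {
  if (is.null(results)) results <- run_base_case(bundle)
  stopifnot(all(.strategy_names %in% names(results)))
  cmp <- compute_icer(results$combined, results$nifedipine,
                      wtp = param_value(bundle, "wtp_threshold"))
  fx <- param_value(bundle, "exchange_rate_rmb_per_usd")
  tab <- data.frame(
    strategy = c("combined", "nifedipine"),
    cost_usd = c(cmp$intervention$cost, cmp$comparator$cost),
    cost_rmb = fx * c(cmp$intervention$cost, cmp$comparator$cost),
    qalys = c(cmp$intervention$qalys, cmp$comparator$qalys),
    cer = c(cmp$intervention$cer, cmp$comparator$cer),
    icer = c(cmp$icer, NA_real_),
    stringsAsFactors = FALSE)
  tab$display <- sprintf("cost %.2f USD; %.2f QALYs; CER %.2f",
                         tab$cost_usd, tab$qalys, tab$cer)
  tab
}
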