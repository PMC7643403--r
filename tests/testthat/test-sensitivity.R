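test_that("distribution fits match method-of-moments closed forms", {
  g <- fit_distribution(list(base = 16.31, low = 14.68, high = 17.95,
                             family = "gamma"))
  expect_identical(g$family, "gamma")
  expect_equal(g$sd, (17.95 - 14.68) / 3.92, tolerance = 1e-12)
  expect_equal(g$shape, 382.2826, tolerance = 1e-4)
  expect_equal(g$scale, 0.0426648, tolerance = 1e-6)
  expect_equal(g$shape * g$scale, 16.31, tolerance = 1e-9)  # mean preserved
  bt <- fit_distribution(list(base = 0.5, low = 0.45, high = 0.55,
                              family = "beta"))
  expect_identical(bt$family, "beta")
  expect_equal(bt$alpha, bt$beta, tolerance = 1e-9)  # symmetric case
  expect_equal(bt$alpha, 191.58, tolerance = 1e-2)
  expect_equal(bt$alpha / (bt$alpha + bt$beta), 0.5)
  fx <- fit_distribution(list(base = 0.05, low = 0.05, high = 0.05,
                              family = "fixed"))
  expect_identical(fx$r(4), rep(0.05, 4))
  expect_error(fit_distribution(list(base = 0, low = -1, high = 1,
                                     family = "gamma")), "base > 0")
  expect_error(fit_distribution(list(base = 1.5, low = 1, high = 2,
                                     family = "beta")), "mean")
  expect_error(fit_distribution(list(base = 0.5, low = 0, high = 4,
                                     family = "beta")), "sd too large")
})

test_that("fitted samplers recover their target moments", {
  set.seed(11)
  n <- 50000
  b <- paper_default_bundle()
  p <- b$parameters
  for (nm in c("drug_cost_combined", "cost_stroke", "utility_post_stroke",
               "p_stroke_stroke")) {
    s <- fit_distribution(p[p$name == nm, ])
    x <- s$r(n)
    se <- s$sd / sqrt(n)
    expect_lt(abs(mean(x) - s$mean), 3 * se)
  }
})

test_that("one-way rows bracket the base ICER and sort by spread", {
  b <- paper_default_bundle()
  torn <- one_way_sensitivity(b)
  expect_true(all(diff(torn$spread) <= 1e-12))
  expect_equal(torn$spread,
               abs(torn$icer_at_high - torn$icer_at_low), tolerance = 1e-12)
  # every eligible parameter plus the discount rate has a row
  reg_probs <- grep("^p_", torn$parameter, value = TRUE)
  expect_length(reg_probs, 10)
  expect_true(all(c("utility_well", "cost_mi", "drug_cost_combined",
                    "discount_rate") %in% torn$parameter))
  expect_identical(nrow(torn), 22L)
  # utility_well at +10% would exceed 1: clamped and flagged
  expect_true(torn$clamped[torn$parameter == "utility_well"])
  expect_equal(torn$high[torn$parameter == "utility_well"], 1)
  # discount rate varied over its own range, both reruns finite
  dr <- torn[torn$parameter == "discount_rate", ]
  expect_equal(c(dr$low, dr$high), c(0.01, 0.08))
  expect_true(is.finite(dr$icer_at_low) && is.finite(dr$icer_at_high))
})

test_that("zero perturbation collapses every spread to zero", {
  b <- paper_default_bundle()
  torn <- one_way_sensitivity(b, perturbation = 0)
  base_icer <- base_case_table(b)$icer[1]
  expect_equal(torn$spread[torn$parameter != "discount_rate"],
               rep(0, 21), tolerance = 1e-9)
  expect_equal(torn$icer_at_low[torn$parameter == "utility_well"],
               base_icer, tolerance = 1e-9)
})

test_that("parameters the ICER cannot depend on have zero spread", {
  # make the MI family unreachable in both arms: its costs, utilities and
  # downstream probabilities then provably cannot move the ICER
  b <- paper_default_bundle()
  b <- set_param(b, "p_well_mi_combined", 0)
  b <- set_param(b, "p_well_mi_nifedipine", 0)
  b <- set_param(b, "p_well_stroke_combined", 0)
  b <- set_param(b, "p_well_stroke_nifedipine", 1e-4)
  torn <- one_way_sensitivity(b)
  for (nm in c("cost_mi", "utility_post_mi", "p_mi_mi", "p_post_mi_death"))
    expect_equal(torn$spread[torn$parameter == nm], 0, tolerance = 1e-9)
  expect_gt(torn$spread[torn$parameter == "p_well_stroke_nifedipine"], 0)
})

test_that("PSA is seed-reproducible and collapses under zero variance", {
  b <- paper_default_bundle()
  p1 <- run_psa(b, 40, seed = 42)
  p2 <- run_psa(b, 40, seed = 42)
  expect_identical(p1$pairs, p2$pairs)  # bit-identical given the seed
  expect_identical(p1$ceac, p2$ceac)
  p3 <- run_psa(b, 40, seed = 43)
  expect_false(identical(p1$pairs, p3$pairs))
  # degenerate samplers: every pair equals the base case exactly
  bz <- b
  bz$parameters$low <- bz$parameters$base
  bz$parameters$high <- bz$parameters$base
  pz <- run_psa(bz, 5, seed = 1)
  res <- run_base_case(b)
  expect_equal(pz$pairs$delta_cost,
               rep(res$combined$total_cost - res$nifedipine$total_cost, 5),
               tolerance = 1e-12)
  expect_equal(pz$pairs$delta_qalys,
               rep(res$combined$total_qalys - res$nifedipine$total_qalys, 5),
               tolerance = 1e-12)
  # CEAC is then a unit step at the base ICER
  base_icer <- base_case_table(b)$icer[1]
  expect_equal(pz$ceac$probability,
               as.numeric(pz$ceac$wtp >= base_icer - 1e-9))
})

test_that("the CEAC starts at the cost-saving fraction and rises with WTP", {
  b <- paper_default_bundle()
  ps <- run_psa(b, 200, seed = 5)
  expect_equal(ps$ceac$probability[ps$ceac$wtp == 0],
               mean(ps$pairs$delta_cost <= 0))
  # combined is costlier & more effective in every draw here, so the
  # acceptability curve is non-decreasing in the threshold
  expect_true(all(ps$pairs$delta_qalys > 0))
  expect_true(all(diff(ps$ceac$probability) >= 0))
  expect_true(all(ps$ceac$probability >= 0 & ps$ceac$probability <= 1))
  expect_equal(ps$p_ce_at_threshold,
               ps$ceac$probability[nrow(ps$ceac)])  # threshold ends the grid
  expect_identical(ps$n_rejected, 0L)
})

test_that("derived-mode PSA samples BPV effects instead of arm incidences", {
  b <- paper_default_bundle(sample_mode = "derived")
  ps <- run_psa(b, 30, seed = 9)
  expect_identical(ps$mode, "derived")
  expect_true(all(ps$pairs$delta_qalys > 0))
})
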