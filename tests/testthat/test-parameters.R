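test_that("default bundle carries the base-case inputs and validates", {
  b <- paper_default_bundle()
  expect_s3_class(b, "cea_bundle")
  expect_identical(validate_bundle(b), b)
  expect_equal(param_value(b, "utility_well"), 0.98)
  expect_equal(param_value(b, "utility_stroke"), 0.5)
  expect_equal(param_value(b, "drug_cost_nifedipine"), 16.31)
  expect_equal(param_value(b, "drug_cost_combined"), 102.42)
  expect_equal(param_value(b, "bpv_delta_sd_combined"), 2.99)
  expect_equal(param_value(b, "bpv_delta_cv_combined"), 0.01)
  # post-MI annual cost is the midpoint both +/-10% endpoints back-solve to
  expect_equal(param_value(b, "cost_post_mi"), 2041.84)
  expect_equal(1837.66 / 0.9, 2041.84, tolerance = 1e-4)
  expect_equal(2246.03 / 1.1, 2041.84, tolerance = 1e-4)
  s <- cea_settings(b)
  expect_identical(s$n_cycles, 20L)
  expect_equal(s$discount_rate, 0.05)
  expect_equal(s$wtp_threshold, 9764.95)
  hs <- health_states(b)
  expect_identical(hs$name,
                   c("well", "stroke", "post_stroke", "mi", "post_mi",
                     "dead"))
  expect_equal(hs$utility[hs$name == "dead"], 0)
  expect_equal(hs$annual_cost[hs$name == "dead"], 0)
})

test_that("default ranges are base +/- 10% except where reported otherwise", {
  b <- paper_default_bundle()
  p <- b$parameters
  reg_exceptions <- c(
    # settings and derivation inputs with their own reported ranges
    "n_cycles", "cycle_length_years", "discount_rate", "wtp_threshold",
    "exchange_rate_rmb_per_usd", "baseline_age",
    "utility_well",             # high capped at 1
    "stroke_increment_per_sd",  # reported 0.003-0.004
    "mi_increment_per_cv",      # reported 0.0073-0.0089
    "bpv_delta_cv_nifedipine",  # zero effect, no range
    "p_well_mi_combined",       # reported 0.0017-0.0021
    "p_well_stroke_combined"    # reported 0.0009-0.0011
  )
  chk <- p[!p$name %in% reg_exceptions, ]
  expect_true(all(abs(chk$low / (chk$base * 0.9) - 1) < 0.01))
  expect_true(all(abs(chk$high / (chk$base * 1.1) - 1) < 0.01))
})

test_that("bundles round-trip exactly through YAML, JSON and CSV", {
  b <- paper_default_bundle(reward_timing = "half",
                            drug_cost_states = "well_only")
  for (ext in c("yaml", "json", "csv")) {
    path <- file.path(tempdir(), paste0("params.", ext))
    write_parameters(b, path)
    b2 <- load_parameters(path)
    expect_equal(b2$parameters, b$parameters, tolerance = 1e-12)
    if (ext != "csv")  # CSV carries the flat table only
      expect_identical(b2$conventions, b$conventions)
    unlink(path)
  }
})

test_that("the shipped fixture file equals the in-code default bundle", {
  path <- system.file("extdata", "hypertension_bpv_params.yaml",
                      package = "bpvcea")
  expect_true(nzchar(path))
  b <- load_parameters(path)
  expect_equal(b$parameters, paper_default_bundle()$parameters,
               tolerance = 1e-12)
})

test_that("validation names missing and invalid parameters", {
  b <- paper_default_bundle()
  # out-of-bound utility
  bad <- b
  i <- match("utility_stroke", bad$parameters$name)
  bad$parameters$base[i] <- 1.2
  bad$parameters$high[i] <- 1.2
  err <- expect_error(validate_bundle(bad), class = "cea_invalid_parameter")
  expect_match(conditionMessage(err), "utility_stroke")
  # missing parameter
  bad <- b
  bad$parameters <- bad$parameters[bad$parameters$name != "cost_mi", ]
  err <- expect_error(validate_bundle(bad), class = "cea_missing_parameter")
  expect_match(conditionMessage(err), "cost_mi")
  # unknown parameter name
  bad <- b
  extra <- bad$parameters[1, ]
  extra$name <- "not_a_real_parameter"
  bad$parameters <- rbind(bad$parameters, extra)
  err <- expect_error(validate_bundle(bad), class = "cea_invalid_parameter")
  expect_match(conditionMessage(err), "not_a_real_parameter")
  # low > base
  bad <- b
  i <- match("cost_stroke", bad$parameters$name)
  bad$parameters$low[i] <- bad$parameters$base[i] + 1
  expect_error(validate_bundle(bad), class = "cea_invalid_parameter")
})

test_that("file loader rejects unknown keys and reports missing fields", {
  b <- paper_default_bundle()
  path <- file.path(tempdir(), "params_edit.yaml")
  write_parameters(b, path)
  doc <- yaml::read_yaml(path)
  doc$parameters$utility_well$surprise <- 1
  yaml::write_yaml(doc, path)
  err <- expect_error(load_parameters(path),
                      class = "cea_invalid_parameter")
  expect_match(conditionMessage(err), "surprise")
  doc$parameters$utility_well$surprise <- NULL
  doc$parameters$utility_well$family <- NULL
  yaml::write_yaml(doc, path)
  err <- expect_error(load_parameters(path),
                      class = "cea_missing_parameter")
  expect_match(conditionMessage(err), "family")
  unlink(path)
  expect_error(load_parameters(file.path(tempdir(), "no_such_file.yaml")),
               "not found")
})

test_that("write_results writes deterministic CSV tables", {
  out <- file.path(tempdir(), "res_out")
  tab <- data.frame(strategy = c("combined", "nifedipine"),
                    cost_usd = c(1758.437, 1085.271),
                    qalys = c(12.684, 12.492),
                    cer = c(138.63, 86.88), icer = c(3507.8, NA))
  torn <- data.frame(parameter = c("a", "b", "c"),
                     icer_at_low = c(1, 2, 3), icer_at_high = c(2, 8, 5),
                     spread = c(1, 6, 2))
  empty <- data.frame(iteration = integer(), delta_cost = numeric(),
                      delta_qalys = numeric())
  paths <- write_results(list(base_case = tab, tornado = torn,
                              psa_scatter = empty), out)
  expect_true(all(file.exists(paths)))
  got <- read.csv(file.path(out, "base_case.csv"))
  expect_identical(names(got),
                   c("strategy", "cost_usd", "qalys", "cer", "icer"))
  expect_equal(got$cost_usd, tab$cost_usd)
  got_t <- read.csv(file.path(out, "tornado.csv"))
  expect_identical(got_t$parameter, c("b", "c", "a"))  # spread-descending
  got_e <- read.csv(file.path(out, "psa_scatter.csv"))
  expect_identical(nrow(got_e), 0L)
  expect_identical(names(got_e),
                   c("iteration", "delta_cost", "delta_qalys"))
  unlink(out, recursive = TRUE)
})
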