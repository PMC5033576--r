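# Calibration of the dependent parameters and the balanced-growth
# composition, checked against the published subtype baselines and by
# definitional round trips.

test_that("P_sleep calibration reproduces the subtype baselines", {
  # SCC matches the published value at its full printed precision; the
  # published ADC value (0.265733) embeds a rounded intermediate growth
  # rate - the full-precision solution is 0.265712
  expect_equal(calibrate_p_sleep(scc_profile, scc_ind), 0.27960,
               tolerance = 2e-5)
  expect_equal(calibrate_p_sleep(adc_profile, adc_ind), 0.265712,
               tolerance = 5e-6)
})

test_that("P_sleep round-trips through the growth-rate solver", {
  for (s in c("ADC", "SCC")) {
    prof <- subtype_profile(s)
    p <- calibrate_full(prof, subtype_independents(s))
    expect_equal(solve_growth_rate(p)$T_d, prof$T_d, tolerance = 1e-6)
  }
})

test_that("dependent-parameter calibrations hit the Table targets", {
  expect_equal(calibrate_r_ndiff(scc_profile, scc_ind), 0.01, tolerance = 0.1)
  expect_equal(round(calibrate_r_ndiff(adc_profile, adc_ind), 4), 9e-4)
  expect_equal(round_duration(calibrate_t_a(adc_profile, adc_ind)), 4L)
  expect_equal(round_duration(calibrate_t_n(adc_profile, adc_ind)), 23L)
  expect_equal(round_duration(calibrate_t_n(scc_profile, scc_ind)), 79L)
  expect_equal(as.integer(solve_n_limp(scc_profile, scc_ind)), 22L)
  expect_equal(as.integer(solve_n_limp(adc_profile, adc_ind)), 18L)
})

test_that("calibrations invert their balanced-growth relations exactly", {
  for (s in c("ADC", "SCC")) {
    prof <- subtype_profile(s)
    p <- calibrate_full(prof, subtype_independents(s))
    b <- balanced_composition(p)
    expect_equal(b$GF, prof$GF, tolerance = 1e-6)
    expect_equal(b$AF, prof$AF, tolerance = 1e-6)
    expect_equal(b$NF, prof$NF, tolerance = 1e-6)
    expect_equal(b$T_d, prof$T_d, tolerance = 1e-3)
  }
})

test_that("degenerate targets collapse to zero clearance times", {
  prof0 <- proliferation_profile(T_d = 109, GF = 0.36, AF = 0, NF = 0.2,
                                 SF = 2e-4)
  expect_equal(calibrate_t_a(prof0, scc_ind), 0)
  profn <- proliferation_profile(T_d = 109, GF = 0.36, AF = 0.01, NF = 0,
                                 SF = 2e-4)
  expect_equal(calibrate_t_n(profn, scc_ind), 0)
})

test_that("N_LIMP solution matches an exhaustive integer search", {
  # brute-force oracle: minimize |LHS(n) - RHS| of the generation-flux sum
  brute <- function(profile, ind) {
    a <- log(2) / (profile$T_d * 24)
    ps <- calibrate_p_sleep(profile, ind)
    x <- a + ind$R_A
    A <- x / expm1(x * ind$T_C)
    B <- (1 + ind$P_sym) * ps / (x + 1 / ind$T_G0)
    nsnl <- profile$SF / ((1 + A * B) * profile$GF - profile$SF)
    rhs <- 1 / ((1 - ind$P_sym) * nsnl)
    lhs <- vapply(1:64, function(n) {
      sum(2^(0:(n - 1)) / (1 + ind$P_sym)^(1:n))
    }, numeric(1))
    which.min(abs(lhs - rhs))
  }
  for (s in c("ADC", "SCC")) {
    prof <- subtype_profile(s)
    ind <- subtype_independents(s)
    expect_equal(as.integer(solve_n_limp(prof, ind)), brute(prof, ind))
  }
  # and on perturbed targets
  prof2 <- proliferation_profile(T_d = 150, GF = 0.25, AF = 0.01, NF = 0.1,
                                 SF = 4e-4)
  expect_equal(as.integer(solve_n_limp(prof2, scc_ind)),
               brute(prof2, scc_ind))
})

test_that("growth rate responds monotonically to its drivers", {
  base <- baseline_params("SCC")
  a0 <- solve_growth_rate(base)$a
  bump <- function(which, f) {
    p <- unclass(base)
    p[[which]] <- p[[which]] * f
    solve_growth_rate(structure(p, class = "kinetic_params"))$a
  }
  for (f in c(1.1, 1.3)) {
    expect_gt(bump("P_sym", f), a0)        # faster self-renewal
    expect_lt(bump("P_sleep", f), a0)      # more dormancy
    expect_lt(bump("R_A", 10 * f), a0)     # more spontaneous loss
    expect_lt(bump("T_C_stem", f), a0)     # slower cycle
  }
})

test_that("composition fractions are normalized for random valid sets", {
  sets <- random_valid_params(12, seed = 101)
  expect_gte(length(sets), 8)
  for (p in sets) {
    b <- balanced_composition(p)
    expect_equal(b$SF + b$LF + b$DF, 1, tolerance = 1e-12)
    expect_equal(b$GF + b$QF + b$DF, 1, tolerance = 1e-12)
    expect_equal(b$living_of_total + b$AF + b$NF, 1, tolerance = 1e-12)
    expect_true(all(c(b$SF, b$LF, b$DF, b$GF, b$QF, b$AF, b$NF) >= 0))
    expect_true(all(c(b$SF, b$LF, b$DF, b$GF, b$QF, b$AF, b$NF) <= 1))
  }
})

test_that("unreachable profiles yield structured failures, not crashes", {
  # GF far below what the independents allow forces a negative R_NDiff
  prof <- proliferation_profile(T_d = 109, GF = 0.95, AF = 0.01, NF = 0.01,
                                SF = 2e-4)
  res <- calibrate_full(prof, scc_ind)
  expect_true(is_calibration_failure(res))
  expect_error(calibrate_full(prof, scc_ind, on_failure = "error"),
               class = "ckrsim_unreachable_profile")
  # a doubling time too short for the cycle time cannot be reached
  fast <- proliferation_profile(T_d = 2, GF = 0.36, AF = 0.01, NF = 0.2,
                                SF = 2e-4)
  expect_true(is_calibration_failure(calibrate_full(fast, scc_ind)))
})

test_that("tidy and glance expose the composition", {
  b <- balanced_composition(baseline_params("SCC"))
  td <- generics::tidy(b)
  expect_named(td, c("quantity", "value", "denominator"))
  expect_equal(nrow(td), 9)
  g <- generics::glance(b)
  expect_equal(g$T_d, 109, tolerance = 1e-4)
})
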