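# The discrete-time population simulator: deterministic toy checks,
# conservation, stationarity at balanced growth, and drug action arithmetic.

test_that("pure stem doubling: population doubles every cycle", {
  # no losses, no dormancy, always-symmetric division
  p <- toy_params(R_A = 0, P_sleep = 0, P_sym = 1)
  st <- toy_state(p, Cs = c(100, 100))
  v0 <- sum(st$Cs)
  st2 <- step_state(st, n = 2)          # one full T_C = 2 ticks
  expect_equal(sum(st2$Cs), 2 * v0)
  st4 <- step_state(st2, n = 2)
  expect_equal(sum(st4$Cs), 4 * v0)
})

test_that("two expectation-mode ticks match a hand calculation", {
  # stem-only toy with apoptosis, dormancy and G0 return; worked by hand
  p <- toy_params(R_A = 0.01, P_sleep = 0.5, P_sym = 1, P_G0toG1 = 1,
                  T_G0 = 10)
  st <- toy_state(p, Cs = c(100, 80), g0s = 50)
  s1 <- step_state(st)
  # tick 1: losses Cs->(99,79.2), g0->49.5, apo_in=1.8+0.5
  #         exits 4.95 (all return); mitosis 79.2 -> 158.4 newborns,
  #         half sleep; conveyor head = 79.2 + 4.95
  expect_equal(s1$Cs, c(79.2 + 4.95, 99), tolerance = 1e-12)
  expect_equal(s1$g0s, 49.5 - 4.95 + 79.2, tolerance = 1e-12)
  expect_equal(s1$apo, 2.3, tolerance = 1e-12)
  s2 <- step_state(s1)
  expect_equal(s2$Cs, c(98.01 + 12.25125, 83.3085), tolerance = 1e-12)
  expect_equal(s2$g0s, 123.75 * 0.99 * 0.9 + 98.01, tolerance = 1e-12)
  # pool: clearance 1/T_A = 0.2 applied to the old content, then inflow
  expect_equal(s2$apo, 2.3 * 0.8 + 0.01 * (84.15 + 99) + 1.2375,
               tolerance = 1e-12)
})

test_that("cells are conserved at every tick of an expectation run", {
  sch <- treatment_schedule(day = c(1, 8), drug = c("cisplatin", "gemcitabine"),
                            ckr = c(0.3, 0.2), onset_h = 5 * 24)
  tr <- simulate_tumor(baseline_params("SCC"), 500, duration_days = 30,
                       schedule = sch)
  expect_lt(attr(tr, "conservation_error"), 1e-9)
})

test_that("a balanced-growth initial state is stationary in composition", {
  for (s in c("ADC", "SCC")) {
    p <- baseline_params(s)
    b <- balanced_composition(p)
    tr <- simulate_tumor(p, 523.6, duration_days = 10)
    last <- tr[nrow(tr), ]
    tot <- last$volume_mm3 * attr(tr, "cell_density")
    expect_equal(last$cycling / last$living, b$GF, tolerance = 1e-3)
    expect_equal(last$g0 / last$living, b$QF, tolerance = 1e-3)
    expect_equal(last$diff / last$living, b$DF, tolerance = 1e-3)
    expect_equal(last$stem / last$living, b$SF, tolerance = 5e-3)
    expect_equal(last$apoptotic / tot, b$AF, tolerance = 5e-3)
    expect_equal(last$necrotic / tot, b$NF, tolerance = 5e-3)
  }
})

test_that("free growth is exponential at the closed-form rate", {
  sets <- c(list(baseline_params("SCC")), random_valid_params(6, seed = 7))
  # restrict to the clinically stated doubling-time regime (a 90 d window
  # cannot pin down a multi-year doubling time to 1%)
  sets <- Filter(function(p) solve_growth_rate(p)$T_d <= 600, sets)
  expect_gte(length(sets), 3)
  for (p in sets) {
    a <- solve_growth_rate(p)$a
    tr <- simulate_tumor(p, 100, duration_days = 90)
    fit <- doubling_time(tr)
    expect_gt(fit$r_squared, 0.9999)
    expect_equal(fit$T_d, log(2) / a / 24, tolerance = 0.01)
  }
})

test_that("zero kill rates reproduce free growth exactly", {
  p <- baseline_params("SCC")
  sch <- treatment_schedule(day = c(1, 8), drug = c("cisplatin", "gemcitabine"),
                            ckr = c(0, 0), onset_h = 24)
  free <- simulate_tumor(p, 500, duration_days = 20)
  treated <- simulate_tumor(p, 500, duration_days = 20, schedule = sch)
  expect_identical(free$volume_mm3, treated$volume_mm3)
})

test_that("administration hits the phase compartments arithmetically", {
  p <- baseline_params("SCC")       # CKF_stem = 0.5
  st <- initialize_state(100, p)
  cyc_s <- sum(st$Cs); cyc_l <- sum(st$Cl); g0 <- st$g0s + sum(st$g0l)
  hit <- apply_administration(
    st, data.frame(drug = c("cisplatin", "gemcitabine"), ckr = c(0.3, 0.2)))
  # LIMP cycling: 0.5 hit; stem cycling: 0.5 * CKF = 0.25 hit
  expect_equal(sum(hit$Cl), 0.5 * cyc_l, tolerance = 1e-12)
  expect_equal(sum(hit$Cs), 0.75 * cyc_s, tolerance = 1e-12)
  # dormant cells only see cisplatin (0.3; stem side scaled by CKF)
  expect_equal(hit$g0hit_l + hit$g0hit_s,
               0.3 * sum(st$g0l) + 0.15 * st$g0s, tolerance = 1e-9)
  expect_equal(sum(hit$H), 0.5 * cyc_l + 0.25 * cyc_s, tolerance = 1e-9)
  expect_equal(hit$diff, st$diff)   # DIFF cells are never direct targets
})

test_that("cycle-specific drug at CKR 1 empties the cycle, spares G0", {
  p_sensitive <- calibrate_full(scc_profile,
                                c(scc_ind[setdiff(names(scc_ind), "CKF_stem")],
                                  list(CKF_stem = 1)))
  st <- initialize_state(100, p_sensitive)
  hit <- apply_administration(st, data.frame(drug = "gemcitabine", ckr = 1))
  expect_equal(sum(hit$Cs) + sum(hit$Cl), 0)
  expect_equal(hit$g0s, st$g0s)
  expect_equal(hit$g0hit_s + hit$g0hit_l, 0)
  expect_equal(hit$diff, st$diff)
})

test_that("unknown drugs are rejected", {
  st <- initialize_state(10, baseline_params("SCC"))
  expect_error(apply_administration(st, data.frame(drug = "5FU", ckr = 0.2)),
               "unknown drug")
  expect_error(treatment_schedule(1, "5FU", 0.2), "unknown drug")
})

test_that("cycling-hit cohorts are cleared within two cycles", {
  p <- baseline_params("SCC")
  st <- initialize_state(100, p)
  hit <- apply_administration(st, data.frame(drug = "gemcitabine", ckr = 0.5))
  later <- step_state(hit, n = 2 * attr(st, "pd")$Ll + 2)
  expect_equal(sum(later$H), 0)
})

test_that("final volume decreases monotonically with CKR", {
  p <- baseline_params("SCC")
  finals <- vapply(c(0, 0.2, 0.45, 0.7, 1), function(k) {
    sch <- treatment_schedule(day = c(1, 1, 8, 22, 22, 29),
                              drug = c("cisplatin", "gemcitabine",
                                       "gemcitabine", "cisplatin",
                                       "gemcitabine", "gemcitabine"),
                              ckr = c(k, 0.2, 0.2, k, 0.2, 0.2),
                              onset_h = 7 * 24)
    tr <- simulate_tumor(p, 925, duration_days = 42, schedule = sch)
    tr$volume_mm3[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
})

test_that("a doublet regimen causes regression and repopulation cycles", {
  p <- baseline_params("SCC")
  sch <- treatment_schedule(
    day = c(1, 1, 8, 22, 22, 29, 43, 43, 50),
    drug = c("cisplatin", "gemcitabine", "gemcitabine", "cisplatin",
             "gemcitabine", "gemcitabine", "cisplatin", "gemcitabine",
             "gemcitabine"),
    ckr = c(0.4, 0.2, 0.2, 0.4, 0.2, 0.2, 0.4, 0.2, 0.2), onset_h = 7 * 24)
  tr <- simulate_tumor(p, 523.6, duration_days = 70, schedule = sch)
  after <- tr$volume_mm3[tr$time_h >= 7 * 24]
  expect_true(any(diff(after) < 0))          # treatment-induced regression
  expect_true(any(diff(after) > 0))          # repopulation in between
  expect_lt(min(after), tr$volume_mm3[1])    # net shrinkage below baseline
  free <- simulate_tumor(p, 523.6, duration_days = 70)
  expect_lt(after[length(after)], free$volume_mm3[nrow(free)])
})

test_that("expectation mode is deterministic; stochastic mode is seeded", {
  p <- baseline_params("SCC")
  e1 <- simulate_tumor(p, 50, duration_days = 15)
  e2 <- simulate_tumor(p, 50, duration_days = 15)
  expect_identical(e1$volume_mm3, e2$volume_mm3)
  s1 <- simulate_tumor(p, 0.5, duration_days = 15, mode = "stochastic", seed = 3)
  s2 <- simulate_tumor(p, 0.5, duration_days = 15, mode = "stochastic", seed = 3)
  s3 <- simulate_tumor(p, 0.5, duration_days = 15, mode = "stochastic", seed = 4)
  expect_identical(s1$volume_mm3, s2$volume_mm3)
  expect_false(identical(s1$volume_mm3, s3$volume_mm3))
  expect_error(simulate_tumor(p, 1, 5, mode = "stochastic"), "seed")
})

test_that("stochastic ensemble mean tracks the expectation-mode run", {
  p <- baseline_params("SCC")
  sch <- treatment_schedule(day = 1, drug = "cisplatin", ckr = 0.4,
                            onset_h = 3 * 24)
  expec <- simulate_tumor(p, 0.2, duration_days = 20, schedule = sch)
  finals <- vapply(1:30, function(s) {
    tr <- simulate_tumor(p, 0.2, duration_days = 20, schedule = sch,
                         mode = "stochastic", seed = s)
    tr$volume_mm3[nrow(tr)]
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expec$volume_mm3[nrow(expec)]), 3 * se)
})

test_that("doubling_time handles exact, negative and flat trajectories", {
  tr <- tibble::tibble(time_h = seq(0, 2400, by = 24),
                       volume_mm3 = 100 * 2^(time_h / (100 * 24)))
  # suppressWarnings: lm's "essentially perfect fit" on exact fixtures
  expect_equal(suppressWarnings(doubling_time(tr))$T_d, 100, tolerance = 1e-9)
  shrink <- tibble::tibble(time_h = tr$time_h,
                           volume_mm3 = 100 * 2^(-tr$time_h / (50 * 24)))
  fit <- suppressWarnings(doubling_time(shrink))
  expect_true(fit$negative_growth)
  expect_equal(fit$T_d, -50, tolerance = 1e-9)
  flat <- tibble::tibble(time_h = tr$time_h, volume_mm3 = rep(100, nrow(tr)))
  expect_equal(suppressWarnings(doubling_time(flat))$T_d, Inf)
})
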