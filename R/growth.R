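# Balanced-exponential-growth mathematics.
#
# In balanced growth every compartment grows as e^(a t) and all fractions are
# time-invariant. The stem-cell renewal balance fixes a: a newborn stem cell
# reaches its own mitosis through the cycle directly (prob 1 - P_sleep) or via
# a memoryless G0 visit (prob P_sleep, return prob P_G0toG1 at rate 1/T_G0),
# dying by apoptosis at rate R_A throughout; each stem mitosis produces
# (1 + P_sym) stem daughters on average. Discounting at rate a (the Laplace
# transform of the generation-time distribution) gives
#   (1 + P_sym) e^{-(a+R_A)T_C} [(1-P_sleep) + P_sleep g(a)] = 1,
#   g(a) = P_G0toG1 (1/T_G0) / (a + R_A + 1/T_G0),
# which is the implicit growth-rate relation solved below and, rearranged for
# P_sleep, the closed-form P_sleep calibration.

# per-class Laplace-domain quantities at growth rate a
class_quantities <- function(a, R_A, T_C, T_G0, P_G0toG1, P_sleep) {
  x <- a + R_A
  E <- exp(-x * T_C)                        # survival+discount through one cycle
  g <- P_G0toG1 * (1 / T_G0) / (x + 1 / T_G0)   # discounted G0 return prob
  psi <- (1 - P_sleep) + P_sleep * g        # newborn -> G1-entry transform
  cyc <- if (abs(x) < 1e-12) T_C else (1 - E) / x  # cycling occupancy per G1 entry
  list(
    E = E, g = g, psi = psi,
    phi = E * psi,                          # newborn -> own-mitosis transform
    cyc_per_newborn = psi * cyc,
    g0_per_newborn = P_sleep / (x + 1 / T_G0),
    nec_flux_per_newborn = P_sleep * (1 - P_G0toG1) * (1 / T_G0) / (x + 1 / T_G0)
  )
}

growth_balance <- function(a, p) {
  qs <- class_quantities(a, p$R_A, p$T_C_stem, p$T_G0_stem,
                         p$P_G0toG1_stem, p$P_sleep)
  (1 + p$P_sym) * qs$phi - 1
}

#' Solve the intrinsic growth rate of a parameter set
#'
#' Finds the balanced-growth rate `a` (per hour) for which the stem-cell
#' renewal balance holds, by bracketed root finding on `[-0.1, 0.1]` per hour.
#' Only stem-cell kinetics enter: LIMP kinetics change the population
#' composition but not the growth rate.
#'
#' @param params A [kinetic_params()] object.
#' @return List with `a` (per hour), `T_d` (days, `log(2)/a/24`; negative for
#'   a shrinking tumor) and `negative_growth` flag.
#' @examples
#' solve_growth_rate(baseline_params("SCC"))$T_d   # ~109 days
#' @export
solve_growth_rate <- function(params) {
  p <- params
  f <- function(a) growth_balance(a, p)
  # doubling times of 26-700 d sit well inside [-0.1, 0.1] per hour; the
  # bracket widens only for configurations far outside that regime (the
  # upper bound of a is log(2 (1 + P_sym)) / T_C for a loss-free tumor)
  lo <- -0.1 + 1e-12
  hi <- max(0.1, log(4) / p$T_C_stem)
  tries <- 0L
  while (f(lo) * f(hi) > 0 && tries < 8L) {
    lo <- 2 * lo
    hi <- 2 * hi
    tries <- tries + 1L
  }
  if (f(lo) * f(hi) > 0) {
    stop("solve_growth_rate: no real growth rate for parameter set ",
         "(T_C_stem = ", p$T_C_stem, ", P_sym = ", p$P_sym,
         ", P_sleep = ", p$P_sleep, ")", call. = FALSE)
  }
  a <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  list(a = a, T_d = log(2) / a / 24, negative_growth = a < 0)
}

#' Balanced-growth population composition
#'
#' Computes the steady-state composition of the exponentially growing
#' population: fractions of living cells that are stem, LIMP, DIFF, cycling
#' (GF) or dormant (QF), fractions of total cells that are apoptotic (AF) or
#' necrotic (NF), and the derived ratios SLF (stem/LIMP) and SDF (stem/DIFF).
#'
#' All compartments are expressed per unit stem-mitosis flux. With
#' `r = 2 phi_L` the discounted LIMP doubling factor, the newborn influx into
#' LIMP generation g is `(1 - P_sym) r^(g-1)`, terminal divisions feed DIFF,
#' DIFF is cleared at `R_ADiff + R_NDiff`, and the apoptotic/necrotic pools
#' are exponential clearances with means `T_A`, `T_N`.
#'
#' @param params A [kinetic_params()] object.
#' @return An object of class `growth_solution`: growth rate (`a`, `T_d`),
#'   equal-kinetics intermediates `A` and `B`, population ratios
#'   (`ratio_A_P`, `ratio_N_P`, `ratio_G0_P`, `ratio_S_L`) and the
#'   composition fractions (`SF`, `LF`, `DF`, `GF`, `QF`, `AF`, `NF`,
#'   `SLF`, `SDF`).
#' @examples
#' balanced_composition(baseline_params("SCC"))
#' @export
balanced_composition <- function(params) {
  p <- params
  gr <- solve_growth_rate(p)
  a <- gr$a
  x <- a + p$R_A
  S <- class_quantities(a, p$R_A, p$T_C_stem, p$T_G0_stem, p$P_G0toG1_stem, p$P_sleep)
  L <- class_quantities(a, p$R_A, p$T_C_limp, p$T_G0_limp, p$P_G0toG1_limp, p$P_sleep)

  nb_stem <- 1 + p$P_sym                      # stem newborns per stem mitosis
  r <- 2 * L$phi                              # discounted LIMP doubling factor
  g <- seq_len(p$N_LIMP)
  nb_limp <- (1 - p$P_sym) * r^(g - 1)        # newborn influx per generation
  flux_diff <- (1 - p$P_sym) * r^p$N_LIMP     # terminal divisions -> 2 DIFF each

  N_S <- nb_stem * (S$cyc_per_newborn + S$g0_per_newborn)
  N_Lp <- sum(nb_limp) * L$cyc_per_newborn
  N_Lg0 <- sum(nb_limp) * L$g0_per_newborn
  N_L <- N_Lp + N_Lg0
  N_P <- nb_stem * S$cyc_per_newborn + N_Lp
  N_G0 <- nb_stem * S$g0_per_newborn + N_Lg0
  denom_diff <- a + p$R_ADiff + p$R_NDiff
  if (denom_diff <= 0) stop("balanced_composition: DIFF pool diverges (a + R_ADiff + R_NDiff <= 0)", call. = FALSE)
  N_D <- flux_diff / denom_diff
  if (a + 1 / p$T_A <= 0 || a + 1 / p$T_N <= 0) {
    stop("balanced_composition: dead-cell pool diverges at this growth rate", call. = FALSE)
  }
  F_A <- p$R_A * (N_P + N_G0) + p$R_ADiff * N_D
  N_A <- F_A / (a + 1 / p$T_A)
  F_N <- nb_stem * S$nec_flux_per_newborn + sum(nb_limp) * L$nec_flux_per_newborn +
    p$R_NDiff * N_D
  N_N <- F_N / (a + 1 / p$T_N)

  living <- N_S + N_L + N_D
  total <- living + N_A + N_N

  # equal-kinetics intermediates of the closed-form calibration
  A <- x / expm1(x * p$T_C_stem)
  B <- (1 + p$P_sym) * p$P_sleep / (x + 1 / p$T_G0_stem)

  structure(list(
    a = a, T_d = gr$T_d, negative_growth = gr$negative_growth,
    A = A, B = B,
    ratio_A_P = N_A / N_P, ratio_N_P = N_N / N_P,
    ratio_G0_P = N_G0 / N_P, ratio_S_L = N_S / N_L,
    SF = N_S / living, LF = N_L / living, DF = N_D / living,
    GF = N_P / living, QF = N_G0 / living,
    AF = N_A / total, NF = N_N / total,
    SLF = (N_S / living) / (N_L / living), SDF = N_S / N_D,
    living_of_total = living / total
  ), class = "growth_solution")
}

#' @export
print.growth_solution <- function(x, ...) {
  cat(sprintf("<growth_solution> a = %.6g /h (T_d = %.4g d%s)\n", x$a, x$T_d,
              if (x$negative_growth) ", shrinking" else ""))
  cat(sprintf("  living: SF %.3g | LF %.3g | DIFF %.3g | GF %.3g | QF %.3g\n",
              x$SF, x$LF, x$DF, x$GF, x$QF))
  cat(sprintf("  total:  AF %.3g | NF %.3g\n", x$AF, x$NF))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.growth_solution <- function(x, ...) {
  tibble::tibble(
    quantity = c("SF", "LF", "DF", "GF", "QF", "AF", "NF", "SLF", "SDF"),
    value = c(x$SF, x$LF, x$DF, x$GF, x$QF, x$AF, x$NF, x$SLF, x$SDF),
    denominator = c(rep("living", 5), "total", "total", "LIMP", "DIFF")
  )
}

#' @export
glance.growth_solution <- function(x, ...) {
  tibble::tibble(a = x$a, T_d = x$T_d, negative_growth = x$negative_growth)
}

unreachable <- function(stage, msg) {
  cond <- structure(
    class = c("ckrsim_unreachable_profile", "error", "condition"),
    list(message = paste0("profile unreachable at ", stage, ": ", msg),
         call = NULL, stage = stage)
  )
  stop(cond)
}

#' Closed-form calibration of the dependent parameters
#'
#' Given a target proliferation profile and values for the independent
#' parameters, these functions invert the balanced-growth relations for the
#' dependent parameters, in order: `calibrate_p_sleep()` (from `T_d`),
#' `calibrate_r_ndiff()` (from `GF`), `calibrate_t_a()` (from `AF`),
#' `calibrate_t_n()` (from `NF`) and `solve_n_limp()` (from `SF`).
#' Stem and LIMP kinetics are assumed identical here, as in the baseline
#' workflow. An unreachable target (e.g. `P_sleep` outside \[0, 1\] or a
#' negative transition rate) raises a classed condition
#' `ckrsim_unreachable_profile`; [calibrate_full()] converts it to a
#' structured failure object usable as a filter predicate.
#'
#' All values are returned at full precision. For reporting, durations are
#' conventionally rounded *up* to whole hours ([round_duration()]) — a
#' clearance pool in an hourly simulator must persist at least the computed
#' time — while `N_LIMP` is rounded to the nearest integer.
#'
#' @param profile A [proliferation_profile()].
#' @param independents Named list with `T_C`, `T_G0`, `R_A`, `R_ADiff`,
#'   `P_G0toG1`, `P_sym` (additionally `R_NDiff`/`P_sleep` are read when
#'   already calibrated; see `calibrate_full()` for the one-shot interface).
#' @return The calibrated scalar (`calibrate_*`, `solve_n_limp`), or a full
#'   `kinetic_params` ([calibrate_full()]).
#' @examples
#' calibrate_p_sleep(subtype_profile("SCC"), subtype_independents("SCC")) # 0.27960
#' @export
calibrate_p_sleep <- function(profile, independents) {
  ind <- independents
  a <- log(2) / (profile$T_d * 24)
  x <- a + ind$R_A
  num <- 1 - exp(x * ind$T_C) / (1 + ind$P_sym)
  den <- 1 - (ind$P_G0toG1 / ind$T_G0) / (x + 1 / ind$T_G0)
  ps <- num / den
  if (!is.finite(ps) || ps < 0 || ps > 1) {
    unreachable("P_sleep", sprintf("required P_sleep = %.4g outside [0, 1]", ps))
  }
  ps
}

# equal-kinetics intermediates (mitosis flux per cycling cell; G0/cycling ratio)
calib_ab <- function(a, ind, p_sleep) {
  x <- a + ind$R_A
  list(A = x / expm1(x * ind$T_C),
       B = (1 + ind$P_sym) * p_sleep / (x + 1 / ind$T_G0))
}

#' @rdname calibrate_p_sleep
#' @export
calibrate_r_ndiff <- function(profile, independents) {
  ind <- independents
  if (profile$GF <= 0 || profile$GF >= 1) {
    unreachable("R_NDiff", "GF must lie in (0, 1)")
  }
  a <- log(2) / (profile$T_d * 24)
  ps <- if (!is.null(ind$P_sleep)) ind$P_sleep else calibrate_p_sleep(profile, ind)
  ab <- calib_ab(a, ind, ps)
  denom <- (1 / ab$A) * (1 / profile$GF - 1) - ab$B
  rnd <- (1 - ind$P_sym) / denom - a - ind$R_ADiff
  if (!is.finite(rnd) || rnd < 0 || denom <= 0) {
    unreachable("R_NDiff", sprintf("required R_NDiff = %.4g negative", rnd))
  }
  rnd
}

#' @rdname calibrate_p_sleep
#' @export
calibrate_t_a <- function(profile, independents) {
  ind <- complete_dependents(profile, independents, upto = "R_NDiff")
  a <- log(2) / (profile$T_d * 24)
  if (profile$AF == 0) return(0)
  ab <- calib_ab(a, ind, ind$P_sleep)
  ratio_a_p <- (profile$AF / profile$GF) / (1 - profile$AF - profile$NF)  # N_A/N_P
  nd_p <- (1 - ind$P_sym) * ab$A / (a + ind$R_ADiff + ind$R_NDiff)        # N_DIFF/N_P
  inflow <- ind$R_A * (1 + ab$A * ab$B) + ind$R_ADiff * nd_p              # per N_P
  ta <- 1 / (inflow / ratio_a_p - a)
  if (!is.finite(ta) || ta <= 0) {
    unreachable("T_A", sprintf("required T_A = %.4g not positive", ta))
  }
  ta
}

#' @rdname calibrate_p_sleep
#' @export
calibrate_t_n <- function(profile, independents) {
  ind <- complete_dependents(profile, independents, upto = "R_NDiff")
  a <- log(2) / (profile$T_d * 24)
  if (profile$NF == 0) return(0)
  ab <- calib_ab(a, ind, ind$P_sleep)
  ratio_n_p <- (profile$NF / profile$GF) / (1 - profile$AF - profile$NF)  # N_N/N_P
  nd_p <- (1 - ind$P_sym) * ab$A / (a + ind$R_ADiff + ind$R_NDiff)
  inflow <- (1 - ind$P_G0toG1) / ind$T_G0 * ab$A * ab$B + ind$R_NDiff * nd_p
  tn <- 1 / (inflow / ratio_n_p - a)
  if (!is.finite(tn) || tn <= 0) {
    unreachable("T_N", sprintf("required T_N = %.4g not positive", tn))
  }
  tn
}

#' @rdname calibrate_p_sleep
#' @export
solve_n_limp <- function(profile, independents) {
  ind <- complete_dependents(profile, independents, upto = "P_sleep")
  if (profile$SF >= profile$GF) unreachable("N_LIMP", "SF must be below GF")
  a <- log(2) / (profile$T_d * 24)
  ab <- calib_ab(a, ind, ind$P_sleep)
  # N_S/N_L from SF: stem + LIMP population is (1 + N_G0/N_P) N_P of living
  nsnl <- profile$SF / ((1 + ab$A * ab$B) * profile$GF - profile$SF)
  if (nsnl <= 0) unreachable("N_LIMP", "stem-to-LIMP ratio not positive")
  # sum_{n=0}^{N-1} 2^n/(1+P_sym)^(n+1) = 1/((1-P_sym) N_S/N_L); geometric in
  # r = 2/(1+P_sym), so r^N = 1 + (r-1)(1+P_sym)/((1-P_sym) N_S/N_L)
  r <- 2 / (1 + ind$P_sym)
  rhs <- 1 / ((1 - ind$P_sym) * nsnl)
  n_cont <- if (abs(r - 1) < 1e-12) 2 * rhs else
    log(1 + rhs * (1 + ind$P_sym) * (r - 1)) / log(r)
  n <- as.integer(round(n_cont))
  if (n < 1L) unreachable("N_LIMP", sprintf("continuous solution %.3g below 1", n_cont))
  attr(n, "continuous") <- n_cont
  n
}

# run the calibration chain up to a given stage, filling `independents`
complete_dependents <- function(profile, independents, upto) {
  ind <- independents
  if (is.null(ind$P_sleep)) ind$P_sleep <- calibrate_p_sleep(profile, ind)
  if (upto == "P_sleep") return(ind)
  if (is.null(ind$R_NDiff)) ind$R_NDiff <- calibrate_r_ndiff(profile, ind)
  ind
}

#' Calibrate a complete parameter set against a profile
#'
#' Runs the full calibration chain. In the baseline workflow (`N_LIMP`
#' absent from `independents`) five dependents are solved: `P_sleep`,
#' `R_NDiff`, `T_A`, `T_N` and `N_LIMP`. In the sampling workflow
#' (`N_LIMP` and `CKF_stem` supplied) only the first four are solved and
#' `SF` is left to downstream filters.
#'
#' @inheritParams calibrate_p_sleep
#' @param on_failure `"error"` re-raises the `ckrsim_unreachable_profile`
#'   condition; `"object"` (default) returns a structured failure of class
#'   `calibration_failure` with the offending stage and message.
#' @return A `kinetic_params` object, or a `calibration_failure`.
#' @seealso [is_calibration_failure()]
#' @examples
#' p <- calibrate_full(subtype_profile("ADC"), subtype_independents("ADC"))
#' p$N_LIMP  # 18
#' @export
calibrate_full <- function(profile, independents, on_failure = c("object", "error")) {
  on_failure <- match.arg(on_failure)
  ind <- independents
  run <- function() {
    ind$P_sleep <- calibrate_p_sleep(profile, ind)
    ind$R_NDiff <- calibrate_r_ndiff(profile, ind)
    t_a <- calibrate_t_a(profile, ind)
    t_n <- calibrate_t_n(profile, ind)
    n_limp <- if (is.null(ind$N_LIMP)) solve_n_limp(profile, ind) else ind$N_LIMP
    kinetic_params(
      T_C = ind$T_C, T_G0 = ind$T_G0,
      T_A = max(t_a, 1e-9), T_N = max(t_n, 1e-9),
      R_A = ind$R_A, R_ADiff = ind$R_ADiff, R_NDiff = ind$R_NDiff,
      P_G0toG1 = ind$P_G0toG1, P_sym = ind$P_sym, P_sleep = ind$P_sleep,
      N_LIMP = n_limp,
      CKF_stem = if (is.null(ind$CKF_stem)) 1 else ind$CKF_stem
    )
  }
  if (on_failure == "error") return(run())
  tryCatch(run(), ckrsim_unreachable_profile = function(e) {
    structure(list(stage = e$stage, message = conditionMessage(e)),
              class = "calibration_failure")
  })
}

#' @rdname calibrate_full
#' @param x Object to test.
#' @export
is_calibration_failure <- function(x) inherits(x, "calibration_failure")

#' @export
print.calibration_failure <- function(x, ...) {
  cat("<calibration_failure>", x$message, "\n")
  invisible(x)
}

#' Reporting rounding conventions
#'
#' Dead-cell clearance times are reported rounded up to whole hours (the pool
#' must persist at least the computed time in an hourly simulator); `N_LIMP`
#' is rounded to the nearest integer by [solve_n_limp()] itself. Round-trip
#' invariants always use the unrounded values.
#'
#' @param x Duration in hours.
#' @return Integer hours.
#' @export
round_duration <- function(x) as.integer(ceiling(x - 1e-9))
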