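# Sensitivity machinery: one-factor-at-a-time elasticities, Latin hypercube
# sampling with biological filters, and partial rank correlation coefficients.

#' Latin hypercube sample over parameter ranges
#'
#' Stratified uniform sampling: for each parameter, exactly one draw falls in
#' each of `n` equal-probability strata of \[0, 1\]; draws are then rescaled
#' to `[min, max]` and integer parameters rounded to the nearest integer.
#'
#' @param ranges Tibble with columns `parameter`, `min`, `max`, `integer`
#'   (see [parameter_ranges()]).
#' @param n Sample size (>= 2).
#' @param seed RNG seed; the same `(ranges, n, seed)` always yields the same
#'   sample.
#' @return Tibble with `n` rows, one column per parameter.
#' @examples
#' lhs_sample(parameter_ranges("clinical"), n = 10, seed = 1)
#' @export
lhs_sample <- function(ranges, n, seed) {
  if (n < 2) stop("lhs_sample: n must be >= 2", call. = FALSE)
  withr::with_seed(seed, {
    cols <- purrr::pmap(ranges, function(parameter, min, max, integer, ...) {
      x <- (sample.int(n) - stats::runif(n)) / n
      v <- min + (max - min) * x
      if (integer) round(v) else v
    })
  })
  names(cols) <- ranges$parameter
  tibble::as_tibble(cols)
}

sample_row_params <- function(row) {
  kinetic_params(
    T_C_stem = row$T_C_stem, T_C_limp = row$T_C_limp,
    T_G0_stem = row$T_G0_stem, T_G0_limp = row$T_G0_limp,
    T_A = row$T_A, T_N = row$T_N,
    R_A = row$R_A, R_ADiff = row$R_ADiff, R_NDiff = row$R_NDiff,
    P_G0toG1_stem = row$P_G0toG1_stem, P_G0toG1_limp = row$P_G0toG1_limp,
    P_sym = row$P_sym, P_sleep = row$P_sleep,
    N_LIMP = row$N_LIMP, CKF_stem = row$CKF_stem
  )
}

#' Biological relevance filters for sampled parameter sets
#'
#' Evaluates per-row exclusion rules on a sample of full parameter sets and
#' returns a keep mask with reason codes. Two presets exist:
#'
#' * `"sensitivity"`: positive growth rate, doubling time >= 26 days, and
#'   stem-cell fraction of living cells <= 1 per mille.
#' * `"clinical"`: additionally to non-negative calibrated transition
#'   parameters (`P_sleep`, `R_NDiff`), the doubling time must lie within
#'   10% of the subtype target, SF <= 1e-3, `T_A` <= 24 h, `T_N` <= 200 h
#'   and `R_NDiff` <= 0.02 per hour.
#'
#' @param sample Tibble of full parameter columns (one row per set); rows
#'   where calibration failed may carry `NA` dependents plus a
#'   `calib_failure` column, which is reported as the exclusion reason.
#' @param preset `"sensitivity"` or `"clinical"`.
#' @param profile Subtype [proliferation_profile()]; required for the
#'   `"clinical"` preset (supplies the T_d target).
#' @return Tibble `(row, keep, reason, T_d, SF)`; `reason` is `NA` for kept
#'   rows. Exclusion counts are attached as attribute `counts`.
#' @export
apply_filters <- function(sample, preset = c("sensitivity", "clinical"),
                          profile = NULL) {
  preset <- match.arg(preset)
  if (preset == "clinical" && is.null(profile)) {
    stop("the clinical preset needs the subtype profile", call. = FALSE)
  }
  n <- nrow(sample)
  out <- purrr::map_dfr(seq_len(n), function(i) {
    rw <- sample[i, ]
    if ("calib_failure" %in% names(rw) && !is.na(rw$calib_failure)) {
      return(tibble::tibble(row = i, keep = FALSE, reason = rw$calib_failure,
                            T_d = NA_real_, SF = NA_real_))
    }
    comp <- tryCatch(balanced_composition(sample_row_params(rw)),
                     error = function(e) NULL)
    if (is.null(comp)) {
      return(tibble::tibble(row = i, keep = FALSE,
                            reason = "composition undefined",
                            T_d = NA_real_, SF = NA_real_))
    }
    reason <- NA_character_
    if (comp$negative_growth) {
      reason <- "negative growth"
    } else if (preset == "sensitivity" && comp$T_d < 26) {
      reason <- "T_d below 26 d"
    } else if (preset == "clinical" &&
               abs(comp$T_d - profile$T_d) > 0.1 * profile$T_d) {
      reason <- "T_d beyond +/-10% of target"
    } else if (comp$SF > 1e-3) {
      reason <- "stem fraction above 1 per mille"
    } else if (preset == "clinical" && rw$T_A > 24) {
      reason <- "T_A above 24 h"
    } else if (preset == "clinical" && rw$T_N > 200) {
      reason <- "T_N above 200 h"
    } else if (preset == "clinical" && rw$R_NDiff > 0.02) {
      reason <- "R_NDiff above 0.02 per h"
    }
    tibble::tibble(row = i, keep = is.na(reason), reason = reason,
                   T_d = comp$T_d, SF = comp$SF)
  })
  counts <- dplyr::count(dplyr::filter(out, !.data$keep), .data$reason)
  structure(out, counts = counts)
}

#' Proliferation features of a parameter set
#'
#' The macroscopic features of the balanced-growth tumor at diagnosis:
#' doubling time and population constitution. Thin wrapper over
#' [balanced_composition()] used as the input space of the second PRCC study.
#'
#' @param params A [kinetic_params()] object.
#' @return One-row tibble `(T_d, SF, LF, GF, QF, AF, NF, SLF, SDF)`.
#' @export
proliferation_features <- function(params) {
  b <- balanced_composition(params)
  tibble::tibble(T_d = b$T_d, SF = b$SF, LF = b$LF, GF = b$GF, QF = b$QF,
                 AF = b$AF, NF = b$NF, SLF = b$SLF, SDF = b$SDF)
}

#' Partial rank correlation coefficients
#'
#' Replaces all columns by their ranks (ties get average ranks) and computes,
#' for each input, the partial correlation with the output controlling for
#' all remaining inputs, via the precision matrix of the rank correlation
#' matrix. Two-sided p-values use a t distribution with
#' `n - 2 - (p - 1)` degrees of freedom (`p` inputs); coefficients with
#' `p < 0.01` are flagged significant.
#'
#' @param inputs Data frame or matrix of inputs (n x p).
#' @param output Numeric vector of length n.
#' @return Tibble `(parameter, prcc, p_value, significant)`.
#' @export
prcc <- function(inputs, output) {
  X <- as.matrix(inputs)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(output) == n)
  if (n <= p + 2) stop("prcc: need n > p + 2 observations", call. = FALSE)
  R <- apply(cbind(X, .y = output), 2, rank, ties.method = "average")
  C <- stats::cor(R)
  # collinear inputs make the control set rank deficient; name them
  cc <- abs(C[seq_len(p), seq_len(p), drop = FALSE]); diag(cc) <- 0
  if (any(cc > 1 - 1e-10)) {
    bad <- colnames(X)[apply(cc > 1 - 1e-10, 2, any)]
    stop("prcc: rank-deficient control set; collinear columns: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  k <- p + 1L
  P <- tryCatch(solve(C), error = function(e) NULL)
  if (!is.null(P)) {
    pr <- -P[seq_len(p), k] / sqrt(diag(P)[seq_len(p)] * P[k, k])
  } else {
    # the correlation matrix is singular because some input determines the
    # output exactly in rank space; fall back to the residual-regression
    # definition, which remains well defined input by input
    Rd <- as.data.frame(R)
    names(Rd) <- c(colnames(X), ".y")
    pr <- vapply(seq_len(p), function(j) {
      ctrl <- colnames(X)[-j]
      r1 <- stats::resid(stats::lm(stats::reformulate(ctrl, colnames(X)[j]),
                                   data = Rd))
      r2 <- stats::resid(stats::lm(stats::reformulate(ctrl, ".y"), data = Rd))
      if (stats::sd(r1) < 1e-12 || stats::sd(r2) < 1e-12) return(0)
      max(-1, min(1, stats::cor(r1, r2)))
    }, numeric(1))
  }
  df <- n - 2 - (p - 1)
  tstat <- pr * sqrt(df / pmax(1 - pr^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  tibble::tibble(parameter = colnames(X), prcc = unname(pr),
                 p_value = unname(pval), significant = pval < 0.01)
}

#' One-factor-at-a-time sensitivity measures
#'
#' Perturbs one parameter by `+delta` and `-delta` (fractions of its baseline
#' value) and expresses the relative output change per 1% input change:
#' `SM = ((CKR_perturbed - CKR_base)/CKR_base) / ((p_perturbed - p_base)/p_base)`.
#' Integer parameters are rounded after perturbation and the actually applied
#' change enters the denominator.
#'
#' @param evaluate Function mapping a [kinetic_params()] object to the output
#'   measure (typically the CKR_sum matching a target shrinkage).
#' @param baseline Baseline [kinetic_params()].
#' @param which Parameter name to perturb.
#' @param delta Relative perturbation; 0.10 by default, conventionally 0.05
#'   for the strongly acting fractions `P_sym` and `P_sleep`.
#' @param integer Round the perturbed value to the nearest integer.
#' @param ckr_base Optional precomputed baseline output (saves one
#'   evaluation when scanning many parameters).
#' @return Tibble `(parameter, sm_plus, sm_minus, delta, failed)`; a failed
#'   evaluation at a perturbed point yields `NA` measures with `failed = TRUE`.
#' @export
ofat_measures <- function(evaluate, baseline, which,
                          delta = if (which %in% c("P_sym", "P_sleep")) 0.05 else 0.10,
                          integer = which == "N_LIMP", ckr_base = NULL) {
  p0 <- baseline[[which]]
  if (is.null(p0)) stop("unknown parameter: ", which, call. = FALSE)
  if (is.null(ckr_base)) ckr_base <- evaluate(baseline)
  one_side <- function(sgn) {
    p1 <- p0 * (1 + sgn * delta)
    if (integer) p1 <- round(p1)
    if (p1 == p0) return(list(sm = 0, ok = TRUE))
    mod <- unclass(baseline)
    mod[[which]] <- p1
    mod <- structure(mod, class = "kinetic_params")
    val <- tryCatch(evaluate(mod), error = function(e) NA_real_)
    if (is.na(val)) return(list(sm = NA_real_, ok = FALSE))
    list(sm = ((val - ckr_base) / ckr_base) / ((p1 - p0) / p0), ok = TRUE)
  }
  up <- one_side(1); dn <- one_side(-1)
  tibble::tibble(parameter = which, sm_plus = up$sm, sm_minus = dn$sm,
                 delta = delta, failed = !(up$ok && dn$ok))
}

#' Variability-weighted OFAT sensitivity score
#'
#' `SC = |(SM_plus - SM_minus)/2| * (range / mean)`, the average elasticity
#' weighted by the normalized parameter variability; the mean is taken under
#' a uniform distribution over the range.
#'
#' @param sm_plus,sm_minus Sensitivity measures from [ofat_measures()].
#' @param min,max Parameter value range.
#' @return The score (scalar).
#' @export
ofat_score <- function(sm_plus, sm_minus, min, max) {
  m <- (min + max) / 2
  if (m == 0) stop("ofat_score: zero mean over the range", call. = FALSE)
  abs((sm_plus - sm_minus) / 2) * ((max - min) / m)
}

#' Full OFAT scan of a baseline
#'
#' Runs [ofat_measures()] for every parameter in `ranges` and attaches the
#' variability-weighted score.
#'
#' @inheritParams ofat_measures
#' @param ranges Tibble as from [parameter_ranges()]; also supplies the
#'   range/mean variability weights.
#' @return Tibble `(parameter, sm_plus, sm_minus, delta, failed, sc)`.
#' @export
ofat_analysis <- function(evaluate, baseline,
                          ranges = parameter_ranges("sensitivity")) {
  ckr_base <- evaluate(baseline)
  purrr::pmap_dfr(ranges, function(parameter, min, max, integer, ...) {
    m <- ofat_measures(evaluate, baseline, parameter, integer = integer,
                       ckr_base = ckr_base)
    m$sc <- if (m$failed) NA_real_ else
      ofat_score(m$sm_plus, m$sm_minus, min, max)
    m
  })
}

# ---- the reference shrinkage scenario -------------------------------------

#' The virtual-tumor shrinkage scenario of the sensitivity analyses
#'
#' A macroscopically homogeneous spherical tumor of 925 mm^3 grows freely for
#' one week, then receives three 3-week cisplatin + gemcitabine cycles
#' (gemcitabine on cycle days 1 and 8, cisplatin on day 1) and must have
#' shrunk 72% (to 258 mm^3) by simulation day 49. Encoded as a
#' [clinical_case()] whose observed reduction is exactly 72%.
#'
#' @param ckr_b Assumed gemcitabine kill rate.
#' @return A `clinical_case`.
#' @export
sensitivity_scenario <- function(ckr_b = 0.2) {
  clinical_case(
    case_id = "ofat-72pct", histology = "SCC",
    V0 = 925, V1 = 925 * (1 - 0.72),
    interval_cts = 49, interval_ct1_onset = 7,
    schedule = tibble::tibble(
      day = c(1, 1, 8, 22, 22, 29, 43, 43, 50),
      drug = c("cisplatin", "gemcitabine", "gemcitabine",
               "cisplatin", "gemcitabine", "gemcitabine",
               "cisplatin", "gemcitabine", "gemcitabine")),
    ckr_b = ckr_b
  )
}

#' CKR_sum matching the reference scenario for one parameter set
#'
#' Root-solves the cisplatin CKR so that the [sensitivity_scenario()] tumor
#' shows the target 72% shrinkage, and returns `CKR_cis + CKR_B`. This is
#' the output measure of the OFAT and LHS/PRCC sensitivity analyses.
#'
#' @param params A [kinetic_params()] object.
#' @param ckr_b Gemcitabine kill rate.
#' @param tol Root tolerance on CKR.
#' @return `CKR_sum` (scalar); raises `ckrsim_no_solution` when the target
#'   shrinkage is not reachable in \[0, 1\].
#' @export
scenario_ckr_sum <- function(params, ckr_b = 0.2, tol = 1e-5) {
  estimate_ckr_cis(sensitivity_scenario(ckr_b), params, tol = tol)$ckr_sum
}

#' LHS/PRCC sensitivity pipeline
#'
#' The sampling-based global sensitivity workflow: draw a Latin hypercube
#' sample of all model parameters, discard biologically non-relevant sets
#' (negative growth, doubling time < 26 d, stem fraction > 1 per mille),
#' estimate the `CKR_sum` matching the reference 72%-shrinkage scenario for
#' every survivor, and compute PRCCs of `CKR_sum` both against the model
#' parameters (first study) and against the proliferation features at
#' diagnosis `T_d, SF, LF, GF, QF, AF, NF` (second study).
#'
#' @param n LHS sample size.
#' @param seed RNG seed for the sample.
#' @param ckr_b Gemcitabine kill rate (fixed).
#' @param tol Root tolerance on CKR.
#' @param progress Print progress every 50 sets.
#' @return List with the sample, the filter mask, the per-survivor results
#'   (features + `ckr_sum`), and the two PRCC tables (`prcc_params`,
#'   `prcc_features`).
#' @export
lhs_prcc_analysis <- function(n, seed, ckr_b = 0.2, tol = 1e-5,
                              progress = FALSE) {
  ranges <- parameter_ranges("sensitivity")
  smp <- lhs_sample(ranges, n, seed)
  mask <- apply_filters(smp, "sensitivity")
  keep <- which(mask$keep)
  results <- purrr::map_dfr(seq_along(keep), function(j) {
    i <- keep[j]
    if (progress && j %% 50 == 0) message("  set ", j, "/", length(keep))
    p <- sample_row_params(smp[i, ])
    ck <- tryCatch(scenario_ckr_sum(p, ckr_b, tol),
                   ckrsim_no_solution = function(e) NA_real_)
    dplyr::bind_cols(tibble::tibble(row = i, ckr_sum = ck),
                     proliferation_features(p))
  })
  ok <- results[!is.na(results$ckr_sum), ]
  maybe_prcc <- function(X) {
    if (nrow(ok) > ncol(X) + 2) prcc(X, ok$ckr_sum) else {
      message("lhs_prcc_analysis: only ", nrow(ok),
              " estimable survivors; need > ", ncol(X) + 2,
              " for this PRCC study - skipped (increase n)")
      NULL
    }
  }
  prcc_params <- maybe_prcc(smp[ok$row, ranges$parameter])
  prcc_features <- maybe_prcc(ok[, c("T_d", "SF", "LF", "GF", "QF", "AF", "NF")])
  list(sample = smp, mask = mask, results = results,
       n_survivors = length(keep), n_estimated = nrow(ok),
       prcc_params = prcc_params, prcc_features = prcc_features)
}
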