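# Estimation of the cisplatin cell kill rate from two-time-point volumetry.
#
# The observable is the relative volume change between two CT acquisitions.
# With the kinetic parameters and the second drug's kill rate (CKR_B) fixed,
# the simulated reduction is a strictly increasing function of the cisplatin
# CKR, so the value matching the observed reduction is found by bracketed
# root finding on [0, 1]. Only relative volumes enter, so estimates are
# invariant to cell_density and to the (unknown) absolute tumor burden.

#' Relative volume reduction between two scans
#'
#' @param V0,V1 Tumor volume at the first / second CT, any common unit.
#' @return Reduction as percent of initial volume, `100 (V0 - V1) / V0`;
#'   negative for a growing tumor.
#' @examples
#' relative_reduction(100264, 46776)   # 53.35 (clinical case 1)
#' relative_reduction(123016, 131160)  # -6.62 (case 9, progression)
#' @export
relative_reduction <- function(V0, V1) {
  stopifnot(all(V0 > 0))
  100 * (V0 - V1) / V0
}

#' Construct a clinical case record
#'
#' Two-time-point volumetry with the administration schedule given between
#' the scans. Day 1 of `schedule` is treatment onset; the simulator clock is
#' anchored at whichever of the first CT and treatment onset comes first
#' (onset may precede the first CT, as in clinical case 7).
#'
#' @param case_id Identifier.
#' @param histology `"ADC"` or `"SCC"`.
#' @param V0,V1 Volume at first / second CT, mm^3.
#' @param interval_cts Days between the CT acquisitions.
#' @param interval_ct1_onset Days from first CT to treatment onset (may be
#'   negative).
#' @param schedule Data frame `(day, drug)` of administrations between the
#'   two CTs.
#' @param ckr_b Assumed cell kill rate of the second (non-cisplatin) drug.
#' @param interval_ct2_surgery Optional days from second CT to surgery.
#' @param resection_cm Optional numeric length-3 vector: the three mutually
#'   perpendicular dimensions of the resected tumor, cm.
#' @param extra_schedule Optional data frame `(day, drug)` of administrations
#'   between the second CT and surgery.
#' @return An object of class `clinical_case`.
#' @export
clinical_case <- function(case_id, histology, V0, V1, interval_cts,
                          interval_ct1_onset, schedule, ckr_b = 0.2,
                          interval_ct2_surgery = NA_real_,
                          resection_cm = NULL, extra_schedule = NULL) {
  stopifnot(V0 > 0, V1 > 0, nrow(schedule) > 0)
  histology <- match.arg(toupper(histology), c("ADC", "SCC"))
  structure(list(
    case_id = case_id, histology = histology, V0 = V0, V1 = V1,
    interval_cts = interval_cts, interval_ct1_onset = interval_ct1_onset,
    schedule = tibble::as_tibble(schedule), ckr_b = ckr_b,
    interval_ct2_surgery = interval_ct2_surgery,
    resection_cm = resection_cm,
    extra_schedule = if (is.null(extra_schedule)) NULL
                     else tibble::as_tibble(extra_schedule)
  ), class = "clinical_case")
}

#' @export
print.clinical_case <- function(x, ...) {
  cat(sprintf("<clinical_case %s> %s, V: %g -> %g mm^3 (%.2f%%) over %g d\n",
              x$case_id, x$histology, x$V0, x$V1,
              relative_reduction(x$V0, x$V1), x$interval_cts))
  invisible(x)
}

# schedule with cisplatin at ckr_cis and every other drug at ckr_b
doublet_schedule <- function(days_tbl, ckr_cis, ckr_b, onset_h = 0) {
  ckr <- ifelse(tolower(days_tbl$drug) == "cisplatin", ckr_cis, ckr_b)
  treatment_schedule(days_tbl$day, days_tbl$drug, ckr, onset_h = onset_h)
}

# simulated relative reduction (%) between the two CTs of a case
case_reduction <- function(params, case, ckr_cis, ckr_b = case$ckr_b,
                           initial_volume = 1000) {
  onset_h <- case$interval_ct1_onset * 24
  s0 <- min(0, onset_h)
  ct1 <- -s0
  ct2 <- case$interval_cts * 24 - s0
  sched <- doublet_schedule(case$schedule, ckr_cis, ckr_b, onset_h - s0)
  sched <- sched[sched$time_h <= ct2, , drop = FALSE]
  tr <- simulate_tumor(params, initial_volume, duration_days = ct2 / 24,
                       schedule = sched)
  v1 <- tr$volume_mm3[match(ct1, tr$time_h)]
  v2 <- tr$volume_mm3[nrow(tr)]
  100 * (v1 - v2) / v1
}

no_solution <- function(side, f0, f1) {
  msg <- if (side == "low") {
    sprintf("no solution in [0, 1]: tumor shrinks too much even at CKR 0 (residual %+.3f pp)", f0)
  } else {
    sprintf("no solution in [0, 1]: tumor cannot shrink enough even at CKR 1 (residual %+.3f pp)", f1)
  }
  cond <- structure(
    class = c("ckrsim_no_solution", "error", "condition"),
    list(message = msg, call = NULL, side = side, f0 = f0, f1 = f1))
  stop(cond)
}

#' Estimate the cisplatin cell kill rate of a clinical case
#'
#' Root-solves the cisplatin CKR in \[0, 1\] so that the simulated relative
#' volume reduction at the second CT equals the observed one, with the
#' second drug's CKR held at `ckr_b` and all kinetic parameters fixed.
#'
#' @param case A [clinical_case()].
#' @param params A [kinetic_params()] object.
#' @param ckr_b Second-drug kill rate; defaults to the case's value.
#' @param target_reduction Observed reduction to match, percent of initial
#'   volume; defaults to the case's volumetry.
#' @param tol Convergence tolerance on CKR.
#' @return List with `ckr_cis`, `ckr_sum`, `achieved_reduction` (%) and
#'   `converged`. If no root exists in \[0, 1\] a classed error
#'   `ckrsim_no_solution` is raised whose `side` field distinguishes a tumor
#'   that shrinks too much even at CKR 0 from one that cannot shrink enough
#'   at CKR 1.
#' @export
estimate_ckr_cis <- function(case, params, ckr_b = case$ckr_b,
                             target_reduction = relative_reduction(case$V0, case$V1),
                             tol = 1e-6) {
  f <- function(x) case_reduction(params, case, x, ckr_b) - target_reduction
  f0 <- f(0)
  if (f0 >= 0) {
    if (f0 <= 1e-4) {
      return(list(ckr_cis = 0, ckr_sum = ckr_b * has_second_drug(case),
                  achieved_reduction = target_reduction + f0, converged = TRUE))
    }
    no_solution("low", f0, NA_real_)
  }
  f1 <- f(1)
  if (f1 < 0) no_solution("high", f0, f1)
  root <- stats::uniroot(f, c(0, 1), f.lower = f0, f.upper = f1, tol = tol)
  list(ckr_cis = root$root,
       ckr_sum = root$root + ckr_b * has_second_drug(case),
       achieved_reduction = target_reduction + root$f.root,
       converged = TRUE)
}

# CKR_sum adds CKR_B once when the regimen contains a non-cisplatin partner
has_second_drug <- function(case) {
  as.numeric(any(tolower(case$schedule$drug) != "cisplatin"))
}

#' Estimate the CKR distribution over a parameter-set sample
#'
#' Runs [estimate_ckr_cis()] for each kinetic parameter set of a sample
#' (typically a subtype-constrained Latin hypercube sample) and summarizes
#' the distribution of `CKR_sum`. Sets without a solution are recorded, not
#' dropped silently.
#'
#' @param case A [clinical_case()].
#' @param parameter_sets List of [kinetic_params()] objects.
#' @param ckr_b Second-drug kill rate (defaults to the case's value).
#' @param tol Root-finding tolerance on CKR.
#' @return Object of class `ckr_distribution`: tibble of per-set estimates
#'   (`tidy()`) with aggregate percentiles (`glance()`: median, p10, p90,
#'   min, max of `CKR_sum` over converged sets).
#' @export
estimate_ckr_distribution <- function(case, parameter_sets, ckr_b = case$ckr_b,
                                      tol = 1e-6) {
  if (length(parameter_sets) == 0L) {
    stop("estimate_ckr_distribution: empty parameter-set sample", call. = FALSE)
  }
  per_set <- purrr::imap_dfr(parameter_sets, function(p, i) {
    res <- tryCatch(
      estimate_ckr_cis(case, p, ckr_b = ckr_b, tol = tol),
      ckrsim_no_solution = function(e) {
        list(ckr_cis = NA_real_, ckr_sum = NA_real_,
             achieved_reduction = NA_real_, converged = FALSE,
             failure = conditionMessage(e))
      })
    tibble::tibble(
      set = i, ckr_cis = res$ckr_cis, ckr_sum = res$ckr_sum,
      achieved_reduction = res$achieved_reduction, converged = res$converged,
      failure = if (is.null(res$failure)) NA_character_ else res$failure
    )
  })
  ok <- per_set$ckr_sum[per_set$converged]
  summary <- tibble::tibble(
    case_id = case$case_id, n_sets = length(parameter_sets),
    n_converged = length(ok),
    median = stats::median(ok),
    p10 = unname(stats::quantile(ok, 0.10)),
    p90 = unname(stats::quantile(ok, 0.90)),
    min = min(ok), max = max(ok)
  )
  structure(list(per_set = per_set, summary = summary, case = case),
            class = "ckr_distribution")
}

#' @export
print.ckr_distribution <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<ckr_distribution> case %s: CKR_sum median %.3f [p10 %.3f, p90 %.3f] (%d/%d sets)\n",
    s$case_id, s$median, s$p10, s$p90, s$n_converged, s$n_sets))
  invisible(x)
}

#' @export
tidy.ckr_distribution <- function(x, ...) x$per_set

#' @export
glance.ckr_distribution <- function(x, ...) x$summary
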