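# The bundled 13-case NSCLC dataset and the clinical estimation pipeline.
#
# The fixture tables under inst/extdata mirror the published clinical data:
# two-time-point CT volumetry with the administrations given between the
# scans (day 1 = treatment onset), plus the triaxial dimensions of the
# resected specimen and any administrations between the second CT and
# surgery for the 12 operated cases (case 12 has no resection record).

#' The bundled NSCLC clinical dataset
#'
#' Thirteen patients with newly diagnosed NSCLC (9 SCC, 4 ADC) treated
#' preoperatively with a cisplatin doublet (gemcitabine, vinorelbine or
#' docetaxel as partner). `nsclc_case_table()` and `nsclc_schedule_table()`
#' return the raw tables; `nsclc_cases()` assembles [clinical_case()]
#' objects. The assumed partner-drug kill rate `ckr_b` is 0.2, except 0.1
#' for case 9 (the only progressing tumor), chosen so that a cisplatin CKR
#' solution exists for all sampled parameter sets.
#'
#' @return `nsclc_cases()`: a tibble with one row per case and the
#'   `clinical_case` objects in list column `case`.
#' @examples
#' cases <- nsclc_cases()
#' cases$case[[1]]
#' @export
nsclc_cases <- function() {
  tab <- nsclc_case_table()
  sch <- nsclc_schedule_table()
  cases <- purrr::pmap(tab, function(case_id, histology, volume_ct1_mm3,
                                     volume_ct2_mm3, reduction_pct,
                                     interval_cts_d, interval_ct1_onset_d,
                                     ckr_b, interval_ct2_surgery_d,
                                     resect_a_cm, resect_b_cm, resect_c_cm) {
    s <- sch[sch$case_id == case_id, ]
    resection <- c(resect_a_cm, resect_b_cm, resect_c_cm)
    clinical_case(
      case_id = case_id, histology = histology,
      V0 = volume_ct1_mm3, V1 = volume_ct2_mm3,
      interval_cts = interval_cts_d,
      interval_ct1_onset = interval_ct1_onset_d,
      schedule = s[s$period == "between_cts", c("day", "drug")],
      ckr_b = ckr_b,
      interval_ct2_surgery = interval_ct2_surgery_d,
      resection_cm = if (all(is.finite(resection))) resection else NULL,
      extra_schedule = {
        e <- s[s$period == "ct2_to_surgery", c("day", "drug")]
        if (nrow(e)) e else NULL
      }
    )
  })
  dplyr::mutate(tab, case = cases)
}

#' @rdname nsclc_cases
#' @export
nsclc_case_table <- function() {
  readr::read_csv(system.file("extdata", "nsclc_cases.csv", package = "ckrsim"),
                  show_col_types = FALSE)
}

#' @rdname nsclc_cases
#' @export
nsclc_schedule_table <- function() {
  readr::read_csv(system.file("extdata", "nsclc_schedules.csv", package = "ckrsim"),
                  show_col_types = FALSE)
}

#' Triaxial ellipsoid volume of a resected tumor
#'
#' @param a,b,c The three mutually perpendicular maximum diameters, cm.
#' @return Volume in ml, `pi/6 a b c`.
#' @examples
#' ellipsoid_volume(6, 4.5, 3)  # 42.41 ml
#' @export
ellipsoid_volume <- function(a, b, c) {
  stopifnot(all(a > 0), all(b > 0), all(c > 0))
  pi / 6 * a * b * c
}

#' Equivalent spherical diameter of a tumor volume
#'
#' Diameter of the sphere with the same volume, `d = 2 (3V / 4 pi)^(1/3)`;
#' unit-consistent (ml in, cm out).
#'
#' @param V Volume (ml for cm output).
#' @return Equivalent diameter.
#' @examples
#' equivalent_diameter(42.41)  # 4.33 cm
#' @export
equivalent_diameter <- function(V) {
  stopifnot(all(V > 0))
  2 * (3 * V / (4 * pi))^(1 / 3)
}

#' Subtype-constrained Latin hypercube sample of parameter sets
#'
#' Draws the 8 independent parameters (T_C, T_G0, R_A, R_ADiff, P_G0toG1,
#' P_sym, N_LIMP, CKF of stem cells; stem and LIMP kinetics shared) by LHS
#' over their value ranges, calibrates the 4 dependent parameters (P_sleep,
#' R_NDiff, T_A, T_N) against the subtype proliferation profile, and keeps
#' only the sets passing the clinical relevance filters.
#'
#' @param subtype `"ADC"` or `"SCC"`.
#' @param n LHS sample size before filtering.
#' @param seed RNG seed.
#' @return List with `params` (list of surviving [kinetic_params()]),
#'   `table` (full parameter table incl. failures), `mask` (the
#'   [apply_filters()] output) and `profile`.
#' @export
build_subtype_sample <- function(subtype, n, seed) {
  profile <- subtype_profile(subtype)
  smp <- lhs_sample(parameter_ranges("clinical"), n, seed)
  full <- purrr::map_dfr(seq_len(n), function(i) {
    row <- smp[i, ]
    ind <- list(T_C = row$T_C, T_G0 = row$T_G0, R_A = row$R_A,
                R_ADiff = row$R_ADiff, P_G0toG1 = row$P_G0toG1,
                P_sym = row$P_sym, N_LIMP = row$N_LIMP,
                CKF_stem = row$CKF_stem)
    res <- calibrate_full(profile, ind)
    if (is_calibration_failure(res)) {
      tibble::tibble(T_C_stem = row$T_C, T_C_limp = row$T_C,
                     T_G0_stem = row$T_G0, T_G0_limp = row$T_G0,
                     T_A = NA_real_, T_N = NA_real_,
                     R_A = row$R_A, R_ADiff = row$R_ADiff,
                     R_NDiff = NA_real_,
                     P_G0toG1_stem = row$P_G0toG1, P_G0toG1_limp = row$P_G0toG1,
                     P_sym = row$P_sym, P_sleep = NA_real_,
                     N_LIMP = as.integer(row$N_LIMP), CKF_stem = row$CKF_stem,
                     calib_failure = paste0("unreachable profile: ", res$stage))
    } else {
      dplyr::mutate(params_to_table(res), calib_failure = NA_character_)
    }
  })
  mask <- apply_filters(full, "clinical", profile = profile)
  keep <- which(mask$keep)
  if (length(keep) == 0L) {
    stop("build_subtype_sample: no surviving parameter set; increase n",
         call. = FALSE)
  }
  params <- purrr::map(keep, ~ sample_row_params(full[.x, ]))
  list(params = params, table = full, mask = mask, profile = profile,
       subtype = subtype, n = n, seed = seed)
}

#' Estimate the CKR distribution of a clinical case over a subtype sample
#'
#' @param case A [clinical_case()].
#' @param sample A [build_subtype_sample()] result (or a plain list of
#'   [kinetic_params()]).
#' @param ckr_b Partner-drug kill rate; defaults to the case's value.
#' @param tol Root tolerance on CKR.
#' @return A `ckr_distribution` (see [estimate_ckr_distribution()]).
#' @export
run_case <- function(case, sample, ckr_b = case$ckr_b, tol = 1e-6) {
  sets <- if (is.list(sample) && !is.null(sample$params)) sample$params else sample
  estimate_ckr_distribution(case, sets, ckr_b = ckr_b, tol = tol)
}

#' Validate a case against its resected tumor size
#'
#' Extends each per-set simulation from the first CT to the date of surgery,
#' applying any administrations in between with the set's estimated
#' cisplatin CKR, and compares the distribution of predicted equivalent
#' diameters with the equivalent diameter of the resected specimen
#' (triaxial-ellipsoid volume). Quartiles and 1.5 IQR outlier fences follow
#' box-plot convention.
#'
#' @param case A [clinical_case()] with surgery data.
#' @param sample As in [run_case()].
#' @param estimates The `ckr_distribution` from [run_case()].
#' @return A `validation_record`: per-set predictions, quartiles of the
#'   predicted equivalent diameter (cm), the observed one, and predicted vs
#'   observed volume change (%). If the case lacks surgery data, a record
#'   with `skipped = TRUE` is returned with a message.
#' @export
validate_case <- function(case, sample, estimates) {
  sets <- if (is.list(sample) && !is.null(sample$params)) sample$params else sample
  if (is.na(case$interval_ct2_surgery) || is.null(case$resection_cm)) {
    message("case ", case$case_id, ": no surgery record; validation skipped")
    return(structure(list(case_id = case$case_id, skipped = TRUE),
                     class = "validation_record"))
  }
  per_set <- estimates$per_set
  onset_h <- case$interval_ct1_onset * 24
  s0 <- min(0, onset_h)
  ct1 <- -s0
  t_surg <- (case$interval_cts + case$interval_ct2_surgery) * 24 - s0
  days <- dplyr::bind_rows(case$schedule, case$extra_schedule)
  preds <- purrr::map_dfr(which(per_set$converged), function(i) {
    sched <- doublet_schedule(days, per_set$ckr_cis[i], case$ckr_b, onset_h - s0)
    sched <- sched[sched$time_h <= t_surg, , drop = FALSE]
    tr <- simulate_tumor(sets[[i]], case$V0, duration_days = t_surg / 24,
                         schedule = sched)
    # anchor the trajectory so the volume at the first CT equals V0
    anchor <- case$V0 / tr$volume_mm3[match(ct1, tr$time_h)]
    v_surg <- tr$volume_mm3[nrow(tr)] * anchor
    tibble::tibble(set = i, volume_mm3 = v_surg,
                   eq_diam_cm = equivalent_diameter(v_surg / 1000),
                   volume_change_pct = 100 * (case$V0 - v_surg) / case$V0)
  })
  q <- stats::quantile(preds$eq_diam_cm, c(0, 0.25, 0.5, 0.75, 1))
  iqr <- q[[4]] - q[[2]]
  obs_vol <- ellipsoid_volume(case$resection_cm[1], case$resection_cm[2],
                              case$resection_cm[3])
  obs_d <- equivalent_diameter(obs_vol)
  structure(list(
    case_id = case$case_id, skipped = FALSE, predictions = preds,
    quartiles = tibble::tibble(
      min = q[[1]], q1 = q[[2]], median = q[[3]], q3 = q[[4]], max = q[[5]],
      fence_low = q[[2]] - 1.5 * iqr, fence_high = q[[4]] + 1.5 * iqr,
      n_outliers = sum(preds$eq_diam_cm < q[[2]] - 1.5 * iqr |
                         preds$eq_diam_cm > q[[4]] + 1.5 * iqr)),
    observed_volume_ml = obs_vol, observed_eq_diam_cm = obs_d,
    observed_in_iqr = obs_d >= q[[2]] && obs_d <= q[[4]],
    observed_volume_change_pct = 100 * (case$V0 - obs_vol * 1000) / case$V0,
    predicted_median_volume_change_pct = stats::median(preds$volume_change_pct)
  ), class = "validation_record")
}

#' @export
print.validation_record <- function(x, ...) {
  if (x$skipped) {
    cat("<validation_record> case", x$case_id, "- skipped (no surgery data)\n")
    return(invisible(x))
  }
  q <- x$quartiles
  cat(sprintf(
    "<validation_record> case %s: predicted eq. diameter %.2f [Q1 %.2f, Q3 %.2f] cm, observed %.2f cm%s\n",
    x$case_id, q$median, q$q1, q$q3, x$observed_eq_diam_cm,
    if (x$observed_in_iqr) " (within IQR)" else ""))
  invisible(x)
}

#' Generate a synthetic clinical case with known ground truth
#'
#' Simulates a subtype-calibrated tumor under one of the three doublet
#' regimen templates and records the two CT volumes, optionally perturbed by
#' multiplicative log-normal measurement noise. The true cisplatin CKR (and
#' the parameter set used) are attached as attributes, enabling
#' parameter-recovery tests of [estimate_ckr_cis()].
#'
#' @param subtype `"ADC"` or `"SCC"`.
#' @param true_ckr_cis Ground-truth cisplatin kill rate.
#' @param ckr_b Partner-drug kill rate.
#' @param partner `"gemcitabine"`, `"vinorelbine"` (partner on cycle days 1
#'   and 8) or `"docetaxel"` (both drugs on day 1 only); 3-week cycles.
#' @param n_cycles Number of cycles between the CTs.
#' @param interval_ct1_onset Days from first CT to onset.
#' @param interval_cts Days between CTs; defaults to onset + cycles + one
#'   trailing week.
#' @param V0 True tumor volume at the first CT, mm^3.
#' @param noise_sd Standard deviation of log-normal multiplicative noise on
#'   both recorded volumes (0 = noiseless).
#' @param seed Seed for the noise draws.
#' @param params Parameter set of the simulated tumor; defaults to the
#'   subtype baseline.
#' @return A [clinical_case()] with attributes `true_ckr_cis`,
#'   `true_ckr_sum` and `params`.
#' @export
generate_synthetic_case <- function(subtype, true_ckr_cis, ckr_b = 0.2,
                                    partner = c("gemcitabine", "vinorelbine",
                                                "docetaxel"),
                                    n_cycles = 2, interval_ct1_onset = 5,
                                    interval_cts = interval_ct1_onset +
                                      21 * n_cycles + 7,
                                    V0 = 1e5, noise_sd = 0, seed = 1,
                                    params = NULL) {
  partner <- match.arg(partner)
  if (is.null(params)) params <- baseline_params(subtype)
  starts <- 1 + 21 * (seq_len(n_cycles) - 1)
  days <- if (partner == "docetaxel") {
    tibble::tibble(day = rep(starts, each = 2),
                   drug = rep(c("cisplatin", partner), n_cycles))
  } else {
    tibble::tibble(
      day = c(rbind(starts, starts, starts + 7)),
      drug = rep(c("cisplatin", partner, partner), n_cycles))
  }
  onset_h <- interval_ct1_onset * 24
  s0 <- min(0, onset_h)
  ct1 <- -s0
  ct2 <- interval_cts * 24 - s0
  sched <- doublet_schedule(days, true_ckr_cis, ckr_b, onset_h - s0)
  sched <- sched[sched$time_h <= ct2, , drop = FALSE]
  tr <- simulate_tumor(params, V0, duration_days = ct2 / 24, schedule = sched)
  anchor <- V0 / tr$volume_mm3[match(ct1, tr$time_h)]
  v0 <- V0
  v1 <- tr$volume_mm3[nrow(tr)] * anchor
  if (noise_sd > 0) {
    eps <- withr::with_seed(seed, stats::rlnorm(2, meanlog = 0, sdlog = noise_sd))
    v0 <- v0 * eps[1]
    v1 <- v1 * eps[2]
  }
  cs <- clinical_case(
    case_id = sprintf("synthetic-%s-%s", tolower(subtype), seed),
    histology = subtype, V0 = v0, V1 = v1,
    interval_cts = interval_cts, interval_ct1_onset = interval_ct1_onset,
    schedule = days, ckr_b = ckr_b
  )
  attr(cs, "true_ckr_cis") <- true_ckr_cis
  attr(cs, "true_ckr_sum") <- true_ckr_cis + ckr_b
  attr(cs, "params") <- params
  cs
}
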