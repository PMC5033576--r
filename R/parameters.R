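#' Cell-kinetic parameter set
#'
#' Constructs the full parameter vector governing free tumor growth and
#' chemoresistance in the stem-cell-hierarchy model. The tumor population
#' consists of cancer stem cells (unlimited mitotic potential), LIMP cells
#' (LImited Mitotic Potential progenitors performing `N_LIMP` divisions),
#' terminally differentiated DIFF cells, and apoptotic/necrotic dead-cell
#' pools. Stem and LIMP kinetics may differ; passing the convenience
#' arguments `T_C`, `T_G0` or `P_G0toG1` sets both classes at once.
#'
#' @param T_C_stem,T_C_limp Cell cycle duration, hours.
#' @param T_G0_stem,T_G0_limp Mean residence time in the dormant G0 phase,
#'   hours. G0 exit is memoryless with this mean.
#' @param T_A Time for apoptosis to complete and its products to be cleared
#'   from the tumor, hours (mean of an exponential clearance).
#' @param T_N As `T_A`, for necrosis.
#' @param R_A Spontaneous apoptosis rate of living stem and LIMP cells
#'   (cycling and dormant), per hour.
#' @param R_ADiff,R_NDiff Apoptosis / necrosis rate of DIFF cells, per hour.
#' @param P_G0toG1_stem,P_G0toG1_limp Fraction of dormant cells that re-enter
#'   the cell cycle on G0 exit (the rest die through necrosis).
#' @param P_sym Fraction of stem-cell mitoses that are symmetric
#'   (two stem daughters); asymmetric mitoses yield one stem and one LIMP cell.
#' @param P_sleep Fraction of newborn cells with proliferative capacity that
#'   enter G0 after mitosis instead of starting a new cycle.
#' @param N_LIMP Number of mitoses a LIMP lineage performs before terminal
#'   differentiation (integer, >= 1).
#' @param CKF_stem Cell kill factor of stem cells: multiplier adapting a
#'   drug's cell kill rate to the (chemoresistant) stem compartment.
#'   The CKF of LIMP cells is fixed at 1.
#' @param T_C,T_G0,P_G0toG1 Convenience shorthands setting stem and LIMP
#'   values jointly.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params(
#'   T_C = 60, T_G0 = 242, T_A = 7, T_N = 79, R_A = 1e-4,
#'   R_ADiff = 0.017, R_NDiff = 0.01, P_G0toG1 = 0.1,
#'   P_sym = 0.37, P_sleep = 0.2796, N_LIMP = 22, CKF_stem = 0.5
#' )
#' @export
kinetic_params <- function(T_C_stem = NULL, T_C_limp = NULL,
                           T_G0_stem = NULL, T_G0_limp = NULL,
                           T_A, T_N, R_A, R_ADiff, R_NDiff,
                           P_G0toG1_stem = NULL, P_G0toG1_limp = NULL,
                           P_sym, P_sleep, N_LIMP, CKF_stem = 1,
                           T_C = NULL, T_G0 = NULL, P_G0toG1 = NULL) {
  if (!is.null(T_C)) T_C_stem <- T_C_limp <- T_C
  if (!is.null(T_G0)) T_G0_stem <- T_G0_limp <- T_G0
  if (!is.null(P_G0toG1)) P_G0toG1_stem <- P_G0toG1_limp <- P_G0toG1
  p <- list(
    T_C_stem = T_C_stem, T_C_limp = T_C_limp,
    T_G0_stem = T_G0_stem, T_G0_limp = T_G0_limp,
    T_A = T_A, T_N = T_N,
    R_A = R_A, R_ADiff = R_ADiff, R_NDiff = R_NDiff,
    P_G0toG1_stem = P_G0toG1_stem, P_G0toG1_limp = P_G0toG1_limp,
    P_sym = P_sym, P_sleep = P_sleep,
    N_LIMP = as.integer(round(N_LIMP)), CKF_stem = CKF_stem
  )
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  durs <- c("T_C_stem", "T_C_limp", "T_G0_stem", "T_G0_limp", "T_A", "T_N")
  for (d in durs) {
    if (is.null(p[[d]]) || !is.finite(p[[d]]) || p[[d]] <= 0) {
      stop("kinetic_params: duration `", d, "` must be a positive number",
           call. = FALSE)
    }
  }
  for (r in c("R_A", "R_ADiff", "R_NDiff")) {
    if (p[[r]] < 0) stop("kinetic_params: rate `", r, "` must be >= 0", call. = FALSE)
  }
  fr <- c("P_G0toG1_stem", "P_G0toG1_limp", "P_sym", "P_sleep", "CKF_stem")
  for (f in fr) {
    if (is.null(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      stop("kinetic_params: fraction `", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$N_LIMP < 1L) stop("kinetic_params: N_LIMP must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  print(as_tibble(x))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.kinetic_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Target proliferation profile
#'
#' The macroscopic proliferation features that calibration inverts into model
#' parameters: volume doubling time, growth fraction, apoptotic/necrotic
#' fractions of total cells, and stem-cell fraction of living cells.
#'
#' @param T_d Volume doubling time, days (> 0 for a viable tumor).
#' @param GF Growth fraction: proportion of living cells actively cycling.
#' @param AF,NF Apoptotic / necrotic fraction of total tumor cells.
#' @param SF Stem-cell fraction of living cells.
#' @return An object of class `prolif_profile`.
#' @examples
#' proliferation_profile(T_d = 109, GF = 0.36, AF = 0.01, NF = 0.20, SF = 2e-4)
#' @export
proliferation_profile <- function(T_d, GF, AF, NF, SF) {
  stopifnot(T_d > 0, GF >= 0, GF <= 1, AF >= 0, NF >= 0, SF >= 0, SF <= 1)
  if (AF + NF >= 1) stop("AF + NF must be < 1", call. = FALSE)
  if (SF > GF + (1 - GF)) stop("invalid SF", call. = FALSE)
  structure(list(T_d = T_d, GF = GF, AF = AF, NF = NF, SF = SF),
            class = "prolif_profile")
}

#' @export
print.prolif_profile <- function(x, ...) {
  cat(sprintf("<prolif_profile> T_d = %g d, GF = %g, AF = %g, NF = %g, SF = %g\n",
              x$T_d, x$GF, x$AF, x$NF, x$SF))
  invisible(x)
}

#' NSCLC subtype proliferation profiles
#'
#' Representative proliferation profiles for the two NSCLC histological
#' subtypes, assembled from a literature survey of subtype-specific kinetics:
#' adenocarcinoma (ADC: T_d 225 d, GF 0.18, AF 0.01, NF 0.02, SF 5e-5) and
#' squamous cell carcinoma (SCC: T_d 109 d, GF 0.36, AF 0.01, NF 0.20,
#' SF 2e-4). These are the baseline calibration targets; for sample-based
#' workflows SF acts as an upper-bound filter (< 1e-3) rather than a target.
#'
#' @param subtype `"ADC"` or `"SCC"`.
#' @return A [proliferation_profile()].
#' @examples
#' subtype_profile("SCC")
#' @export
subtype_profile <- function(subtype = c("ADC", "SCC")) {
  subtype <- match.arg(toupper(subtype), c("ADC", "SCC"))
  switch(subtype,
    ADC = proliferation_profile(T_d = 225, GF = 0.18, AF = 0.01, NF = 0.02, SF = 5e-5),
    SCC = proliferation_profile(T_d = 109, GF = 0.36, AF = 0.01, NF = 0.20, SF = 2e-4)
  )
}

#' Baseline independent parameters per subtype
#'
#' The biologically representative values assigned to the independent
#' parameters before the dependent ones (P_sleep, R_NDiff, T_A, T_N, N_LIMP)
#' are calibrated against the subtype profile. Stem and LIMP kinetics are
#' assumed identical at baseline.
#'
#' @param subtype `"ADC"` or `"SCC"`.
#' @return Named list with `T_C`, `T_G0`, `R_A`, `R_ADiff`, `P_G0toG1`,
#'   `P_sym` (and `CKF_stem = 0.5`, `CKR_B = 0.2`, the assumed second-drug
#'   kill rate).
#' @export
subtype_independents <- function(subtype = c("ADC", "SCC")) {
  subtype <- match.arg(toupper(subtype), c("ADC", "SCC"))
  switch(subtype,
    ADC = list(T_C = 42, T_G0 = 382, R_A = 3e-4, R_ADiff = 0.008,
               P_G0toG1 = 0.5, P_sym = 0.2, CKF_stem = 0.5, CKR_B = 0.2),
    SCC = list(T_C = 60, T_G0 = 242, R_A = 1e-4, R_ADiff = 0.017,
               P_G0toG1 = 0.1, P_sym = 0.37, CKF_stem = 0.5, CKR_B = 0.2)
  )
}

#' Baseline parameter set per subtype
#'
#' The fully calibrated representative parameter set for a subtype
#' (independents from [subtype_independents()], dependents from
#' [calibrate_full()]).
#'
#' @param subtype `"ADC"` or `"SCC"`.
#' @return A `kinetic_params` object.
#' @export
baseline_params <- function(subtype = c("ADC", "SCC")) {
  subtype <- match.arg(toupper(subtype), c("ADC", "SCC"))
  calibrate_full(subtype_profile(subtype), subtype_independents(subtype))
}

#' Parameter value ranges for sampling
#'
#' The value ranges of the free-growth and therapy parameters used by the
#' Latin hypercube workflows. `which` selects the parameter space:
#' `"sensitivity"` varies all 15 parameters (stem and LIMP kinetics
#' separately, P_sleep and the dead-cell clearance times included);
#' `"clinical"` varies the 8 independent parameters of the
#' subtype-constrained workflow (kinetics shared between stem and LIMP;
#' P_sleep, R_NDiff, T_A and T_N are then calibrated, not sampled).
#'
#' @param which `"sensitivity"` or `"clinical"`.
#' @return A tibble with columns `parameter`, `min`, `max`, `integer`.
#' @examples
#' parameter_ranges("clinical")
#' @export
parameter_ranges <- function(which = c("sensitivity", "clinical")) {
  which <- match.arg(which)
  base <- tibble::tribble(
    ~parameter,        ~min,   ~max,  ~integer,
    "T_C_stem",          18,    134,  FALSE,
    "T_C_limp",          18,    134,  FALSE,
    "T_G0_stem",         90,   1200,  FALSE,
    "T_G0_limp",         90,   1200,  FALSE,
    "T_A",                1,     25,  FALSE,
    "T_N",                1,    200,  FALSE,
    "R_A",                0,  0.001,  FALSE,
    "R_ADiff",       0.0001,   0.02,  FALSE,
    "R_NDiff",            0,   0.02,  FALSE,
    "P_G0toG1_stem",      0,      1,  FALSE,
    "P_G0toG1_limp",      0,      1,  FALSE,
    "P_sym",              0,    0.4,  FALSE,
    "P_sleep",            0,      1,  FALSE,
    "N_LIMP",             8,     24,  TRUE,
    "CKF_stem",           0,      1,  FALSE
  )
  if (which == "sensitivity") return(base)
  shared <- c(T_C_stem = "T_C", T_G0_stem = "T_G0", P_G0toG1_stem = "P_G0toG1")
  out <- dplyr::filter(
    base,
    !.data$parameter %in% c("T_C_limp", "T_G0_limp", "P_G0toG1_limp",
                            "T_A", "T_N", "R_NDiff", "P_sleep")
  )
  dplyr::mutate(out, parameter = dplyr::coalesce(
    unname(shared[.data$parameter]), .data$parameter))
}

#' Read / write parameter sets as flat tables
#'
#' Parameter sets serialize to one row per set with columns named as the
#' model symbols (`T_C_stem`, ..., `CKF_stem`).
#'
#' @param params A `kinetic_params` object or a list of them.
#' @return `params_to_table()`: a tibble; `params_from_table()`: a list of
#'   `kinetic_params`.
#' @export
params_to_table <- function(params) {
  if (inherits(params, "kinetic_params")) params <- list(params)
  purrr::map_dfr(params, ~ tibble::as_tibble(unclass(.x)))
}

#' @rdname params_to_table
#' @param tbl A data frame with one row per parameter set.
#' @export
params_from_table <- function(tbl) {
  purrr::pmap(as.list(tbl), function(...) {
    row <- list(...)
    do.call(kinetic_params, row[names(row) %in% names(formals(kinetic_params))])
  })
}

#' @rdname params_to_table
#' @param file Path to a CSV (one row per set) or YAML (single set) file.
#' @export
read_params <- function(file) {
  if (grepl("\\.ya?ml$", file)) {
    do.call(kinetic_params, yaml::read_yaml(file))
  } else {
    sets <- params_from_table(readr::read_csv(file, show_col_types = FALSE))
    if (length(sets) == 1L) sets[[1L]] else sets
  }
}

#' @rdname params_to_table
#' @export
write_params <- function(params, file) {
  if (grepl("\\.ya?ml$", file)) {
    if (!inherits(params, "kinetic_params")) {
      stop("YAML serialization takes a single parameter set", call. = FALSE)
    }
    yaml::write_yaml(lapply(unclass(params), unclass), file, precision = 12)
  } else {
    readr::write_csv(params_to_table(params), file)
  }
  invisible(file)
}
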