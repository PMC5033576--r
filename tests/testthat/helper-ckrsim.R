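# Shared fixtures for the test suite. Everything is generated in code.

adc_profile <- subtype_profile("ADC")
scc_profile <- subtype_profile("SCC")
adc_ind <- subtype_independents("ADC")
scc_ind <- subtype_independents("SCC")

# Random biologically plausible parameter sets: LHS over the full parameter
# space, filtered for viability, with cycle times rounded to whole hours so
# the discrete simulator realizes exactly the parameters the closed form
# sees (the simulator rounds durations to 1 h ticks).
random_valid_params <- function(n, seed) {
  # roughly 6% of unconstrained draws are viable tumors; oversample
  smp <- lhs_sample(parameter_ranges("sensitivity"), max(400, n * 25), seed)
  smp$T_C_stem <- round(smp$T_C_stem)
  smp$T_C_limp <- round(smp$T_C_limp)
  mask <- apply_filters(smp, "sensitivity")
  keep <- utils::head(which(mask$keep), n)
  lapply(keep, function(i) {
    p <- as.list(smp[i, ])
    do.call(kinetic_params, p)
  })
}

# a minimal stem-only configuration with a 2-tick cycle, used for
# hand-computed expectation checks
toy_params <- function(R_A = 0, P_sleep = 0, P_sym = 1, P_G0toG1 = 1,
                       T_G0 = 10, T_C = 2) {
  kinetic_params(T_C = T_C, T_G0 = T_G0, T_A = 5, T_N = 5,
                 R_A = R_A, R_ADiff = 0, R_NDiff = 0,
                 P_G0toG1 = P_G0toG1, P_sym = P_sym, P_sleep = P_sleep,
                 N_LIMP = 1, CKF_stem = 1)
}

# a toy state with hand-set compartments (stem conveyor, stem G0), built
# directly so extreme toy kinetics need no balanced-growth solution
toy_state <- function(params, Cs, g0s = 0) {
  pd <- ckrsim:::discretize_params(params)
  stopifnot(length(Cs) == pd$Ls)
  structure(list(
    tick = 0L, Cs = Cs, Cl = matrix(0, pd$Ll, pd$G),
    g0s = g0s, g0l = numeric(pd$G), g0hit_s = 0, g0hit_l = 0,
    diff = 0, apo = 0, nec = 0,
    H = numeric(pd$Hlen), hptr = 0L, cell_density = 1e6
  ), class = "tumor_state", params = params, pd = pd)
}
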