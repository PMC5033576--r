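# Discrete-time simulator of the tumor cell population.
#
# The tumor is well mixed: the clinical images carry no information about
# internal metabolic regions, so all kinetic parameters are spatially
# invariant and volume = total cells / cell_density. The cell cycle is a
# fixed-length conveyor of 1 h ticks (positions 1..T_C); G0 exit, spontaneous
# death and dead-cell pool clearance are memoryless per-tick events, matching
# the rate form of the balanced-growth equations. Cells lethally hit by a
# drug never divide; they march through a rudimentary cycle and enter the
# apoptotic pool at the end of the drug's death phase, so each hit cohort's
# death tick is known at administration time and hit cells are tracked as a
# death-schedule queue rather than on the conveyor.

#' Built-in drug catalogue
#'
#' Mechanism abstractions of the four drugs: cisplatin is cell-cycle
#' non-specific (also hits dormant G0 cells) with apoptotic death at the end
#' of G2; gemcitabine, vinorelbine and docetaxel are cycle-specific with
#' death at the end of S, M and M respectively.
#'
#' @return Tibble with columns `drug`, `hits_G0`, `death_phase`.
#' @export
drug_catalogue <- function() {
  tibble::tribble(
    ~drug,         ~hits_G0, ~death_phase,
    "cisplatin",   TRUE,     "G2",
    "gemcitabine", FALSE,    "S",
    "vinorelbine", FALSE,    "M",
    "docetaxel",   FALSE,    "M"
  )
}

#' Build a treatment schedule
#'
#' @param day Administration day, with day 1 = treatment onset.
#' @param drug Drug name (must resolve in [drug_catalogue()]).
#' @param ckr Cell kill rate of that administration's drug, in \[0, 1\].
#' @param onset_h Hour of treatment onset on the simulation clock; day `d`
#'   maps to `onset_h + (d - 1) * 24`.
#' @return Tibble `(time_h, drug, ckr)` sorted by time, class
#'   `treatment_schedule`.
#' @examples
#' treatment_schedule(day = c(1, 8, 22), drug = c("cisplatin", "gemcitabine",
#'   "cisplatin"), ckr = c(0.3, 0.2, 0.3))
#' @export
treatment_schedule <- function(day, drug, ckr, onset_h = 0) {
  drug <- tolower(drug)
  unknown <- setdiff(unique(drug), drug_catalogue()$drug)
  if (length(unknown)) {
    stop("unknown drug(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(ckr >= 0), all(ckr <= 1))
  out <- tibble::tibble(time_h = onset_h + (day - 1) * 24, drug = drug, ckr = ckr)
  out <- dplyr::arrange(out, .data$time_h, .data$drug)
  class(out) <- c("treatment_schedule", class(out))
  out
}

# ---- discretization -------------------------------------------------------

default_phase_fractions <- c(G1 = 0.40, S = 0.39, G2 = 0.19, M = 0.02)

# cumulative phase-end positions (ticks) for a cycle of L ticks
phase_bounds <- function(L, fractions = default_phase_fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  b <- round(cumsum(fractions) * L)
  b[4] <- L
  b <- pmin(pmax(cummax(b), 1), L)
  names(b) <- c("G1", "S", "G2", "M")
  b
}

# precompute everything the tick loop needs
discretize_params <- function(params, dt = 1,
                              phase_fractions = default_phase_fractions) {
  stopifnot(dt == 1)  # hour-scale parameters; the model is defined on 1 h ticks
  p <- params
  Ls <- max(1L, as.integer(round(p$T_C_stem)))
  Ll <- max(1L, as.integer(round(p$T_C_limp)))
  list(
    Ls = Ls, Ll = Ll, bs = phase_bounds(Ls, phase_fractions),
    bl = phase_bounds(Ll, phase_fractions),
    G = p$N_LIMP,
    R_A = p$R_A, R_ADiff = p$R_ADiff, R_NDiff = p$R_NDiff,
    diff_apo_share = if (p$R_ADiff + p$R_NDiff > 0)
      p$R_ADiff / (p$R_ADiff + p$R_NDiff) else 0,
    pexit_s = min(1, 1 / p$T_G0_stem), pexit_l = min(1, 1 / p$T_G0_limp),
    PG0s = p$P_G0toG1_stem, PG0l = p$P_G0toG1_limp,
    P_sym = p$P_sym, P_sleep = p$P_sleep, CKF = p$CKF_stem,
    prem_a = min(1, 1 / p$T_A), prem_n = min(1, 1 / p$T_N),
    Hlen = 2L * max(Ls, Ll) + 3L
  )
}

# ---- state ----------------------------------------------------------------

#' Initialize a tumor state at balanced growth
#'
#' Builds a population whose compartment fractions equal the
#' [balanced_composition()] of the parameter set and whose intra-cycle age
#' distribution is the stationary exponential-growth profile (density
#' proportional to `exp(-(a + R_A) age)`), so that free growth starts with no
#' transient.
#'
#' @param initial_volume Tumor volume in mm^3.
#' @param params A [kinetic_params()] object.
#' @param cell_density Cells per mm^3 (default 1e6). Relative volume changes
#'   are invariant to this choice.
#' @param dt Tick length, hours (only 1 supported).
#' @param phase_fractions Split of the cell cycle into G1/S/G2/M; defaults to
#'   typical mammalian proportions (0.40/0.39/0.19/0.02).
#' @param stochastic Round occupancies to whole cells.
#' @return A `tumor_state` object.
#' @export
initialize_state <- function(initial_volume, params, cell_density = 1e6,
                             dt = 1, phase_fractions = default_phase_fractions,
                             stochastic = FALSE) {
  stopifnot(initial_volume > 0)
  p <- params
  pd <- discretize_params(p, dt, phase_fractions)
  comp <- balanced_composition(p)
  a <- comp$a
  x <- a + p$R_A
  S <- class_quantities(a, p$R_A, p$T_C_stem, p$T_G0_stem, p$P_G0toG1_stem, p$P_sleep)
  L <- class_quantities(a, p$R_A, p$T_C_limp, p$T_G0_limp, p$P_G0toG1_limp, p$P_sleep)
  nb_stem <- 1 + p$P_sym
  r <- 2 * L$phi
  nb_limp <- (1 - p$P_sym) * r^(seq_len(pd$G) - 1)

  total_cells <- initial_volume * cell_density
  living <- total_cells * comp$living_of_total

  prof_s <- exp(-x * (seq_len(pd$Ls) - 1))
  prof_l <- exp(-x * (seq_len(pd$Ll) - 1))
  # per-lineage cycling and G0 targets (relative), then scale to composition
  cyc_s <- nb_stem * S$cyc_per_newborn
  cyc_l <- nb_limp * L$cyc_per_newborn
  g0_s <- nb_stem * S$g0_per_newborn
  g0_l <- nb_limp * L$g0_per_newborn
  scale <- living * (comp$GF + comp$QF) / (cyc_s + sum(cyc_l) + g0_s + sum(g0_l))

  Cs <- prof_s / sum(prof_s) * cyc_s * scale
  Cl <- outer(prof_l / sum(prof_l), cyc_l * scale)
  st <- list(
    tick = 0L,
    Cs = Cs, Cl = Cl,
    g0s = g0_s * scale, g0l = g0_l * scale,
    g0hit_s = 0, g0hit_l = 0,
    diff = living * comp$DF,
    apo = total_cells * comp$AF, nec = total_cells * comp$NF,
    H = numeric(pd$Hlen), hptr = 0L,
    cell_density = cell_density
  )
  if (stochastic) {
    # allocate whole cells multinomially over all compartments: plain
    # rounding would systematically distort sparse bins (e.g. the few
    # stem cells spread over many age positions)
    w <- c(st$Cs, as.vector(st$Cl), st$g0s, st$g0l, st$diff, st$apo, st$nec)
    cnt <- as.vector(stats::rmultinom(1L, round(sum(w)), prob = w))
    ncs <- length(st$Cs); ncl <- length(st$Cl); ng <- length(st$g0l)
    st$Cs <- cnt[seq_len(ncs)]
    st$Cl <- matrix(cnt[ncs + seq_len(ncl)], nrow(st$Cl), ncol(st$Cl))
    st$g0s <- cnt[ncs + ncl + 1L]
    st$g0l <- cnt[ncs + ncl + 1L + seq_len(ng)]
    st$diff <- cnt[ncs + ncl + ng + 2L]
    st$apo <- cnt[ncs + ncl + ng + 3L]
    st$nec <- cnt[ncs + ncl + ng + 4L]
  }
  structure(st, class = "tumor_state", params = p, pd = pd)
}

state_counts <- function(st) {
  hit <- sum(st$H) + st$g0hit_s + st$g0hit_l
  cycling <- sum(st$Cs) + sum(st$Cl)
  g0 <- st$g0s + sum(st$g0l)
  living <- cycling + g0 + st$diff + hit
  c(living = living, cycling = cycling, g0 = g0, diff = st$diff, hit = hit,
    stem = sum(st$Cs) + st$g0s,
    limp = sum(st$Cl) + sum(st$g0l),
    apoptotic = st$apo, necrotic = st$nec,
    total = living + st$apo + st$nec)
}

#' @export
print.tumor_state <- function(x, ...) {
  cnt <- state_counts(x)
  cat(sprintf("<tumor_state> t = %d h, volume = %.4g mm^3\n",
              x$tick, cnt[["total"]] / x$cell_density))
  print(round(cnt, 2))
  invisible(x)
}

#' Tumor volume of a state
#' @param state A `tumor_state`.
#' @return Volume in mm^3 (all cells, living and dead, at `cell_density`).
#' @export
state_volume <- function(state) {
  unname(state_counts(state)[["total"]] / state$cell_density)
}

# ---- tick loop ------------------------------------------------------------

# Advance `n` ticks. Record matrix (n x 10) returned alongside the state.
# Order within a tick: spontaneous losses -> G0 exits -> conveyor advance,
# mitosis and newborn routing -> scheduled hit deaths -> pool clearance.
advance_state <- function(st, n, stochastic = FALSE, record = TRUE) {
  pd <- attr(st, "pd"); p <- attr(st, "params")
  Cs <- st$Cs; Cl <- st$Cl; g0s <- st$g0s; g0l <- st$g0l
  g0hs <- st$g0hit_s; g0hl <- st$g0hit_l
  diffc <- st$diff; apo <- st$apo; nec <- st$nec
  H <- st$H; hptr <- st$hptr; Hlen <- pd$Hlen
  G <- pd$G; Ls <- pd$Ls; Ll <- pd$Ll
  RA <- pd$R_A
  rec <- if (record) matrix(NA_real_, nrow = n, ncol = 10) else NULL
  max_imbalance <- 0
  draw <- function(size, prob) {
    if (stochastic) stats::rbinom(length(size), size, prob) else size * prob
  }
  for (k in seq_len(n)) {
    before <- sum(Cs) + sum(Cl) + g0s + sum(g0l) + g0hs + g0hl + diffc +
      sum(H) + apo + nec
    apo_in <- 0; nec_in <- 0
    # 1. spontaneous losses
    if (RA > 0) {
      dCs <- draw(Cs, RA); Cs <- Cs - dCs
      dCl <- draw(Cl, RA); Cl <- Cl - dCl
      dg0 <- draw(c(g0s, g0l, g0hs, g0hl), RA)
      g0s <- g0s - dg0[1L]; g0l <- g0l - dg0[2:(G + 1L)]
      g0hs <- g0hs - dg0[G + 2L]; g0hl <- g0hl - dg0[G + 3L]
      dH <- draw(H, RA); H <- H - dH
      apo_in <- apo_in + sum(dCs) + sum(dCl) + sum(dg0) + sum(dH)
    }
    # DIFF losses are competing risks: joint per-tick loss R_ADiff + R_NDiff
    # split proportionally (sequential thinning would bias the clearance
    # rate by R_ADiff * R_NDiff per tick)
    if (stochastic) {
      dtot <- stats::rbinom(1L, diffc, min(1, pd$R_ADiff + pd$R_NDiff))
      dda <- stats::rbinom(1L, dtot, pd$diff_apo_share)
      ddn <- dtot - dda
    } else {
      dda <- diffc * pd$R_ADiff
      ddn <- diffc * pd$R_NDiff
    }
    diffc <- diffc - dda - ddn
    apo_in <- apo_in + dda; nec_in <- nec_in + ddn
    # 2. G0 exits
    ex_s <- draw(g0s, pd$pexit_s); g0s <- g0s - ex_s
    ret_s <- draw(ex_s, pd$PG0s); nec_in <- nec_in + (ex_s - ret_s)
    ex_l <- draw(g0l, pd$pexit_l); g0l <- g0l - ex_l
    ret_l <- draw(ex_l, pd$PG0l); nec_in <- nec_in + sum(ex_l - ret_l)
    ex_hs <- draw(g0hs, pd$pexit_s); g0hs <- g0hs - ex_hs
    ret_hs <- draw(ex_hs, pd$PG0s); nec_in <- nec_in + (ex_hs - ret_hs)
    ex_hl <- draw(g0hl, pd$pexit_l); g0hl <- g0hl - ex_hl
    ret_hl <- draw(ex_hl, pd$PG0l); nec_in <- nec_in + (ex_hl - ret_hl)
    # hit G0 cells re-entering the cycle die at the end of G2 of a
    # rudimentary cycle
    if (ret_hs > 0) {
      i <- (hptr + pd$bs[["G2"]]) %% Hlen + 1L
      H[i] <- H[i] + ret_hs
    }
    if (ret_hl > 0) {
      i <- (hptr + pd$bl[["G2"]]) %% Hlen + 1L
      H[i] <- H[i] + ret_hl
    }
    # 3. conveyor advance and mitosis
    mit_s <- Cs[Ls]
    Cs <- c(0, Cs[-Ls])
    mit_l <- Cl[Ll, ]
    Cl <- rbind(0, Cl[-Ll, , drop = FALSE])
    if (stochastic) {
      sym <- stats::rbinom(1L, mit_s, pd$P_sym)
      nb_s <- mit_s + sym
      nb_l <- c(mit_s - sym, 2 * mit_l[-G])
    } else {
      nb_s <- (1 + pd$P_sym) * mit_s
      nb_l <- c((1 - pd$P_sym) * mit_s, 2 * mit_l[-G])
    }
    diffc <- diffc + 2 * mit_l[G]
    sl_s <- draw(nb_s, pd$P_sleep); g0s <- g0s + sl_s
    sl_l <- draw(nb_l, pd$P_sleep); g0l <- g0l + sl_l
    Cs[1L] <- (nb_s - sl_s) + ret_s
    Cl[1L, ] <- (nb_l - sl_l) + ret_l
    # 4. scheduled deaths of lethally hit cohorts
    hptr <- (hptr + 1L) %% Hlen
    apo_in <- apo_in + H[hptr + 1L]
    H[hptr + 1L] <- 0
    # 5. dead-cell pool clearance
    rem_a <- draw(apo, pd$prem_a); rem_n <- draw(nec, pd$prem_n)
    apo <- apo - rem_a + apo_in
    nec <- nec - rem_n + nec_in
    if (!stochastic) {
      after <- sum(Cs) + sum(Cl) + g0s + sum(g0l) + g0hs + g0hl + diffc +
        sum(H) + apo + nec
      births <- mit_s + sum(mit_l)
      imb <- abs(after - (before + births - rem_a - rem_n)) / max(after, 1)
      if (imb > max_imbalance) max_imbalance <- imb
    }
    if (record) {
      hit <- sum(H) + g0hs + g0hl
      cyc <- sum(Cs) + sum(Cl)
      g0tot <- g0s + sum(g0l)
      rec[k, ] <- c(cyc + g0tot + diffc + hit, cyc, g0tot, diffc, hit,
                    sum(Cs) + g0s, sum(Cl) + sum(g0l), apo, nec,
                    cyc + g0tot + diffc + hit + apo + nec)
    }
  }
  st$Cs <- Cs; st$Cl <- Cl; st$g0s <- g0s; st$g0l <- g0l
  st$g0hit_s <- g0hs; st$g0hit_l <- g0hl
  st$diff <- diffc; st$apo <- apo; st$nec <- nec
  st$H <- H; st$hptr <- hptr
  st$tick <- st$tick + n
  list(state = st, record = rec, max_imbalance = max_imbalance)
}

#' Advance a tumor state by one or more ticks
#'
#' One tick applies, in order: spontaneous losses (rate `R_A` for stem/LIMP
#' cells, `R_ADiff`/`R_NDiff` for DIFF); memoryless G0 exits (re-entry with
#' `P_G0toG1`, necrosis otherwise); conveyor advance with mitosis at the end
#' of M (symmetric stem division with probability `P_sym`; LIMP generation g
#' yields two cells of generation g+1, terminal products become DIFF;
#' newborns enter G0 with probability `P_sleep`); scheduled deaths of
#' lethally hit cohorts; and exponential clearance of the dead-cell pools.
#'
#' @param state A `tumor_state`.
#' @param n Number of 1 h ticks.
#' @param stochastic Sample per-cell fates (binomial draws) instead of
#'   propagating expectations.
#' @return The advanced `tumor_state`.
#' @export
step_state <- function(state, n = 1L, stochastic = FALSE) {
  advance_state(state, n, stochastic = stochastic, record = FALSE)$state
}

#' Apply an instantaneous drug administration to a state
#'
#' All lethal lesions occur instantaneously at administration time. In every
#' proliferative phase a fraction `min(1, sum(ckr))` of LIMP cells and
#' `min(1, CKF_stem * sum(ckr))` of stem cells is lethally hit (drug effects
#' are additive); dormant cells are hit only by G0-active drugs (cisplatin).
#' Hit cohorts are allocated to drugs proportionally to their CKR and carry
#' the drug's death phase: they continue through a rudimentary cycle (never
#' dividing) and join the apoptotic pool at the end of that phase, wrapping
#' into the next cycle if the phase was already passed. Hit dormant cells
#' follow normal G0 exit rules; on re-entry they die at the end of G2, on
#' exit to necrosis they die necrotically.
#'
#' @param state A `tumor_state`.
#' @param drugs Data frame with columns `drug` and `ckr` (one row per drug
#'   given at this administration).
#' @param stochastic Sample hit counts binomially.
#' @return The post-administration `tumor_state`.
#' @export
apply_administration <- function(state, drugs, stochastic = FALSE) {
  pd <- attr(state, "pd")
  cat_tbl <- drug_catalogue()
  unknown <- setdiff(tolower(drugs$drug), cat_tbl$drug)
  if (length(unknown)) {
    stop("unknown drug(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  drugs <- dplyr::inner_join(
    dplyr::mutate(drugs, drug = tolower(.data$drug)), cat_tbl, by = "drug")
  drugs <- drugs[drugs$ckr > 0, , drop = FALSE]
  if (nrow(drugs) == 0L) return(state)

  ksum <- sum(drugs$ckr)
  kL <- min(1, ksum)
  kS <- min(1, pd$CKF * ksum)
  share <- drugs$ckr / ksum
  H <- state$H; Hlen <- pd$Hlen; hptr <- state$hptr

  hit_conveyor <- function(C, L, bounds, kfrac) {
    # returns list(remaining conveyor, per-drug x position hit counts)
    pos <- seq_len(L)
    hit_tot <- if (stochastic) stats::rbinom(L, C, kfrac) else C * kfrac
    remaining <- C - hit_tot
    for (d in seq_len(nrow(drugs))) {
      left_share <- sum(share[d:length(share)])
      take <- if (d == nrow(drugs)) hit_tot else {
        if (stochastic) stats::rbinom(L, hit_tot, share[d] / left_share)
        else hit_tot * share[d] / left_share
      }
      hit_tot <- hit_tot - take
      b <- bounds[[drugs$death_phase[d]]]
      # cells at position pos die on completing tick b of this cycle, or of
      # the rudimentary cycle if already past it (hit cells never divide)
      offset <- ifelse(pos <= b, b - pos + 1L, (L - pos + 1L) + b)
      idx <- (hptr + offset) %% Hlen + 1L
      for (i in which(take > 0)) H[idx[i]] <<- H[idx[i]] + take[i]
    }
    remaining
  }
  if (kS > 0) state$Cs <- hit_conveyor(state$Cs, pd$Ls, pd$bs, kS)
  if (kL > 0) {
    for (g in seq_len(pd$G)) {
      state$Cl[, g] <- hit_conveyor(state$Cl[, g], pd$Ll, pd$bl, kL)
    }
  }
  # dormant cells: only G0-active drugs contribute
  k0 <- min(1, sum(drugs$ckr[drugs$hits_G0]))
  if (k0 > 0) {
    k0S <- min(1, pd$CKF * k0)
    h_s <- if (stochastic) stats::rbinom(1L, state$g0s, k0S) else state$g0s * k0S
    h_l <- if (stochastic) stats::rbinom(length(state$g0l), state$g0l, k0)
           else state$g0l * k0
    state$g0s <- state$g0s - h_s
    state$g0l <- state$g0l - h_l
    state$g0hit_s <- state$g0hit_s + h_s
    state$g0hit_l <- state$g0hit_l + sum(h_l)
  }
  state$H <- H
  state
}

#' Simulate tumor growth and treatment response
#'
#' Runs the discrete-time population model from a balanced-growth initial
#' state, applying scheduled drug administrations instantaneously at their
#' times. In `expectation` mode compartment means are propagated
#' deterministically (bit-reproducible); in `stochastic` mode all cell fates
#' are sampled binomially from a seeded generator.
#'
#' @param params A [kinetic_params()] object.
#' @param initial_volume Tumor volume at simulation start, mm^3.
#' @param duration_days Simulated time span, days.
#' @param schedule A [treatment_schedule()] (or `NULL` for free growth).
#' @param mode `"expectation"` or `"stochastic"`.
#' @param seed RNG seed; required in stochastic mode.
#' @param cell_density Cells per mm^3.
#' @param phase_fractions Cycle phase split, see [initialize_state()].
#' @return A `tumor_trajectory`: tibble with `time_h`, `volume_mm3` and
#'   compartment counts, with the final state, conservation audit and run
#'   settings as attributes.
#' @examples
#' tr <- simulate_tumor(baseline_params("SCC"), 523.6, duration_days = 60)
#' doubling_time(tr)
#' @export
simulate_tumor <- function(params, initial_volume, duration_days,
                           schedule = NULL, mode = c("expectation", "stochastic"),
                           seed = NULL, cell_density = 1e6,
                           phase_fractions = default_phase_fractions) {
  mode <- match.arg(mode)
  stochastic <- mode == "stochastic"
  if (stochastic && is.null(seed)) {
    stop("stochastic mode requires a seed", call. = FALSE)
  }
  run <- function() {
    st <- initialize_state(initial_volume, params, cell_density = cell_density,
                           phase_fractions = phase_fractions,
                           stochastic = stochastic)
    n_ticks <- as.integer(round(duration_days * 24))
    admin_ticks <- integer(0)
    if (!is.null(schedule) && nrow(schedule) > 0) {
      if (any(schedule$time_h < 0)) {
        stop("administration before simulation start; shift the clock",
             call. = FALSE)
      }
      admin_ticks <- as.integer(round(schedule$time_h))
    }
    rec <- matrix(NA_real_, nrow = n_ticks + 1L, ncol = 10)
    cnt <- state_counts(st)
    rec[1L, ] <- cnt[c("living", "cycling", "g0", "diff", "hit", "stem",
                       "limp", "apoptotic", "necrotic", "total")]
    cons_err <- 0
    breaks <- sort(unique(c(admin_ticks[admin_ticks <= n_ticks], n_ticks)))
    done <- 0L
    for (b in breaks) {
      at <- sort(unique(admin_ticks[admin_ticks == done]))
      for (tk in at) {
        st <- apply_administration(
          st, schedule[as.integer(round(schedule$time_h)) == tk, , drop = FALSE],
          stochastic = stochastic)
      }
      if (b > done) {
        out <- advance_state(st, b - done, stochastic = stochastic)
        st <- out$state
        rec[(done + 2L):(b + 1L), ] <- out$record
        cons_err <- max(cons_err, out$max_imbalance)
        done <- b
      }
    }
    # administrations falling exactly on the final tick boundary
    for (tk in admin_ticks[admin_ticks == n_ticks]) {
      st <- apply_administration(
        st, schedule[as.integer(round(schedule$time_h)) == tk, , drop = FALSE],
        stochastic = stochastic)
    }
    traj <- tibble::tibble(
      time_h = as.numeric(0:n_ticks),
      volume_mm3 = rec[, 10] / cell_density,
      living = rec[, 1], cycling = rec[, 2], g0 = rec[, 3], diff = rec[, 4],
      hit = rec[, 5], stem = rec[, 6], limp = rec[, 7],
      apoptotic = rec[, 8], necrotic = rec[, 9]
    )
    structure(traj, class = c("tumor_trajectory", class(traj)),
              params = params, mode = mode, seed = seed,
              cell_density = cell_density, final_state = st,
              conservation_error = cons_err)
  }
  if (stochastic) withr::with_seed(seed, run()) else run()
}

#' Doubling time from a volume trajectory
#'
#' Least-squares fit of log-volume against time over a window of the
#' trajectory; returns `ln 2 / slope` in days.
#'
#' @param trajectory A `tumor_trajectory` or data frame with `time_h` and
#'   `volume_mm3`.
#' @param from_h,to_h Fit window in hours; by default the fit skips an
#'   initial transient of twice the stem cell cycle time when parameters are
#'   attached, otherwise uses the whole series.
#' @return List with `T_d` (days; negative when the tumor shrinks),
#'   `negative_growth`, `slope` (per hour) and `r_squared`.
#' @export
doubling_time <- function(trajectory, from_h = NULL, to_h = NULL) {
  tr <- trajectory
  stopifnot(nrow(tr) >= 2, all(tr$volume_mm3 > 0))
  if (is.null(from_h)) {
    p <- attr(tr, "params")
    from_h <- if (!is.null(p)) 2 * p$T_C_stem else min(tr$time_h)
  }
  if (is.null(to_h)) to_h <- max(tr$time_h)
  win <- tr[tr$time_h >= from_h & tr$time_h <= to_h, ]
  if (nrow(win) < 2) stop("doubling_time: empty fit window", call. = FALSE)
  fit <- stats::lm(log(volume_mm3) ~ time_h, data = win)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  if (abs(slope) < 1e-14) {
    return(list(T_d = Inf, negative_growth = FALSE, slope = 0, r_squared = r2))
  }
  list(T_d = log(2) / slope / 24, negative_growth = slope < 0,
       slope = slope, r_squared = r2)
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  cat(sprintf("<tumor_trajectory> %d ticks, %s mode, V: %.4g -> %.4g mm^3\n",
              nrow(x) - 1L, attr(x, "mode"),
              x$volume_mm3[1], x$volume_mm3[nrow(x)]))
  NextMethod()
}

#' Write a trajectory to CSV
#' @param trajectory A `tumor_trajectory`.
#' @param file Output path.
#' @export
write_trajectory <- function(trajectory, file) {
  readr::write_csv(tibble::as_tibble(trajectory), file)
  invisible(file)
}
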