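# Fewest-switches surface hopping with local-diabatization electronic
# propagation and energy-based decoherence. The inner loop lives in
# src/engine.cpp; this file provides settings, the per-trajectory and
# ensemble drivers, and small pure-R reference implementations of the hop
# probability and decoherence damping used in oracle tests.

#' Surface-hopping run settings
#'
#' @param dt nuclear/electronic time step, fs
#' @param t_max maximum propagation time, ps
#' @param decoherence_C energy-based decoherence constant, kcal/mol
#'   (default 0.1 hartree = 62.75 kcal/mol, the standard value)
#' @param max_hop_gap optional hop gate: hops with S0/S1 gap larger than this
#'   (eV) are forbidden; `NULL` disables the gate
#' @param record_stride store every `record_stride`-th step
#' @param stop_window once on S0, stop after the trajectory has dwelt in a
#'   single torsional basin for this long (ps)
#' @param gamma_override if non-`NULL`, a list with any of `gamma_s1`,
#'   `gamma_s0`, `T_s1` replacing the model's bath settings; `gamma_zero =
#'   TRUE` switches all friction off (microcanonical propagation)
#' @param gamma_zero logical, disable all Langevin coupling
#' @param seed base integer seed; trajectory i uses `seed + i`
#' @return list of class `sh_settings`
#' @export
sh_settings <- function(dt = 0.1, t_max = 15, decoherence_C = 62.75,
                        max_hop_gap = NULL, record_stride = 50L,
                        stop_window = 0.5, gamma_override = NULL,
                        gamma_zero = FALSE, seed = 1) {
  stopifnot(dt > 0, t_max > 0)
  structure(list(dt = dt, t_max = t_max, decoherence_C = decoherence_C,
                 max_hop_gap = max_hop_gap, record_stride = as.integer(record_stride),
                 stop_window = stop_window, gamma_override = gamma_override,
                 gamma_zero = isTRUE(gamma_zero), seed = as.integer(seed)),
            class = "sh_settings")
}

.apply_gamma_override <- function(params, settings) {
  ov <- settings$gamma_override
  if (!is.null(ov)) for (k in names(ov)) params[[k]] <- ov[[k]]
  params
}

#' Run one surface-hopping trajectory
#'
#' Velocity-Verlet nuclear propagation on the active adiabat (with
#' state-dependent Langevin coupling), local-diabatization electronic
#' propagation, fewest-switches hops with velocity rescaling along the
#' gradient-difference direction (frustrated hops leave the velocities
#' untouched), and energy-based decoherence. Stops at `t_max` or once the
#' trajectory has settled on S0 in one torsional basin for
#' `settings$stop_window` ps. Fully reproducible from (ic, seed).
#'
#' @param params `bv_model_params`
#' @param ic one row of [draw_initial_conditions()] output (or a list with
#'   `q` = c(theta6, theta5, r) and `p` = momenta)
#' @param settings an [sh_settings()] object
#' @param seed integer seed for this trajectory (defaults to `settings$seed`)
#' @return object of class `sh_trajectory`: list with `series` (data.frame),
#'   `hops` (data.frame of hop events), `final_state`, `final_theta6`,
#'   `initial` (the ic), `seed`, `valid`
#' @export
run_trajectory <- function(params, ic, settings = sh_settings(), seed = NULL) {
  params <- validate_model_parameters(.apply_gamma_override(params, settings))
  if (is.null(seed)) seed <- settings$seed
  if (inherits(ic, "data.frame")) {
    q0 <- c(ic$theta6_deg[1], ic$theta5_deg[1], ic$r_hb_A[1])
    p0 <- c(ic$p_theta6[1], ic$p_theta5[1], ic$p_r[1])
  } else {
    q0 <- ic$q
    p0 <- ic$p
  }
  res <- cpp_run_trajectory(params, q0, p0, 1L, settings$dt,
                            settings$t_max * 1000,
                            settings$decoherence_C,
                            if (is.null(settings$max_hop_gap)) -1 else settings$max_hop_gap,
                            settings$record_stride, as.numeric(seed),
                            settings$stop_window * 1000,
                            settings$gamma_zero)
  traj <- list(series = as.data.frame(res$series),
               hops = as.data.frame(res$hops),
               final_state = res$final_state,
               final_theta6 = res$final_theta6,
               final_theta5 = res$final_theta5,
               final_r = res$final_r,
               t_end_fs = res$t_end_fs,
               n_hops = res$n_hops,
               initial = list(q = q0, p = p0),
               seed = seed,
               valid = res$exit_code != 2L,
               exit_code = res$exit_code)
  class(traj) <- "sh_trajectory"
  traj
}

#' @export
print.sh_trajectory <- function(x, ...) {
  cat(sprintf("surface-hopping trajectory: %.2f ps, final state S%d, %d hop event(s)%s\n",
              x$t_end_fs / 1000, x$final_state, nrow(x$hops),
              if (!x$valid) " [INVALID]" else ""))
  invisible(x)
}

#' Run an ensemble of independent surface-hopping trajectories
#'
#' One counter-derived seed per trajectory (`seed + i`), so the ensemble is
#' reproducible and order-independent: permuting the initial conditions
#' permutes the trajectories identically.
#'
#' @param params `bv_model_params`
#' @param ics initial conditions from [draw_initial_conditions()]
#' @param settings [sh_settings()]
#' @param seeds optional explicit integer seed per trajectory
#' @return object of class `sh_ensemble`: list of `sh_trajectory` plus a
#'   `manifest` attribute (seeds, settings, failure count)
#' @export
run_ensemble <- function(params, ics, settings = sh_settings(), seeds = NULL) {
  n <- if (inherits(ics, "data.frame")) nrow(ics) else length(ics)
  if (is.null(seeds)) seeds <- settings$seed + seq_len(n)
  stopifnot(length(seeds) == n)
  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    ic_i <- if (inherits(ics, "data.frame")) ics[i, , drop = FALSE] else ics[[i]]
    trajs[[i]] <- run_trajectory(params, ic_i, settings, seed = seeds[i])
  }
  n_failed <- sum(!vapply(trajs, `[[`, logical(1), "valid"))
  structure(trajs, class = "sh_ensemble",
            manifest = list(seeds = seeds, settings = settings,
                            n = n, n_failed = n_failed))
}

#' @export
print.sh_ensemble <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("surface-hopping ensemble: %d trajectories (%d failed)\n",
              m$n, m$n_failed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pure-R reference pieces (mirrors of the engine's formulas, for tests and
# for inspecting the algorithm at the R level).

#' Fewest-switches hop probability from population flux
#'
#' Standard flux form: the probability of leaving the active state over one
#' step is the fractional population lost by the active state, clipped to
#' `[0, 1]`. If `max_hop_gap` is set and the current gap exceeds it, the hop
#' is forbidden (probability 0).
#'
#' @param pop_active_t,pop_active_tdt active-state populations before/after
#'   the electronic step
#' @param gap_eV current S0/S1 gap, eV
#' @param max_hop_gap optional gate, eV
#' @return hop probability in `[0, 1]`
#' @export
fssh_hop_probability <- function(pop_active_t, pop_active_tdt, gap_eV = 0,
                                 max_hop_gap = NULL) {
  if (!is.null(max_hop_gap) && gap_eV > max_hop_gap) return(0)
  if (pop_active_t <= 0) return(0)
  min(1, max(0, (pop_active_t - pop_active_tdt) / pop_active_t))
}

#' Energy-based decoherence damping of the non-active amplitude
#'
#' Non-active amplitudes decay with time constant
#' \eqn{\tau = (\hbar/|\Delta E|)(1 + C/E_{kin})}; the active amplitude is
#' rescaled to restore unit norm. Kinetic energy is floored at 1e-8 kcal/mol.
#'
#' @param coeffs complex length-2 coefficient vector (S0, S1)
#' @param active active state index (0 or 1)
#' @param gap |E1 - E0|, kcal/mol
#' @param ekin kinetic energy, kcal/mol
#' @param dt step, fs
#' @param C decoherence constant, kcal/mol
#' @return damped, renormalized complex coefficient vector
#' @export
apply_decoherence <- function(coeffs, active, gap, ekin, dt, C = 62.75) {
  stopifnot(length(coeffs) == 2)
  j <- 2 - active            # non-active index in 1-based R terms
  a <- active + 1
  ekin <- max(ekin, 1e-8)
  if (gap > 1e-12 && Mod(coeffs[j])^2 > 0) {
    tau <- (lumir_constants$hbar / gap) * (1 + C / ekin)
    coeffs[j] <- coeffs[j] * exp(-dt / tau)
    pj <- Mod(coeffs[j])^2
    pa <- Mod(coeffs[a])^2
    if (pa > 0) coeffs[a] <- coeffs[a] * sqrt((1 - pj) / pa)
  }
  coeffs
}
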