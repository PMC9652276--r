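# Ground-state thermal sampling on S0 and extraction of vertical-excitation
# initial conditions (the desk-scale stand-in for the 20 ps ground-state
# QM/MM trajectories from which the surface-hopping swarm was launched).

#' Specification of a ground-state sampling run
#'
#' @param variant `"set-A"` (full-strength His290 H-bond) or `"set-B"`
#'   (marginal H-bond); used to pick packaged parameters downstream and kept
#'   as metadata here.
#' @param n_frames number of frames to record (>= 1)
#' @param dt integration time step, fs
#' @param duration total run length, ps (the default 120 ps samples a window
#'   long against the ~1 ps hydrogen-bond correlation time, so the frame pool
#'   covers many independent pocket configurations)
#' @param equilibration discarded initial segment, ps (`< duration`)
#' @param seed integer RNG seed
#' @return list of class `ensemble_spec`
#' @export
ensemble_spec <- function(variant = c("set-A", "set-B"), n_frames = 2000,
                          dt = 0.1, duration = 120, equilibration = 10,
                          seed = 1) {
  variant <- match.arg(variant)
  stopifnot(n_frames >= 1, duration > equilibration, equilibration >= 0, dt > 0)
  structure(list(variant = variant, n_frames = n_frames, dt = dt,
                 duration = duration, equilibration = equilibration,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Ground-state molecular dynamics on the S0 surface
#'
#' Velocity-Verlet integration on the lower adiabat with a stochastic
#' velocity-rescaling (canonical sampling) thermostat at `params$T`. Frames
#' are recorded after the equilibration window at a fixed stride chosen to
#' return `spec$n_frames` frames. Bitwise reproducible for a given seed.
#'
#' @param params `bv_model_params`
#' @param spec an [ensemble_spec()]
#' @param start optional starting coordinates (defaults to the planar
#'   reactant geometry)
#' @return data.frame of class `md_frames` with columns `time_fs`,
#'   `theta6_deg`, `theta5_deg`, `r_hb_A`, `p_theta6`, `p_theta5`, `p_r`,
#'   `energy_kcal`
#' @export
ground_state_md <- function(params, spec, start = NULL) {
  params <- validate_model_parameters(params)
  stopifnot(inherits(spec, "ensemble_spec"))
  if (is.null(start)) start <- coords(0, 0, params$r0_hb)
  start <- .check_coords(start)
  n_steps <- round(spec$duration * 1000 / spec$dt)
  n_equil <- round(spec$equilibration * 1000 / spec$dt)
  stride <- max(1L, floor((n_steps - n_equil) / spec$n_frames))
  res <- cpp_ground_state_md(params,
                             c(start[["theta6"]], start[["theta5"]], start[["r_hb"]]),
                             c(0, 0, 0),
                             spec$dt, n_steps, n_equil, stride,
                             50.0, as.numeric(spec$seed))
  frames <- as.data.frame(res$frames)
  frames <- frames[seq_len(min(nrow(frames), spec$n_frames)), , drop = FALSE]
  attr(frames, "variant") <- spec$variant
  attr(frames, "params") <- params
  class(frames) <- c("md_frames", "data.frame")
  frames
}

#' Draw vertical-excitation initial conditions from sampled frames
#'
#' Each initial condition copies coordinates and momenta from a sampled frame,
#' places the system on S1 and sets the electronic coefficient vector to
#' (0, 1).
#'
#' @param frames an `md_frames` data.frame from [ground_state_md()]
#' @param n number of initial conditions
#' @param seed integer RNG seed (same seed, same selection)
#' @param replace sample with replacement? Without replacement requires
#'   `n <= nrow(frames)`.
#' @return data.frame of class `sh_initial_conditions` with the frame columns
#'   plus `ic_id` and `source_frame`
#' @export
draw_initial_conditions <- function(frames, n, seed = 1, replace = FALSE) {
  if (is.null(frames) || nrow(frames) == 0) stop("empty frame set")
  if (!replace && n > nrow(frames))
    stop("n exceeds available frames; set replace = TRUE to sample with replacement")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  idx <- sample.int(nrow(frames), n, replace = replace)
  ics <- frames[idx, c("theta6_deg", "theta5_deg", "r_hb_A",
                       "p_theta6", "p_theta5", "p_r"), drop = FALSE]
  ics$ic_id <- seq_len(n)
  ics$source_frame <- idx
  rownames(ics) <- NULL
  attr(ics, "variant") <- attr(frames, "variant")
  class(ics) <- c("sh_initial_conditions", "data.frame")
  ics
}
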