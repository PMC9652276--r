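# Reduced-dimensional two-state diabatic model of biliverdin D-ring
# photoisomerization. Coordinates: theta6 (C15=C16 double-bond torsion, deg),
# theta5 (C14-C15 single-bond torsion, deg), r_hb (D-ring carbonyl ... His290
# hydrogen-bond distance, A).

.param_names <- c(
  "E_vert", "V6_S1", "V6_S0", "V5", "chi",
  "theta6_CI", "w0", "sigma_w",
  "D_hb", "a_hb", "r0_hb", "lambda_hb",
  "theta_off", "w_cw", "k_cage", "r_cage",
  "h_strain", "theta_strain", "sigma_strain", "s6",
  "I6", "I5", "m_r",
  "gamma_s1", "T_s1", "gamma_s0", "T"
)

.nonneg_params <- c(
  "V6_S1", "V6_S0", "V5", "w0", "sigma_w", "D_hb", "a_hb", "lambda_hb",
  "w_cw", "k_cage", "h_strain", "sigma_strain", "s6", "I6", "I5", "m_r", "gamma_s1", "T_s1",
  "gamma_s0", "T"
)

#' Model parameters for the two-state biliverdin torsional Hamiltonian
#'
#' Constructs (and validates) the full parameter set of the reduced
#' three-coordinate model. Calling it with no arguments returns the packaged
#' set-A calibration (strong His290 H-bond); use
#' [packaged_parameters()] for the shipped variants.
#'
#' The diabatic matrix is
#' \deqn{V_{11} = \tfrac{V_6^{S0}}{2}\,[1-\cos(\theta_6-\delta(r))] -
#'   D_{hb}\mu(r) + V_5\sin^2\theta_5 + \chi\sin\theta_6\sin\theta_5 + cage
#'   + rep}
#' \deqn{V_{22} = E_{vert} - \tfrac{s_6 V_6^{S1}}{2}(1-\cos\theta_6)
#'   + W_{cw}(\theta_6) - \lambda_{hb} D_{hb}\,\mu(r)
#'   \left[\tfrac{1+\cos\theta_6}{2}\right]^2
#'   + V_5\sin^2\theta_5 + \chi\sin\theta_6\sin\theta_5 + cage + rep}
#' \deqn{V_{12} = w_0 \exp[-(\theta_6-\theta_6^{CI})^2/2\sigma_w^2]}
#' with \eqn{\mu(r) = 2e^{-a(r-r_0)} - e^{-2a(r-r_0)}} the Morse binding
#' profile, \eqn{\delta(r) = \theta_{off}(1-\mu(r))} the H-bond-controlled
#' ground-state planarity offset, a harmonic pocket cage plus a fixed
#' short-range repulsion on \eqn{r}, and \eqn{W_{cw}} a smooth wall closing
#' the clockwise (negative \eqn{\theta_6}) rotation channel. The planarity
#' factor \eqn{[(1+\cos\theta_6)/2]^2} stabilizes the planar Franck-Condon
#' region of the excited diabat in proportion to the H-bond binding, creating
#' the His290-controlled excited-state torsional barrier; it vanishes at the
#' rotated product.
#'
#' @param ... named parameter overrides; see Details for the field list.
#' @details Fields (units): `E_vert` vertical excitation energy (kcal/mol);
#'   `V6_S1`, `V6_S0` excited/ground-diabat D6 torsional amplitudes
#'   (kcal/mol); `V5` D5 amplitude (kcal/mol); `chi` hula-twist D5-D6
#'   coupling (kcal/mol); `theta6_CI` seam location (deg); `w0`, `sigma_w`
#'   diabatic coupling peak (kcal/mol) and width (deg); `D_hb`, `a_hb`,
#'   `r0_hb` H-bond Morse depth (kcal/mol), range (1/A) and equilibrium (A);
#'   `lambda_hb` dimensionless planarity coupling; `theta_off` ground-state
#'   D6 offset released when the H-bond is weak (deg); `w_cw`
#'   clockwise-wall amplitude (kcal/mol); `k_cage`, `r_cage` pocket cage
#'   (kcal/mol/A^2, A); `s6` D6 barrier scale factor; `I6`, `I5` torsional
#'   inertias (amu A^2); `m_r` H-bond reduced mass (amu); `gamma_s1`, `T_s1`
#'   excited-state bath friction (1/ps) and temperature (K); `gamma_s0`
#'   ground-state bath friction (1/ps); `T` temperature (K).
#' @return an object of class `bv_model_params` (a validated named list)
#' @seealso [packaged_parameters()], [torsional_barrier()],
#'   [locate_conical_intersection()]
#' @export
model_parameters <- function(...) {
  p <- .default_params_set_a()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .param_names)
    if (length(bad)) stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_model_parameters(p)
}

# Packaged set-A calibration (see the methods vignette for the procedure).
.default_params_set_a <- function() {
  list(
    E_vert = 55.0, V6_S1 = 46.0, V6_S0 = 57.05, V5 = 8.0, chi = 3.0,
    theta6_CI = 90.0, w0 = 0.80, sigma_w = 12.0,
    D_hb = 4.0, a_hb = 2.0, r0_hb = 1.9, lambda_hb = 7.5567830637,
    theta_off = 8.0, w_cw = 30.0, k_cage = 0.5, r_cage = 3.5,
    h_strain = 3.8, theta_strain = 112.7, sigma_strain = 8.0, s6 = 1.0,
    I6 = 110.0, I5 = 60.0, m_r = 12.0,
    gamma_s1 = 3.0, T_s1 = 750.0, gamma_s0 = 50.0, T = 300.0
  )
}

#' Validate a model parameter set
#'
#' @param p named list of parameters
#' @return the validated `bv_model_params` object
#' @export
validate_model_parameters <- function(p) {
  missing <- setdiff(.param_names, names(p))
  if (length(missing)) stop("missing model parameter(s): ", paste(missing, collapse = ", "))
  p <- p[.param_names]
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("non-finite model parameter(s): ",
                                  paste(names(vals)[!is.finite(vals)], collapse = ", "))
  neg <- .nonneg_params[unlist(p[.nonneg_params]) < 0]
  if (length(neg)) stop("negative value for non-negative parameter(s): ",
                        paste(neg, collapse = ", "))
  if (p$r0_hb <= 0) stop("r0_hb must be positive")
  structure(p, class = "bv_model_params")
}

#' @export
print.bv_model_params <- function(x, ...) {
  cat("Two-state biliverdin torsional model parameters\n")
  cat(sprintf("  E_vert %.2f kcal/mol | D_hb %.2f kcal/mol | lambda_hb %.3f | s6 %.4f\n",
              x$E_vert, x$D_hb, x$lambda_hb, x$s6))
  cat(sprintf("  coupling w0 %.3f kcal/mol at theta6 = %.0f deg (sigma %.1f deg)\n",
              x$w0, x$theta6_CI, x$sigma_w))
  cat(sprintf("  baths: S1 %.0f K / %.2f ps^-1, S0 %.0f K / %.2f ps^-1\n",
              x$T_s1, x$gamma_s1, x$T, x$gamma_s0))
  invisible(x)
}

#' Coordinates on the reduced model
#'
#' @param theta6,theta5 D6 and D5 torsion angles, degrees (wrapped to the
#'   principal branch (-180, 180])
#' @param r_hb O_D...His290 hydrogen-bond distance, Angstrom; must be > 0
#' @return named numeric vector of class `bv_coords`
#' @export
coords <- function(theta6, theta5, r_hb) {
  theta6 <- as.numeric(theta6); theta5 <- as.numeric(theta5)
  r_hb <- as.numeric(r_hb)
  if (any(!is.finite(c(theta6, theta5, r_hb)))) stop("non-finite coordinate")
  if (any(r_hb <= 0)) stop("r_hb must be strictly positive")
  structure(c(theta6 = wrap_angle(theta6), theta5 = wrap_angle(theta5),
              r_hb = r_hb), class = "bv_coords")
}

.check_coords <- function(x) {
  if (inherits(x, "bv_coords")) return(x)
  if (is.numeric(x) && length(x) == 3) return(coords(x[[1]], x[[2]], x[[3]]))
  stop("coordinates must be a bv_coords object or a numeric vector (theta6, theta5, r_hb)")
}

#' Diabatic Hamiltonian matrix at a geometry
#'
#' @param params a `bv_model_params` object
#' @param x coordinates ([coords()] or length-3 numeric)
#' @return symmetric 2x2 matrix (kcal/mol), rows/cols = (reactant-ground,
#'   excited-product) diabats
#' @export
diabatic_hamiltonian <- function(params, x) {
  params <- validate_model_parameters(params)
  x <- .check_coords(x)
  d <- cpp_diabatic(params, x[["theta6"]], x[["theta5"]], x[["r_hb"]])
  m <- matrix(c(d$V11, d$V12, d$V12, d$V22), 2, 2)
  dimnames(m) <- list(c("d1", "d2"), c("d1", "d2"))
  m
}

#' Adiabatic surfaces, gradients and mixing angle at a geometry
#'
#' Eigen-decomposition of the 2x2 diabatic matrix with analytic
#' (Hellmann-Feynman) gradients.
#'
#' @inheritParams diabatic_hamiltonian
#' @return list with `E0`, `E1`, `gap` (kcal/mol), `gap_eV`, `mixing_angle`
#'   (radians), and `grad0`/`grad1` (kcal/mol per degree for the torsions,
#'   per Angstrom for `r_hb`)
#' @export
adiabatic_surfaces <- function(params, x) {
  params <- validate_model_parameters(params)
  x <- .check_coords(x)
  a <- cpp_adiabatic(params, x[["theta6"]], x[["theta5"]], x[["r_hb"]])
  a$gap_eV <- a$gap / lumir_constants$kcal_per_ev
  names(a$grad0) <- names(a$grad1) <- c("theta6", "theta5", "r_hb")
  a
}

#' Locate the conical-intersection seam (minimum-gap point)
#'
#' Grid scan over (theta6, r_hb) — the S0/S1 gap of this Hamiltonian is
#' independent of theta5 because all theta5-dependent terms are common to the
#' two diabats — followed by Nelder-Mead refinement. When `w0 = 0` the seam is
#' a true diabatic crossing and the returned gap vanishes; for `w0 > 0` the
#' minimum-gap point of the adiabatic surfaces is returned. The search covers
#' the physically accessible pocket region (`r_hb` in `r_range`).
#'
#' @param params model parameters
#' @param theta6_range,r_range search box (deg, A)
#' @param gap_tol diagnostic threshold: error if no gap below `gap_tol`
#'   \* max(w0, 1) * 2 is found (kcal/mol)
#' @return list with `coords` (a [coords()] vector), `gap` (kcal/mol) and
#'   `gap_eV`
#' @export
locate_conical_intersection <- function(params,
                                        theta6_range = c(5, 175),
                                        r_range = c(1.7, 4.5),
                                        gap_tol = 50) {
  params <- validate_model_parameters(params)
  th <- seq(theta6_range[1], theta6_range[2], by = 1)
  r <- seq(r_range[1], r_range[2], by = 0.05)
  g <- expand.grid(theta6 = th, r_hb = r)
  gap <- cpp_adiabatic_grid(params, g$theta6, rep(0, nrow(g)), g$r_hb)[, "gap"]
  i <- which.min(gap)
  start <- c(g$theta6[i], g$r_hb[i])
  obj <- function(z) {
    z1 <- min(max(z[1], theta6_range[1]), theta6_range[2])
    z2 <- min(max(z[2], r_range[1]), r_range[2])
    cpp_adiabatic(params, z1, 0, z2)$gap
  }
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  best <- pmin(pmax(opt$par, c(theta6_range[1], r_range[1])),
               c(theta6_range[2], r_range[2]))
  gmin <- min(opt$value, gap[i])
  if (gmin > gap_tol) {
    stop(sprintf("no low-gap seam found: minimal gap reached = %.3f kcal/mol", gmin))
  }
  if (opt$value <= gap[i]) {
    out <- coords(best[1], 0, best[2])
    gv <- opt$value
  } else {
    out <- coords(g$theta6[i], 0, g$r_hb[i])
    gv <- gap[i]
  }
  list(coords = out, gap = gv, gap_eV = gv / lumir_constants$kcal_per_ev)
}

#' Relaxed torsional profile along D6
#'
#' At each theta6 grid point the energy of the requested adiabatic surface is
#' minimized over (theta5, r_hb), warm-started from the previous point.
#'
#' @param params model parameters
#' @param state `"S0"` or `"S1"`
#' @param theta6 grid of D6 values (deg)
#' @param theta5_start,r_start starting point for the inner minimization
#' @return data.frame with `theta6` and relaxed `energy`
#' @export
relaxed_torsional_profile <- function(params, state = c("S1", "S0"),
                                      theta6 = seq(-20, 90, by = 0.25),
                                      theta5_start = 0, r_start = NULL) {
  params <- validate_model_parameters(params)
  state <- match.arg(state)
  if (is.null(r_start)) r_start <- params$r0_hb
  e <- cpp_relaxed_profile(params, theta6, if (state == "S1") 1L else 0L,
                           theta5_start, r_start)
  data.frame(theta6 = theta6, energy = e)
}

#' Relaxed excited-state (or ground-state) D6 torsional barrier
#'
#' Relaxed scan on a fine theta6 grid between the Franck-Condon minimum and
#' the seam location `theta6_CI`; the barrier is the profile maximum minus the
#' profile minimum on the reactant side. Deterministic.
#'
#' @param params model parameters
#' @param state adiabatic surface, `"S1"` (default) or `"S0"`
#' @param grid_step theta6 grid spacing, degrees (<= 0.5)
#' @return barrier height, kcal/mol
#' @export
torsional_barrier <- function(params, state = c("S1", "S0"), grid_step = 0.25) {
  params <- validate_model_parameters(params)
  state <- match.arg(state)
  stopifnot(grid_step <= 0.5)
  prof <- relaxed_torsional_profile(
    params, state, theta6 = seq(-20, params$theta6_CI, by = grid_step))
  if (any(!is.finite(prof$energy)))
    stop("inner minimization failed at theta6 = ",
         prof$theta6[which(!is.finite(prof$energy))[1]], " deg")
  # Franck-Condon minimum: lowest point on the reactant side (theta6 < 60 deg)
  react <- prof$theta6 < 60
  i_min <- which(react)[which.min(prof$energy[react])]
  e_min <- prof$energy[i_min]
  after <- prof$energy[seq(i_min, nrow(prof))]
  max(after) - e_min
}

#' Rescale the model so the relaxed S1 D6 barrier matches a target
#'
#' Monotone search over the D6 barrier scale factor `s6` (the relaxed S1
#' barrier decreases monotonically with `s6`, which multiplies the S1 diabat's
#' torsional drive toward the product well); only `s6` changes.
#'
#' @param params model parameters
#' @param target requested relaxed S1 barrier, kcal/mol (> 0)
#' @param tol barrier tolerance (kcal/mol)
#' @return a `bv_model_params` copy with adjusted `s6`
#' @export
scale_d6_barrier <- function(params, target, tol = 0.01) {
  params <- validate_model_parameters(params)
  stopifnot(target > 0)
  f <- function(s6) {
    p <- params
    p$s6 <- s6
    torsional_barrier(p, "S1") - target
  }
  cur <- f(params$s6)
  if (abs(cur) <= tol) return(params)
  # the barrier decreases with s6 while the product drive still dominates the
  # seam region, then grows again once the crossing moves inside theta6_CI;
  # search the physical (decreasing) branch only
  grid <- exp(seq(log(0.1), log(20), length.out = 25))
  fb <- vapply(grid, f, numeric(1))
  i_min <- which.min(fb)
  dec <- seq_len(i_min)
  if (max(fb[dec]) < 0 || min(fb[dec]) > 0)
    stop(sprintf("target barrier %.2f kcal/mol unreachable with s6 in [0.1, 20]", target))
  i_hi <- which(fb[dec] <= 0)[1]
  root <- uniroot(f, c(grid[i_hi - 1], grid[i_hi]), tol = 1e-5)
  out <- params
  out$s6 <- root$root
  achieved <- torsional_barrier(out, "S1")
  if (abs(achieved - target) > tol)
    stop(sprintf("barrier scaling did not converge: achieved %.4f, target %.4f",
                 achieved, target))
  out
}

# ---------------------------------------------------------------------------
# Parameter file IO: flat key-value YAML, keys = ModelParameters field names.

#' Read model parameters from a flat key-value YAML file
#'
#' @param path file path
#' @return `bv_model_params`
#' @export
load_model_parameters <- function(path) {
  p <- yaml::read_yaml(path)
  p <- p[!vapply(p, is.character, logical(1))] # drop annotation fields
  validate_model_parameters(p)
}

#' Write model parameters to a flat key-value YAML file
#'
#' @param params `bv_model_params`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_model_parameters <- function(params, path) {
  params <- validate_model_parameters(params)
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' Packaged model parameter sets
#'
#' `"set-A"` carries the full-strength D-ring carbonyl to His290 hydrogen bond;
#' `"set-B"` only marginally features it (same topology, weak Morse depth).
#' Both are the frozen output of the calibration procedure described in the
#' methods vignette.
#'
#' @param variant `"set-A"` or `"set-B"`
#' @return `bv_model_params`
#' @export
packaged_parameters <- function(variant = c("set-A", "set-B")) {
  variant <- match.arg(variant)
  file <- if (variant == "set-A") "params_set_a.yaml" else "params_set_b.yaml"
  path <- system.file("extdata", file, package = "lumir")
  if (!nzchar(path)) stop("packaged parameter file not found: ", file)
  load_model_parameters(path)
}
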