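# Physical constants in the package's internal unit system
# (kcal/mol, amu, Angstrom, fs, degrees at the interface).

#' Unit and physical constants used by the model
#'
#' Energy is carried in kcal/mol, distances in Angstrom, time in fs and
#' angles in degrees at every user-facing interface. The only place eV
#' appears is the surface-hopping energy-gap gate.
#'
#' @format A named list with elements
#' \describe{
#'   \item{kcal_per_ev}{1 eV in kcal/mol (23.0609)}
#'   \item{kB}{Boltzmann constant, kcal/mol/K}
#'   \item{hbar}{reduced Planck constant, kcal/mol * fs}
#'   \item{kcal_per_mech}{1 amu A^2 / fs^2 in kcal/mol}
#' }
#' @export
lumir_constants <- list(
  kcal_per_ev = 23.0609,
  kB = 0.0019872041,
  hbar = 15.17873,
  kcal_per_mech = 2390.0574
)

#' Wrap an angle to the principal branch (-180, 180]
#'
#' @param theta angle(s) in degrees
#' @return wrapped angle(s) in degrees
#' @export
wrap_angle <- function(theta) {
  th <- (theta + 180) %% 360 - 180
  th[th == -180] <- 180
  th
}
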