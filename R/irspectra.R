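# Surrogate IR calculator for the carbonyl-stretch region (CO_D and CO_A).
# Per-frame frequencies come from an additive frequency map driven by the
# hydrogen-bond environment of each frame; spectra are sums of Lorentzian
# lines on a fixed wavenumber grid. The map values are package conventions
# that reproduce the sign structure of the early Lumi-R minus Pr difference
# spectrum; they are not quantum-chemical results.

#' Additive carbonyl frequency map
#'
#' @param nu0_COD,nu0_COA base stretch frequencies of the free carbonyls,
#'   1/cm
#' @param shift_isomerized offset applied to CO_D in isomerized (Lumi-R)
#'   frames, 1/cm
#' @param shift_water shift when a water molecule H-bonds CO_D, 1/cm
#' @param shift_his290 shift when His290 H-bonds CO_D, 1/cm
#' @param shift_isomerized_COA isomerization offset of CO_A, 1/cm
#' @param width_COD,width_COA Lorentzian half-widths at half maximum, 1/cm
#' @param intensity_COD,intensity_COA band intensity factors
#' @param his290_cutoff distance criterion for the His290 H-bond, Angstrom
#' @return list of class `frequency_map`
#' @export
frequency_map <- function(nu0_COD = 1710, nu0_COA = 1745,
                          shift_isomerized = -23, shift_water = +13,
                          shift_his290 = -7, shift_isomerized_COA = -3,
                          width_COD = 6, width_COA = 6,
                          intensity_COD = 1, intensity_COA = 0.35,
                          his290_cutoff = 3.5) {
  stopifnot(nu0_COD > 0, nu0_COA > 0, width_COD > 0, width_COA > 0)
  structure(list(nu0_COD = nu0_COD, nu0_COA = nu0_COA,
                 shift_isomerized = shift_isomerized,
                 shift_water = shift_water, shift_his290 = shift_his290,
                 shift_isomerized_COA = shift_isomerized_COA,
                 width_COD = width_COD, width_COA = width_COA,
                 intensity_COD = intensity_COD, intensity_COA = intensity_COA,
                 his290_cutoff = his290_cutoff),
            class = "frequency_map")
}

#' Per-frame carbonyl stretch frequencies
#'
#' \eqn{\nu = \nu_0 + \sum \textrm{active feature shifts}}: the water H-bond
#' to CO_D (indicator `water_bridge_OD`, or `OD_water` below 2.4 Angstrom),
#' the His290 H-bond (`OD_His290` below the map cutoff) and the
#' isomerized-chromophore offset.
#'
#' @param frames pocket feature data.frame
#' @param map a [frequency_map()]
#' @param isomerized is this an isomerized (Lumi-R) ensemble? (the Pr
#'   reference uses `FALSE`)
#' @return data.frame with `nu_COD`, `nu_COA`, 1/cm
#' @export
frame_frequencies <- function(frames, map = frequency_map(), isomerized = TRUE) {
  if (!is.null(frames$water_bridge_OD)) {
    water <- as.logical(frames$water_bridge_OD)
  } else if (!is.null(frames$OD_water)) {
    water <- frames$OD_water < 2.4
  } else stop("missing indicator: need water_bridge_OD or OD_water")
  if (is.null(frames$OD_His290)) stop("missing indicator: need OD_His290")
  his <- frames$OD_His290 < map$his290_cutoff
  nu_cod <- map$nu0_COD +
    ifelse(isomerized, map$shift_isomerized, 0) +
    ifelse(water, map$shift_water, 0) +
    ifelse(his, map$shift_his290, 0)
  nu_coa <- map$nu0_COA + ifelse(isomerized, map$shift_isomerized_COA, 0)
  data.frame(nu_COD = nu_cod, nu_COA = nu_coa)
}

#' Spectrum grid constructor
#'
#' @param wavenumber strictly increasing grid, 1/cm
#' @param intensity intensities (absorption spectra are non-negative;
#'   difference spectra may be signed)
#' @param metadata free-form list
#' @return data.frame of class `spectrum_grid`
#' @export
spectrum_grid <- function(wavenumber, intensity, metadata = list()) {
  if (any(diff(wavenumber) <= 0)) stop("wavenumber grid must be strictly increasing")
  if (length(intensity) != length(wavenumber)) stop("grid/intensity length mismatch")
  out <- data.frame(wavenumber = wavenumber, intensity = intensity)
  attr(out, "metadata") <- metadata
  class(out) <- c("spectrum_grid", "data.frame")
  out
}

#' Ensemble IR spectrum by Lorentzian broadening
#'
#' One Lorentzian per frame per band, summed on the grid; the stick list is
#' kept in the metadata.
#'
#' @param frames pocket feature data.frame (>= 1 frame)
#' @param map [frequency_map()]
#' @param grid wavenumber grid, 1/cm
#' @param isomerized passed to [frame_frequencies()]
#' @param normalize `"none"` (default) or `"peak"` (maximum set to 1)
#' @return `spectrum_grid`
#' @export
ensemble_spectrum <- function(frames, map = frequency_map(),
                              grid = seq(1650, 1760, by = 0.5),
                              isomerized = TRUE, normalize = c("none", "peak")) {
  normalize <- match.arg(normalize)
  if (nrow(frames) < 1) stop("need at least one frame")
  nu <- frame_frequencies(frames, map, isomerized)
  lorentz_sum <- function(centers, width, weight) {
    s <- numeric(length(grid))
    for (c0 in centers) s <- s + 1 / (1 + ((grid - c0) / width)^2)
    s * weight
  }
  y <- lorentz_sum(nu$nu_COD, map$width_COD, map$intensity_COD) +
       lorentz_sum(nu$nu_COA, map$width_COA, map$intensity_COA)
  y <- y / nrow(frames)
  if (normalize == "peak" && max(y) > 0) y <- y / max(y)
  spectrum_grid(grid, y,
                metadata = list(n_frames = nrow(frames),
                                sticks_COD = nu$nu_COD, sticks_COA = nu$nu_COA,
                                isomerized = isomerized, normalize = normalize))
}

#' Weighted average of spectra on a common grid
#'
#' Weights are normalized to sum to one; the result is the pointwise convex
#' combination.
#'
#' @param spectra list of `spectrum_grid` objects on the same grid
#' @param weights non-negative weights, one per spectrum
#' @return `spectrum_grid`
#' @export
weighted_average <- function(spectra, weights) {
  stopifnot(length(spectra) == length(weights), all(weights >= 0), sum(weights) > 0)
  g0 <- spectra[[1]]$wavenumber
  for (s in spectra[-1])
    if (!isTRUE(all.equal(s$wavenumber, g0))) stop("spectrum grid mismatch")
  w <- weights / sum(weights)
  y <- Reduce(`+`, Map(function(s, wi) wi * s$intensity, spectra, w))
  spectrum_grid(g0, y, metadata = list(weights = w))
}

#' Difference spectrum (sample minus reference) with optional rigid shift
#'
#' The sample spectrum is rigidly shifted by `shift_cm1` (linear
#' re-interpolation onto the common grid; the paper-style use is the 8 1/cm
#' shift that aligns calculated spectra with experiment in D2O) before
#' subtracting the reference.
#'
#' @param sample,reference `spectrum_grid` objects on the same grid
#' @param shift_cm1 rigid shift applied to the sample, 1/cm
#' @return signed `spectrum_grid`; metadata records the shift
#' @export
difference_spectrum <- function(sample, reference, shift_cm1 = 0) {
  if (!isTRUE(all.equal(sample$wavenumber, reference$wavenumber)))
    stop("spectrum grid mismatch")
  y <- sample$intensity
  if (shift_cm1 != 0) {
    y <- approx(sample$wavenumber + shift_cm1, y, xout = sample$wavenumber,
                rule = 1)$y
    y[is.na(y)] <- 0
  }
  spectrum_grid(sample$wavenumber, y - reference$intensity,
                metadata = list(shift_cm1 = shift_cm1))
}

#' Normalize a spectrum to the peak of a named reference spectrum
#'
#' Implements the cluster-comparison convention of scaling all spectra to the
#' highest peak of one of them.
#'
#' @param spectrum `spectrum_grid` to rescale
#' @param reference `spectrum_grid` supplying the peak
#' @return rescaled `spectrum_grid`
#' @export
normalize_to_reference <- function(spectrum, reference) {
  peak <- max(reference$intensity)
  if (peak <= 0) stop("reference spectrum has no positive peak")
  spectrum_grid(spectrum$wavenumber, spectrum$intensity / peak,
                metadata = c(attr(spectrum, "metadata"),
                             list(normalized_to_peak = peak)))
}
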