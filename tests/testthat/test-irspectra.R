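# Surrogate IR: frequency map, Lorentzian spectra, weighted averages,
# difference spectra.

test_that("frame frequencies are the additive map, hand-summed", {
  map <- frequency_map()
  base <- data.frame(OD_His290 = 5, OD_water = 5, water_bridge_OD = FALSE)
  nu <- frame_frequencies(base, map, isomerized = FALSE)
  expect_equal(nu$nu_COD, map$nu0_COD)
  expect_equal(nu$nu_COA, map$nu0_COA)
  wet <- data.frame(OD_His290 = 5, OD_water = 1.9, water_bridge_OD = TRUE)
  nu <- frame_frequencies(wet, map, isomerized = TRUE)
  expect_equal(nu$nu_COD, map$nu0_COD + map$shift_isomerized + map$shift_water)
  his <- data.frame(OD_His290 = 2.0, OD_water = 5, water_bridge_OD = FALSE)
  nu <- frame_frequencies(his, map, isomerized = FALSE)
  expect_equal(nu$nu_COD, map$nu0_COD + map$shift_his290)
  expect_error(frame_frequencies(data.frame(x = 1), map), "indicator")
})

test_that("a single frame gives one Lorentzian peaked at its frequency", {
  map <- frequency_map()
  fr <- data.frame(OD_His290 = 5, OD_water = 1.9, water_bridge_OD = TRUE)
  sp <- ensemble_spectrum(fr, map, isomerized = TRUE)
  nu <- frame_frequencies(fr, map, TRUE)$nu_COD
  peak <- sp$wavenumber[which.max(sp$intensity)]
  expect_lt(abs(peak - nu), 0.5 + 1e-9) # within grid resolution
  expect_true(all(sp$intensity >= 0))
})

test_that("spectra are additive in frames (linearity before normalization)", {
  map <- frequency_map()
  f1 <- data.frame(OD_His290 = 5, OD_water = 1.9, water_bridge_OD = TRUE)
  f2 <- data.frame(OD_His290 = 5, OD_water = 4.5, water_bridge_OD = FALSE)
  s1 <- ensemble_spectrum(f1, map)
  s2 <- ensemble_spectrum(f2, map)
  s12 <- ensemble_spectrum(rbind(f1, f2), map)
  # per-frame normalization: the 2-frame spectrum is the mean of the two
  expect_equal(s12$intensity, (s1$intensity + s2$intensity) / 2,
               tolerance = 1e-12)
  # integral doubles before the per-frame normalization
  expect_equal(sum(s12$intensity) * 2, sum(s1$intensity) + sum(s2$intensity),
               tolerance = 1e-9)
})

test_that("cluster spectra reproduce the documented band structure", {
  cfg <- pocket_generator_config()
  fr <- generate_early_ensemble(cfg, 12000, seed = 21)
  map <- frequency_map()
  sp <- lapply(0:2, function(k)
    ensemble_spectrum(fr[fr$hidden_cluster == k, ], map))
  peak_at <- function(s) s$wavenumber[which.max(s$intensity)]
  # Cl2's main carbonyl peak sits near Cl0's (water-bonded position), while
  # Cl1 (water bond lost) peaks elsewhere
  expect_lt(abs(peak_at(sp[[1]]) - peak_at(sp[[3]])), 4)
  expect_gt(abs(peak_at(sp[[2]]) - peak_at(sp[[1]])), 6)
  # water-bonded frames sit at higher frequency than water-free Cl1 frames
  expect_gt(peak_at(sp[[1]]), peak_at(sp[[2]]))
})

test_that("weighted averaging is convex, exact on constants, permutation-safe", {
  g <- seq(1650, 1760, by = 0.5)
  const <- function(v) spectrum_grid(g, rep(v, length(g)))
  s <- list(const(1), const(2), const(3))
  avg <- weighted_average(s, c(0.18, 0.81, 0.01))
  expect_true(all(abs(avg$intensity - 1.83) < 1e-12))
  # weights (1, 0, 0) returns the first spectrum exactly
  expect_equal(weighted_average(s, c(1, 0, 0))$intensity, s[[1]]$intensity)
  # permutation invariance under paired reordering
  avg2 <- weighted_average(s[c(2, 3, 1)], c(0.81, 0.01, 0.18))
  expect_equal(avg$intensity, avg2$intensity, tolerance = 1e-12)
  # unnormalized weights are normalized
  avg3 <- weighted_average(s, c(18, 81, 1))
  expect_equal(avg$intensity, avg3$intensity, tolerance = 1e-12)
  expect_error(weighted_average(list(const(1), spectrum_grid(g + 1, g * 0)),
                                c(1, 1)), "mismatch")
})

test_that("difference spectra subtract, shift and vanish on self-difference", {
  g <- seq(1650, 1760, by = 0.5)
  cfg <- pocket_generator_config()
  fr <- generate_early_ensemble(cfg, 2000, seed = 22)
  map <- frequency_map()
  sp <- ensemble_spectrum(fr, map)
  self <- difference_spectrum(sp, sp, shift_cm1 = 0)
  expect_true(all(self$intensity == 0))
  # a rigid 8 1/cm shift moves the extremum by 8 within the grid step
  single <- ensemble_spectrum(fr[1, , drop = FALSE], map)
  shifted <- difference_spectrum(single, spectrum_grid(g, rep(0, length(g))),
                                 shift_cm1 = 8)
  p0 <- single$wavenumber[which.max(single$intensity)]
  p1 <- shifted$wavenumber[which.max(shifted$intensity)]
  expect_lt(abs((p1 - p0) - 8), 0.5 + 1e-9)
  # toy two-point arithmetic
  a <- spectrum_grid(c(1, 2), c(5, 1))
  b <- spectrum_grid(c(1, 2), c(2, 3))
  expect_equal(difference_spectrum(a, b)$intensity, c(3, -2))
})

test_that("the early-Lumi-R minus Pr difference has the documented sign structure", {
  cfg <- pocket_generator_config()
  map <- frequency_map()
  early <- generate_early_ensemble(cfg, 12000, seed = 23)
  pr <- generate_pr_reference(cfg, 8000, seed = 24)
  cl_spectra <- lapply(0:2, function(k)
    ensemble_spectrum(early[early$hidden_cluster == k, ], map))
  avg <- weighted_average(cl_spectra, cfg$cluster_weights)
  pr_sp <- ensemble_spectrum(pr, map, isomerized = FALSE)
  diff <- difference_spectrum(avg, pr_sp)
  # restrict to the CO_D region
  cod <- diff$wavenumber < 1730
  pos_at <- diff$wavenumber[cod][which.max(diff$intensity[cod])]
  neg_at <- diff$wavenumber[cod][which.min(diff$intensity[cod])]
  expect_gt(max(diff$intensity[cod]), 0)
  expect_lt(min(diff$intensity[cod]), 0)
  # the positive (Lumi-R) lobe lies below the negative (Pr) lobe
  expect_lt(pos_at, neg_at)
})

test_that("normalization to a reference peak follows the cluster convention", {
  g <- seq(1650, 1760, by = 0.5)
  ref <- spectrum_grid(g, 2 * exp(-(g - 1700)^2 / 50))
  s <- spectrum_grid(g, exp(-(g - 1690)^2 / 50))
  ns <- normalize_to_reference(s, ref)
  expect_equal(max(normalize_to_reference(ref, ref)$intensity), 1)
  expect_equal(ns$intensity, s$intensity / 2)
})
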