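# Surface-hopping engine: electronic propagation, norm and energy
# conservation, hop mechanics, decoherence, reproducibility.

test_that("uncoupled model keeps populations constant and never hops", {
  p <- model_parameters(w0 = 0)
  ic <- list(q = c(10, 0, p$r0_hb), p = c(0.02, 0, 0))
  tr <- run_trajectory(p, ic, sh_settings(t_max = 2, seed = 3))
  expect_equal(nrow(tr$hops), 0L)
  expect_identical(tr$final_state, 1L)
  expect_true(all(abs(tr$series$pop_S1 - 1) < 1e-12))
})

test_that("electronic norm is conserved at every stored step", {
  p <- packaged_parameters("set-A")
  ic <- list(q = c(5, -2, p$r0_hb), p = c(0.05, 0, 0))
  tr <- run_trajectory(p, ic, sh_settings(t_max = 5, seed = 17))
  expect_true(all(tr$series$pop_S1 >= -1e-8 & tr$series$pop_S1 <= 1 + 1e-8))
})

test_that("microcanonical propagation conserves energy to 1e-3 kcal/mol over 10 ps", {
  p <- model_parameters(w0 = 0) # stay on S1; no hops, no friction
  ic <- list(q = c(8, -4, p$r0_hb + 0.05), p = c(0.03, -0.02, 0.01))
  tr <- run_trajectory(p, ic, sh_settings(t_max = 10, seed = 1,
                                          gamma_zero = TRUE,
                                          record_stride = 100L))
  drift <- max(abs(tr$series$energy_kcal - tr$series$energy_kcal[1]))
  expect_lt(drift, 1e-3)
})

test_that("local-diabatization step matches a 100x-substepped reference", {
  # per-step changes of realistic magnitude for dt = 0.1 fs dynamics
  cre <- c(sqrt(0.3), sqrt(0.7)); cim <- c(0, 0)
  one <- cpp_ld_propagate(cre, cim, 0, 25, 0.02, 24.94, 5e-4, 0.1, 1L)
  ref <- cpp_ld_propagate(cre, cim, 0, 25, 0.02, 24.94, 5e-4, 0.1, 100L)
  expect_lt(max(abs(one - ref)), 1e-6)
  # unitarity
  expect_equal(sum(one[, 1]^2 + one[, 2]^2), 1, tolerance = 1e-12)
})

test_that("fewest-switches probability: flux form, clipping, gap gate", {
  expect_identical(fssh_hop_probability(0.8, 0.8), 0)
  expect_identical(fssh_hop_probability(0.8, 0.9), 0)        # inflow, not outflow
  expect_equal(fssh_hop_probability(0.8, 0.6), 0.25)
  expect_identical(fssh_hop_probability(0.5, -1), 1)          # clipped to 1
  expect_identical(fssh_hop_probability(0.8, 0.2, gap_eV = 0.6,
                                        max_hop_gap = 0.5), 0)
  expect_equal(fssh_hop_probability(0.8, 0.2, gap_eV = 0.4,
                                    max_hop_gap = 0.5), 0.75)
  # Monte-Carlo frequency oracle at p = 0.3
  set.seed(99)
  hops <- sum(runif(1e5) < fssh_hop_probability(1, 0.7))
  sigma <- sqrt(1e5 * 0.3 * 0.7)
  expect_lt(abs(hops - 0.3e5), 3 * sigma)
})

test_that("a tiny hop gate forbids all hops", {
  p <- packaged_parameters("set-A")
  fr <- ground_state_md(p, ensemble_spec("set-A", n_frames = 100, seed = 6))
  ics <- draw_initial_conditions(fr, 5, seed = 7)
  ens <- run_ensemble(p, ics, sh_settings(t_max = 3, seed = 2,
                                          max_hop_gap = 1e-9))
  for (tr in ens) {
    expect_identical(tr$final_state, 1L)
    expect_true(!any(tr$hops$accepted))
  }
})

test_that("hops conserve total energy exactly (rescaling bookkeeping)", {
  # no friction anywhere: any energy change beyond integrator error must come
  # from hop bookkeeping; the small step isolates it (Verlet error ~ dt^2,
  # a rescaling error would be gap-sized and dt-independent)
  p <- packaged_parameters("set-A")
  fr <- ground_state_md(p, ensemble_spec("set-A", n_frames = 500, seed = 16))
  ics <- draw_initial_conditions(fr, 30, seed = 3)
  ens <- run_ensemble(p, ics, sh_settings(dt = 0.02, t_max = 6, seed = 5,
                                          gamma_zero = TRUE,
                                          record_stride = 50L))
  n_hops <- 0
  for (tr in ens) {
    if (any(tr$hops$accepted)) {
      n_hops <- n_hops + sum(tr$hops$accepted)
      # energy through the first seam hop and the following 0.5 ps; without
      # friction the later wandering can reach the uncoupled high-energy
      # crossing on the blocked clockwise side, where an adiabatic
      # integrator is expected to accumulate error, so only funnel hops
      # (D6 in the seam region) are scored
      seam <- tr$hops$accepted & tr$hops$theta6_deg > 45 &
        tr$hops$theta6_deg < 135
      if (!any(seam)) next
      t_hop <- tr$hops$time_fs[seam][1]
      # a rescaling error would appear instantaneously and be of the order
      # of the gap; 150 fs on either side brackets the hop while staying
      # clear of the wrap-side trivial crossing that frictionless product
      # flights can reach
      win <- tr$series$time_fs >= t_hop - 150 & tr$series$time_fs <= t_hop + 150
      e <- tr$series$energy_kcal[win]
      expect_lt(max(abs(e - e[1])), 1e-3)
    }
  }
  expect_gt(n_hops, 5) # the check exercised real hops
})

test_that("energy-based decoherence matches the closed form and restores the norm", {
  hbar <- lumir_constants$hbar
  c0 <- complex(real = c(sqrt(0.2), sqrt(0.8)), imaginary = c(0, 0))
  out <- apply_decoherence(c0, active = 1, gap = 10, ekin = 5, dt = 0.1,
                           C = 62.75)
  tau <- (hbar / 10) * (1 + 62.75 / 5)
  expect_equal(Mod(out[1]), sqrt(0.2) * exp(-0.1 / tau), tolerance = 1e-12)
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  # already-collapsed coefficients are unchanged
  c1 <- complex(real = c(0, 1), imaginary = c(0, 0))
  expect_identical(apply_decoherence(c1, 1, 10, 5, 0.1), c1)
})

test_that("trajectories are bitwise reproducible and ensembles order-independent", {
  p <- packaged_parameters("set-A")
  fr <- ground_state_md(p, ensemble_spec("set-A", n_frames = 200, seed = 8))
  ics <- draw_initial_conditions(fr, 4, seed = 9)
  t1 <- run_trajectory(p, ics[2, ], sh_settings(t_max = 4), seed = 77)
  t2 <- run_trajectory(p, ics[2, ], sh_settings(t_max = 4), seed = 77)
  expect_identical(t1$series, t2$series)
  expect_identical(t1$hops, t2$hops)
  ens <- run_ensemble(p, ics, sh_settings(t_max = 3, seed = 1),
                      seeds = 201:204)
  perm <- c(3, 1, 4, 2)
  ens_p <- run_ensemble(p, ics[perm, ], sh_settings(t_max = 3, seed = 1),
                        seeds = (201:204)[perm])
  for (i in seq_along(perm))
    expect_identical(ens_p[[i]]$series, ens[[perm[i]]]$series)
})

test_that("empty ensembles are empty", {
  p <- model_parameters()
  ens <- run_ensemble(p, list(), sh_settings())
  expect_length(ens, 0)
  expect_identical(attr(ens, "manifest")$n_failed, 0L)
})
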