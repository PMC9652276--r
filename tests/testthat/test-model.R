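# Model Hamiltonian: closed form, adiabats, gradients, seam, barrier.

test_that("diabatic matrix matches an independent closed-form evaluation", {
  p <- model_parameters()
  # independent R transcription of the documented functional form
  ref_diab <- function(p, th6, th5, r) {
    th6d <- wrap_angle(th6)
    th6 <- th6d * pi / 180; th5 <- th5 * pi / 180
    x <- p$a_hb * (r - p$r0_hb)
    mu <- 2 * exp(-x) - exp(-2 * x)
    delta <- p$theta_off * pi / 180 * (1 - mu)
    common <- p$V5 * sin(th5)^2 + p$chi * sin(th6) * sin(th5) +
      0.5 * p$k_cage * (r - p$r_cage)^2 + 50 * exp(-8 * (r - 0.8)) +
      p$h_strain * exp(-0.5 * ((th6 - p$theta_strain * pi / 180) /
                                 (p$sigma_strain * pi / 180))^2)
    v11 <- 0.5 * p$V6_S0 * (1 - cos(th6 - delta)) - p$D_hb * mu + common
    uu <- 0.5 * (1 + cos(th6))
    sig <- 1 / (1 + exp(th6 / (10 * pi / 180)))
    v22 <- p$E_vert - 0.5 * p$s6 * p$V6_S1 * (1 - cos(th6)) +
      p$w_cw * sin(th6)^2 * sig - p$lambda_hb * p$D_hb * mu * uu^2 + common
    v12 <- p$w0 * exp(-0.5 * ((th6d - p$theta6_CI) / p$sigma_w)^2)
    matrix(c(v11, v12, v12, v22), 2, 2)
  }
  for (x in list(c(0, 0, 1.9), c(45, -10, 2.2), c(95, -25, 3.1),
                 c(-120, 30, 1.7), c(170, 5, 4.0))) {
    expect_equal(unname(diabatic_hamiltonian(p, x)),
                 ref_diab(p, x[1], x[2], x[3]), tolerance = 1e-10)
  }
})

test_that("coupling vanishes far from the seam and w0 = 0 gives a diagonal matrix", {
  p <- model_parameters()
  h <- diabatic_hamiltonian(p, coords(p$theta6_CI - 6 * p$sigma_w, 0, 2))
  expect_lt(abs(h[1, 2]), 1e-6 * p$w0)
  p0 <- model_parameters(w0 = 0)
  for (th in c(-150, -60, 0, 60, 90, 150))
    expect_identical(diabatic_hamiltonian(p0, coords(th, 0, 2))[1, 2], 0)
})

test_that("adiabatic energies agree with eigen() and are ordered", {
  p <- model_parameters()
  set.seed(4)
  for (i in 1:40) {
    x <- coords(runif(1, -180, 180), runif(1, -60, 60), runif(1, 1.2, 5))
    a <- adiabatic_surfaces(p, x)
    ev <- eigen(diabatic_hamiltonian(p, x), symmetric = TRUE)$values
    expect_equal(a$E0, min(ev), tolerance = 1e-10)
    expect_equal(a$E1, max(ev), tolerance = 1e-10)
    expect_gte(a$gap, 0)
  }
})

test_that("analytic gradients match central finite differences to 1e-6 relative", {
  p <- model_parameters()
  set.seed(11)
  hstep <- 1e-4
  worst <- 0
  for (i in 1:100) {
    x <- c(runif(1, -170, 170), runif(1, -60, 60), runif(1, 1.3, 4.5))
    a <- adiabatic_surfaces(p, x)
    for (k in 1:3) {
      cd <- function(h, which) {
        xp <- x; xm <- x
        xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
        (adiabatic_surfaces(p, xp)[[which]] -
           adiabatic_surfaces(p, xm)[[which]]) / (2 * h)
      }
      # Richardson-extrapolated central differences (steps 1e-4 and 5e-5)
      # cancel the h^2 truncation term, which matters near the low-gap seam
      fd0 <- (4 * cd(hstep / 2, "E0") - cd(hstep, "E0")) / 3
      fd1 <- (4 * cd(hstep / 2, "E1") - cd(hstep, "E1")) / 3
      worst <- max(worst, abs(a$grad0[k] - fd0) / max(abs(fd0), 1),
                   abs(a$grad1[k] - fd1) / max(abs(fd1), 1))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("all energies are periodic in the torsions", {
  p <- model_parameters()
  for (x in list(c(10, 5, 2), c(100, -20, 3), c(-170, 40, 1.8))) {
    h1 <- diabatic_hamiltonian(p, coords(x[1], x[2], x[3]))
    h2 <- diabatic_hamiltonian(p, coords(x[1] + 360, x[2] - 360, x[3]))
    expect_equal(h1, h2, tolerance = 1e-12)
  }
})

test_that("coordinates validate their domain", {
  expect_error(coords(0, 0, -1), "r_hb")
  expect_error(coords(NA, 0, 2), "non-finite")
  expect_equal(coords(190, 0, 2)[["theta6"]], -170)
  expect_error(model_parameters(D_hb = -1), "negative")
  expect_error(model_parameters(nonsense = 2), "unknown")
})

test_that("seam location: packaged set near 90 deg; w0 = 0 crossing is exact", {
  p <- packaged_parameters("set-A")
  ci <- locate_conical_intersection(p)
  expect_lt(abs(abs(ci$coords[["theta6"]]) - 90), 10)
  # minimality against the scan grid
  th <- seq(5, 175, by = 1)
  g <- expand.grid(theta6 = th, r = seq(1.7, 4.5, by = 0.05))
  gaps <- cpp_adiabatic_grid(p, g$theta6, rep(0, nrow(g)), g$r)[, "gap"]
  expect_lte(ci$gap, min(gaps) + 1e-9)
  # with the coupling switched off the seam is a true degeneracy, and its
  # position matches an independent bisection of the diabatic crossing
  p0 <- model_parameters(w0 = 0)
  ci0 <- locate_conical_intersection(p0)
  expect_lt(ci0$gap, 1e-6)
  r_star <- ci0$coords[["r_hb"]]
  f <- function(th) {
    h <- diabatic_hamiltonian(p0, coords(th, 0, r_star))
    h[1, 1] - h[2, 2]
  }
  th_star <- uniroot(f, c(60, 130), tol = 1e-10)$root
  expect_equal(ci0$coords[["theta6"]], th_star, tolerance = 1e-3)
})

test_that("relaxed S1 barrier: packaged value, closed-form limit, grid refinement", {
  p <- packaged_parameters("set-A")
  b <- torsional_barrier(p, "S1")
  expect_equal(b, 1.6, tolerance = 0.02)
  # pure planarity-term limit: no product drive, no hula, no strain -> the
  # relaxed S1 profile is lambda*D*mu*[1 - ((1+cos)/2)^2] and the barrier is
  # its value at theta6_CI (profile maximal at 90 within the scan window)
  pp <- model_parameters(V6_S1 = 0, chi = 0, h_strain = 0, w0 = 0,
                         theta_off = 0, k_cage = 0)
  b0 <- torsional_barrier(pp, "S1")
  mu_at <- function(r) 2 * exp(-pp$a_hb * (r - pp$r0_hb)) -
    exp(-2 * pp$a_hb * (r - pp$r0_hb))
  expect_equal(b0, pp$lambda_hb * pp$D_hb * (1 - 0.25), tolerance = 0.02)
  # refinement oracle: 10x finer grid changes the result by < 1%
  b_fine <- torsional_barrier(p, "S1", grid_step = 0.025)
  expect_lt(abs(b - b_fine) / b_fine, 0.01)
})

test_that("barrier scaling is exact and monotone in lambda_hb", {
  p <- packaged_parameters("set-A")
  # identity: rescaling to the current barrier leaves s6 unchanged
  b <- torsional_barrier(p, "S1")
  expect_equal(scale_d6_barrier(p, b)$s6, p$s6, tolerance = 1e-3)
  for (target in c(1.6, 3.0, 5.2)) {
    ps <- scale_d6_barrier(p, target)
    expect_equal(torsional_barrier(ps, "S1"), target, tolerance = 0.01)
    expect_equal(unclass(ps)[setdiff(names(ps), "s6")],
                 unclass(p)[setdiff(names(p), "s6")])
  }
  # independent bisection oracle for one target
  f <- function(s6) {
    q <- p; q$s6 <- s6
    torsional_barrier(q, "S1") - 3.0
  }
  s_star <- uniroot(f, c(0.5, 1.0), tol = 1e-6)$root
  expect_equal(scale_d6_barrier(p, 3.0)$s6, s_star, tolerance = 1e-3)
  # stronger H-bond planarity coupling never lowers the S1 barrier
  lams <- seq(0.8, 1.2, by = 0.1) * p$lambda_hb
  bars <- vapply(lams, function(l) {
    q <- p; q$lambda_hb <- l
    torsional_barrier(q, "S1")
  }, numeric(1))
  expect_true(all(diff(bars) > -1e-8))
})

test_that("parameter files round-trip through YAML", {
  p <- packaged_parameters("set-A")
  tmp <- tempfile(fileext = ".yaml")
  write_model_parameters(p, tmp)
  p2 <- load_model_parameters(tmp)
  expect_equal(unclass(p), unclass(p2), tolerance = 1e-12)
  pb <- packaged_parameters("set-B")
  expect_lt(pb$D_hb, p$D_hb)
})
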