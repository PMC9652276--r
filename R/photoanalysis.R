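# Ensemble statistics of the photochemical step: state populations with
# bootstrap bands, exponential lifetime fits with latency, reactive/direction
# classification, quantum yield, hop-geometry statistics, H-bond
# stratification, and the barrier-lifetime scan.

.traj_s1_indicator <- function(traj, grid_fs) {
  s <- traj$series
  # active state as a right-continuous step function of time; after the
  # trajectory stopped, it stays in its final state
  idx <- findInterval(grid_fs, s$time_fs)
  idx[idx < 1] <- 1
  out <- s$active_state[idx]
  out[grid_fs > traj$t_end_fs] <- traj$final_state
  as.numeric(out == 1)
}

#' Electronic-state populations of a trajectory ensemble
#'
#' At each grid time the fraction of trajectories running on each state, with
#' a 95 percent bootstrap confidence band over trajectories.
#'
#' @param trajectories an `sh_ensemble` or list of `sh_trajectory`
#' @param dt_grid population grid spacing, fs
#' @param n_boot bootstrap resamples (>= 1000 recommended)
#' @param seed bootstrap seed
#' @return data.frame of class `population_curve` with columns `time_fs`,
#'   `P_S1`, `P_S0`, `lo`, `hi` (band on `P_S1`); the per-trajectory S1
#'   indicator matrix is kept in attribute `indicator` for refitting
#' @export
state_populations <- function(trajectories, dt_grid = 10, n_boot = 1000,
                              seed = 1) {
  trajs <- Filter(function(t) isTRUE(t$valid), trajectories)
  if (!length(trajs)) stop("no valid trajectories")
  t_end <- max(vapply(trajs, `[[`, numeric(1), "t_end_fs"))
  grid <- seq(0, t_end, by = dt_grid)
  M <- vapply(trajs, .traj_s1_indicator, numeric(length(grid)), grid_fs = grid)
  M <- t(M) # n_traj x n_grid
  p1 <- colMeans(M)
  n <- nrow(M)
  if (n_boot > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    W <- matrix(0, n_boot, n)
    for (b in seq_len(n_boot)) {
      tb <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      W[b, ] <- tb
    }
    B <- (W %*% M) / n
    qs <- apply(B, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    lo <- pmin(qs[1, ], p1); hi <- pmax(qs[2, ], p1)
  } else {
    lo <- p1; hi <- p1
  }
  out <- data.frame(time_fs = grid, P_S1 = p1, P_S0 = 1 - p1, lo = lo, hi = hi)
  attr(out, "indicator") <- M
  attr(out, "n_trajectories") <- n
  class(out) <- c("population_curve", "data.frame")
  out
}

.fit_latency_exp <- function(t_ps, p) {
  # least-squares fit of P(t) = 1 (t < t0), exp(-(t - t0)/tau) (t >= t0)
  model <- function(par, t) {
    tau <- exp(par[1]); t0 <- par[2]
    ifelse(t < t0, 1, exp(-(t - t0) / tau))
  }
  obj <- function(par) sum((p - model(par, t_ps))^2)
  i95 <- which(p < 0.95)
  t0_init <- if (length(i95)) t_ps[i95[1]] else 0
  mid <- p > 0.05 & p < 0.9
  tau_init <- if (sum(mid) > 3) {
    fitc <- coef(lm(log(p[mid]) ~ t_ps[mid]))
    max(1e-3, -1 / fitc[2])
  } else max(1e-3, diff(range(t_ps)) / 3)
  best <- NULL
  for (start in list(c(log(tau_init), t0_init), c(log(tau_init), 0))) {
    o <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 4000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(tau = exp(best$par[1]), t0 = max(0, best$par[2]),
       rss = best$value, converged = best$convergence == 0)
}

#' Exponential decay fit (with latency) of an S1 population curve
#'
#' Fits \eqn{P_{S1}(t) = 1} for \eqn{t < t_0} and
#' \eqn{\exp(-(t-t_0)/\tau)} for \eqn{t \ge t_0} by least squares, with a 95
#' percent bootstrap confidence interval on \eqn{\tau} obtained by refitting
#' resampled curves.
#'
#' @param curve a [state_populations()] result (or a data.frame with
#'   `time_fs` and `P_S1`)
#' @param n_boot bootstrap refits for the CI (0 disables)
#' @param seed bootstrap seed
#' @return list of class `decay_fit` with `tau` (ps), `t0` (ps), `rss`,
#'   `ci` (ps), `n_boot`
#' @export
fit_exponential_decay <- function(curve, n_boot = 500, seed = 1) {
  t_ps <- curve$time_fs / 1000
  fit <- .fit_latency_exp(t_ps, curve$P_S1)
  if (!fit$converged) stop("decay fit did not converge (rss = ", fit$rss, ")")
  ci <- c(NA_real_, NA_real_)
  M <- attr(curve, "indicator")
  if (n_boot > 0 && !is.null(M)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    n <- nrow(M)
    taus <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      pb <- colMeans(M[sample.int(n, n, replace = TRUE), , drop = FALSE])
      taus[b] <- .fit_latency_exp(t_ps, pb)$tau
    }
    ci <- quantile(taus, c(0.025, 0.975), names = FALSE)
  }
  structure(list(tau = fit$tau, t0 = fit$t0, rss = fit$rss,
                 ci = ci, n_boot = n_boot),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("exponential decay: tau = %.3f ps (95%% CI %.3f-%.3f), latency t0 = %.3f ps\n",
              x$tau, x$ci[1], x$ci[2], x$t0))
  invisible(x)
}

#' Classify one trajectory as reactive/nonreactive and by rotation direction
#'
#' Reactive: the final D6 torsion lies beyond `reactive_threshold` on the
#' product side and stays there over the final `stability_window` ps.
#' Direction: sign of the D6 displacement between the start and the first
#' accepted S1-to-S0 hop (positive = counterclockwise). Trajectories still on
#' S1 at the end are `"unresolved"`.
#'
#' @param traj `sh_trajectory`
#' @param reactive_threshold degrees (default 120)
#' @param stability_window ps (default 0.5)
#' @return list with `outcome` ("reactive"/"nonreactive"/"unresolved"),
#'   `direction` ("ccw"/"cw"/NA), `hop_theta6`, `final_theta6`
#' @export
classify_trajectory <- function(traj, reactive_threshold = 120,
                                stability_window = 0.5) {
  acc <- traj$hops[traj$hops$accepted & traj$hops$from_state == 1L, , drop = FALSE]
  hop_th6 <- if (nrow(acc)) acc$theta6_deg[1] else NA_real_
  direction <- NA_character_
  if (!is.na(hop_th6)) {
    d0 <- traj$series$theta6_deg[1]
    direction <- if (hop_th6 - d0 >= 0) "ccw" else "cw"
  }
  if (traj$final_state != 0L || !traj$valid) {
    return(list(outcome = "unresolved", direction = direction,
                hop_theta6 = hop_th6, final_theta6 = traj$final_theta6))
  }
  s <- traj$series
  win <- s$time_fs >= traj$t_end_fs - stability_window * 1000
  stable_product <- all(abs(s$theta6_deg[win]) > reactive_threshold)
  reactive <- abs(traj$final_theta6) > reactive_threshold && stable_product
  list(outcome = if (reactive) "reactive" else "nonreactive",
       direction = direction, hop_theta6 = hop_th6,
       final_theta6 = traj$final_theta6)
}

#' Classify a whole ensemble
#'
#' @inheritParams classify_trajectory
#' @param trajectories `sh_ensemble` or list of trajectories
#' @return object of class `ensemble_summary`: counts, quantum yield with
#'   Wilson 95 percent CI, direction counts, mean hop gap (eV)
#' @export
classify_ensemble <- function(trajectories, reactive_threshold = 120,
                              stability_window = 0.5) {
  cls <- lapply(trajectories, classify_trajectory,
                reactive_threshold = reactive_threshold,
                stability_window = stability_window)
  outcome <- vapply(cls, `[[`, character(1), "outcome")
  direction <- vapply(cls, function(x) {
    d <- x$direction
    if (is.na(d) || !length(d)) NA_character_ else d
  }, character(1))
  n_total <- length(cls)
  n_reactive <- sum(outcome == "reactive")
  n_nonreactive <- sum(outcome == "nonreactive")
  n_unresolved <- sum(outcome == "unresolved")
  n_failed <- sum(!vapply(trajectories, `[[`, logical(1), "valid"))
  gaps <- unlist(lapply(trajectories, function(t) {
    h <- t$hops
    h$gap_eV[h$accepted & h$from_state == 1L]
  }))
  qy <- quantum_yield(c(reactive = n_reactive, nonreactive = n_nonreactive))
  structure(list(n_total = n_total, n_reactive = n_reactive,
                 n_nonreactive = n_nonreactive, n_unresolved = n_unresolved,
                 n_failed = n_failed,
                 quantum_yield = qy$phi, qy_ci = qy$ci,
                 n_ccw = sum(direction == "ccw" & outcome == "reactive", na.rm = TRUE),
                 n_cw = sum(direction == "cw" & outcome == "reactive", na.rm = TRUE),
                 mean_hop_gap_eV = if (length(gaps)) mean(gaps) else NA_real_,
                 outcomes = outcome, directions = direction),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble: %d trajectories (%d reactive, %d nonreactive, %d unresolved, %d failed)\n",
              x$n_total, x$n_reactive, x$n_nonreactive, x$n_unresolved, x$n_failed))
  cat(sprintf("quantum yield = %.3f (95%% CI %.3f-%.3f); reactive direction: %d ccw / %d cw\n",
              x$quantum_yield, x$qy_ci[1], x$qy_ci[2], x$n_ccw, x$n_cw))
  invisible(x)
}

#' Photoisomerization quantum yield with Wilson binomial CI
#'
#' @param counts either a named vector `c(reactive = , nonreactive = )` or an
#'   `ensemble_summary`
#' @param conf confidence level
#' @return list with `phi` and `ci`
#' @export
quantum_yield <- function(counts, conf = 0.95) {
  if (inherits(counts, "ensemble_summary"))
    counts <- c(reactive = counts$n_reactive, nonreactive = counts$n_nonreactive)
  k <- counts[["reactive"]]
  n <- k + counts[["nonreactive"]]
  if (n == 0) stop("no resolved trajectories")
  phi <- k / n
  z <- qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  centre <- (phi + z^2 / (2 * n)) / den
  half <- z * sqrt(phi * (1 - phi) / n + z^2 / (4 * n^2)) / den
  list(phi = phi, ci = c(max(0, centre - half), min(1, centre + half)), n = n)
}

#' Geometry statistics at accepted S1-to-S0 hops
#'
#' @param trajectories ensemble or list of trajectories
#' @param reactive_threshold passed to [classify_trajectory()] for the
#'   reactive/nonreactive split
#' @return list with `hops` (pooled data.frame with an `outcome` column),
#'   `median_theta6`, `median_theta5`, `median_gap_eV`, and per-outcome
#'   medians
#' @export
hop_geometry_stats <- function(trajectories, reactive_threshold = 120) {
  rows <- lapply(seq_along(trajectories), function(i) {
    t <- trajectories[[i]]
    h <- t$hops[t$hops$accepted & t$hops$from_state == 1L, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    h$trajectory <- i
    h$outcome <- classify_trajectory(t, reactive_threshold)$outcome
    h
  })
  hops <- do.call(rbind, rows)
  if (is.null(hops) || !nrow(hops)) stop("no accepted S1->S0 hops in the ensemble")
  by_outcome <- split(abs(hops$theta6_deg), hops$outcome)
  list(hops = hops,
       n_hops = nrow(hops),
       median_theta6 = median(abs(hops$theta6_deg)),
       median_theta5 = median(hops$theta5_deg),
       median_gap_eV = median(hops$gap_eV),
       median_theta6_by_outcome = vapply(by_outcome, median, numeric(1)))
}

#' Lifetime fits stratified by initial H-bond distance
#'
#' Splits trajectories by their initial `r_hb` below/above `r_cut` and fits
#' the S1 decay per stratum.
#'
#' @param trajectories ensemble
#' @param r_cut stratification cutoff, Angstrom
#' @param ... passed to [fit_exponential_decay()]
#' @return list with `bonded` and `unbonded` entries (each a `decay_fit`, or
#'   `NULL` if the stratum is empty) and the stratum sizes
#' @export
stratify_by_hbond <- function(trajectories, r_cut = 2.5, ...) {
  r0 <- vapply(trajectories, function(t) t$series$r_hb_A[1], numeric(1))
  strata <- list(bonded = trajectories[r0 < r_cut],
                 unbonded = trajectories[r0 >= r_cut])
  fits <- lapply(strata, function(ts) {
    if (!length(ts)) return(NULL)
    fit_exponential_decay(state_populations(ts, n_boot = 0), ...)
  })
  c(fits, list(n = vapply(strata, length, integer(1)), r_cut = r_cut))
}

#' Barrier-lifetime scan with log-linear fit and extrapolation
#'
#' For each requested relaxed S1 barrier the model is rescaled with
#' [scale_d6_barrier()], an ensemble is run, and the S1 lifetime fitted; a
#' weighted linear regression of \eqn{\ln\tau} on the barrier provides the
#' activated-process check and the extrapolation with prediction interval.
#' The maximum propagation time is grown with the expected lifetime so the
#' slower ensembles still show a measurable decay.
#'
#' @param params base model parameters (set-A calibration)
#' @param barriers barrier grid, kcal/mol (>= 3 points)
#' @param n_per_point trajectories per barrier
#' @param settings base [sh_settings()]
#' @param seed master seed (sampling + per-barrier ensembles)
#' @param extrapolate_to optional barrier (kcal/mol) at which to evaluate the
#'   fitted line
#' @param n_boot bootstrap refits per lifetime CI
#' @return list of class `barrier_scan`: `table` (barrier, tau, CI), `fit`
#'   (lm of log tau), `r_squared`, `extrapolation` (tau in ps with prediction
#'   interval)
#' @export
lifetime_barrier_scan <- function(params, barriers = c(1.6, 2.8, 4.0, 5.2),
                                  n_per_point = 150, settings = sh_settings(),
                                  seed = 1, extrapolate_to = NULL,
                                  n_boot = 200) {
  if (length(barriers) < 3) stop("need at least 3 barrier points")
  params <- validate_model_parameters(params)
  spec <- ensemble_spec("set-A", n_frames = max(2000, n_per_point), seed = seed)
  frames <- ground_state_md(params, spec)
  base_tau <- NULL
  rows <- list()
  for (i in seq_along(barriers)) {
    b <- barriers[i]
    pb <- scale_d6_barrier(params, b)
    # grow the horizon with the expected Arrhenius slowdown
    t_max_i <- min(90, max(settings$t_max,
                           settings$t_max * exp(0.9 * (b - barriers[1]))))
    set_i <- settings
    set_i$t_max <- t_max_i
    set_i$record_stride <- max(settings$record_stride,
                               as.integer(50 * ceiling(t_max_i / 15)))
    ics <- draw_initial_conditions(frames, n_per_point, seed = seed + 1000 * i,
                                   replace = n_per_point > nrow(frames))
    ens <- run_ensemble(pb, ics, set_i, seeds = seed + 100000 * i + seq_len(n_per_point))
    curve <- state_populations(ens, dt_grid = 20, n_boot = 0)
    fit <- fit_exponential_decay(curve, n_boot = n_boot, seed = seed + i)
    rows[[i]] <- data.frame(barrier = b, tau = fit$tau,
                            tau_lo = fit$ci[1], tau_hi = fit$ci[2],
                            s6 = pb$s6, t_max = t_max_i)
    if (i == 1) base_tau <- fit$tau
  }
  tab <- do.call(rbind, rows)
  if (sum(is.finite(tab$tau)) < 3) stop("fewer than 3 converged scan points")
  se_log <- (log(tab$tau_hi) - log(tab$tau_lo)) / (2 * 1.96)
  w <- 1 / pmax(se_log, 1e-3)^2
  fit <- lm(log(tau) ~ barrier, data = tab, weights = w)
  r2 <- summary(fit)$r.squared
  extrapolation <- NULL
  if (!is.null(extrapolate_to)) {
    pr <- predict(fit, newdata = data.frame(barrier = extrapolate_to),
                  interval = "prediction", weights = mean(w))
    extrapolation <- list(barrier = extrapolate_to,
                          tau = exp(pr[1, "fit"]),
                          lo = exp(pr[1, "lwr"]), hi = exp(pr[1, "upr"]))
  }
  structure(list(table = tab, fit = fit, r_squared = r2,
                 slope = unname(coef(fit)[2]),
                 extrapolation = extrapolation),
            class = "barrier_scan")
}

#' @export
print.barrier_scan <- function(x, ...) {
  cat("barrier-lifetime scan:\n")
  print(x$table[, c("barrier", "tau", "tau_lo", "tau_hi")], row.names = FALSE)
  cat(sprintf("ln(tau) ~ barrier: slope %.3f per kcal/mol, R^2 = %.3f\n",
              x$slope, x$r_squared))
  if (!is.null(x$extrapolation))
    cat(sprintf("extrapolated tau at %.1f kcal/mol: %.1f ps (%.1f-%.1f)\n",
                x$extrapolation$barrier, x$extrapolation$tau,
                x$extrapolation$lo, x$extrapolation$hi))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Calibrate the model against the ensemble observables
#'
#' Derivative-free (Nelder-Mead) minimization of a weighted squared relative
#' error over a chosen subset of model parameters. The loss combines the
#' relaxed S1 barrier (deterministic) with the set-A/set-B lifetimes, the
#' set-A quantum yield and the pooled hop-geometry median obtained from
#' fixed-seed ensembles of `n_traj` trajectories, so the objective is
#' deterministic for a given seed. The shipped parameter files are the frozen
#' result of this procedure (see the methods vignette).
#'
#' @param initial_params starting `bv_model_params` (set-A)
#' @param targets named list with `barrier` (kcal/mol), `tau_A`, `tau_B`
#'   (ps), `phi_A`, `hop_theta6` (deg); defaults to the calibration targets
#' @param budget maximum objective evaluations
#' @param free names of the parameters allowed to vary
#' @param n_traj ensemble size per objective evaluation
#' @param weak_D_hb Morse depth used for the set-B variant
#' @param seed evaluation seed
#' @param loss_threshold calibration accepted when the loss falls below this
#' @return list with `params`, `loss`, `achieved` (target table), `trace`
#' @export
calibrate_model <- function(initial_params,
                            targets = list(barrier = 1.6, tau_A = 2.24,
                                           tau_B = 0.48, phi_A = 0.15,
                                           hop_theta6 = 90),
                            budget = 60,
                            free = c("w0", "sigma_w", "T_s1", "lambda_hb"),
                            n_traj = 150, weak_D_hb = 0.3, seed = 7,
                            loss_threshold = 0.02) {
  initial_params <- validate_model_parameters(initial_params)
  trace <- list()
  evaluate <- function(p) {
    p <- validate_model_parameters(p)
    barrier <- tryCatch(torsional_barrier(p, "S1"), error = function(e) NA_real_)
    if (!is.finite(barrier)) return(list(loss = 1e6))
    obs <- measure_ensemble_observables(p, n_traj = n_traj,
                                        weak_D_hb = weak_D_hb, seed = seed)
    loss <-
      4 * ((barrier - targets$barrier) / targets$barrier)^2 +
      ((obs$tau_A - targets$tau_A) / targets$tau_A)^2 +
      ((obs$tau_B - targets$tau_B) / targets$tau_B)^2 +
      ((obs$phi_A - targets$phi_A) / targets$phi_A)^2 +
      ((obs$hop_theta6 - targets$hop_theta6) / 30)^2
    c(list(loss = loss, barrier = barrier), obs)
  }
  ev0 <- evaluate(initial_params)
  if (is.finite(ev0$loss) && ev0$loss <= loss_threshold) {
    return(list(params = initial_params, loss = ev0$loss, achieved = ev0,
                trace = list(ev0), converged = TRUE))
  }
  x0 <- log(unlist(initial_params[free]))
  obj <- function(x) {
    p <- initial_params
    p[free] <- as.list(exp(x))
    ev <- evaluate(p)
    trace[[length(trace) + 1]] <<- c(setNames(exp(x), free), loss = ev$loss)
    ev$loss
  }
  opt <- optim(x0, obj, method = "Nelder-Mead",
               control = list(maxit = budget, reltol = 1e-4))
  out <- initial_params
  out[free] <- as.list(exp(opt$par))
  ach <- evaluate(out)
  list(params = validate_model_parameters(out), loss = ach$loss,
       achieved = ach, trace = trace, converged = ach$loss <= loss_threshold)
}

#' Measure the calibration observables of a parameter set
#'
#' Runs fixed-seed set-A and set-B ensembles and reports the fitted
#' lifetimes, set-A quantum yield and pooled hop-geometry median.
#'
#' @param params set-A style parameters
#' @param n_traj trajectories per ensemble
#' @param weak_D_hb Morse depth of the derived set-B variant
#' @param seed master seed
#' @param t_max propagation horizon, ps
#' @return list with `tau_A`, `tau_B`, `phi_A`, `hop_theta6`, `n_multi_hop`
#' @export
measure_ensemble_observables <- function(params, n_traj = 150, weak_D_hb = 0.3,
                                         seed = 7, t_max = 15) {
  params <- validate_model_parameters(params)
  pb <- params
  pb$D_hb <- weak_D_hb
  st <- sh_settings(t_max = t_max, seed = seed)
  run_one <- function(p, sd, variant) {
    spec <- ensemble_spec(variant, n_frames = max(2000, n_traj), seed = sd)
    fr <- ground_state_md(p, spec)
    ics <- draw_initial_conditions(fr, n_traj, seed = sd + 1,
                                   replace = n_traj > nrow(fr))
    run_ensemble(p, ics, st, seeds = sd + 10 + seq_len(n_traj))
  }
  ensA <- run_one(params, seed, "set-A")
  ensB <- run_one(pb, seed + 500000, "set-B")
  tau_A <- fit_exponential_decay(state_populations(ensA, n_boot = 0), n_boot = 0)$tau
  tau_B <- fit_exponential_decay(state_populations(ensB, n_boot = 0), n_boot = 0)$tau
  sumA <- classify_ensemble(ensA)
  hops <- hop_geometry_stats(ensA)
  n_down <- vapply(ensA, function(t)
    sum(t$hops$accepted & t$hops$from_state == 1L), numeric(1))
  list(tau_A = tau_A, tau_B = tau_B, phi_A = sumA$quantum_yield,
       hop_theta6 = hops$median_theta6,
       n_multi_hop = sum(n_down > 1), n_cw = sumA$n_cw)
}
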