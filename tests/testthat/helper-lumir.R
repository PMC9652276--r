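# Shared fixtures for the test suite. Heavy surface-hopping ensembles are
# memoised so the acceptance-level checks reuse one computation.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# a quick, small model variant for cheap dynamical tests (weak coupling off
# the calibrated defaults is fine here: these tests probe mechanics, not the
# calibrated observables)
toy_params <- function(...) model_parameters(...)

# set-A / set-B ensembles at acceptance scale (500 trajectories, 15 ps)
acceptance_ensemble <- function(variant = "set-A", n = 500, seed = 101) {
  key <- sprintf("ens_%s_%d_%d", variant, n, seed)
  memo(key, {
    p <- packaged_parameters(variant)
    spec <- ensemble_spec(variant, n_frames = max(2000, n), seed = seed)
    frames <- ground_state_md(p, spec)
    ics <- draw_initial_conditions(frames, n, seed = seed + 1,
                                   replace = n > nrow(frames))
    run_ensemble(p, ics, sh_settings(t_max = 15, seed = seed),
                 seeds = seed + 10 + seq_len(n))
  })
}

# hand-built minimal trajectory object for analysis-stage unit tests:
# stays on S1 until hop_time_ps, then on S0 at final_theta6
make_toy_traj <- function(hop_time_ps, final_theta6 = 5, t_end_ps = 10,
                          hop_theta6 = 92, r0 = 1.9, dt_fs = 100,
                          theta6_0 = 0) {
  times <- seq(0, t_end_ps * 1000, by = dt_fs)
  hopped <- hop_time_ps * 1000 <= max(times)
  active <- ifelse(times >= hop_time_ps * 1000, 0L, 1L)
  th6 <- ifelse(times >= hop_time_ps * 1000, final_theta6, theta6_0)
  series <- data.frame(time_fs = times, theta6_deg = th6, theta5_deg = 0,
                       r_hb_A = r0, active_state = active,
                       pop_S1 = as.numeric(active == 1L), gap_eV = 1,
                       energy_kcal = 0)
  hops <- if (hopped) {
    data.frame(time_fs = hop_time_ps * 1000, from_state = 1L,
               to_state = 0L, gap_eV = 0.05, theta6_deg = hop_theta6,
               theta5_deg = 0, r_hb_A = r0, accepted = TRUE)
  } else {
    data.frame(time_fs = numeric(0), from_state = integer(0),
               to_state = integer(0), gap_eV = numeric(0),
               theta6_deg = numeric(0), theta5_deg = numeric(0),
               r_hb_A = numeric(0), accepted = logical(0))
  }
  structure(list(series = series, hops = hops,
                 final_state = if (hopped) 0L else 1L,
                 final_theta6 = final_theta6, final_theta5 = 0, final_r = r0,
                 t_end_fs = max(times), n_hops = 1L,
                 initial = list(q = c(theta6_0, 0, r0), p = c(0, 0, 0)),
                 seed = 1, valid = TRUE, exit_code = 1L),
            class = "sh_trajectory")
}
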