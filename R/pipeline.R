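# Supporting engineering: feature-table IO with schema checks, run
# configuration, and the end-to-end pipeline driver with stage caching.
# CSV for frames/curves (inspectable), JSON for reports and manifests.

.feature_table_required <- function() c("time_ps", .pocket_features)

#' Read a pocket feature table from CSV
#'
#' Validates the documented header; unknown columns are preserved verbatim.
#'
#' @param path CSV file path
#' @param required required column names (defaults to the pocket feature
#'   schema)
#' @return data.frame
#' @export
read_feature_table <- function(path, required = .feature_table_required()) {
  if (!file.exists(path)) stop("no such file: ", path)
  frames <- read.csv(path, check.names = FALSE)
  miss <- setdiff(required, names(frames))
  if (length(miss))
    stop("malformed feature table header; missing column(s): ",
         paste(miss, collapse = ", "),
         "; expected at least: ", paste(required, collapse = ", "))
  frames
}

#' Write a pocket feature table to CSV
#'
#' Numeric columns round-trip losslessly (15 significant digits).
#'
#' @param frames data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(frames, path) {
  write.csv(frames, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if needed)
#' @param seed global seed; recorded in every output manifest
#' @param stages subset of `c("photo", "pocket")`
#' @param photo list of overrides for the photochemistry chain
#'   (`variant`, `n_traj`, `t_max`, `n_frames`)
#' @param pocket list of overrides for the Lumi-R chain (`n_early`, `n_pr`,
#'   `n_replicas`, `shift_cm1`)
#' @param verbose print stage progress?
#' @return list of class `run_config`
#' @export
run_config <- function(out_dir, seed = 1, stages = c("photo", "pocket"),
                       photo = list(), pocket = list(), verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 photo = photo, pocket = pocket, verbose = verbose),
            class = "run_config")
}

.config_repr <- function(config) {
  paste(deparse(unclass(config[setdiff(names(config), "verbose")])),
        collapse = "\n")
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested chains — `photo`: ground-state sampling, the
#' surface-hopping ensemble and its photochemical statistics; `pocket`:
#' synthetic pocket generation, intermediate characterization and the IR
#' difference spectrum — writing per-stage CSV artifacts and a JSON summary
#' report into `config$out_dir`. A rerun with an unchanged configuration is
#' a cache hit and returns the stored report byte-identically.
#'
#' @param config a [run_config()]
#' @return the report (list), invisibly; also written to
#'   `<out_dir>/report.json`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  repr_path <- file.path(config$out_dir, "config.txt")
  report_path <- file.path(config$out_dir, "report.json")
  repr <- .config_repr(config)
  if (file.exists(repr_path) && file.exists(report_path) &&
      identical(paste(readLines(repr_path), collapse = "\n"), repr)) {
    return(invisible(jsonlite::read_json(report_path, simplifyVector = TRUE)))
  }
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  report <- list(seed = config$seed, stages = list())

  if ("photo" %in% config$stages) {
    say("stage: photochemistry")
    ph <- utils::modifyList(list(variant = "set-A", n_traj = 200, t_max = 15,
                                 n_frames = 2000), config$photo)
    params <- packaged_parameters(ph$variant)
    spec <- ensemble_spec(ph$variant, n_frames = ph$n_frames, seed = config$seed)
    frames <- ground_state_md(params, spec)
    write.csv(frames, file.path(config$out_dir, "ground_state_frames.csv"),
              row.names = FALSE)
    ics <- draw_initial_conditions(frames, ph$n_traj, seed = config$seed + 1)
    ens <- run_ensemble(params, ics,
                        sh_settings(t_max = ph$t_max, seed = config$seed + 2))
    curve <- state_populations(ens, n_boot = 1000, seed = config$seed)
    write.csv(as.data.frame(curve),
              file.path(config$out_dir, "population_curve.csv"),
              row.names = FALSE)
    fit <- fit_exponential_decay(curve, n_boot = 200, seed = config$seed)
    summ <- classify_ensemble(ens)
    hops <- hop_geometry_stats(ens)
    report$stages$photo <- list(
      variant = ph$variant, n_trajectories = summ$n_total,
      n_failed = summ$n_failed,
      tau_ps = fit$tau, tau_ci_ps = fit$ci, latency_ps = fit$t0,
      quantum_yield = summ$quantum_yield, qy_ci = summ$qy_ci,
      n_reactive = summ$n_reactive, n_ccw = summ$n_ccw, n_cw = summ$n_cw,
      hop_theta6_median_deg = hops$median_theta6,
      mean_hop_gap_eV = summ$mean_hop_gap_eV)
  }

  if ("pocket" %in% config$stages) {
    say("stage: binding pocket")
    pk <- utils::modifyList(list(n_early = 20000, n_pr = 10000,
                                 n_replicas = 10, shift_cm1 = 8), config$pocket)
    cfg <- pocket_generator_config(seed = config$seed)
    early <- generate_early_ensemble(cfg, n_frames = pk$n_early,
                                     seed = config$seed + 10)
    pr <- generate_pr_reference(cfg, n_frames = pk$n_pr, seed = config$seed + 11)
    write_feature_table(early, file.path(config$out_dir, "early_frames.csv"))
    cl <- pca_cluster(early)
    reps <- generate_relaxation_replicas(cfg, seed = config$seed + 12,
                                         n_replicas = pk$n_replicas)
    relax <- estimate_relaxation_lifetime(reps)
    late <- reps[reps$hidden_state == "late", , drop = FALSE]
    contacts_early <- contact_count_probabilities(early)
    contacts_late <- contact_count_probabilities(late)
    hb_early <- hbond_probability_table(early)
    hb_late <- hbond_probability_table(late)
    map <- frequency_map()
    spectra <- lapply(0:2, function(k)
      ensemble_spectrum(early[early$hidden_cluster == k, , drop = FALSE], map))
    avg <- weighted_average(spectra, cfg$cluster_weights)
    pr_spec <- ensemble_spectrum(pr, map, isomerized = FALSE)
    diff <- difference_spectrum(avg, pr_spec, shift_cm1 = pk$shift_cm1)
    write.csv(as.data.frame(diff),
              file.path(config$out_dir, "difference_spectrum.csv"),
              row.names = FALSE)
    report$stages$pocket <- list(
      n_early = nrow(early),
      cluster_weights = as.list(cl$weights),
      ari_vs_truth = adjusted_rand_index(cl$labels, early$hidden_cluster),
      tau_late_us = relax$tau_us, tau_late_ci_us = relax$ci_us,
      p2_early = unname(contacts_early$p["P2"]),
      p2_late = unname(contacts_late$p["P2"]),
      hbond_early = setNames(hb_early$probability, hb_early$interaction),
      hbond_late = setNames(hb_late$probability, hb_late$interaction),
      difference_spectrum_shift_cm1 = pk$shift_cm1,
      difference_extrema = list(
        positive_at = diff$wavenumber[which.max(diff$intensity)],
        negative_at = diff$wavenumber[which.min(diff$intensity)]))
  }

  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(repr, repr_path)
  invisible(report)
}
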