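# Synthetic generator for chromophore-binding-pocket feature trajectories.
# Emulates the statistical structure of the ground-state (Pr), early Lumi-R
# and late Lumi-R ensembles: a 3-component cluster mixture in the early
# intermediate, irreversible exponential early->late switching, and the
# early-vs-late contrasts in the hydrogen-bond / salt-bridge features.
# Emission means and widths are package conventions chosen to realize the
# qualitative contrasts (unimodal vs bimodal, shorter vs longer, which
# interaction takes over); they are not measurements.

.pocket_features <- c("OD_His290", "OD_water", "Tyr263_Asp207", "ND_Tyr263",
                      "OD_Arg466", "OB_Ser257", "OB_Tyr216",
                      "Asp207_Arg466_c1", "Asp207_Arg466_c2")

# emission = list(mean, sd) or list(w, mean, sd, mean2, sd2) for a 2-component mixture
.g1 <- function(mean, sd) list(mean = mean, sd = sd)
.g2 <- function(w, m1, s1, m2, s2) list(w = w, mean = m1, sd = s1, mean2 = m2, sd2 = s2)

#' Default pocket-generator configuration
#'
#' Per-state, per-feature emission distributions (Gaussian or two-component
#' mixtures, Angstrom), the early-cluster mixture weights, the early-to-late
#' switching lifetime and the replica layout. All distances are donor-acceptor
#' heavy-atom distances.
#'
#' @param cluster_weights early-Lumi-R cluster weights (Cl0, Cl1, Cl2)
#' @param tau_late_us early-to-late relaxation lifetime, microseconds
#' @param frame_interval_ps frame spacing of relaxation replicas, ps
#' @param replica_length_us length of each relaxation replica, microseconds
#' @param n_replicas number of independent relaxation replicas
#' @param seed default seed
#' @return list of class `pocket_config`
#' @export
pocket_generator_config <- function(cluster_weights = c(0.18, 0.81, 0.01),
                                    tau_late_us = 0.4,
                                    frame_interval_ps = 100,
                                    replica_length_us = 2,
                                    n_replicas = 10,
                                    seed = 1) {
  if (any(cluster_weights < 0)) stop("invalid mixture: negative weight")
  if (abs(sum(cluster_weights) - 1) > 1e-9) stop("invalid mixture: weights must sum to 1")
  emissions <- list(
    # resting Pr state: His290 H-bonded carbonyl, no N_D...Tyr263 bond,
    # tight Asp207-Arg466 salt bridge, short Tyr263...Asp207
    Pr = list(
      OD_His290 = .g1(2.00, 0.18), OD_water = .g1(3.50, 0.50),
      Tyr263_Asp207 = .g1(1.85, 0.15), ND_Tyr263 = .g1(4.80, 0.50),
      OD_Arg466 = .g1(5.20, 0.35), OB_Ser257 = .g1(1.80, 0.15),
      OB_Tyr216 = .g1(4.00, 0.50),
      Asp207_Arg466_c1 = .g1(2.75, 0.12), Asp207_Arg466_c2 = .g1(2.80, 0.15),
      pyrrole_water_p = 0.10
    ),
    # early Lumi-R clusters: N_D...Tyr263 H-bond is the shared hallmark;
    # Cl0 keeps the water H-bond to CO_D, Cl1 has lost it, Cl2 has a long
    # Tyr263...Asp207 distance
    # The bridging water ties the carbonyl H-bond network together: the
    # early pocket toggles between two well-defined configurations, so its
    # presence (Cl0) comes with a coherently tighter environment in every
    # contact, and losing it (Cl1) loosens the same contacts. This
    # correlated, tight two-state signature is what makes the clusters
    # recoverable from the feature table by variance-based methods.
    early_cl0 = list(
      OD_His290 = .g1(4.00, 0.18), OD_water = .g1(1.90, 0.15),
      Tyr263_Asp207 = .g1(1.80, 0.12), ND_Tyr263 = .g1(1.92, 0.12),
      OD_Arg466 = .g1(4.70, 0.15), OB_Ser257 = .g1(1.70, 0.10),
      OB_Tyr216 = .g1(3.70, 0.20),
      Asp207_Arg466_c1 = .g1(2.68, 0.10), Asp207_Arg466_c2 = .g1(2.72, 0.10),
      pyrrole_water_p = 0.15
    ),
    early_cl1 = list(
      OD_His290 = .g1(4.90, 0.18), OD_water = .g1(4.20, 0.25),
      Tyr263_Asp207 = .g1(1.95, 0.12), ND_Tyr263 = .g1(2.08, 0.12),
      OD_Arg466 = .g1(5.30, 0.15), OB_Ser257 = .g1(1.92, 0.10),
      OB_Tyr216 = .g1(4.30, 0.20),
      Asp207_Arg466_c1 = .g1(2.80, 0.10), Asp207_Arg466_c2 = .g1(2.86, 0.10),
      pyrrole_water_p = 0.15
    ),
    early_cl2 = list(
      OD_His290 = .g1(4.00, 0.18), OD_water = .g2(0.8, 1.90, 0.15, 4.20, 0.25),
      Tyr263_Asp207 = .g1(4.50, 0.40), ND_Tyr263 = .g1(1.92, 0.12),
      OD_Arg466 = .g1(4.70, 0.15), OB_Ser257 = .g1(1.70, 0.10),
      OB_Tyr216 = .g1(3.70, 0.20),
      Asp207_Arg466_c1 = .g1(2.68, 0.10), Asp207_Arg466_c2 = .g1(2.72, 0.10),
      pyrrole_water_p = 0.15
    ),
    # late Lumi-R: mobile Arg466 (bimodal O_D...Arg466), weakened salt
    # bridge and Tyr263 contacts, Ser257 released, Tyr216 strengthened,
    # pyrrole water takes over the D-ring interaction
    late = list(
      OD_His290 = .g1(5.00, 0.80), OD_water = .g1(3.80, 0.70),
      Tyr263_Asp207 = .g2(0.35, 1.90, 0.20, 4.20, 0.60),
      ND_Tyr263 = .g1(3.60, 0.80),
      OD_Arg466 = .g2(0.50, 2.90, 0.25, 5.20, 0.50),
      OB_Ser257 = .g2(0.40, 1.85, 0.20, 4.00, 0.70),
      OB_Tyr216 = .g1(1.90, 0.20),
      Asp207_Arg466_c1 = .g2(0.50, 2.80, 0.20, 4.20, 0.60),
      Asp207_Arg466_c2 = .g2(0.40, 2.85, 0.20, 4.50, 0.70),
      pyrrole_water_p = 0.80
    )
  )
  structure(list(cluster_weights = cluster_weights,
                 tau_late_us = tau_late_us,
                 frame_interval_ps = frame_interval_ps,
                 replica_length_us = replica_length_us,
                 n_replicas = n_replicas,
                 water_hb_cutoff = 2.4,
                 emissions = emissions,
                 seed = seed),
            class = "pocket_config")
}

.sample_emission <- function(spec, n) {
  if (!is.null(spec$w)) {
    pick <- runif(n) < spec$w
    x <- numeric(n)
    x[pick] <- rnorm(sum(pick), spec$mean, spec$sd)
    x[!pick] <- rnorm(sum(!pick), spec$mean2, spec$sd2)
  } else {
    x <- rnorm(n, spec$mean, spec$sd)
  }
  pmax(x, 0.5) # distances strictly positive
}

.emit_frames <- function(em, n, water_cutoff) {
  out <- as.data.frame(lapply(em[.pocket_features], .sample_emission, n = n))
  names(out) <- .pocket_features
  out$water_bridge_OD <- out$OD_water < water_cutoff
  out$pyrrole_water_D <- runif(n) < em$pyrrole_water_p
  out
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Generate an early-Lumi-R ensemble from the three-cluster mixture
#'
#' Frames are drawn from the cluster mixture (weights from the config):
#' Cl0 keeps the water H-bond to the D-ring carbonyl, Cl1 has lost it, Cl2
#' has a long Tyr263-Asp207 distance; the N_D-Tyr263 H-bond is short in all
#' early frames. Ground-truth cluster labels are attached only when
#' `ground_truth = TRUE`.
#'
#' @param config [pocket_generator_config()]
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param ground_truth attach `hidden_state` / `hidden_cluster` columns?
#' @return data.frame of pocket feature frames
#' @export
generate_early_ensemble <- function(config = pocket_generator_config(),
                                    n_frames = 20000, seed = config$seed,
                                    ground_truth = TRUE) {
  stopifnot(inherits(config, "pocket_config"))
  .with_seed(seed, {
    lab <- sample.int(3, n_frames, replace = TRUE,
                      prob = config$cluster_weights) - 1L
    frames <- vector("list", 3)
    for (k in 0:2) {
      nk <- sum(lab == k)
      if (!nk) next
      em <- config$emissions[[paste0("early_cl", k)]]
      frames[[k + 1]] <- .emit_frames(em, nk, config$water_hb_cutoff)
    }
    out <- do.call(rbind, frames)
    ord <- order(c(which(lab == 0), which(lab == 1), which(lab == 2)))
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out <- cbind(time_ps = seq_len(n_frames) * config$frame_interval_ps, out)
    if (ground_truth) {
      out$hidden_state <- "early"
      out$hidden_cluster <- lab
    }
    out
  })
}

#' Generate a Pr reference ensemble
#'
#' @inheritParams generate_early_ensemble
#' @return data.frame of pocket feature frames
#' @export
generate_pr_reference <- function(config = pocket_generator_config(),
                                  n_frames = 20000, seed = config$seed,
                                  ground_truth = TRUE) {
  stopifnot(inherits(config, "pocket_config"))
  .with_seed(seed, {
    out <- .emit_frames(config$emissions$Pr, n_frames, config$water_hb_cutoff)
    out <- cbind(time_ps = seq_len(n_frames) * config$frame_interval_ps, out)
    if (ground_truth) {
      out$hidden_state <- "Pr"
      out$hidden_cluster <- NA_integer_
    }
    out
  })
}

#' Generate pure late-Lumi-R frames
#'
#' Convenience sampler of the late-state emission model (the state the
#' relaxation replicas switch into), used for state-contrast analyses.
#'
#' @inheritParams generate_early_ensemble
#' @return data.frame of pocket feature frames
#' @export
generate_late_frames <- function(config = pocket_generator_config(),
                                 n_frames = 10000, seed = config$seed,
                                 ground_truth = TRUE) {
  stopifnot(inherits(config, "pocket_config"))
  .with_seed(seed, {
    out <- .emit_frames(config$emissions$late, n_frames, config$water_hb_cutoff)
    out <- cbind(time_ps = seq_len(n_frames) * config$frame_interval_ps, out)
    if (ground_truth) {
      out$hidden_state <- "late"
      out$hidden_cluster <- NA_integer_
    }
    out
  })
}

#' Generate early-to-late relaxation replicas
#'
#' Each replica starts in the early state and switches irreversibly to the
#' late state at an exponentially distributed time with mean `tau_late_us`.
#' Early frames are drawn from the cluster mixture; late frames show the
#' bimodal O_D-Arg466 distance, the weakened salt bridge and Tyr263 contacts
#' and the pyrrole-water takeover.
#'
#' @param config [pocket_generator_config()]
#' @param seed RNG seed
#' @param n_replicas,replica_length_us optional overrides of the config
#' @param ground_truth attach hidden-state columns?
#' @return data.frame with `replica`, `time_us` and the feature columns
#' @export
generate_relaxation_replicas <- function(config = pocket_generator_config(),
                                         seed = config$seed,
                                         n_replicas = config$n_replicas,
                                         replica_length_us = config$replica_length_us,
                                         ground_truth = TRUE) {
  stopifnot(inherits(config, "pocket_config"))
  .with_seed(seed, {
    n_frames <- round(replica_length_us * 1e6 / config$frame_interval_ps)
    dt_us <- config$frame_interval_ps * 1e-6
    reps <- vector("list", n_replicas)
    for (r in seq_len(n_replicas)) {
      t_switch <- if (config$tau_late_us > 0 && is.finite(config$tau_late_us))
        rexp(1, rate = 1 / config$tau_late_us) else Inf
      times <- seq_len(n_frames) * dt_us
      is_late <- times >= t_switch
      n_early <- sum(!is_late)
      n_late <- sum(is_late)
      early <- if (n_early) {
        lab <- sample.int(3, n_early, replace = TRUE,
                          prob = config$cluster_weights) - 1L
        parts <- lapply(0:2, function(k) {
          nk <- sum(lab == k)
          if (!nk) return(NULL)
          f <- .emit_frames(config$emissions[[paste0("early_cl", k)]], nk,
                            config$water_hb_cutoff)
          f$hidden_cluster <- k
          f
        })
        e <- do.call(rbind, parts)
        e[order(order(lab)), , drop = FALSE]
      } else NULL
      late <- if (n_late) {
        f <- .emit_frames(config$emissions$late, n_late, config$water_hb_cutoff)
        f$hidden_cluster <- NA_integer_
        f
      } else NULL
      f <- rbind(early, late)
      rownames(f) <- NULL
      f <- cbind(replica = r, time_us = times, f)
      f$hidden_state <- ifelse(is_late, "late", "early")
      f$switch_time_us <- t_switch
      reps[[r]] <- f
    }
    out <- do.call(rbind, reps)
    if (!ground_truth)
      out <- out[, setdiff(names(out), c("hidden_state", "hidden_cluster",
                                         "switch_time_us"))]
    rownames(out) <- NULL
    out
  })
}
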