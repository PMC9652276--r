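# Intermediate-characterization statistics for binding-pocket feature tables:
# distance distributions with a unimodality (dip) test, salt-bridge contact
# counts, hydrogen-bond probability tables, censored exponential relaxation
# kinetics, and PCA + Ward clustering with population weights.

#' Dip-type unimodality statistic
#'
#' Smallest half-bandwidth `d` such that a distribution function that is
#' convex left of a mode and concave right of it fits inside the Kolmogorov
#' band of half-width `d` around the empirical CDF (computed by bisection
#' with incremental convex-minorant feasibility checks). Implemented in this
#' package because no dip-test routine ships with the environment. The
#' statistic attains the exact lower bound `1/(2n)` for equally spaced data
#' and `1/4` for two equal point masses, like Hartigan's dip.
#'
#' @param x numeric sample
#' @return the statistic (a number in `[1/(2n), 1/4]`)
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < 2) return(0)
  cpp_dip_statistic(x)
}

#' Dip test of unimodality with Monte-Carlo null
#'
#' P-value from `n_sim` samples of the same size drawn from the uniform
#' distribution (the asymptotically least-favourable unimodal null for the
#' dip). The null distribution is cached per sample size within a session.
#'
#' @param x numeric sample
#' @param n_sim null simulations
#' @param seed RNG seed for the null draws
#' @return list with `dip`, `p_value`, `n`
#' @export
dip_test <- function(x, n_sim = 200, seed = 1) {
  x <- x[is.finite(x)]
  d <- dip_statistic(x)
  n <- length(x)
  key <- sprintf("dip_null_%d_%d_%d", n, n_sim, seed)
  null <- .lumir_cache[[key]]
  if (is.null(null)) {
    null <- .with_seed(seed, vapply(seq_len(n_sim), function(i)
      cpp_dip_statistic(runif(n)), numeric(1)))
    .lumir_cache[[key]] <- null
  }
  p <- (1 + sum(null >= d)) / (n_sim + 1)
  list(dip = d, p_value = p, n = n)
}

.lumir_cache <- new.env(parent = emptyenv())

#' Distance distributions with kernel density and bimodality flag
#'
#' @param frames pocket feature data.frame
#' @param pairs feature column names to analyse
#' @param bandwidth kernel bandwidth passed to [stats::density()] (`"nrd0"`
#'   default)
#' @param alpha dip-test significance level for the bimodality flag
#' @param max_n cap on the sample size used for the dip test (subsampled
#'   deterministically for speed)
#' @return named list per pair: `histogram` (hist object), `density`,
#'   `dip`, `p_value`, `bimodal`
#' @export
distance_distributions <- function(frames, pairs, bandwidth = "nrd0",
                                   alpha = 0.05, max_n = 500) {
  if (nrow(frames) < 100) stop("need at least 100 frames")
  bad <- setdiff(pairs, names(frames))
  if (length(bad))
    stop("unknown pair name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(.pocket_features, collapse = ", "))
  out <- lapply(pairs, function(p) {
    x <- frames[[p]]
    h <- graphics::hist(x, breaks = "FD", plot = FALSE)
    dn <- if (length(unique(x)) > 1) density(x, bw = bandwidth) else NULL
    xs <- if (length(x) > max_n) x[round(seq(1, length(x), length.out = max_n))] else x
    dt <- if (length(unique(xs)) > 1) dip_test(xs) else list(dip = 0, p_value = 1)
    list(histogram = h, density = dn, dip = dt$dip, p_value = dt$p_value,
         bimodal = dt$p_value < alpha)
  })
  names(out) <- pairs
  out
}

#' Asp207-Arg466 salt-bridge contact-count probabilities
#'
#' A contact is a distance below `cutoff` (3 Angstrom rule); the per-frame
#' count is the number of the two contact distances below the cutoff.
#'
#' @param frames feature data.frame with `Asp207_Arg466_c1`, `Asp207_Arg466_c2`
#' @param cutoff contact cutoff, Angstrom
#' @return list of class `contact_table`: `p` (P0, P1, P2), `se`
#'   (multinomial standard errors), `n_frames`
#' @export
contact_count_probabilities <- function(frames, cutoff = 3.0) {
  need <- c("Asp207_Arg466_c1", "Asp207_Arg466_c2")
  miss <- setdiff(need, names(frames))
  if (length(miss)) stop("missing contact column(s): ", paste(miss, collapse = ", "))
  counts <- (frames$Asp207_Arg466_c1 < cutoff) + (frames$Asp207_Arg466_c2 < cutoff)
  n <- length(counts)
  p <- vapply(0:2, function(k) mean(counts == k), numeric(1))
  names(p) <- c("P0", "P1", "P2")
  se <- sqrt(p * (1 - p) / n)
  structure(list(p = p, se = se, n_frames = n, cutoff = cutoff),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("Asp207-Arg466 contacts (< %.1f A, n = %d): P0 = %.3f, P1 = %.3f, P2 = %.3f\n",
              x$cutoff, x$n_frames, x$p[1], x$p[2], x$p[3]))
  invisible(x)
}

#' Default hydrogen-bond definitions for the pocket features
#'
#' Distance criteria use 3.5 Angstrom for O/N donor-acceptor pairs; indicator
#' columns are used directly.
#'
#' @param cutoff distance criterion, Angstrom
#' @return named list of definitions (`list(column, cutoff)` or
#'   `list(indicator)`)
#' @export
default_hbond_definitions <- function(cutoff = 3.5) {
  list(
    "OD...His290" = list(column = "OD_His290", cutoff = cutoff),
    "OD...water" = list(column = "OD_water", cutoff = cutoff),
    "Tyr263...Asp207" = list(column = "Tyr263_Asp207", cutoff = cutoff),
    "ND...Tyr263" = list(column = "ND_Tyr263", cutoff = cutoff),
    "OB...Ser257" = list(column = "OB_Ser257", cutoff = cutoff),
    "OB...Tyr216" = list(column = "OB_Tyr216", cutoff = cutoff),
    "pyrrole-water...D-ring" = list(indicator = "pyrrole_water_D")
  )
}

#' Hydrogen-bond probability table
#'
#' Fraction of frames satisfying each named interaction definition, with
#' binomial standard errors.
#'
#' @param frames feature data.frame
#' @param definitions named list as in [default_hbond_definitions()]
#' @return data.frame with `interaction`, `probability`, `se`
#' @export
hbond_probability_table <- function(frames, definitions = default_hbond_definitions()) {
  n <- nrow(frames)
  rows <- lapply(names(definitions), function(nm) {
    d <- definitions[[nm]]
    sat <- if (!is.null(d$indicator)) as.logical(frames[[d$indicator]])
           else frames[[d$column]] < d$cutoff
    p <- mean(sat)
    data.frame(interaction = nm, probability = p, se = sqrt(p * (1 - p) / n))
  })
  do.call(rbind, rows)
}

#' Early-to-late relaxation lifetime from replica first-passage times
#'
#' Classifies each replica's late-state onset as the first sustained crossing
#' of a feature threshold (running mean over `window` frames above
#' `threshold`), then fits a censored exponential by maximum likelihood:
#' \eqn{\hat\tau = \sum_i t_i / n_{events}} with right-censoring at the
#' replica end, and a profile-likelihood 95 percent CI.
#'
#' @param replicas data.frame from [generate_relaxation_replicas()] (or the
#'   same schema): needs `replica`, `time_us` and the classifier feature
#' @param feature classifier feature column (default `Tyr263_Asp207`, whose
#'   running mean moves from ~1.9 to ~3.4 Angstrom on the transition)
#' @param threshold sustained-crossing threshold, Angstrom (3.0 by default:
#'   safely above the early-state running mean even when the rare long-distance
#'   early cluster contributes several frames to one window)
#' @param window running-mean window, frames (>= 10)
#' @return list of class `relaxation_fit`: `tau_us`, `ci_us`, `n_events`,
#'   `n_censored`, `first_passage_us`
#' @export
estimate_relaxation_lifetime <- function(replicas, feature = "Tyr263_Asp207",
                                         threshold = 3.0, window = 10) {
  stopifnot(window >= 1)
  ids <- unique(replicas$replica)
  if (length(ids) < 5) stop("need at least 5 replicas")
  times <- numeric(length(ids))
  event <- logical(length(ids))
  for (i in seq_along(ids)) {
    rr <- replicas[replicas$replica == ids[i], , drop = FALSE]
    rr <- rr[order(rr$time_us), , drop = FALSE]
    x <- rr[[feature]]
    if (length(x) >= window) {
      rm <- stats::filter(x, rep(1 / window, window), sides = 1)
      hit <- which(!is.na(rm) & rm > threshold)
    } else hit <- integer(0)
    if (length(hit)) {
      times[i] <- rr$time_us[hit[1] - window + 1L] # onset of the window
      event[i] <- TRUE
    } else {
      times[i] <- max(rr$time_us)
      event[i] <- FALSE
    }
  }
  n_events <- sum(event)
  if (n_events == 0) stop("no late-state events detected: censoring-only data")
  total <- sum(times)
  tau <- total / n_events
  # profile likelihood CI: l(tau) = -n_e log tau - total / tau
  ll <- function(t) -n_events * log(t) - total / t
  l0 <- ll(tau)
  crit <- qchisq(0.95, 1) / 2
  f <- function(t) l0 - ll(t) - crit
  lo <- tryCatch(uniroot(f, c(tau * 1e-3, tau))$root, error = function(e) NA_real_)
  hi <- tryCatch(uniroot(f, c(tau, tau * 1e3))$root, error = function(e) NA_real_)
  structure(list(tau_us = tau, ci_us = c(lo, hi), n_events = n_events,
                 n_censored = sum(!event),
                 first_passage_us = setNames(times, ids), event = event),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("early->late relaxation: tau = %.3f us (95%% CI %.3f-%.3f), %d events, %d censored\n",
              x$tau_us, x$ci_us[1], x$ci_us[2], x$n_events, x$n_censored))
  invisible(x)
}

#' PCA + Ward hierarchical clustering of pocket frames
#'
#' Features are standardized and projected on the leading principal
#' components (those explaining at least `var_explained` of the variance);
#' agglomerative clustering with Ward linkage (Euclidean metric) is cut at
#' `K` clusters. For more than `exact_max` frames, Ward clustering runs on a
#' deterministic subsample and the remaining frames are assigned to the
#' nearest cluster centroid in PC space.
#'
#' @param frames feature data.frame
#' @param feature_columns columns to use (default: all distance features
#'   present)
#' @param K number of clusters
#' @param component_rule `"variance"` (default) keeps the leading components
#'   explaining `var_explained` of the variance; `"kaiser"` keeps components
#'   whose eigenvalue exceeds the average (at least 2)
#' @param var_explained PC selection threshold for `component_rule =
#'   "variance"`
#' @param exact_max largest n for exact hierarchical clustering
#' @param subsample_n subsample size used above `exact_max`
#' @return object of class `clustering_result`: `labels` (0-based),
#'   `weights`, `loadings`, `n_components`, `silhouette`, `merge_heights`
#' @export
pca_cluster <- function(frames, feature_columns = NULL, K = 3,
                        component_rule = c("variance", "kaiser"),
                        var_explained = 0.9, exact_max = 6000,
                        subsample_n = 4000) {
  component_rule <- match.arg(component_rule)
  if (is.null(feature_columns))
    feature_columns <- intersect(.pocket_features, names(frames))
  X <- as.matrix(frames[, feature_columns, drop = FALSE])
  n <- nrow(X)
  if (K > n) stop("K exceeds the number of frames")
  if (K == 1) {
    return(structure(list(labels = rep(0L, n), weights = setNames(1, "0"),
                          loadings = NULL, n_components = 0,
                          silhouette = NA_real_),
                     class = "clustering_result"))
  }
  keep <- apply(X, 2, sd) > 0
  X <- X[, keep, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  ncomp <- if (component_rule == "kaiser") {
    max(2L, sum(ev > mean(ev)))
  } else {
    max(2L, min(which(cumsum(ev) / sum(ev) >= var_explained)))
  }
  ncomp <- min(ncomp, ncol(pc$x))
  Y <- pc$x[, seq_len(ncomp), drop = FALSE]
  if (n <= exact_max) {
    hc <- hclust(dist(Y), method = "ward.D2")
    labels <- cutree(hc, k = K)
    heights <- tail(hc$height, K)
  } else {
    idx <- round(seq(1, n, length.out = min(subsample_n, n)))
    hc <- hclust(dist(Y[idx, , drop = FALSE]), method = "ward.D2")
    sub_lab <- cutree(hc, k = K)
    centroids <- t(vapply(seq_len(K), function(k)
      colMeans(Y[idx[sub_lab == k], , drop = FALSE]), numeric(ncomp)))
    d2 <- vapply(seq_len(K), function(k)
      rowSums(sweep(Y, 2, centroids[k, ])^2), numeric(n))
    labels <- max.col(-d2, ties.method = "first")
    heights <- tail(hc$height, K)
  }
  # deterministic label order: clusters numbered by decreasing population,
  # ties broken by lowest frame index
  sizes <- tabulate(labels, K)
  first_idx <- vapply(seq_len(K), function(k) which(labels == k)[1], numeric(1))
  ord <- order(-sizes, first_idx)
  relab <- integer(K)
  relab[ord] <- seq_len(K) - 1L
  labels0 <- relab[labels]
  weights <- tabulate(labels0 + 1L, K) / n
  names(weights) <- as.character(seq_len(K) - 1L)
  sil <- .mean_silhouette(Y, labels0, max_n = 2000)
  structure(list(labels = labels0, weights = weights,
                 loadings = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 n_components = ncomp, silhouette = sil,
                 merge_heights = heights),
            class = "clustering_result")
}

.mean_silhouette <- function(Y, labels0, max_n = 2000) {
  n <- nrow(Y)
  idx <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  Ys <- Y[idx, , drop = FALSE]
  ls <- labels0[idx]
  K <- length(unique(ls))
  if (K < 2) return(NA_real_)
  D <- as.matrix(dist(Ys))
  s <- vapply(seq_along(idx), function(i) {
    di <- vapply(sort(unique(ls)), function(k) {
      mask <- ls == k
      mask[i] <- FALSE
      if (!any(mask)) return(Inf)
      mean(D[i, mask])
    }, numeric(1))
    own <- which(sort(unique(ls)) == ls[i])
    a <- di[own]
    b <- min(di[-own])
    if (!is.finite(a) || !is.finite(b)) return(NA_real_)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s, na.rm = TRUE)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("PCA (%d components) + Ward clustering: %d clusters\n",
              x$n_components, length(x$weights)))
  cat("weights:", paste(sprintf("%s = %.3f", names(x$weights), x$weights),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer/character label vectors of equal length
#' @return the ARI (1 = identical partitions up to relabeling)
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  ai <- sum(comb2(rowSums(tab)))
  bj <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- ai * bj / comb2(n)
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
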