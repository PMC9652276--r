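# Pocket analysis: dip statistic, distributions, contacts, H-bond tables,
# censored relaxation kinetics, clustering.

test_that("dip statistic attains its known exact values", {
  # equally spaced data: exact lower bound 1/(2n)
  for (n in c(10, 50, 200))
    expect_equal(dip_statistic(seq_len(n) / n), 1 / (2 * n), tolerance = 1e-6)
  # two equal point masses: 1/4
  expect_equal(dip_statistic(c(rep(0, 50), rep(1, 50))), 0.25, tolerance = 1e-6)
  # scale and location invariance
  set.seed(1)
  x <- rnorm(300)
  expect_equal(dip_statistic(x), dip_statistic(5 + 3 * x), tolerance = 1e-8)
  # separating two modes increases the statistic
  d1 <- dip_statistic(c(rnorm(200, 0), rnorm(200, 2)))
  d2 <- dip_statistic(c(rnorm(200, 0), rnorm(200, 8)))
  expect_gt(d2, d1)
})

test_that("dip test separates planted bimodality from unimodal samples", {
  set.seed(5)
  bimodal <- c(rnorm(400, 0, 1), rnorm(400, 4, 1)) # 4-SD separation, 50/50
  expect_lt(dip_test(bimodal, n_sim = 200)$p_value, 0.05)
  expect_gt(dip_test(rnorm(800), n_sim = 200)$p_value, 0.05)
  expect_gt(dip_test(runif(800), n_sim = 200)$p_value, 0.05)
})

test_that("distance distributions flag modality and validate names", {
  cfg <- pocket_generator_config()
  late <- generate_late_frames(cfg, 2000, seed = 2)
  early <- generate_early_ensemble(cfg, 2000, seed = 3)
  dd <- distance_distributions(late, c("OD_Arg466", "OB_Tyr216"))
  expect_true(dd$OD_Arg466$bimodal)
  expect_false(dd$OB_Tyr216$bimodal)
  dd_e <- distance_distributions(early, "OD_Arg466")
  expect_false(dd_e$OD_Arg466$bimodal)
  expect_error(distance_distributions(early, "no_such_pair"), "valid names")
  expect_error(distance_distributions(early[1:10, ], "OD_Arg466"), "100")
})

test_that("contact-count probabilities match a hand count and sum to one", {
  toy <- data.frame(Asp207_Arg466_c1 = c(2.9, 2.9, 3.1, 2.5),
                    Asp207_Arg466_c2 = c(2.9, 3.1, 3.1, 2.5))
  ct <- contact_count_probabilities(toy, cutoff = 3.0)
  expect_equal(unname(ct$p), c(0.25, 0.25, 0.5))
  expect_equal(sum(ct$p), 1, tolerance = 1e-12)
  all_close <- data.frame(Asp207_Arg466_c1 = rep(2.5, 10),
                          Asp207_Arg466_c2 = rep(2.5, 10))
  expect_equal(unname(contact_count_probabilities(all_close)$p["P2"]), 1,
               ignore_attr = TRUE)
  expect_error(contact_count_probabilities(data.frame(x = 1)), "missing")
  # early-vs-late contrast: the salt bridge weakens
  cfg <- pocket_generator_config()
  early <- generate_early_ensemble(cfg, 4000, seed = 4)
  late <- generate_late_frames(cfg, 4000, seed = 5)
  expect_gt(contact_count_probabilities(early)$p["P2"],
            contact_count_probabilities(late)$p["P2"])
})

test_that("hydrogen-bond probabilities: indicators, hand count, state contrast", {
  toy <- data.frame(ND_Tyr263 = c(2, 2, 4, 2, 4, 2, 2, 4, 2, 2),
                    pyrrole_water_D = rep(TRUE, 10))
  tab <- hbond_probability_table(toy, list(
    "ND...Tyr263" = list(column = "ND_Tyr263", cutoff = 3.5),
    "pyrrole" = list(indicator = "pyrrole_water_D")))
  expect_equal(tab$probability, c(0.7, 1))
  cfg <- pocket_generator_config()
  early <- generate_early_ensemble(cfg, 4000, seed = 6)
  late <- generate_late_frames(cfg, 4000, seed = 7)
  he <- hbond_probability_table(early)
  hl <- hbond_probability_table(late)
  p <- function(tab, nm) tab$probability[tab$interaction == nm]
  # the pyrrole water takes over the D-ring interaction in the late state
  expect_gt(p(hl, "pyrrole-water...D-ring"), p(hl, "ND...Tyr263"))
  expect_gt(p(he, "ND...Tyr263"), p(he, "pyrrole-water...D-ring"))
  # probabilities are permutation invariant
  he2 <- hbond_probability_table(early[sample(nrow(early)), ])
  expect_equal(he$probability, he2$probability)
})

test_that("censored exponential MLE is exact on degenerate input and recovers tau", {
  # all replicas switch at exactly 0.4 us
  reps <- do.call(rbind, lapply(1:6, function(r)
    data.frame(replica = r, time_us = seq(0.05, 2, by = 0.05),
               Tyr263_Asp207 = c(rep(1.9, 7), rep(4.2, 33)))))
  fit <- estimate_relaxation_lifetime(reps, window = 1)
  expect_equal(fit$tau_us, 0.4, tolerance = 1e-9)
  expect_identical(fit$n_events, 6L)
  # censored-MLE oracle: 200 exponential first-passage times, tau = 1,
  # censored at 2 us; compare against survival::survreg
  set.seed(9)
  t_true <- rexp(200, 1)
  obs <- pmin(t_true, 2)
  ev <- as.numeric(t_true < 2)
  tau_hat <- sum(obs) / sum(ev)
  expect_equal(abs(tau_hat - 1) / 1 < 0.15, TRUE)
  sr <- survival::survreg(survival::Surv(obs, ev) ~ 1, dist = "exponential")
  expect_equal(tau_hat, exp(unname(coef(sr))), tolerance = 1e-6)
  expect_error(estimate_relaxation_lifetime(reps[reps$replica < 5, ],
                                            window = 1), "5 replicas")
})

test_that("relaxation estimator recovers the generator lifetime", {
  cfg <- pocket_generator_config(n_replicas = 60, replica_length_us = 2)
  reps <- generate_relaxation_replicas(cfg, seed = 10)
  fit <- estimate_relaxation_lifetime(reps)
  expect_lt(abs(fit$tau_us - 0.4) / 0.4, 0.2)
  # the profile CI brackets the estimate
  expect_lt(fit$ci_us[1], fit$tau_us)
  expect_gt(fit$ci_us[2], fit$tau_us)
})

test_that("PCA + Ward clustering recovers planted structure", {
  # K = 1: single label with weight one
  cfg <- pocket_generator_config()
  fr <- generate_early_ensemble(cfg, 300, seed = 11)
  c1 <- pca_cluster(fr, K = 1)
  expect_true(all(c1$labels == 0L))
  expect_equal(unname(c1$weights), 1)
  # three well-separated planted Gaussians (6 SD pairwise, every feature
  # informative so the separation survives standardization): ARI > 0.95
  set.seed(13)
  n <- 900
  lab <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  X <- data.frame(a = rnorm(n, c(0, 6, 12)[lab + 1]),
                  b = rnorm(n, c(0, 6, 0)[lab + 1]),
                  c = rnorm(n, c(0, 0, 6)[lab + 1]))
  cl <- pca_cluster(X, feature_columns = c("a", "b", "c"), K = 3)
  expect_gt(adjusted_rand_index(cl$labels, lab), 0.95)
  expect_equal(sum(cl$weights), 1, tolerance = 1e-12)
  expect_error(pca_cluster(X[1:2, ], feature_columns = c("a", "b"), K = 3),
               "exceeds")
})

test_that("own ARI agrees with mclust and clustering is stable to column order", {
  set.seed(14)
  a <- sample(0:2, 300, replace = TRUE)
  b <- ifelse(runif(300) < 0.9, a, sample(0:2, 300, replace = TRUE))
  expect_equal(adjusted_rand_index(a, b),
               unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  expect_equal(adjusted_rand_index(a, a), 1)
  cfg <- pocket_generator_config()
  fr <- generate_early_ensemble(cfg, 3000, seed = 15)
  cols <- intersect(c("OD_His290", "OD_water", "Tyr263_Asp207", "ND_Tyr263",
                      "OD_Arg466", "OB_Ser257", "OB_Tyr216",
                      "Asp207_Arg466_c1", "Asp207_Arg466_c2"), names(fr))
  cl1 <- pca_cluster(fr, cols, K = 3)
  cl2 <- pca_cluster(fr, rev(cols), K = 3)
  expect_equal(adjusted_rand_index(cl1$labels, cl2$labels), 1, tolerance = 1e-9)
  expect_equal(sort(unname(cl1$weights)), sort(unname(cl2$weights)),
               tolerance = 1e-12)
})
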