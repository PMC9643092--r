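test_that("correlated latent draws honor the target correlation matrix", {
  id <- diag(3)
  z <- draw_correlated_latents(1e5, id, seed = 2)
  expect_true(all(abs(cor(z)[upper.tri(id)]) < 0.02))

  corr <- rctdistill:::latent_correlation(0.5, -0.2, 0.1)
  z2 <- draw_correlated_latents(1e5, corr, seed = 3)
  emp <- cor(z2)
  expect_lt(abs(emp["te", "part"] - 0.5), 0.02)
  expect_lt(abs(emp["te", "pred"] + 0.2), 0.02)
  expect_lt(abs(emp["part", "pred"] - 0.1), 0.02)
  # margins are standard normal
  expect_true(all(abs(colMeans(z2)) < 0.02))
  expect_true(all(abs(apply(z2, 2, sd) - 1) < 0.02))
})

test_that("infeasible correlation matrices are rejected", {
  bad <- rctdistill:::latent_correlation(0.9, 0.9, -0.9)
  expect_error(draw_correlated_latents(10, bad), "not PD")
  expect_error(sim_scenario(rho_te_part = 0.9, rho_te_pred = 0.9,
                            rho_part_pred = -0.9), "not PD")
  asym <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(draw_correlated_latents(10, asym), "symmetric")
})

test_that("the default scenario correlation matrix is barely positive definite", {
  sc <- sim_scenario()
  expect_equal(det(sc$corr), 0.014, tolerance = 1e-9)
  expect_silent(chol(sc$corr))
})

test_that("replicates apply exact rank thresholds and arm logic", {
  sc <- sim_scenario(taumax = -0.3, n_per_arm = 500, seed = 10)
  rep1 <- simulate_trial_replicate(sc, seed = 77)
  rep2 <- simulate_trial_replicate(sc, seed = 77)
  expect_identical(rep1, rep2)
  N <- 1000
  expect_identical(sum(rep1$responder), as.integer(round(0.4 * N)))
  expect_identical(sum(rep1$arm), 500L)
  expect_true(all(rep1$arm[rep1$enrolled] == 1L))
  # effect applied only to enrolled intervention-arm responders
  treated <- rep1$responder & rep1$enrolled
  expect_identical(sum(treated) > 0, TRUE)
})

test_that("null replicates have arm-exchangeable outcomes", {
  sc <- sim_scenario(taumax = 0, n_per_arm = 2000, seed = 5)
  pvals <- vapply(1:20, function(i) {
    r <- simulate_trial_replicate(sc, seed = 100 + i)
    t.test(outcome ~ arm, data = r)$p.value
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 4)   # ~binomial(20, 0.05)
})

test_that("responder-enrollee overlap exceeds the independence bound", {
  # with correlation 0.3 between the two latents, the joint top-40% mass is
  # strictly above 0.16; the Monte-Carlo orthant oracle gives the target
  oracle <- joint_top_fraction_probability(0.3, 0.4, n_draws = 2e6, seed = 8)
  expect_gt(oracle, 0.16)
  sc <- sim_scenario(taumax = -0.1, n_per_arm = 4000, seed = 6)
  fr <- vapply(1:10, function(i) {
    r <- simulate_trial_replicate(sc, seed = 200 + i)
    int <- r$arm == 1L
    mean(r$responder[int] & r$enrolled[int])
  }, numeric(1))
  expect_lt(abs(mean(fr) - oracle), 0.02)
})

test_that("orthant probability oracle hits its closed-form endpoints", {
  expect_equal(joint_top_fraction_probability(0, 0.4, n_draws = 4e6, seed = 1),
               0.16, tolerance = 0.002)
  expect_equal(joint_top_fraction_probability(1 - 1e-9, 0.4, n_draws = 4e6,
                                              seed = 1),
               0.40, tolerance = 0.002)
  # monotone non-decreasing in rho
  probs <- vapply(c(-0.5, 0, 0.3, 0.6, 0.9),
                  function(r) joint_top_fraction_probability(r, 0.4,
                                                             n_draws = 2e6,
                                                             seed = 4),
                  numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("the Welch test helper matches stats::t.test", {
  set.seed(30)
  for (i in 1:20) {
    y1 <- rnorm(sample(5:50, 1), sd = runif(1, 0.5, 2))
    y0 <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    expect_equal(rctdistill:::welch_p(y1, y0),
                 t.test(y1, y0)$p.value, tolerance = 1e-12)
  }
})

test_that("within-replicate distilled subsets are nested", {
  sc <- sim_scenario(taumax = -0.2, n_per_arm = 300, seed = 11)
  r <- simulate_trial_replicate(sc, seed = 12)
  pred_rank <- rank(-r$pred_latent, ties.method = "first")
  keep <- lapply(c(1, 0.6, 0.25), function(f) which(pred_rank <= round(f * 600)))
  expect_true(all(keep[[3]] %in% keep[[2]]))
  expect_true(all(keep[[2]] %in% keep[[1]]))
  expect_length(keep[[3]], 150L)
})

test_that("power grids are reproducible and respond to effect size", {
  sc <- sim_scenario(taumax = c(0, -0.4), n_per_arm = 400, reps = 150,
                     seed = 42)
  g1 <- estimate_power_grid(sc)
  g2 <- estimate_power_grid(sc)
  expect_identical(g1, g2)
  expect_identical(nrow(g1), 10L)
  expect_equal(g1$mc_se,
               sqrt(g1$rejection_rate * (1 - g1$rejection_rate) / g1$reps))
  # power at a large effect dominates the null at every retention level
  null_rate <- g1$rejection_rate[g1$taumax == 0]
  alt_rate <- g1$rejection_rate[g1$taumax == -0.4]
  expect_true(all(alt_rate > null_rate))
})

test_that("unpredictable participation yields no distillation gain", {
  # prediction uncorrelated with everything: trimming only shrinks the
  # sample, so no retention level can beat the full-sample power, and the
  # per-subject effect concentration stays constant across levels
  sc <- sim_scenario(taumax = -0.3, rho_te_pred = 0, rho_part_pred = 0,
                     n_per_arm = 1500, reps = 400, seed = 13)
  g <- estimate_power_grid(sc)
  full <- g$rejection_rate[g$retention_fraction == 1]
  expect_true(all(g$rejection_rate <= full + 3 * pmax(g$mc_se, 1e-3)))
  # and at the null the curve is genuinely flat at the nominal level
  sc0 <- sim_scenario(taumax = 0, rho_te_pred = 0, rho_part_pred = 0,
                      n_per_arm = 1500, reps = 400, seed = 17)
  g0 <- estimate_power_grid(sc0)
  expect_true(all(abs(g0$rejection_rate - 0.05) <=
                    3 * pmax(g0$mc_se, 1e-3)))
})

test_that("sample-size calibration brackets and converges", {
  # degenerate: no effect, target at the nominal level
  sc0 <- sim_scenario(taumax = 0, n_per_arm = 500, seed = 14)
  n0 <- calibrate_sample_size(sc0, target_power = 0.05, seed = 14)
  expect_true(isTRUE(attr(n0, "degenerate")))

  sc <- sim_scenario(taumax = -0.4, n_per_arm = 500, seed = 15)
  n_lo <- calibrate_sample_size(sc, target_power = 0.3, tolerance = 0.03,
                                reps = 1000, n_bounds = c(50, 2000), seed = 15)
  n_hi <- calibrate_sample_size(sc, target_power = 0.7, tolerance = 0.03,
                                reps = 1000, n_bounds = c(50, 2000), seed = 15)
  expect_gt(n_hi, n_lo)
  expect_lt(abs(attr(n_lo, "achieved_power") - 0.3), 0.05)
  expect_lt(abs(attr(n_hi, "achieved_power") - 0.7), 0.05)
  expect_error(calibrate_sample_size(sc, target_power = 0.999, reps = 1000,
                                     n_bounds = c(10, 30), seed = 16),
               "unreachable")
})

test_that("scenario validation rejects malformed fields", {
  expect_error(sim_scenario(taumax = numeric(0)), "taumax")
  expect_error(sim_scenario(taumax = 0.2), "taumax")
  expect_error(sim_scenario(retention_grid = c(0.5, 0.5)), "retention_grid")
  expect_error(sim_scenario(n_per_arm = 1), "n_per_arm")
})
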