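test_that("the generator is deterministic in its seed and varies across seeds", {
  spec <- list(n = 20, signal = c(TYR341 = -0.6, ALA513 = 0.4))
  s1 <- simulate_decomposition(spec$n, spec$signal, n_noise_residues = 3, seed = 42)
  s2 <- simulate_decomposition(spec$n, spec$signal, n_noise_residues = 3, seed = 42)
  s3 <- simulate_decomposition(spec$n, spec$signal, n_noise_residues = 3, seed = 43)
  expect_identical(s1$energies, s2$energies)
  expect_identical(s1$activities, s2$activities)
  expect_false(isTRUE(all.equal(s1$energies, s3$energies)))
  # truth embeds the generating parameters
  expect_equal(s1$truth$rho[["TYR341"]], -0.6)
  expect_equal(unname(s1$truth$rho[s1$truth$noise_residues]), rep(0, 3))
})

test_that("large-n sample correlations converge to the planted values", {
  sim <- simulate_decomposition(10000, signal = c(TYR341 = 0.99, GLN178 = 0),
                                n_noise_residues = 1, seed = 7)
  prof <- residue_correlations(sim$energies, sim$activities)
  r <- setNames(prof$r, prof$residue)
  expect_lt(abs(r[["TYR341"]] - 0.99), 0.005)
  expect_lt(abs(r[["GLN178"]]), 0.03)
  expect_lt(abs(r[[sim$truth$noise_residues[1]]]), 0.03)
})

test_that("a strong negative signal is estimated near its target at moderate n", {
  sim <- simulate_decomposition(500, signal = c(TYR1 = -0.9),
                                n_noise_residues = 2, seed = 21)
  prof <- residue_correlations(sim$energies, sim$activities)
  expect_lt(abs(prof$r[prof$residue == "TYR1"] - (-0.9)), 0.05)
})

test_that("mean estimated correlations satisfy the asymptotic-error bound", {
  # parameter recovery: mean r over replicates within 2 (1 - rho^2) / sqrt(n - 1)
  rhos <- c(TYR341 = -0.6, ALA513 = -0.3, LEU338 = 0.5)
  n_compounds <- 60
  set.seed(13)
  est <- replicate(200, {
    sim <- simulate_decomposition(n_compounds, rhos, n_noise_residues = 0)
    prof <- residue_correlations(sim$energies, sim$activities)
    setNames(prof$r, prof$residue)[names(rhos)]
  })
  mean_r <- rowMeans(est)
  bound <- 2 * (1 - rhos^2) / sqrt(n_compounds - 1)
  for (res in names(rhos)) {
    expect_lt(abs(mean_r[[res]] - rhos[[res]]), bound[[res]])
  }
})

test_that("generator validates its specification", {
  expect_error(simulate_decomposition(2, c(TYR1 = -0.5)), "n_compounds >= 3")
  expect_error(simulate_decomposition(8, c(TYR1 = -1.5)), "inside")
  expect_error(simulate_decomposition(8, c(-0.5)), "named")
  expect_error(simulate_decomposition(8, numeric(), n_noise_residues = 0),
               "at least one residue")
  expect_error(simulate_decomposition(8, c(XYZ99 = -0.5)), "XYZ99")
})

test_that("uniform activity option matches the requested mean and sd", {
  sim <- simulate_decomposition(20000, c(TYR1 = -0.5), seed = 9,
                                activity_dist = "uniform",
                                activity_mean = 7.8, activity_sd = 0.7)
  expect_lt(abs(mean(sim$activities$pic50) - 7.8), 0.02)
  expect_lt(abs(sd(sim$activities$pic50) - 0.7), 0.02)
})

test_that("recovery experiment summarises selection behaviour", {
  # a single replicate reports that replicate's values verbatim
  one <- recovery_experiment(30, signal = c(TYR341 = -0.7),
                             n_noise_residues = 1, n_reps = 1, seed = 5)
  expect_equal(one$n_reps, 1L)
  expect_true(is.na(one$per_residue$sd_r[1]))
  expect_equal(one$per_residue$rho_true, c(-0.7, 0))
  expect_true(all(one$per_residue$selected_rate %in% c(0, 1)))

  # plain sign rule at large n: perfect sensitivity, but noise residues are
  # still admitted about half the time — the screened rule fixes that
  big <- recovery_experiment(300, signal = c(TYR341 = -0.6, SER339 = -0.6),
                             n_noise_residues = 4, n_reps = 40, seed = 6)
  expect_gte(big$sensitivity, 0.99)
  expect_gt(big$specificity, 0.25)
  expect_lt(big$specificity, 0.75)

  scr <- recovery_experiment(300, signal = c(TYR341 = -0.6, SER339 = -0.6),
                             n_noise_residues = 4, n_reps = 40, seed = 6,
                             alpha = 0.05)
  expect_gte(scr$sensitivity, 0.99)
  expect_gte(scr$specificity, 0.9)
})

test_that("end-to-end pipeline recovers a planted 7-residue cluster at large n", {
  planted <- setNames(rep(-0.75, 7),
                      c("GLN178", "SER339", "TYR341", "ARG499",
                        "PHE504", "VAL509", "ALA513"))
  # Bonferroni-corrected screen across the 12 candidate residues gives
  # family-wise control of false inclusions; recovery is then exact except
  # for rare (~1%) extreme null draws, so require 9 of 10 replicates exact.
  set.seed(17)
  exact <- vapply(1:10, function(i) {
    sim <- simulate_decomposition(250, signal = planted, n_noise_residues = 5,
                                  seed = NULL)
    pl <- run_cluster_pipeline(sim$energies, sim$activities, alpha = 0.05 / 12)
    setequal(pl$residues, names(planted))
  }, logical(1))
  expect_gte(sum(exact), 9)
})

test_that("profile p-values agree with stats::cor.test", {
  sim <- simulate_decomposition(25, signal = c(TYR341 = -0.5),
                                n_noise_residues = 3, seed = 8)
  prof <- residue_correlations(sim$energies, sim$activities)
  for (res in prof$residue) {
    ct <- stats::cor.test(sim$energies[[res]], sim$activities$pic50)
    expect_equal(prof$p_value[prof$residue == res], ct$p.value,
                 tolerance = 1e-10)
  }
})
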