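test_that("pearson_r matches published values and exact cases", {
  # the strongest negatively correlated residue of the COX-2 dataset
  tyr341 <- c(-3.47, -4.47, -4.03, -5.72, -4.41, -2.10, -1.93, -4.67)
  pic50 <- unname(printed_cox2_pic50())
  expect_equal(pearson_r(tyr341, pic50), -0.79, tolerance = 0.02 / 0.79)
  expect_identical(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
})

test_that("pearson_r rejects degenerate inputs instead of returning NA", {
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(c(1, 2), c(2, 1)), "at least 3")
  expect_error(pearson_r(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(pearson_r(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("pearson_r agrees with the brute-force covariance oracle and stats::cor", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 10))
    y <- rnorm(n, sd = runif(1, 0.5, 10))
    r <- pearson_r(x, y)
    expect_equal(r, oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(r, stats::cor(x, y), tolerance = 1e-12)
  }
})

test_that("pearson_r is symmetric, affine-invariant and bounded", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(10)
    y <- rnorm(10)
    a <- runif(1, -5, 5)
    while (a == 0) a <- runif(1, -5, 5)
    b <- runif(1, -5, 5)
    r <- pearson_r(x, y)
    expect_equal(pearson_r(y, x), r)
    expect_equal(pearson_r(a * x + b, y), sign(a) * r, tolerance = 1e-12)
    expect_lte(abs(r), 1)
  }
})

test_that("residue profile reproduces the published twelve correlations", {
  prof <- residue_correlations(cox2_energies(), cox2_activities())
  expected <- c(GLN178 = -0.62, SER339 = -0.61, TYR341 = -0.79, ARG499 = -0.29,
                PHE504 = -0.28, VAL509 = 0.20, ALA513 = -0.22, VAL335 = 0.03,
                LEU338 = 0.80, TYR371 = 0.63, ILE503 = 0.44, SER516 = 0.09)
  got <- setNames(prof$r, prof$residue)
  for (res in names(expected)) {
    expect_lt(abs(got[[res]] - expected[[res]]), 0.03 + 1e-12)
  }
  expect_true(all(prof$defined))
  expect_equal(unique(prof$n), 8L)
})

test_that("residue profile pairs by compound id, warns on extras, flags zero variance", {
  E <- toy_energies()
  A <- toy_activities()
  # shuffling activity rows must not change the profile (id pairing)
  expect_equal(residue_correlations(E, A),
               residue_correlations(E, A[c(3, 1, 4, 2), ]))
  expect_warning(
    residue_correlations(E, dplyr::bind_rows(A, tibble::tibble(compound = "zz",
                                                               pic50 = 7))),
    "ignoring")
  E$GLY2 <- -2.5
  expect_warning(residue_correlations(E, A), "zero")
  prof <- suppressWarnings(residue_correlations(E, A))
  expect_false(prof$defined[prof$residue == "GLY2"])
  expect_true(is.na(prof$r[prof$residue == "GLY2"]))

  expect_error(residue_correlations(E, A[1:3, ]), "no activity")
})

test_that("component correlations reproduce the published five values", {
  cc <- component_correlations(cox2_components(), cox2_activities())
  expected <- c(elec = -0.04, vdw = -0.07, polar_solv = -0.16,
                sasa = -0.27, binding = -0.27)
  got <- setNames(cc$r, cc$component)
  for (comp in names(expected)) {
    expect_lt(abs(got[[comp]] - expected[[comp]]), 0.02 + 1e-12)
  }
  # a component identical to the activity vector correlates perfectly
  C <- cox2_components()
  C$binding <- cox2_activities()$pic50
  cc2 <- component_correlations(C, cox2_activities())
  expect_equal(cc2$r[cc2$component == "binding"], 1, ignore_attr = TRUE)
})

test_that("cluster energies sum the chosen residue columns", {
  E <- cox2_energies()
  ce <- cluster_energy(E, cox2_cluster())
  # hand-sum of the seven printed celecoxib entries
  expect_equal(ce$energy[ce$compound == "celecoxib"], -45.23)
  # singleton equals that column
  expect_equal(cluster_energy(E, "PHE504")$energy, E$PHE504)
  # all columns equal row sums
  expect_equal(cluster_energy(E, residue_labels(E))$energy,
               rowSums(as.matrix(E[, -1])))
  # additivity over disjoint subsets
  s1 <- c("GLN178", "SER339")
  s2 <- c("TYR341", "ALA513")
  expect_equal(cluster_energy(E, c(s1, s2))$energy,
               cluster_energy(E, s1)$energy + cluster_energy(E, s2)$energy)
  expect_error(cluster_energy(E, character()), "empty")
  expect_error(cluster_energy(E, "TRP999"), "TRP999")
})

test_that("cluster correlation scores the published cluster and is order-invariant", {
  E <- cox2_energies()
  A <- cox2_activities()
  fit <- cluster_correlation(E, A, cox2_cluster())
  expect_lt(abs(fit$r - (-0.60)), 0.03)
  expect_equal(fit$r, -0.5917860249, tolerance = 1e-9)

  # any permutation of the residue set gives the identical r
  set.seed(1)
  for (i in 1:5) {
    expect_identical(cluster_correlation(E, A, sample(cox2_cluster()))$r, fit$r)
  }
  # singleton cluster equals the profile entry for that residue
  prof <- residue_correlations(E, A)
  expect_equal(cluster_correlation(E, A, "TYR341")$r,
               prof$r[prof$residue == "TYR341"])
  expect_lt(abs(cluster_correlation(E, A, "TYR341")$r - (-0.79)), 0.02)
})

test_that("tidy and glance expose the cluster result as tibbles", {
  fit <- loo_cv(cox2_energies(), cox2_activities(), cox2_cluster())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("compound", "energy", "pic50"))
  gl <- glance(fit)
  expect_equal(gl$n_residues, 7L)
  expect_equal(gl$r, fit$r)
  expect_equal(gl$cv_q2, fit$cv$q2)
})
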