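test_that("sign rule keeps the six negatively correlated COX-2 residues", {
  prof <- residue_correlations(cox2_energies(), cox2_activities())
  neg <- select_by_sign(prof, "negative")
  # the rule as written excludes VAL509 (its own r is positive)
  expect_setequal(neg, c("GLN178", "SER339", "TYR341", "ARG499",
                         "PHE504", "ALA513"))
  pos <- select_by_sign(prof, "positive")
  expect_setequal(pos, c("VAL509", "VAL335", "LEU338", "TYR371",
                         "ILE503", "SER516"))
  # partition: every defined residue has exactly one sign here (no exact zeros)
  expect_setequal(c(neg, pos), prof$residue)
})

test_that("sign selection handles boundaries: all-positive, exact zero, undefined", {
  prof <- tibble::tibble(residue = c("ALA1", "GLY2", "TRP3"),
                         r = c(0.5, 0.0, NA), n = 5L,
                         defined = c(TRUE, TRUE, FALSE))
  expect_length(select_by_sign(prof, "negative"), 0L)
  # r == 0 excluded under strict_zero, included otherwise
  expect_false("GLY2" %in% select_by_sign(prof, "negative", strict_zero = TRUE))
  expect_true("GLY2" %in% select_by_sign(prof, "negative", strict_zero = FALSE))
  # undefined residues are never selected
  expect_false("TRP3" %in% select_by_sign(prof, "positive", strict_zero = FALSE))
  expect_error(select_by_sign(prof[0, ]), "empty")
})

test_that("site assignment intersects selections with each SAR site", {
  ps <- assign_sites(cox2_cluster(), cox2_sites())
  expect_setequal(ps$residue[ps$site == "Site-1"], c("PHE504", "VAL509"))
  expect_setequal(ps$residue[ps$site == "Site-2"],
                  c("GLN178", "SER339", "ARG499"))
  expect_setequal(ps$residue[ps$site == "Site-3"], c("TYR341", "ALA513"))

  # empty selection: every site still listed, with no members
  empty <- assign_sites(character(), cox2_sites())
  expect_setequal(unique(empty$site), c("Site-1", "Site-2", "Site-3"))
  expect_true(all(is.na(empty$residue)))

  # residues in no site are reported as unassigned
  un <- assign_sites(c("TYR341", "LEU338"), cox2_sites())
  expect_equal(un$residue[un$site == "unassigned"], "LEU338")
})

test_that("the pipeline reproduces cluster_correlation under overrides", {
  E <- cox2_energies()
  A <- cox2_activities()
  pl <- run_cluster_pipeline(E, A, residues = cox2_cluster(),
                             sites = cox2_sites())
  expect_lt(abs(pl$cluster$r - (-0.60)), 0.03)
  expect_identical(pl$cluster$r, cluster_correlation(E, A, cox2_cluster())$r)
  expect_setequal(pl$residues, cox2_cluster())

  # default sign-rule run drops VAL509; its r is pinned by recomputation
  pl6 <- run_cluster_pipeline(E, A)
  expect_setequal(pl6$residues, setdiff(cox2_cluster(), "VAL509"))
  expect_equal(pl6$cluster$r, -0.6502402078, tolerance = 1e-9)

  # single-residue override equals the profile entry
  pl1 <- run_cluster_pipeline(E, A, residues = "TYR341")
  expect_equal(pl1$cluster$r, pl1$profile$r[pl1$profile$residue == "TYR341"])

  # determinism: identical inputs give identical results
  expect_equal(run_cluster_pipeline(E, A, sites = cox2_sites()),
               run_cluster_pipeline(E, A, sites = cox2_sites()))
})

test_that("the pipeline errors when selection is empty and no override given", {
  # every residue rises with activity, so negative-sign selection keeps nothing
  E <- tibble::tibble(compound = c("a", "b", "c", "d"),
                      ALA1 = c(1, 2, 3, 4.5), GLY2 = c(0.5, 1.8, 2.1, 3.9))
  A <- tibble::tibble(compound = c("a", "b", "c", "d"),
                      pic50 = c(6, 7, 7.5, 8.2))
  expect_error(run_cluster_pipeline(E, A, sign = "negative"), "override")
})
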