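# Independent brute-force oracles and small fixtures used across tests.

# Two-pass covariance/variance Pearson correlation, written independently of
# pearson_r(): explicit mean pass, then explicit moment sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0
  sxx <- 0
  syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Full enumeration of residue subsets scored with stats::cor, ranked with the
# same documented tie-break (objective, then smaller k, then label).
oracle_enumerate <- function(energies, activities, k_min, k_max,
                             objective = "most_negative_r") {
  res <- setdiff(names(energies), "compound")
  pic50 <- activities$pic50[match(energies$compound, activities$compound)]
  rows <- list()
  for (k in k_min:k_max) {
    cmb <- utils::combn(res, k, simplify = FALSE)
    for (members in cmb) {
      s <- rowSums(as.matrix(energies[members]))
      if (stats::var(s) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        k = k,
        label = paste(sort(members), collapse = "+"),
        r = stats::cor(s, pic50)
      )
    }
  }
  out <- do.call(rbind, rows)
  key <- if (objective == "most_negative_r") out$r else -abs(out$r)
  out[order(key, out$k, out$label), ]
}

# 4-compound x 3-residue toy matrix with distinct, hand-set structure.
toy_energies <- function() {
  tibble::tibble(
    compound = c("c1", "c2", "c3", "c4"),
    ALA1 = c(-1.0, -2.0, -3.0, -4.0),
    GLY2 = c(-5.0, -1.5, -4.0, -2.5),
    TRP3 = c(2.0, 1.0, -1.0, -2.0)
  )
}

toy_activities <- function() {
  tibble::tibble(compound = c("c1", "c2", "c3", "c4"),
                 pic50 = c(6.1, 6.9, 7.6, 8.4))
}

# Printed per-residue energies for the packaged COX-2 dataset, transcribed
# independently of the shipped CSVs (residue-major, as published).
printed_cox2_energies <- function() {
  list(
    GLN178 = c(-2.78, -4.06, -4.34, -1.25, -7.09, 0.69, 1.15, -0.02),
    SER339 = c(-4.41, -5.66, -8.08, -8.51, -6.03, -4.81, -3.91, -4.29),
    TYR341 = c(-3.47, -4.47, -4.03, -5.72, -4.41, -2.10, -1.93, -4.67),
    PHE504 = c(-10.22, -12.88, -13.90, -15.15, -13.76, -13.31, -13.23, -13.46),
    ARG499 = c(-7.01, -6.97, -2.82, -13.00, -7.58, -1.95, -3.32, -1.21),
    VAL509 = c(-11.56, -10.76, -10.93, -13.66, -12.10, -13.54, -11.63, -10.50),
    ALA513 = c(-5.78, -4.29, -4.28, -6.77, -5.41, -6.08, -3.76, -6.35),
    VAL335 = c(-4.70, -5.49, -4.89, -6.07, -6.01, -4.15, -6.18, -5.93),
    LEU338 = c(-9.22, -8.10, -9.80, -10.33, -9.11, -10.90, -11.86, -9.46),
    TYR371 = c(-2.18, -1.21, -2.62, -4.38, -4.00, -3.10, -5.43, -3.19),
    ILE503 = c(-5.38, -5.84, -6.38, -4.39, -6.62, -5.36, -8.13, -7.36),
    SER516 = c(1.86, -8.44, -5.76, -0.90, 1.22, 2.53, -9.18, 0.87)
  )
}

# Compound order of the printed per-residue table.
printed_cox2_compounds <- function() {
  c("celecoxib", "polmacoxib", "valdecoxib", "celecoxib-analog",
    "SC-558", "SC-58125", "rofecoxib", "DuP-697")
}

printed_cox2_pic50 <- function() {
  c(celecoxib = 7.40, polmacoxib = 8.57, valdecoxib = 8.30,
    `celecoxib-analog` = 8.10, `SC-558` = 8.03, `SC-58125` = 7.40,
    rofecoxib = 6.30, `DuP-697` = 8.04)
}

# Published component energies (vdw, elec, polar_solv, sasa, binding).
printed_cox2_components <- function() {
  list(
    celecoxib = c(-224.66, -134.98, 182.56, -20.95, -198.03),
    `celecoxib-analog` = c(-267.01, -165.37, 183.58, -20.43, -269.24),
    valdecoxib = c(-223.09, -141.71, 158.65, -18.30, -224.45),
    polmacoxib = c(-227.50, -135.45, 166.50, -20.16, -216.61),
    `SC-558` = c(-264.45, -150.19, 167.53, -20.66, -267.77),
    `SC-58125` = c(-257.63, -97.15, 159.46, -20.57, -215.89),
    rofecoxib = c(-236.89, -136.90, 167.51, -18.19, -224.48),
    `DuP-697` = c(-265.36, -54.28, 109.36, -19.36, -229.64)
  )
}
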