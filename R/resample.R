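# Run code with a reproducible, self-contained RNG state: the caller's
# .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Permutation test for a cluster correlation
#'
#' Assesses whether a cluster's cumulative-energy correlation with activity
#' could arise by chance: activity labels are permuted across compounds
#' `n_perm` times, the cluster correlation recomputed each time, and the
#' p-value is the smoothed exceedance rate `(b + 1) / (n_perm + 1)` where `b`
#' counts permutations at least as extreme as the observed r. The smoothing
#' makes the estimator conservative and never exactly zero; the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @inheritParams cluster_correlation
#' @param n_perm Number of label permutations (99 or more recommended).
#' @param seed Integer seed; the test is fully determined by (inputs, seed).
#' @param alternative `"two_sided"` (on |r|), `"less"` or `"greater"`.
#' @return The `cluster_cor` for the observed data, augmented with fields
#'   `p_value`, `n_perm`, `alternative`, `seed`.
#' @examples
#' permutation_test(cox2_energies(), cox2_activities(), cox2_cluster(),
#'                  n_perm = 199, seed = 1)
#' @export
permutation_test <- function(energies, activities, residues, n_perm = 999L,
                             seed = NULL,
                             alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n_perm <- as.integer(n_perm)
  stopifnot(n_perm >= 1L)
  obs <- cluster_correlation(energies, activities, residues)
  x <- obs$energies$energy
  y <- obs$energies$pic50
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  # permuting y leaves its variance unchanged, so only the cross term varies
  yc_sd <- sqrt(sum((y - mean(y))^2))
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    yp <- sample(y)
    sum(xc * (yp - mean(yp))) / (sx * yc_sd)
  }, numeric(1)))
  b <- switch(alternative,
    two_sided = sum(abs(r_perm) >= abs(obs$r)),
    less      = sum(r_perm <= obs$r),
    greater   = sum(r_perm >= obs$r)
  )
  obs$p_value <- (b + 1) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs$alternative <- alternative
  obs$seed <- seed
  obs
}

#' Bootstrap confidence interval for a cluster correlation
#'
#' Percentile bootstrap over compound-level resamples: compounds are drawn
#' with replacement, the cluster correlation recomputed on each resample, and
#' the interval taken from the empirical quantiles. Resamples in which either
#' vector has zero variance (e.g. the same compound drawn every time) leave
#' the correlation undefined and are redrawn; the redraw count is reported.
#'
#' @inheritParams permutation_test
#' @param n_boot Number of bootstrap resamples.
#' @param level Interval coverage (default 0.95).
#' @return The observed `cluster_cor` augmented with field `ci`, a list
#'   `low`/`high`/`level`/`n_boot`/`n_redrawn`.
#' @export
bootstrap_ci <- function(energies, activities, residues, n_boot = 1999L,
                         seed = NULL, level = 0.95) {
  n_boot <- as.integer(n_boot)
  stopifnot(n_boot >= 1L, level > 0, level < 1)
  energies <- as_energy_matrix(energies)
  if (nrow(energies) < 4L) {
    stop("bootstrap needs at least 4 compounds, got ", nrow(energies),
         call. = FALSE)
  }
  obs <- cluster_correlation(energies, activities, residues)
  x <- obs$energies$energy
  y <- obs$energies$pic50
  n <- length(x)
  n_redrawn <- 0L
  r_boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[idx]) > 0 && stats::var(y[idx]) > 0) {
        return(pearson_r(x[idx], y[idx]))
      }
      n_redrawn <<- n_redrawn + 1L
    }
  }, numeric(1)))
  qs <- stats::quantile(r_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  obs$ci <- list(low = qs[1], high = qs[2], level = level, n_boot = n_boot,
                 n_redrawn = n_redrawn)
  obs$seed <- seed
  obs
}

#' Leave-one-out cross-validation of the cluster-energy score
#'
#' Tests the predictive claim behind a cluster: that its cumulative energy
#' can predict activity for an unseen compound. Each compound is held out in
#' turn; a univariate least-squares line pIC50 ~ cluster energy is fitted on
#' the rest and used to predict the held-out compound. Reports
#' `q2 = 1 - PRESS / SS_tot` (cross-validated R-squared; at or below zero
#' means no predictive value) and the RMSE of the held-out predictions.
#'
#' @inheritParams cluster_correlation
#' @return The observed `cluster_cor` augmented with field `cv`, a list with
#'   `predictions` (tibble `compound`/`pic50`/`predicted`), `q2` and `rmse`.
#' @examples
#' loo_cv(cox2_energies(), cox2_activities(), cox2_cluster())$cv$q2
#' @export
loo_cv <- function(energies, activities, residues) {
  energies <- as_energy_matrix(energies)
  if (nrow(energies) < 4L) {
    stop("leave-one-out CV needs at least 4 compounds, got ", nrow(energies),
         call. = FALSE)
  }
  obs <- cluster_correlation(energies, activities, residues)
  x <- obs$energies$energy
  y <- obs$energies$pic50
  n <- length(x)
  pred <- vapply(seq_len(n), function(i) {
    xt <- x[-i]
    yt <- y[-i]
    if (stats::var(xt) == 0) {
      stop("training fold without compound ", obs$energies$compound[i],
           " has zero cluster-energy variance", call. = FALSE)
    }
    slope <- sum((xt - mean(xt)) * (yt - mean(yt))) / sum((xt - mean(xt))^2)
    mean(yt) + slope * (x[i] - mean(xt))
  }, numeric(1))
  press <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  obs$cv <- list(
    predictions = tibble::tibble(compound = obs$energies$compound,
                                 pic50 = y, predicted = pred),
    q2 = 1 - press / ss_tot,
    rmse = sqrt(mean((y - pred)^2))
  )
  obs
}
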