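#' Pearson product-moment correlation with strict domain checks
#'
#' The correlation statistic at the core of the analysis. Unlike
#' [stats::cor()], degenerate inputs are hard errors rather than silent `NA`s:
#' a zero-variance vector, fewer than three pairs, or a length mismatch all
#' stop. A Spearman rank variant is available for robustness studies.
#'
#' @param x,y Numeric vectors of equal length, at least 3, each with nonzero
#'   variance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation coefficient, a single number in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3), c(3, 2, 1)) # -1
#' @export
pearson_r <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("x and y must be numeric", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("correlation needs at least 3 observations, got ", length(x),
         call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite with no missing values", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc^2)
  sy <- sum(yc^2)
  if (sx == 0 || sy == 0) {
    stop("zero variance in ", if (sx == 0) "x" else "y",
         "; correlation is undefined", call. = FALSE)
  }
  r <- sum(xc * yc) / sqrt(sx * sy)
  # guard against floating-point drift just past +/-1
  max(-1, min(1, r))
}

#' Residue-wise correlation profile
#'
#' Correlates each residue's per-compound energy contribution with activity,
#' pairing rows by compound identifier. This is the per-residue screening
#' step: residues whose contribution becomes more favourable (more negative)
#' as potency rises get negative `r` and are candidates for the cluster.
#'
#' Residue columns with zero variance across compounds have no defined
#' correlation; they are flagged (`defined = FALSE`, `r = NA`) and excluded
#' from downstream selection rather than coerced to zero.
#'
#' @param energies An energy matrix (see [as_energy_matrix()]).
#' @param activities An activity table covering every compound in `energies`.
#' @param method Correlation method, passed to [pearson_r()].
#' @return A tibble with one row per residue: `residue`, `r`, `n` (compounds
#'   used), `p_value` (two-sided test of zero correlation, via the exact t
#'   transform) and `defined`, in the matrix's column order. Class
#'   `"residue_profile"`.
#' @examples
#' residue_correlations(cox2_energies(), cox2_activities())
#' @export
residue_correlations <- function(energies, activities,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  energies <- as_energy_matrix(energies)
  if (nrow(energies) < 3L) {
    stop("need at least 3 compounds to correlate, got ", nrow(energies),
         call. = FALSE)
  }
  pic50 <- match_activities(energies, activities)
  res <- residue_labels(energies)
  r <- vapply(res, function(rl) {
    v <- energies[[rl]]
    if (stats::var(v) == 0) {
      warning("residue ", rl, " has zero energy variance; correlation undefined",
              call. = FALSE)
      return(NA_real_)
    }
    pearson_r(v, pic50, method = method)
  }, numeric(1))
  out <- tibble::tibble(
    residue = res,
    r = unname(r),
    n = nrow(energies),
    p_value = cor_pvalue(unname(r), nrow(energies)),
    defined = !is.na(r)
  )
  class(out) <- c("residue_profile", class(out))
  out
}

#' Energy-component correlation profile
#'
#' Correlates each total MM-PBSA energy term (van der Waals, electrostatic,
#' polar solvation, SASA, total binding energy) with activity. Comparing this
#' profile with the best residue cluster shows how much sharper a localized
#' cumulative energy tracks potency than the whole-protein terms do.
#'
#' @param components A component table (see [as_component_table()]).
#' @param activities An activity table covering every compound.
#' @param method Correlation method, passed to [pearson_r()].
#' @return A tibble `component`/`r`/`n` with five rows.
#' @examples
#' component_correlations(cox2_components(), cox2_activities())
#' @export
component_correlations <- function(components, activities,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  components <- as_component_table(components)
  activities <- as_activity_table(activities)
  missing <- setdiff(components$compound, activities$compound)
  if (length(missing)) {
    stop("no activity value for compound(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pic50 <- activities$pic50[match(components$compound, activities$compound)]
  comps <- c("vdw", "elec", "polar_solv", "sasa", "binding")
  tibble::tibble(
    component = comps,
    r = unname(vapply(comps, function(cc) pearson_r(components[[cc]], pic50,
                                                    method = method),
                      numeric(1))),
    n = nrow(components)
  )
}

#' Cumulative cluster energy per compound
#'
#' Sums each compound's per-residue contributions over a chosen residue
#' cluster, giving the cluster's cumulative binding energy (kJ/mol) — the
#' single score that is then correlated with activity.
#'
#' @param energies An energy matrix.
#' @param residues Character vector of residue labels; all must be matrix
#'   columns.
#' @return A tibble `compound`/`energy` in the matrix's row order.
#' @examples
#' cluster_energy(cox2_energies(), cox2_cluster())
#' @export
cluster_energy <- function(energies, residues) {
  energies <- as_energy_matrix(energies)
  residues <- parse_residue(residues)$label
  if (length(residues) == 0L) stop("residue set is empty", call. = FALSE)
  if (anyDuplicated(residues)) residues <- unique(residues)
  unknown <- setdiff(residues, residue_labels(energies))
  if (length(unknown)) {
    stop("residue(s) not in the energy matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- energy_values(energies)[, residues, drop = FALSE]
  tibble::tibble(compound = energies$compound, energy = unname(rowSums(m)))
}

#' Correlate a residue cluster's cumulative energy with activity
#'
#' The central scoring operation: sum the cluster's per-residue energies per
#' compound ([cluster_energy()]) and correlate the sums with pIC50. The
#' result is invariant to the order residues are listed in.
#'
#' @param energies An energy matrix with at least 3 compounds.
#' @param activities An activity table covering every compound.
#' @param residues Character vector of residue labels forming the cluster.
#' @param method Correlation method, passed to [pearson_r()].
#' @return A `cluster_cor` object: fields `residues` (sorted), `energies`
#'   (tibble `compound`/`energy`/`pic50`), `r`, `n`, `method`. [tidy()] gives
#'   the per-compound table, [glance()] the one-row summary;
#'   [ggplot2::autoplot()] draws the calibration scatter.
#' @examples
#' cluster_correlation(cox2_energies(), cox2_activities(), cox2_cluster())
#' @export
cluster_correlation <- function(energies, activities, residues,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  energies <- as_energy_matrix(energies)
  pic50 <- match_activities(energies, activities)
  ce <- cluster_energy(energies, residues)
  ce$pic50 <- pic50
  r <- pearson_r(ce$energy, ce$pic50, method = method)
  new_cluster_cor(
    residues = sort(parse_residue(residues)$label),
    energies = ce,
    r = r,
    n = nrow(ce),
    method = method
  )
}

# Two-sided p-value for a Pearson correlation under the bivariate-normal
# null, via the exact t transform t = r sqrt((n-2)/(1-r^2)) on n-2 df.
cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  t <- r[ok] * sqrt((n - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

new_cluster_cor <- function(residues, energies, r, n, method = "pearson", ...) {
  structure(
    list(residues = residues, energies = energies, r = r, n = n,
         method = method, ...),
    class = "cluster_cor"
  )
}

#' @export
print.cluster_cor <- function(x, ...) {
  cat("<cluster_cor> ", length(x$residues), " residues: ",
      paste(x$residues, collapse = ", "), "\n", sep = "")
  cat(sprintf("  r = %.4f (%s, n = %d compounds)\n", x$r, x$method, x$n))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p = %.4g (%d permutations, %s)\n",
                x$p_value, x$n_perm, x$alternative))
  }
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap %d%% CI [%.3f, %.3f] (%d resamples)\n",
                round(100 * x$ci$level), x$ci$low, x$ci$high, x$ci$n_boot))
  }
  if (!is.null(x$cv)) {
    cat(sprintf("  LOO-CV q2 = %.3f, RMSE = %.3f\n", x$cv$q2, x$cv$rmse))
  }
  invisible(x)
}
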