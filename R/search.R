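#' Exhaustive residue-cluster search
#'
#' Enumerates every residue subset of each size in `[k_min, k_max]`, scores
#' each by the correlation of its cumulative energy with activity, and ranks
#' the results. This is the brute-force oracle against which a hand-picked
#' or greedily grown cluster can be judged: it answers "how good is the
#' chosen cluster relative to everything else of its size?".
#'
#' Objectives: `"most_negative_r"` ranks ascending in r (most negative
#' first), matching the favourable-binding sign convention;
#' `"max_abs_r"` ranks by |r| descending. Ties are broken by smaller subset
#' first, then lexicographic residue order, so output is deterministic.
#' Correlations are reported raw, with the number of subsets scored, for the
#' user to judge multiplicity.
#'
#' @param energies An energy matrix (>= 3 compounds).
#' @param activities An activity table covering its compounds.
#' @param k_min,k_max Subset-size bounds.
#' @param objective Ranking objective.
#' @param sites Optional site map; with `require_site_coverage = TRUE`, only
#'   subsets containing at least one residue from every site are scored.
#' @param require_site_coverage Enforce one-residue-per-site coverage?
#' @param top_m Number of top-ranked clusters to keep.
#' @param budget Maximum number of subsets allowed; exceeding it errors with
#'   advice to use [greedy_cluster()].
#' @return A tibble `rank`/`k`/`residues` (list-column of sorted labels) /
#'   `label`/`r`, plus attribute `n_subsets` (count scored).
#' @examples
#' search_clusters(cox2_energies(), cox2_activities(), k_min = 1, k_max = 2)
#' @export
search_clusters <- function(energies, activities, k_min = 1L,
                            k_max = k_min,
                            objective = c("most_negative_r", "max_abs_r"),
                            sites = NULL, require_site_coverage = FALSE,
                            top_m = 10L, budget = 1e6) {
  objective <- match.arg(objective)
  energies <- as_energy_matrix(energies)
  res <- residue_labels(energies)
  p <- length(res)
  k_min <- as.integer(k_min)
  k_max <- as.integer(k_max)
  stopifnot(1L <= k_min, k_min <= k_max, k_max <= p, top_m >= 1L)
  total <- sum(choose(p, k_min:k_max))
  if (total > budget) {
    stop("exhaustive search over ", format(total, big.mark = ","),
         " subsets exceeds the budget of ", format(budget, big.mark = ","),
         "; use greedy_cluster() instead", call. = FALSE)
  }
  pic50 <- match_activities(energies, activities)
  m <- energy_values(energies)
  site_of <- NULL
  if (require_site_coverage) {
    if (is.null(sites)) stop("site coverage requires a site map", call. = FALSE)
    sm <- as_site_map(sites)
    site_of <- stats::setNames(sm$site, sm$residue)
  }
  rows <- list()
  n_scored <- 0L
  for (k in k_min:k_max) {
    idx <- utils::combn(p, k)
    for (j in seq_len(ncol(idx))) {
      members <- res[idx[, j]]
      if (!is.null(site_of)) {
        covered <- unique(site_of[members[members %in% names(site_of)]])
        if (!setequal(covered, unique(site_of))) next
      }
      s <- rowSums(m[, idx[, j], drop = FALSE])
      if (stats::var(s) == 0) next  # degenerate sum: correlation undefined
      n_scored <- n_scored + 1L
      rows[[n_scored]] <- tibble::tibble(
        k = k,
        label = paste(sort(members), collapse = "+"),
        residues = list(sort(members)),
        r = pearson_r(s, pic50)
      )
    }
  }
  if (n_scored == 0L) stop("no subset satisfied the constraints", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  key <- if (objective == "most_negative_r") out$r else -abs(out$r)
  out <- out[order(key, out$k, out$label), ]
  out <- utils::head(out, top_m)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1L)
  attr(out, "n_subsets") <- n_scored
  attr(out, "objective") <- objective
  out
}

#' Greedy forward cluster search
#'
#' Grows a cluster one residue at a time, at each step adding the residue
#' that most improves the objective of the cumulative-energy correlation.
#' Deterministic: ties are broken by lexicographic residue order. Greedy can
#' never beat the exhaustive optimum at equal size, but scales to residue
#' counts where enumeration is infeasible.
#'
#' @inheritParams search_clusters
#' @param k Target cluster size.
#' @return A `cluster_cor` for the selected cluster, with attribute `path`
#'   giving the residues in addition order.
#' @examples
#' greedy_cluster(cox2_energies(), cox2_activities(), k = 3)
#' @export
greedy_cluster <- function(energies, activities, k,
                           objective = c("most_negative_r", "max_abs_r")) {
  objective <- match.arg(objective)
  energies <- as_energy_matrix(energies)
  res <- residue_labels(energies)
  k <- as.integer(k)
  stopifnot(1L <= k, k <= length(res))
  pic50 <- match_activities(energies, activities)
  m <- energy_values(energies)
  score <- function(s) {
    if (stats::var(s) == 0) return(Inf)  # undefined sums never win
    r <- pearson_r(s, pic50)
    if (objective == "most_negative_r") r else -abs(r)
  }
  chosen <- character()
  current <- rep(0, nrow(m))
  for (step in seq_len(k)) {
    cand <- sort(setdiff(res, chosen))  # lexicographic tie-break via order
    sc <- vapply(cand, function(rl) score(current + m[, rl]), numeric(1))
    best <- cand[which.min(sc)]
    chosen <- c(chosen, best)
    current <- current + m[, best]
  }
  out <- cluster_correlation(energies,
                             tibble::tibble(compound = energies$compound,
                                            pic50 = pic50),
                             chosen)
  attr(out, "path") <- chosen
  attr(out, "objective") <- objective
  out
}
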