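#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster correlation result
#'
#' `tidy()` returns the per-compound table (cumulative cluster energy and
#' activity); `glance()` returns a one-row summary with the correlation and
#' whatever inference has been attached (permutation p, bootstrap CI, LOO-CV
#' statistics).
#'
#' @param x A `cluster_cor` object from [cluster_correlation()] or one of the
#'   inference helpers.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @examples
#' fit <- cluster_correlation(cox2_energies(), cox2_activities(), cox2_cluster())
#' tidy(fit)
#' glance(fit)
#' @export
tidy.cluster_cor <- function(x, ...) {
  x$energies
}

#' @rdname tidy.cluster_cor
#' @export
glance.cluster_cor <- function(x, ...) {
  out <- tibble::tibble(
    n_residues = length(x$residues),
    residues = paste(x$residues, collapse = "+"),
    r = x$r,
    n = x$n,
    method = x$method
  )
  if (!is.null(x$p_value)) {
    out$p_value <- x$p_value
    out$n_perm <- x$n_perm
  }
  if (!is.null(x$ci)) {
    out$ci_low <- x$ci$low
    out$ci_high <- x$ci$high
  }
  if (!is.null(x$cv)) {
    out$cv_q2 <- x$cv$q2
    out$cv_rmse <- x$cv$rmse
  }
  out
}

#' @rdname tidy.cluster_cor
#' @export
tidy.cluster_pipeline <- function(x, ...) {
  x$profile
}

#' @rdname tidy.cluster_cor
#' @export
glance.cluster_pipeline <- function(x, ...) {
  glance(x$cluster)
}
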