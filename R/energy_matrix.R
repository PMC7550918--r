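#' Validate a compound-by-residue energy matrix
#'
#' An energy matrix is a wide tibble: a `compound` column of unique compound
#' identifiers plus one numeric column per residue, named by canonical residue
#' label (e.g. `TYR341`), holding that residue's binding-energy contribution in
#' kJ/mol. Negative values are favourable contributions. Every cell must be
#' present and finite.
#'
#' @param x A data frame in the wide compound-by-residue layout. The compound
#'   column is `compound` if present, otherwise the first column.
#' @return A validated tibble with `compound` first and residue columns in
#'   their original order.
#' @examples
#' as_energy_matrix(data.frame(compound = c("a", "b"),
#'                             TYR341 = c(-3.5, -4.5), PHE504 = c(-10, -12)))
#' @export
as_energy_matrix <- function(x) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  if (!"compound" %in% names(x)) {
    names(x)[1L] <- "compound"
  }
  x <- dplyr::relocate(x, "compound")
  res <- setdiff(names(x), "compound")
  if (nrow(x) < 1L || length(res) < 1L) {
    stop("energy matrix needs at least one compound and one residue", call. = FALSE)
  }
  parse_residue(res)  # errors on any malformed residue header
  names(x)[-1L] <- toupper(res)
  if (anyDuplicated(names(x))) {
    stop("duplicate residue column(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  }
  x$compound <- as.character(x$compound)
  if (anyDuplicated(x$compound)) {
    stop("duplicate compound identifier(s): ",
         paste(unique(x$compound[duplicated(x$compound)]), collapse = ", "),
         call. = FALSE)
  }
  for (r in setdiff(names(x), "compound")) {
    v <- x[[r]]
    if (!is.numeric(v)) {
      stop("non-numeric energy value(s) in column ", r, call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      i <- which(!is.finite(v))[1L]
      stop("missing or non-finite energy for compound '", x$compound[i],
           "', residue ", r, call. = FALSE)
    }
  }
  x
}

#' @rdname as_energy_matrix
#' @return `residue_labels()` returns the residue column names in order.
#' @export
residue_labels <- function(x) {
  setdiff(names(x), "compound")
}

# numeric matrix view: compounds in rows, residues in columns
energy_values <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "compound")])
  rownames(m) <- x$compound
  m
}

#' Validate an activity table
#'
#' An activity table maps compound identifiers to pIC50 values (the negative
#' base-10 logarithm of the molar IC50, dimensionless). Values outside the
#' typical biological range (0, 15) trigger a warning, not an error.
#'
#' @param x A data frame with columns `compound` and `pic50` (the first two
#'   columns are used if not so named).
#' @return A validated two-column tibble.
#' @export
as_activity_table <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  x <- tibble::as_tibble(x)
  if (!all(c("compound", "pic50") %in% names(x))) {
    x <- x[, 1:2]
    names(x) <- c("compound", "pic50")
  }
  x <- dplyr::select(x, "compound", "pic50")
  x$compound <- as.character(x$compound)
  if (anyDuplicated(x$compound)) {
    stop("duplicate compound identifier(s): ",
         paste(unique(x$compound[duplicated(x$compound)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(x$pic50) || anyNA(x$pic50) || any(!is.finite(x$pic50))) {
    stop("pIC50 values must all be finite numbers", call. = FALSE)
  }
  if (any(x$pic50 <= 0 | x$pic50 >= 15)) {
    warning("pIC50 value(s) outside the typical biological range (0, 15)",
            call. = FALSE)
  }
  x
}

# Pair an energy matrix with activities by compound identifier (never by row
# position). Compounds present in the activity table but absent from the
# matrix are ignored with a warning; the reverse is an error.
match_activities <- function(energies, activities) {
  energies <- as_energy_matrix(energies)
  activities <- as_activity_table(activities)
  missing <- setdiff(energies$compound, activities$compound)
  if (length(missing)) {
    stop("no activity value for compound(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(activities$compound, energies$compound)
  if (length(extra)) {
    warning("ignoring activity for compound(s) absent from the energy matrix: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  activities$pic50[match(energies$compound, activities$compound)]
}
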