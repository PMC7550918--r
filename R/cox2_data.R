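#' The COX-2 diarylheterocyclic inhibitor dataset
#'
#' The packaged worked example: per-residue MM-PBSA binding-energy
#' contributions for eight diarylheterocyclic COX-2 inhibitors (celecoxib,
#' polmacoxib, valdecoxib, celecoxib-analog, SC-558, SC-58125, rofecoxib,
#' DuP-697) across the twelve active-site residues that interact consistently
#' with this scaffold, together with the compounds' pIC50 values, the total
#' MM-PBSA energy components per compound, and the three
#' structure-activity-relationship sites of the binding pocket (Site-1, the
#' para-substituent pocket of one aryl ring; Site-2, the
#' sulfonamide/sulfomethyl pocket; Site-3, the central-ring substituent
#' region).
#'
#' Energies are in kJ/mol, negative meaning favourable binding. Residue
#' numbering is COX-2 (murine 3LN1 convention; the selectivity residue Val509
#' corresponds to Val523 in PGHS-1 numbering).
#'
#' @return
#' * `cox2_energies()`: 8-compound x 12-residue energy-matrix tibble.
#' * `cox2_activities()`: `compound`/`pic50` tibble (8 rows).
#' * `cox2_components()`: per-compound `vdw`, `elec`, `polar_solv`, `sasa`,
#'   `binding` energies (kJ/mol).
#' * `cox2_sites()`: `site`/`residue` tibble mapping residues to SAR sites.
#' * `cox2_cluster()`: the published 7-residue cluster
#'   (GLN178, SER339, TYR341, ARG499, PHE504, VAL509, ALA513), kept as an
#'   explicit override because the plain negative-sign selection rule
#'   excludes VAL509 (its residue-wise correlation is positive).
#' * `cox2_fixture()`: all of the above in one list.
#' @examples
#' cox2_energies()
#' residue_correlations(cox2_energies(), cox2_activities())
#' @export
cox2_energies <- function() {
  read_energy_matrix(cox2_file("cox2_residue_energies.csv"))
}

#' @rdname cox2_energies
#' @export
cox2_activities <- function() {
  read_activity_table(cox2_file("cox2_activities.csv"))
}

#' @rdname cox2_energies
#' @export
cox2_components <- function() {
  as_component_table(read_delim_quiet(cox2_file("cox2_energy_components.csv"),
                                      delim = ","))
}

#' @rdname cox2_energies
#' @export
cox2_sites <- function() {
  as_site_map(read_delim_quiet(cox2_file("cox2_sites.csv"), delim = ","))
}

#' @rdname cox2_energies
#' @export
cox2_cluster <- function() {
  c("GLN178", "SER339", "TYR341", "ARG499", "PHE504", "VAL509", "ALA513")
}

#' @rdname cox2_energies
#' @export
cox2_fixture <- function() {
  list(
    energies = cox2_energies(),
    activities = cox2_activities(),
    components = cox2_components(),
    sites = cox2_sites(),
    cluster = cox2_cluster()
  )
}

cox2_file <- function(name) {
  path <- system.file("extdata", name, package = "resclust")
  if (path == "") {
    stop("packaged dataset file not found: ", name, call. = FALSE)
  }
  path
}

#' Validate an energy-component table
#'
#' Per-compound total MM-PBSA energy terms: van der Waals (`vdw`),
#' electrostatic (`elec`), polar solvation (`polar_solv`), nonpolar
#' solvent-accessible-surface-area (`sasa`) and total binding energy
#' (`binding`), all in kJ/mol.
#'
#' @param x A data frame with a `compound` column and the five component
#'   columns.
#' @return A validated tibble.
#' @export
as_component_table <- function(x) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  if (!"compound" %in% names(x)) names(x)[1L] <- "compound"
  need <- c("vdw", "elec", "polar_solv", "sasa", "binding")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("component table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::select(x, "compound", dplyr::all_of(need))
  x$compound <- as.character(x$compound)
  if (anyDuplicated(x$compound)) {
    stop("duplicate compound identifier(s) in component table", call. = FALSE)
  }
  for (nm in need) {
    if (!is.numeric(x[[nm]]) || anyNA(x[[nm]]) || any(!is.finite(x[[nm]]))) {
      stop("component '", nm, "' must be finite numeric for every compound",
           call. = FALSE)
    }
  }
  x
}

#' Validate a site map
#'
#' A site map assigns residues to named structure-activity-relationship sites
#' of the binding pocket. Each residue may belong to at most one site.
#'
#' @param x A data frame with `site` and `residue` columns.
#' @return A validated tibble, residue labels canonicalised.
#' @export
as_site_map <- function(x) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  if (!all(c("site", "residue") %in% names(x))) {
    x <- x[, 1:2]
    names(x) <- c("site", "residue")
  }
  x <- dplyr::select(x, "site", "residue")
  if (nrow(x) == 0L) stop("site map is empty", call. = FALSE)
  x$site <- as.character(x$site)
  x$residue <- parse_residue(x$residue)$label
  dup <- duplicated(x$residue)
  if (any(dup)) {
    stop("residue(s) assigned to more than one site: ",
         paste(unique(x$residue[dup]), collapse = ", "), call. = FALSE)
  }
  x
}
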