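#' Read and write compound-by-residue energy matrices
#'
#' The on-disk dialect is a plain delimited table: header
#' `compound,RES###,...` with one row per compound, decimal-point numbers in
#' kJ/mol, no thousands separators. Residue headers must match
#' `[A-Z]{3}[0-9]+` with a standard amino-acid code. Missing cells are an
#' error unless `fill_missing` supplies an explicit value (decomposition
#' tools omit residues with no contact; silent zero-filling would corrupt
#' correlations, so the fill is always opt-in).
#'
#' @param path File to read or write.
#' @param dialect `"csv"` (comma) or `"tsv"` (tab).
#' @param fill_missing Optional numeric used for empty cells; by default a
#'   missing cell is an error naming its compound and residue.
#' @return `read_energy_matrix()` returns a validated energy-matrix tibble
#'   (see [as_energy_matrix()]) preserving file row and column order.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_energy_matrix(cox2_energies(), path)
#' read_energy_matrix(path)
#' @export
read_energy_matrix <- function(path, dialect = c("csv", "tsv"),
                               fill_missing = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read_delim_quiet(path, delim = if (dialect == "csv") "," else "\t")
  if (ncol(x) < 2L) {
    stop("expected a compound column plus residue columns in ", path,
         call. = FALSE)
  }
  for (r in names(x)[-1L]) {
    v <- x[[r]]
    if (is.character(v)) {
      bad <- trimws(v) != "" & is.na(suppressWarnings(as.numeric(v)))
      if (any(bad)) {
        stop("non-numeric energy '", v[which(bad)[1L]], "' in column ", r,
             ", row ", which(bad)[1L], " of ", path, call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(v))
    }
    if (!is.null(fill_missing)) v[is.na(v)] <- fill_missing
    x[[r]] <- v
  }
  as_energy_matrix(x)
}

#' @rdname read_energy_matrix
#' @param x An energy matrix.
#' @return `write_energy_matrix()` invisibly returns `path`. Values are
#'   written at full precision so that a write/read round trip is exact.
#' @export
write_energy_matrix <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  x <- as_energy_matrix(x)
  if (dialect == "csv") readr::write_csv(x, path) else readr::write_tsv(x, path)
  invisible(path)
}

#' Convert IC50 to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the half-maximal inhibitory
#' concentration expressed in molar: an IC50 of 1 uM is a pIC50 of 6.
#'
#' @param ic50 Strictly positive IC50 value(s).
#' @param unit Concentration unit of `ic50`: molar, milli-, micro- or
#'   nanomolar.
#' @return Numeric pIC50 value(s).
#' @examples
#' pic50_from_ic50(100, "uM") # 4
#' @export
pic50_from_ic50 <- function(ic50, unit = c("M", "mM", "uM", "nM")) {
  unit <- match.arg(unit)
  if (!is.numeric(ic50) || anyNA(ic50) || any(ic50 <= 0)) {
    stop("IC50 values must be strictly positive", call. = FALSE)
  }
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)[[unit]]
  -log10(ic50 * scale)
}

#' Read and write activity tables
#'
#' The file has a compound column and a value column (first two columns are
#' used). With `unit = "pIC50"` values are taken as-is; with a concentration
#' unit they are converted through [pic50_from_ic50()].
#'
#' @param path File to read or write.
#' @param unit `"pIC50"` or the IC50 concentration unit in the file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `read_activity_table()` returns a `compound`/`pic50` tibble.
#' @export
read_activity_table <- function(path, unit = c("pIC50", "M", "mM", "uM", "nM"),
                                dialect = c("csv", "tsv")) {
  unit <- match.arg(unit)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read_delim_quiet(path, delim = if (dialect == "csv") "," else "\t")
  if (ncol(x) < 2L) stop("expected compound and value columns in ", path, call. = FALSE)
  x <- x[, 1:2]
  names(x) <- c("compound", "pic50")
  if (unit != "pIC50") {
    x$pic50 <- pic50_from_ic50(x$pic50, unit)
  }
  as_activity_table(x)
}

#' @rdname read_activity_table
#' @param x An activity table.
#' @export
write_activity_table <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  x <- as_activity_table(x)
  if (dialect == "csv") readr::write_csv(x, path) else readr::write_tsv(x, path)
  invisible(path)
}

#' Read per-frame decomposition contribution files
#'
#' Ingests whitespace-delimited per-residue contribution files of the kind
#' MM-PBSA decomposition tools emit: a header row of residue labels, a first
#' column of frame index or time, and one row per trajectory frame. Each file
#' becomes one compound row whose cell values are aggregated over frames
#' (arithmetic mean by default, matching the convention of averaging evenly
#' spaced snapshots; `"median"` is available for heavy-tailed frames).
#'
#' @param paths Character vector of contribution files, one per compound.
#' @param compound_ids Compound identifiers, same length and order as `paths`.
#' @param aggregate `"mean"` (default) or `"median"` over frames.
#' @return An energy-matrix tibble with one row per input file.
#' @export
read_decomp_contrib <- function(paths, compound_ids,
                                aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(paths) == length(compound_ids), length(paths) >= 1L)
  agg <- if (aggregate == "mean") mean else stats::median
  rows <- purrr::map2(paths, compound_ids, function(p, id) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    x <- utils::read.table(p, header = TRUE, check.names = FALSE)
    if (nrow(x) == 0L || ncol(x) < 2L) {
      stop("empty or column-less contribution file: ", p, call. = FALSE)
    }
    vals <- x[, -1L, drop = FALSE]  # first column is frame index/time
    tibble::tibble(
      compound = id,
      !!!stats::setNames(as.list(vapply(vals, agg, numeric(1))), names(vals))
    )
  })
  res_sets <- purrr::map(rows, ~ setdiff(names(.x), "compound"))
  ref <- res_sets[[1L]]
  for (i in seq_along(res_sets)) {
    diffs <- c(setdiff(ref, res_sets[[i]]), setdiff(res_sets[[i]], ref))
    if (length(diffs)) {
      stop("contribution files disagree on residue set; file ", paths[i],
           " differs in: ", paste(diffs, collapse = ", "), call. = FALSE)
    }
  }
  as_energy_matrix(dplyr::bind_rows(rows))
}

#' Write an analysis result to CSV or JSON
#'
#' Serialises a residue correlation profile (a tibble) or a cluster result
#' (see [cluster_correlation()]). Numeric values are written at full
#' precision; a `rounded` companion at two decimals matches the display
#' convention of published per-residue tables. The JSON schema for cluster
#' results has keys `residues`, `per_compound_sum`, `r`, and `p_value`,
#' `ci`, `cv` where present.
#'
#' @param result A profile tibble or a `cluster_cor` object.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.data.frame(result)) {
    if (nrow(result) == 0L) stop("refusing to write an empty profile", call. = FALSE)
    out <- tibble::as_tibble(result)
    num <- vapply(out, is.numeric, logical(1))
    for (nm in names(out)[num]) out[[paste0(nm, "_rounded")]] <- round(out[[nm]], 2)
    if (format == "csv") {
      readr::write_csv(out, path)
    } else {
      jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    }
  } else if (inherits(result, "cluster_cor")) {
    obj <- list(
      residues = sort(result$residues),
      per_compound_sum = stats::setNames(as.list(result$energies$energy),
                                         result$energies$compound),
      r = result$r,
      r_rounded = round(result$r, 2)
    )
    for (f in c("p_value", "ci", "cv")) if (!is.null(result[[f]])) obj[[f]] <- result[[f]]
    if (format == "json") {
      jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    } else {
      readr::write_csv(tidy(result), path)
    }
  } else {
    stop("write_report() handles data frames and cluster_cor objects", call. = FALSE)
  }
  invisible(path)
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}
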