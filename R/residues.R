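#' Standard three-letter amino-acid codes
#'
#' The twenty standard residue codes accepted in residue labels.
#' @keywords internal
AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Parse residue labels
#'
#' A residue label is a three-letter amino-acid code immediately followed by a
#' positive sequence number, e.g. `"TYR341"`. Labels are case-insensitive on
#' input and canonicalised to upper case; formatting a parsed label gives back
#' the canonical string, so `format_residue(parse_residue(x))` is the identity
#' on canonical labels.
#'
#' @param x Character vector of residue labels.
#' @return `parse_residue()` returns a tibble with columns `name` (three-letter
#'   code), `number` (integer position) and `label` (canonical string).
#' @examples
#' parse_residue(c("TYR341", "gln178"))
#' @export
parse_residue <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-Z]{3})([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("invalid residue label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected three-letter code + number, e.g. TYR341)", call. = FALSE)
  }
  name <- vapply(m, `[`, character(1), 2L)
  number <- as.integer(vapply(m, `[`, character(1), 3L))
  unknown <- !name %in% AA3
  if (any(unknown)) {
    stop("unknown amino-acid code(s) in residue label(s): ",
         paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
  }
  if (any(number < 1L)) {
    stop("residue numbers must be >= 1", call. = FALSE)
  }
  tibble::tibble(name = name, number = number, label = paste0(name, number))
}

#' @rdname parse_residue
#' @param name,number Components of a residue identity, as returned by
#'   `parse_residue()`.
#' @return `format_residue()` returns the canonical character labels.
#' @export
format_residue <- function(name, number) {
  paste0(toupper(name), as.integer(number))
}

#' @rdname parse_residue
#' @return `is_residue_label()` returns a logical vector: does each element
#'   parse as a valid residue label?
#' @export
is_residue_label <- function(x) {
  x <- toupper(trimws(as.character(x)))
  ok <- grepl("^[A-Z]{3}[0-9]+$", x)
  ok[ok] <- substr(x[ok], 1L, 3L) %in% AA3
  ok
}
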