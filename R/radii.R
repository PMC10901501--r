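#' Element radii table
#'
#' Returns the van der Waals and covalent radii used by every distance and
#' volume check in the package. Values are a self-consistent compilation:
#' Bondi/Mantina-style van der Waals radii and Cordero-style covalent radii
#' for the elements common in drug-like ligands plus frequent metal
#' cofactors. All radii are in Angstrom and every element satisfies
#' vdW > covalent.
#'
#' @param path Optional path to an alternative radii file (tab-separated,
#'   columns `element`, `vdw`, `covalent`). The compiled-in table shipped
#'   with the package is used by default; the compilation choice shifts
#'   clash ratios by a few percent, so it is deliberately swappable.
#' @return A data.frame with columns `element`, `vdw`, `covalent`.
#' @export
#' @examples
#' r <- radii_table()
#' r[r$element == "C", ]
radii_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "element_radii.tsv", package = "poseval")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "vdw", "covalent") %in% names(tab)))
  stopifnot(all(tab$vdw > 0), all(tab$covalent > 0), all(tab$vdw > tab$covalent))
  tab
}

#' Look up radii for a vector of element symbols
#'
#' @param elements Character vector of element symbols (case as in the
#'   periodic table, e.g. "Cl", "Zn").
#' @param kind `"vdw"` or `"covalent"`.
#' @param radii A table from [radii_table()].
#' @return Numeric vector of radii in Angstrom.
#' @export
element_radius <- function(elements, kind = c("vdw", "covalent"),
                           radii = radii_table()) {
  kind <- match.arg(kind)
  idx <- match(elements, radii$element)
  if (anyNA(idx)) {
    stop("no radius tabulated for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  radii[[kind]][idx]
}
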