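#' Van der Waals radii
#'
#' Bondi-style van der Waals radii (in Angstrom) for the elements commonly
#' found in biomolecular structures. Used to build the solvent-accessible
#' surface: each atom is represented as a sphere of radius vdW + probe.
#'
#' @param elements Character vector of element symbols (case-insensitive).
#' @param default Radius assigned to elements absent from the table; a
#'   warning lists them.
#' @return Named numeric vector of radii in Angstrom.
#' @examples
#' vdwRadius(c("C", "N", "O"))
#' @export
vdwRadius <- function(elements, default = 1.80) {
  tab <- c(
    H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    MG = 1.73, ZN = 1.39, FE = 1.40, MN = 1.40, "NA" = 2.27, K = 2.75,
    CA = 2.31, SE = 1.90, CU = 1.40, NI = 1.63, CO = 1.40, B = 1.92
  )
  key <- toupper(trimws(elements))
  r <- unname(tab[key])
  unknown <- is.na(r) & !is.na(key) & nzchar(key)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
            "; using default radius ", default, " A", call. = FALSE)
  }
  r[is.na(r)] <- default
  stats::setNames(r, elements)
}
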