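#' Read a structure into an atom table
#'
#' Parses a PDB or mmCIF file (via \pkg{bio3d}) into a plain atom table,
#' one row per atom, with van der Waals radii assigned from a built-in
#' element table. Waters are always removed; other heteroatoms (ligands,
#' ions) are excluded unless `keepHet = TRUE`. Hydrogens are dropped
#' (deposited ribosome structures generally lack them) and, when alternate
#' conformations are present, only the highest-occupancy conformer of each
#' atom is kept. Author residue numbering is preserved verbatim and
#' insertion codes are concatenated into the residue key.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param keepHet Keep non-water HETATM records?
#' @param defaultRadius Radius (Angstrom) for elements missing from the
#'   built-in table.
#' @return A `data.frame` with columns `chain`, `resno`, `insert`,
#'   `resid` (3-letter residue name), `elety` (atom name), `element`,
#'   `x`, `y`, `z`, `radius`, `reskey`.
#' @seealso [computeSasa()], [detectInterfaces()]
#' @examples
#' files <- makeToyComplex(tempfile("toy"), separation = 20)
#' atoms <- readStructure(files$pdb)
#' table(atoms$chain)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          keepHet = FALSE, defaultRadius = 1.80) {
  format <- match.arg(format)
  .assert(file.exists(path), "structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
    ),
    error = function(e) stop("could not parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  .assert(nrow(at) > 0, "no atoms in ", path)

  water <- at$resid %in% c("HOH", "WAT", "DOD")
  at <- at[!water, , drop = FALSE]
  if (!keepHet) at <- at[at$type == "ATOM", , drop = FALSE]
  .assert(nrow(at) > 0, "no polymer atoms left after filtering in ", path)

  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- .elementFromAtomName(at$elety)
  } else {
    miss <- is.na(elem) | elem == ""
    elem[miss] <- .elementFromAtomName(at$elety[miss])
  }
  elem <- toupper(trimws(elem))

  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]

  # Altloc: keep the highest-occupancy conformer per (chain, resno, ins, name).
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert %||% "", at$elety, sep = "\r")
    ord <- order(key, -occ, alt %||% "")
    at <- at[ord, , drop = FALSE]
    elem <- elem[ord]
    dup <- duplicated(paste(at$chain, at$resno, at$insert %||% "", at$elety,
                            sep = "\r"))
    at <- at[!dup, , drop = FALSE]
    elem <- elem[!dup]
  }

  ins <- at$insert
  if (is.null(ins)) ins <- rep("", nrow(at))
  ins[is.na(ins)] <- ""

  out <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ins,
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    element = elem,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    stringsAsFactors = FALSE
  )
  out$radius <- unname(vdwRadius(out$element, default = defaultRadius))
  out$reskey <- .resKey(out$chain, out$resno, out$insert)
  .assert(all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z)),
          "non-finite coordinates in ", path)
  rownames(out) <- NULL
  out
}

# Infer element from a PDB atom name (first alphabetic character that is
# not a digit; two-letter elements only when unambiguous from columns).
.elementFromAtomName <- function(name) {
  nm <- toupper(trimws(name))
  first <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  two <- substr(gsub("[^A-Z]", "", nm), 1, 2)
  out <- first
  out[two %in% c("MG", "ZN", "FE", "MN", "CL", "BR", "SE", "CU", "NI", "CO")] <-
    two[two %in% c("MG", "ZN", "FE", "MN", "CL", "BR", "SE", "CU", "NI", "CO")]
  out
}

#' Split an atom table by chain
#' @param atoms Atom table from [readStructure()].
#' @return Named list of atom tables, one per chain.
#' @export
splitChains <- function(atoms) {
  split(atoms, atoms$chain)
}
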