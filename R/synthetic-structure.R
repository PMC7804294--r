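#' Generate a toy multi-chain complex
#'
#' Builds ideal poly-alanine alpha-helices (rise 1.5 A, 100 degree twist
#' per residue, backbone N/CA/C/O plus CB) and places them as parallel
#' chains with controlled surface-to-surface separations, then writes the
#' same model in both PDB and mmCIF dialects. The ground truth records,
#' for each adjacent chain pair, the minimal inter-atomic gap and whether
#' a rolling probe of the given radius can be excluded (gap < 2 x probe),
#' i.e. whether a SASA-difference contact must exist.
#'
#' @param prefix Output path prefix; writes `<prefix>.pdb` and
#'   `<prefix>.cif`.
#' @param nChains Number of chains (A, B, C, ...).
#' @param chainLength Residues per chain.
#' @param separation Surface gap(s) in Angstrom between consecutive
#'   chains (length 1 or `nChains - 1`). Negative values press the
#'   helices together; below -3 the chains would interpenetrate and an
#'   error is raised.
#' @param probe Probe radius used for the ground-truth contact call.
#' @param jitter Coordinate jitter (sd, Angstrom) applied
#'   deterministically under `seed`; 0 keeps ideal geometry.
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @return List with `pdb`, `cif` (paths), `atoms` (the atom table) and
#'   `groundTruth` (`data.frame`: `chain_a`, `chain_b`, `min_gap`,
#'   `contact`).
#' @export
makeToyComplex <- function(prefix, nChains = 2, chainLength = 12,
                           separation = 0, probe = 1.4, jitter = 0,
                           seed = 1) {
  .assert(nChains >= 1, "need at least one chain")
  if (length(separation) == 1) separation <- rep(separation, max(0, nChains - 1))
  .assert(length(separation) == nChains - 1 || nChains == 1,
          "separation must have length 1 or nChains - 1")
  .assert(all(separation >= -3),
          "separation below -3 A would interpenetrate the chains")

  chains <- LETTERS[seq_len(nChains)]
  helixWidth <- 2 * (2.3 + 1.7)  # helix radius + carbon vdW, both sides
  offsets <- c(0, cumsum(helixWidth + separation))
  atoms <- do.call(rbind, lapply(seq_len(nChains), function(k) {
    a <- .polyAlaHelix(chainLength, chain = chains[k])
    a$x <- a$x + offsets[k]
    a
  }))
  if (jitter > 0) {
    .withSeed(seed, {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
    })
  }
  atoms$radius <- unname(vdwRadius(atoms$element))
  atoms$reskey <- .resKey(atoms$chain, atoms$resno, atoms$insert)

  gt <- NULL
  if (nChains > 1) {
    gt <- do.call(rbind, lapply(seq_len(nChains - 1), function(k) {
      A <- atoms[atoms$chain == chains[k], ]
      B <- atoms[atoms$chain == chains[k + 1], ]
      P <- as.matrix(A[, c("x", "y", "z")])
      Q <- as.matrix(B[, c("x", "y", "z")])
      d <- sqrt(outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2 +
                  outer(P[, 3], Q[, 3], "-")^2)
      gap <- min(d - outer(A$radius, B$radius, "+"))
      data.frame(chain_a = chains[k], chain_b = chains[k + 1],
                 min_gap = gap, contact = gap < 2 * probe,
                 stringsAsFactors = FALSE)
    }))
  }

  pdb <- paste0(prefix, ".pdb")
  cif <- paste0(prefix, ".cif")
  .writePdb(atoms, pdb)
  .writeMmcif(atoms, cif, entry = "toy_complex")
  list(pdb = pdb, cif = cif, atoms = atoms, groundTruth = gt)
}

# Ideal poly-alanine helix along z. Backbone atoms are placed on rotated
# offsets from the CA trace; geometry is idealised, not stereochemical.
.polyAlaHelix <- function(n, chain = "A", radius = 2.3, rise = 1.5,
                          twist = 100) {
  offs <- list(
    N = c(-1.20, -0.80, -0.50),
    CA = c(0, 0, 0),
    C = c(1.20, 0.60, 0.45),
    O = c(1.45, 1.75, 0.60),
    CB = c(-0.30, 1.20, -0.95)
  )
  rows <- list()
  for (i in seq_len(n)) {
    th <- (i - 1) * twist * pi / 180
    ca <- c(radius * cos(th), radius * sin(th), rise * (i - 1))
    rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
    for (nm in names(offs)) {
      p <- ca + as.numeric(rot %*% offs[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = i, insert = "", resid = "ALA", elety = nm,
        element = substr(nm, 1, 1), x = p[1], y = p[2], z = p[3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.writePdb <- function(atoms, path) {
  lines <- character(nrow(atoms) + 1)
  for (i in seq_len(nrow(atoms))) {
    nm <- atoms$elety[i]
    nmField <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    lines[i] <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, nmField, atoms$resid[i], atoms$chain[i], atoms$resno[i],
      atoms$x[i], atoms$y[i], atoms$z[i], 1.00, 0.00, atoms$element[i])
  }
  lines[length(lines)] <- "END"
  writeLines(lines, path)
}

.writeMmcif <- function(atoms, path, entry = "toy") {
  head <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", entry)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  body <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
    seq_len(nrow(atoms)), atoms$element, atoms$elety, atoms$resid,
    atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
    atoms$resno, atoms$resid, atoms$chain, atoms$elety)
  writeLines(c(head, body, "#"), path)
}

#' Sample an Erdos-Renyi random graph
#'
#' Uniform over graphs with `n` nodes and exactly `m` edges (the G(n, m)
#' model used as the null for the randomness test), or, when `p` is
#' given instead, the G(n, p) model.
#'
#' @param n Number of nodes.
#' @param m Number of edges (G(n, m) mode).
#' @param p Edge probability (G(n, p) mode; exclusive with `m`).
#' @param seed Integer seed.
#' @return An \pkg{igraph} graph; its edge list via
#'   [igraph::as_edgelist()].
#' @export
makeErGraph <- function(n, m = NULL, p = NULL, seed = 1) {
  .assert(xor(is.null(m), is.null(p)), "give exactly one of m or p")
  if (!is.null(m)) {
    .assert(m >= 0 && m <= n * (n - 1) / 2, "m out of range for n nodes")
  }
  g <- NULL
  .withSeed(seed, {
    g <- if (!is.null(m)) igraph::sample_gnm(n, m) else igraph::sample_gnp(n, p)
  })
  g
}
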