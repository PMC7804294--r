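#' Detect inter-chain interfaces by SASA difference
#'
#' The operational definition of a contact: surface area buried when two
#' chains are in complex. For each chain pair (A, B) the buried area is
#' \deqn{SASA(A) + SASA(B) - SASA(A \cup B)}
#' where each term is computed over the pair's atoms only. The total is the
#' sum of both sides' losses (not halved; recorded in the `convention`
#' attribute to avoid factor-2 drift). A pair is reported as a contact when
#' its buried area exceeds `burialTol`; interface residues are those losing
#' more than `burialTolRes` of accessible area.
#'
#' Chain pairs whose atoms are never within \eqn{r_i + r_j + 2 \cdot probe}
#' cannot bury area and are skipped without SASA evaluation.
#'
#' @param atoms Atom table from [readStructure()].
#' @param chainPairs Optional 2-column matrix/data.frame of chain ids to
#'   restrict the search; default all pairs.
#' @param probe Probe radius, Angstrom.
#' @param nPoints Quadrature points per atom (see [computeSasa()]).
#' @param burialTol Minimum buried area (A^2) for a pair to count as a
#'   contact; suppresses quadrature noise.
#' @param burialTolRes Minimum per-residue SASA loss (A^2) for a residue to
#'   be listed as an interface residue.
#' @return A `data.frame` of class `InterfaceContacts` with one row per
#'   contact: `chain_a`, `chain_b`, `buried_area`, `n_iface_res_a`,
#'   `n_iface_res_b`, and list-columns `residues_a`, `residues_b` (each a
#'   `data.frame` of `reskey`, `dsasa`). Attributes record `probe`,
#'   `nPoints` and the buried-area `convention`.
#' @examples
#' files <- makeToyComplex(tempfile("toy"), separation = 0)
#' atoms <- readStructure(files$pdb)
#' detectInterfaces(atoms)
#' @export
detectInterfaces <- function(atoms, chainPairs = NULL, probe = 1.4,
                             nPoints = 960, burialTol = 0.1,
                             burialTolRes = 0.1) {
  chains <- unique(atoms$chain)
  .assert(length(chains) >= 2, "need at least two chains to detect interfaces")
  if (is.null(chainPairs)) {
    chainPairs <- t(utils::combn(sort(chains), 2))
  } else {
    chainPairs <- as.matrix(chainPairs)
    bad <- setdiff(unique(as.vector(chainPairs)), chains)
    .assert(length(bad) == 0, "chain id(s) not in structure: ",
            paste(bad, collapse = ", "))
  }

  byChain <- split(atoms, atoms$chain)
  sasaAlone <- list()
  rows <- list()
  for (k in seq_len(nrow(chainPairs))) {
    ca <- as.character(chainPairs[k, 1])
    cb <- as.character(chainPairs[k, 2])
    if (ca == cb) next
    A <- byChain[[ca]]
    B <- byChain[[cb]]
    if (!.chainsCanTouch(A, B, probe)) next
    if (is.null(sasaAlone[[ca]])) sasaAlone[[ca]] <- computeSasa(A, probe, nPoints)
    if (is.null(sasaAlone[[cb]])) sasaAlone[[cb]] <- computeSasa(B, probe, nPoints)
    sAB <- computeSasa(rbind(A, B), probe, nPoints)
    sA <- sasaAlone[[ca]]
    sB <- sasaAlone[[cb]]
    buried <- sA$total + sB$total - sAB$total
    if (buried <= burialTol) next

    resA <- .residueDeltas(sA, sAB, ca)
    resB <- .residueDeltas(sB, sAB, cb)
    resA <- resA[resA$dsasa > burialTolRes, , drop = FALSE]
    resB <- resB[resB$dsasa > burialTolRes, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      chain_a = ca, chain_b = cb, buried_area = buried,
      n_iface_res_a = nrow(resA), n_iface_res_b = nrow(resB),
      stringsAsFactors = FALSE
    )
    rows[[length(rows)]]$residues_a <- list(resA)
    rows[[length(rows)]]$residues_b <- list(resB)
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_a = character(), chain_b = character(),
               buried_area = numeric(), n_iface_res_a = integer(),
               n_iface_res_b = integer(),
               residues_a = I(list()), residues_b = I(list()),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, probe = probe, nPoints = nPoints,
            convention = "total buried area, both sides summed",
            class = c("InterfaceContacts", "data.frame"))
}

# Quick reject: can any atom pair of A and B be within touching distance?
.chainsCanTouch <- function(A, B, probe) {
  reach <- max(A$radius) + max(B$radius) + 2 * probe
  for (d in c("x", "y", "z")) {
    if (min(A[[d]]) - max(B[[d]]) > reach) return(FALSE)
    if (min(B[[d]]) - max(A[[d]]) > reach) return(FALSE)
  }
  m <- .minInterDist2(as.matrix(A[, c("x", "y", "z")]),
                      as.matrix(B[, c("x", "y", "z")]))
  sqrt(m) <= reach
}

.minInterDist2 <- function(P, Q) {
  best <- Inf
  block <- 1024L
  for (s in seq(1L, nrow(P), by = block)) {
    e <- min(s + block - 1L, nrow(P))
    d2 <- outer(P[s:e, 1], Q[, 1], "-")^2 +
      outer(P[s:e, 2], Q[, 2], "-")^2 +
      outer(P[s:e, 3], Q[, 3], "-")^2
    best <- min(best, min(d2))
  }
  best
}

# Per-residue SASA loss of one chain between its isolated and complexed
# states.
.residueDeltas <- function(sAlone, sComplex, chain) {
  a <- sAlone$perResidue
  b <- sComplex$perResidue
  b <- b[b$chain == chain, , drop = FALSE]
  m <- match(a$reskey, b$reskey)
  dsasa <- a$area - ifelse(is.na(m), 0, b$area[m])
  data.frame(reskey = a$reskey, dsasa = dsasa, stringsAsFactors = FALSE)
}

#' Write interface contacts to TSV and JSON
#'
#' The TSV carries the per-pair summary; the JSON additionally carries the
#' full interface-residue lists and the buried-area convention.
#'
#' @param contacts Result of [detectInterfaces()].
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the input.
#' @export
writeContacts <- function(contacts, tsv = NULL, json = NULL) {
  flat <- as.data.frame(contacts)[, c("chain_a", "chain_b", "buried_area",
                                      "n_iface_res_a", "n_iface_res_b")]
  if (!is.null(tsv)) {
    utils::write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    full <- lapply(seq_len(nrow(contacts)), function(i) {
      list(chain_a = contacts$chain_a[i], chain_b = contacts$chain_b[i],
           buried_area = contacts$buried_area[i],
           residues_a = contacts$residues_a[[i]],
           residues_b = contacts$residues_b[[i]])
    })
    jsonlite::write_json(
      list(convention = attr(contacts, "convention"),
           probe = attr(contacts, "probe"), contacts = full),
      json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(contacts)
}

#' Closest approach between two chains
#'
#' Reports the minimal inter-atomic distance between two chains and the
#' residue pair achieving it, for "distant approach" motifs where two
#' extensions face each other without forming a buried-area contact (the
#' default window of 10 Angstrom captures such motifs).
#'
#' @param atoms Atom table.
#' @param chainA,chainB Chain ids.
#' @param maxDist Only report if the minimal distance is below this (A).
#' @return A one-row `data.frame` (`chain_a`, `chain_b`, `min_dist`,
#'   `res_a`, `res_b`, `within_window`) or `NULL` when beyond `maxDist`.
#' @export
closestApproach <- function(atoms, chainA, chainB, maxDist = 10) {
  A <- atoms[atoms$chain == chainA, , drop = FALSE]
  B <- atoms[atoms$chain == chainB, , drop = FALSE]
  .assert(nrow(A) > 0 && nrow(B) > 0, "chain not found")
  P <- as.matrix(A[, c("x", "y", "z")])
  Q <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2 +
    outer(P[, 3], Q[, 3], "-")^2
  w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  dmin <- sqrt(min(d2))
  if (dmin > maxDist) return(NULL)
  data.frame(chain_a = chainA, chain_b = chainB, min_dist = dmin,
             res_a = A$reskey[w[1]], res_b = B$reskey[w[2]],
             within_window = TRUE, stringsAsFactors = FALSE)
}
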