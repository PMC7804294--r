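# Amino-acid classes used for "similar" conservation. Histidine sits with
# the aromatics, matching its use in aromatic-residue acquisition maps.
.AA_CLASSES <- list(
  aromatic = c("F", "Y", "W", "H"),
  basic = c("K", "R"),
  acidic = c("D", "E"),
  polar = c("S", "T", "N", "Q", "C"),
  hydrophobic = c("A", "V", "L", "I", "M", "G", "P")
)

.aaClassOf <- function(aa) {
  for (cl in names(.AA_CLASSES)) {
    if (aa %in% .AA_CLASSES[[cl]]) return(cl)
  }
  NA_character_
}

#' Per-column conservation profile of an alignment
#'
#' Implements the "more than 80% of the sequences" rule per column:
#' a column is strictly conserved when a single residue occurs in more
#' than `threshold` of the sequences, and similar-conserved when one
#' amino-acid class (aromatic FYWH, basic KR, acidic DE, polar STNQC,
#' hydrophobic AVLIMGP) does. Gaps count in the denominator, so a
#' heavily gapped column is never conserved; all-gap columns are flagged.
#'
#' @param msa Aligned FASTA path, a [Biostrings::AAStringSet], or a
#'   character vector of equal-length aligned sequences.
#' @param threshold Conservation threshold (strictly exceeded; default
#'   0.80).
#' @param proteinId Optional protein label.
#' @return A [ConservationProfile-class].
#' @export
conservationProfile <- function(msa, threshold = 0.80, proteinId = "") {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    msa <- Biostrings::readAAStringSet(msa)
  }
  if (is.character(msa)) msa <- Biostrings::AAStringSet(msa)
  .assert(length(msa) >= 2, "need at least two aligned sequences")
  w <- Biostrings::width(msa)
  .assert(length(unique(w)) == 1,
          "ragged alignment: sequence lengths differ (",
          paste(unique(w), collapse = ", "), ")")
  n <- length(msa)
  L <- w[1]

  cons <- Biostrings::consensusMatrix(msa)
  rownames(cons) <- toupper(rownames(cons))
  aaRows <- rownames(cons) %in% unlist(.AA_CLASSES)
  counts <- cons[aaRows, , drop = FALSE]

  idFrac <- apply(counts, 2, max) / n
  consensus <- rownames(counts)[apply(counts, 2, which.max)]
  classCounts <- vapply(.AA_CLASSES, function(aas) {
    colSums(counts[rownames(counts) %in% aas, , drop = FALSE])
  }, numeric(L))
  if (L == 1) classCounts <- matrix(classCounts, nrow = 1,
                                    dimnames = list(NULL, names(.AA_CLASSES)))
  classFrac <- apply(classCounts, 1, max) / n
  consClass <- colnames(classCounts)[apply(classCounts, 1, which.max)]
  allGap <- colSums(counts) == 0
  consensus[allGap] <- "-"
  consClass[allGap] <- NA_character_

  cols <- data.frame(
    column = seq_len(L),
    consensus = consensus,
    identity_fraction = idFrac,
    consensus_class = consClass,
    class_fraction = classFrac,
    strict = idFrac > threshold & !allGap,
    similar = classFrac > threshold & !allGap,
    all_gap = allGap,
    stringsAsFactors = FALSE
  )
  # strict implies similar even when the top residue's class is split
  # across the classification (cannot happen with disjoint classes, but
  # keep the invariant explicit).
  cols$similar <- cols$similar | cols$strict
  new("ConservationProfile", protein_id = proteinId, nSequences = as.integer(n),
      threshold = threshold, columns = cols)
}

#' Conservation of an interface
#'
#' Maps the interface residues of a contact onto alignment columns and
#' reports the fraction that is conserved, strict and similar, per side
#' and combined. Residues without a column mapping are excluded with a
#' warning.
#'
#' @param contact One row of a [detectInterfaces()] result (or a list
#'   with `residues_a`/`residues_b` data.frames carrying `reskey`).
#' @param profiles Named list of [ConservationProfile-class], keyed by
#'   the value in `seqMap$protein_id`.
#' @param seqMap `data.frame` mapping structure residues to columns:
#'   `reskey`, `protein_id`, `column`.
#' @return `data.frame` with one row per side plus a combined row:
#'   `side`, `n_residues`, `n_mapped`, `frac_strict`, `frac_similar`.
#' @export
interfaceConservation <- function(contact, profiles, seqMap) {
  sideStats <- function(res, side) {
    keys <- res$reskey
    m <- match(keys, seqMap$reskey)
    if (anyNA(m)) {
      warning("unmapped interface residue(s) on side ", side, ": ",
              paste(keys[is.na(m)], collapse = ", "), call. = FALSE)
    }
    mapped <- !is.na(m)
    strict <- logical(0)
    similar <- logical(0)
    if (any(mapped)) {
      pid <- seqMap$protein_id[m[mapped]]
      col <- seqMap$column[m[mapped]]
      strict <- mapply(function(p, cc) {
        tab <- profileTable(profiles[[p]])
        tab$strict[tab$column == cc]
      }, pid, col)
      similar <- mapply(function(p, cc) {
        tab <- profileTable(profiles[[p]])
        tab$similar[tab$column == cc]
      }, pid, col)
    }
    data.frame(side = side, n_residues = length(keys), n_mapped = sum(mapped),
               frac_strict = if (sum(mapped)) mean(strict) else NA_real_,
               frac_similar = if (sum(mapped)) mean(similar) else NA_real_,
               stringsAsFactors = FALSE)
  }
  ra <- if (is.data.frame(contact$residues_a)) contact$residues_a else
    contact$residues_a[[1]]
  rb <- if (is.data.frame(contact$residues_b)) contact$residues_b else
    contact$residues_b[[1]]
  a <- sideStats(ra, "a")
  b <- sideStats(rb, "b")
  comb <- data.frame(side = "combined",
                     n_residues = a$n_residues + b$n_residues,
                     n_mapped = a$n_mapped + b$n_mapped,
                     frac_strict = (a$frac_strict * a$n_mapped +
                                    b$frac_strict * b$n_mapped) /
                       max(1, a$n_mapped + b$n_mapped),
                     frac_similar = (a$frac_similar * a$n_mapped +
                                     b$frac_similar * b$n_mapped) /
                       max(1, a$n_mapped + b$n_mapped),
                     stringsAsFactors = FALSE)
  rbind(a, b, comb)
}

#' Aromatic-residue acquisitions between two kingdoms
#'
#' Compares the conservation profiles of a protein in an ancestral
#' kingdom (archaea) and a derived one (eukarya) through a cross-kingdom
#' column map and classifies conserved aromatic columns of the derived
#' profile: `new_in_E` (conserved aromatic in E, not in A), `ancient`
#' (conserved aromatic in both), `strengthened_similar_to_strict`
#' (aromatic, similar-conserved in A, strictly conserved in E). A column
#' counts as conserved-aromatic when it is strictly conserved on an
#' aromatic residue or similar-conserved with the aromatic class.
#'
#' @param profileA,profileE [ConservationProfile-class] for the two
#'   kingdoms.
#' @param crossMap `data.frame` with `column_A`, `column_E`; E columns
#'   absent from the map are an error (supply NA rows for E-only
#'   insertions).
#' @param interfacesE Optional character vector of E alignment columns
#'   that belong to E-specific interfaces, used to set `at_new_interface`.
#' @return `data.frame`: `column_E`, `column_A`, `consensus_E`, `status`,
#'   `at_new_interface`.
#' @export
aromaticAcquisitions <- function(profileA, profileE, crossMap,
                                 interfacesE = NULL) {
  tE <- profileTable(profileE)
  tA <- profileTable(profileA)
  .assert(all(c("column_A", "column_E") %in% names(crossMap)),
          "crossMap needs columns column_A and column_E")

  aromaticCons <- function(tab) {
    (tab$strict & tab$consensus %in% .AA_CLASSES$aromatic) |
      (tab$similar & !is.na(tab$consensus_class) &
         tab$consensus_class == "aromatic")
  }
  consE <- aromaticCons(tE)
  consA <- aromaticCons(tA)

  out <- list()
  for (i in which(consE)) {
    colE <- tE$column[i]
    m <- match(colE, crossMap$column_E)
    .assert(!is.na(m), "E column ", colE, " missing from the cross-kingdom map")
    colA <- crossMap$column_A[m]
    aCons <- !is.na(colA) && consA[tA$column == colA]
    status <- if (!aCons) {
      "new_in_E"
    } else if (!tA$strict[tA$column == colA] && tE$strict[i]) {
      "strengthened_similar_to_strict"
    } else {
      "ancient"
    }
    out[[length(out) + 1L]] <- data.frame(
      column_E = colE, column_A = if (is.na(colA)) NA_integer_ else colA,
      consensus_E = tE$consensus[i], status = status,
      at_new_interface = colE %in% (interfacesE %||% integer()),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(column_E = integer(), column_A = integer(),
                      consensus_E = character(), status = character(),
                      at_new_interface = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Ring atom names per aromatic residue, and side-chain anchors of the
# partner groups.
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
.PRO_RING <- c("N", "CA", "CB", "CG", "CD")

#' Default geometric cutoffs for pi interactions
#'
#' Ring-centroid based distances, Angstrom: pi-pi <= 7.0 (centroid to
#' centroid), cation-pi <= 6.0 (Lys NZ / Arg CZ), anion-pi <= 5.5
#' (Asp CG / Glu CD), proline-pi <= 6.0 (proline ring centroid).
#'
#' @return Named numeric vector.
#' @export
piCutoffs <- function() {
  c(pi_pi = 7.0, cation_pi = 6.0, anion_pi = 5.5, proline_pi = 6.0)
}

#' Classify pi interactions of aromatic residues
#'
#' Computes each aromatic ring centroid from its ring atoms and searches
#' for partner groups within class-specific cutoffs: other aromatic
#' rings (pi-pi), Lys/Arg cationic groups (cation-pi), Asp/Glu anionic
#' carboxylates (anion-pi) and proline rings (proline-pi). For each
#' aromatic residue and class the nearest qualifying partner within the
#' cutoff is reported; pi-pi pairs are reported once (deterministic
#' ordering). Residues with incomplete rings are skipped with a warning.
#'
#' @param atoms Atom table from [readStructure()].
#' @param aromatics Optional character vector of residue keys
#'   (`chain:resno`) to restrict the aromatic side.
#' @param cutoffs Named cutoffs as in [piCutoffs()].
#' @return `data.frame`: `aromatic`, `aromatic_resid`, `partner`,
#'   `partner_resid`, `interaction_class`, `distance`,
#'   `intra_molecular`.
#' @export
classifyPiInteractions <- function(atoms, aromatics = NULL,
                                   cutoffs = piCutoffs()) {
  rings <- .ringCentroids(atoms, .RING_ATOMS)
  if (!is.null(aromatics)) {
    rings <- rings[rings$reskey %in% aromatics, , drop = FALSE]
  }
  if (!nrow(rings)) {
    return(.emptyPiTable())
  }
  allRings <- .ringCentroids(atoms, .RING_ATOMS)

  cat_anchor <- atoms[(atoms$resid == "LYS" & atoms$elety == "NZ") |
                      (atoms$resid == "ARG" & atoms$elety == "CZ"), ,
                      drop = FALSE]
  ani_anchor <- atoms[(atoms$resid == "ASP" & atoms$elety == "CG") |
                      (atoms$resid == "GLU" & atoms$elety == "CD"), ,
                      drop = FALSE]
  pro <- .ringCentroids(atoms[atoms$resid == "PRO", , drop = FALSE],
                        list(PRO = .PRO_RING))

  out <- list()
  emit <- function(i, px, py, pz, pkey, presid, class, cutoff) {
    d <- sqrt((rings$x[i] - px)^2 + (rings$y[i] - py)^2 + (rings$z[i] - pz)^2)
    ok <- d <= cutoff & pkey != rings$reskey[i]
    if (!any(ok)) return()
    j <- which(ok)[which.min(d[ok])]
    out[[length(out) + 1L]] <<- data.frame(
      aromatic = rings$reskey[i], aromatic_resid = rings$resid[i],
      partner = pkey[j], partner_resid = presid[j],
      interaction_class = class, distance = d[j],
      intra_molecular = sub(":.*$", "", pkey[j]) ==
        sub(":.*$", "", rings$reskey[i]),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(rings))) {
    if (nrow(allRings) > 1) {
      emit(i, allRings$x, allRings$y, allRings$z, allRings$reskey,
           allRings$resid, "pi_pi", cutoffs[["pi_pi"]])
    }
    if (nrow(cat_anchor)) {
      emit(i, cat_anchor$x, cat_anchor$y, cat_anchor$z, cat_anchor$reskey,
           cat_anchor$resid, "cation_pi", cutoffs[["cation_pi"]])
    }
    if (nrow(ani_anchor)) {
      emit(i, ani_anchor$x, ani_anchor$y, ani_anchor$z, ani_anchor$reskey,
           ani_anchor$resid, "anion_pi", cutoffs[["anion_pi"]])
    }
    if (nrow(pro)) {
      emit(i, pro$x, pro$y, pro$z, pro$reskey, pro$resid, "proline_pi",
           cutoffs[["proline_pi"]])
    }
  }
  if (!length(out)) return(.emptyPiTable())
  res <- do.call(rbind, out)
  # Report each pi-pi pair once, keyed on the sorted residue pair.
  pp <- res$interaction_class == "pi_pi"
  if (any(pp)) {
    key <- .pairKey(res$aromatic[pp], res$partner[pp])
    drop <- pp
    drop[pp] <- duplicated(key)
    res <- res[!drop, , drop = FALSE]
  }
  res <- res[order(res$aromatic, res$interaction_class, res$partner), ]
  rownames(res) <- NULL
  res
}

.emptyPiTable <- function() {
  data.frame(aromatic = character(), aromatic_resid = character(),
             partner = character(), partner_resid = character(),
             interaction_class = character(), distance = numeric(),
             intra_molecular = logical(), stringsAsFactors = FALSE)
}

.ringCentroids <- function(atoms, ringDefs) {
  sel <- atoms$resid %in% names(ringDefs)
  at <- atoms[sel, , drop = FALSE]
  if (!nrow(at)) {
    return(data.frame(reskey = character(), resid = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (key in unique(at$reskey)) {
    sub <- at[at$reskey == key, , drop = FALSE]
    want <- ringDefs[[sub$resid[1]]]
    ring <- sub[sub$elety %in% want, , drop = FALSE]
    if (nrow(ring) < length(want)) {
      warning("incomplete ", sub$resid[1], " ring at ", key, "; skipped",
              call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      reskey = key, resid = sub$resid[1],
      x = mean(ring$x), y = mean(ring$y), z = mean(ring$z),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(reskey = character(), resid = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
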