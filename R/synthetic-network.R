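# Synthetic kingdom networks in the supplementary-table layout, with
# planted ground truth for every archaeology statistic.

# Protein rosters per evolutionary origin and subunit (unified
# nomenclature: u universal, b bacterial, e archaeal/eukaryotic).
.ROSTER <- list(
  U_SSU = c("uS2", "uS3", "uS4", "uS5", "uS7", "uS8", "uS9", "uS10", "uS11",
            "uS12", "uS13", "uS14", "uS15", "uS17", "uS19"),
  U_LSU = c("uL1", "uL2", "uL3", "uL4", "uL5", "uL6", "uL10", "uL11", "uL13",
            "uL14", "uL15", "uL16", "uL18", "uL22", "uL23", "uL24", "uL29",
            "uL30", "uL33"),
  B_SSU = c("bS6", "bS16", "bS18", "bS20"),
  B_LSU = c("bL9", "bL17", "bL19", "bL20", "bL21", "bL25", "bL27", "bL28",
            "bL31", "bL32", "bL33", "bL34", "bL35", "bL36"),
  A_SSU = c("eS1", "eS4", "eS6", "eS8", "eS17", "eS19", "eS24", "eS25",
            "eS28", "eS31"),
  A_LSU = c("eL8", "eL13", "eL14", "eL15", "eL18", "eL20", "eL21", "eL30",
            "eL31", "eL32", "eL33", "eL34", "eL37", "eL39", "eL42", "eL43"),
  E_SSU = c("eS7", "eS10", "eS12", "eS21", "eS26"),
  E_LSU = c("eL6", "eL22", "eL27", "eL28", "eL29", "eL36")
)

# Universal-core functional contacts: (site, protein, type).
.CORE_FUNCT <- data.frame(rbind(
  c("mRNA", "uS3", "ext_funct"), c("mRNA", "uS4", "G_funct"),
  c("mRNA", "uS5", "G_funct"), c("mRNA", "uS11", "G_funct"),
  c("mRNA", "uS12", "G_funct"),
  c("tRNA_A", "uS12", "G_funct"), c("tRNA_A", "uS13", "G_funct"),
  c("tRNA_A", "uS19", "ext_funct"),
  c("tRNA_P", "uS9", "G_funct"), c("tRNA_P", "uS13", "G_funct"),
  c("tRNA_P", "uS19", "G_funct"),
  c("tRNA_E", "uS7", "G_funct"), c("tRNA_E", "uS11", "G_funct"),
  c("PTC", "uL2", "G_funct"), c("PTC", "uL3", "ext_funct"),
  c("PTC", "uL4", "G_funct"), c("PTC", "uL5", "G_funct"),
  c("PTC", "uL14", "G_funct"), c("PTC", "uL16", "G_funct"),
  c("tunnel", "uL4", "ext_funct"), c("tunnel", "uL22", "ext_funct"),
  c("tunnel", "uL23", "ext_funct")
), stringsAsFactors = FALSE)
names(.CORE_FUNCT) <- c("site", "protein", "type")

# Universal-core protein-protein contacts: (a, b, type).
.CORE_PP <- data.frame(rbind(
  c("uS2", "uS8", "ext_ext"), c("uS10", "uS14", "ext_ext"),
  c("uS9", "uS11", "ext_ext"), c("uL13", "uL15", "ext_ext"),
  c("uL4", "uL15", "ext_ext"), c("uL1", "uL33", "ext_ext"),
  c("uS2", "uS5", "ext_G"), c("uS3", "uS10", "ext_G"),
  c("uS3", "uS14", "ext_G"), c("uS5", "uS8", "ext_G"),
  c("uS7", "uS9", "ext_G"), c("uS8", "uS12", "ext_G"),
  c("uS13", "uS19", "ext_G"), c("uS15", "uS17", "ext_G"),
  c("uL3", "uL6", "ext_G"), c("uL15", "uL18", "ext_G"),
  c("uL22", "uL24", "ext_G"), c("uL23", "uL29", "ext_G"),
  c("uS3", "uS5", "G_G"), c("uS4", "uS5", "G_G"),
  c("uS7", "uS11", "G_G"), c("uL3", "uL13", "G_G"),
  c("uL5", "uL18", "G_G"), c("uL10", "uL11", "G_G"),
  c("uL2", "uL30", "G_G"), c("uL14", "uL24", "G_G"),
  c("uL16", "uL18", "G_G")
), stringsAsFactors = FALSE)
names(.CORE_PP) <- c("a", "b", "type")

# Site-site connections drawn in every network but excluded from the
# connectivity statistics (tRNA/mRNA geometry plus the tRNA arms reaching
# the PTC, which keep the two subunits connected in the drawn graph).
.SITE_SITE <- data.frame(
  a = c("tRNA_A", "tRNA_P", "tRNA_E", "tRNA_A", "PTC", "PTC"),
  b = c("mRNA", "mRNA", "mRNA", "tRNA_P", "tRNA_A", "tRNA_P"),
  stringsAsFactors = FALSE
)

.SITE_COORDS <- data.frame(
  node_id = c("mRNA", "tRNA_A", "tRNA_P", "tRNA_E", "PTC", "tunnel"),
  x = c(10, 90, 90, 90, 180, 215),
  y = c(0, 20, 0, -20, 0, 10),
  z = c(5, 30, 0, -30, 0, 0),
  stringsAsFactors = FALSE
)

.SHORT_LENS <- c(12L, 18L, 24L, 30L, 36L, 44L, 52L, 60L, 68L, 76L)
.LONG_LENS <- c(85L, 88L, 92L, 96L, 101L, 110L, 118L, 126L)
.EXT_CAT_CYCLE <- c("segment", "mix", "helix", "loop", "beta_hairpin")
.EXT_TERM_CYCLE <- c("N", "C", "internal")

#' Generate synthetic kingdom networks with planted ground truth
#'
#' Writes, for the universal core (ABE) and the three kingdoms (B, A, E),
#' a component-level interaction table in the supplementary layout, a
#' component annotation TSV and a node-coordinate TSV, with planted:
#' a 49-edge universal core (45% of whose contacts involve functional
#' sites), per-transition status-pair proportions (defaults: the
#' bacterial 58/19/12/9/2 split, the archaeal 47/19/23/11 split, a
#' eukaryotic transition with 57% of new contacts mediated by
#' newly acquired Ue/Ae extensions and 11 new proteins), functional
#' contact fractions (16/116, 4/104 and 2/102 of new contacts),
#' eukaryotic network contact-type proportions (115/255 ext-G, 99/255
#' ext-ext), extension-size fractions above 80 aa (1%, 2%, 4%, 10% for
#' ABE, B, A, E), two multiplicity-2 pairs in the bacterial network, and
#' centre-of-mass geometry in which each stage's new edges are longer on
#' average than its parent's.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; fully determines all sampled pairings.
#' @param nNewB Number of new protein-protein contacts at the
#'   bacterial transition.
#' @param bFractions Named fractions (labels `U-B`, `B-B`, `Ub-U`,
#'   `Ub-B`, `U-U`) that must each multiply `nNewB` to an integer,
#'   otherwise an error is raised.
#' @return List with `files` (nested paths per kingdom), `graphs`
#'   (the four [RibosomeGraph-class] objects), and `truth` (planted
#'   ground-truth values).
#' @export
makeAnnotatedNetwork <- function(dir, seed = 1, nNewB = 100,
                                 bFractions = c("U-B" = 0.58, "B-B" = 0.19,
                                                "Ub-U" = 0.12, "Ub-B" = 0.09,
                                                "U-U" = 0.02)) {
  .assert(abs(sum(bFractions) - 1) < 1e-9, "bFractions must sum to 1")
  .assert(all(names(bFractions) %in% c("U-B", "B-B", "Ub-U", "Ub-B", "U-U")),
          "unknown bFractions label(s)")
  bCounts <- bFractions * nNewB
  .assert(all(abs(bCounts - round(bCounts)) < 1e-9),
          "infeasible combination: fractions x nNewB must all be integers")
  bCounts <- round(bCounts)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inv <- .extensionInventory()
  coords <- NULL
  tables <- NULL
  .withSeed(seed, {
    coords <- .nodeCoordinates()
    tables <- .buildContactTables(inv, coords, bCounts)
  })

  anns <- .annotationTables(inv)
  files <- list()
  graphs <- list()
  for (k in c("ABE", "B", "A", "E")) {
    protIds <- .kingdomProteins(k)
    nd <- rbind(coords[coords$node_id %in% protIds, ], .SITE_COORDS)
    f <- list(
      contacts = file.path(dir, paste0("contacts_", k, ".tsv")),
      annotation = file.path(dir, paste0("annotation_", k, ".tsv")),
      nodes = file.path(dir, paste0("nodes_", k, ".tsv"))
    )
    utils::write.table(tables[[k]], f$contacts, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(anns[[k]], f$annotation, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(nd, f$nodes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[k]] <- f
    graphs[[k]] <- graphFromTable(tables[[k]], nd,
                                  kingdom = if (k == "ABE") "ABE" else k)
  }

  truth <- .networkTruth(tables, graphs, bCounts, nNewB)
  list(files = files, graphs = graphs, truth = truth)
}

.kingdomProteins <- function(k) {
  r <- .ROSTER
  switch(k,
         ABE = c(r$U_SSU, r$U_LSU),
         B = c(r$U_SSU, r$U_LSU, r$B_SSU, r$B_LSU),
         A = c(r$U_SSU, r$U_LSU, r$A_SSU, r$A_LSU),
         E = c(r$U_SSU, r$U_LSU, r$A_SSU, r$A_LSU, r$E_SSU, r$E_LSU))
}

# ---------------------------------------------------------------------
# Extension inventory: every component of every protein, with the
# kingdoms whose annotation carries it. Lengths are planted so that the
# fraction of extensions above 80 aa is exactly 1/100 (ABE = U set),
# 3/150 (B), 6/150 (A) and 20/200 (E).
.extensionInventory <- function() {
  r <- .ROSTER
  U <- c(r$U_SSU, r$U_LSU)
  A <- c(r$A_SSU, r$A_LSU)
  B <- c(r$B_SSU, r$B_LSU)
  E <- c(r$E_SSU, r$E_LSU)
  rows <- list()
  addRow <- function(protein, id, kind, cat, term, len, status, kingdoms) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protein_id = protein, component_id = id, component_kind = kind,
      category = cat, terminus = term, length_aa = len, status = status,
      kingdoms = paste(kingdoms, collapse = ","), stringsAsFactors = FALSE)
  }
  cyc <- function(v, i) v[(i - 1L) %% length(v) + 1L]

  # Globular domains.
  for (p in U) addRow(p, "G", "globular", "", "", 120L, "U",
                      c("ABE", "B", "A", "E"))
  for (p in B) addRow(p, "G", "globular", "", "", 110L, "B", "B")
  for (p in A) addRow(p, "G", "globular", "", "", 115L, "A", c("A", "E"))
  for (p in E) addRow(p, "G", "globular", "", "", 105L, "E", "E")

  # Universal extensions: 100 across 34 proteins (2 proteins carry 2).
  i <- 0L
  for (p in U) {
    nExt <- if (p %in% c("uL30", "uL33")) 2L else 3L
    for (j in seq_len(nExt)) {
      i <- i + 1L
      len <- if (p == "uL4" && j == 1L) 95L else cyc(.SHORT_LENS, i)
      addRow(p, paste0("uext", j), "extension", cyc(.EXT_CAT_CYCLE, i),
             cyc(.EXT_TERM_CYCLE, i), len, "U", c("ABE", "B", "A", "E"))
    }
  }

  # Bacterial-acquired extensions on universal proteins (Ub), B only.
  ubHosts <- c("uL5", "uL13", "uL23",
               setdiff(U, c("uL5", "uL13", "uL23"))[1:17])
  ubMeta <- list(uL5 = c("mix", "N", 88L), uL13 = c("segment", "N", 85L),
                 uL23 = c("beta_hairpin", "internal", 30L))
  for (i in seq_along(ubHosts)) {
    p <- ubHosts[i]
    meta <- ubMeta[[p]]
    if (!is.null(meta)) {
      addRow(p, "bext1", "extension", meta[1], meta[2], as.integer(meta[3]),
             "Ub", "B")
    } else {
      addRow(p, "bext1", "extension", cyc(.EXT_CAT_CYCLE, i),
             cyc(.EXT_TERM_CYCLE, i), cyc(.SHORT_LENS, i), "Ub", "B")
    }
  }

  # Inherited extensions of bacterial proteins (status B), B only:
  # 30 over 18 proteins, none long.
  i <- 0L
  for (p in B) {
    nExt <- if (match(p, B) <= 12L) 2L else 1L
    for (j in seq_len(nExt)) {
      i <- i + 1L
      addRow(p, paste0("bext", j), "extension", cyc(.EXT_CAT_CYCLE, i + 1L),
             cyc(.EXT_TERM_CYCLE, i), cyc(.SHORT_LENS, i + 4L), "B", "B")
    }
  }

  # Archaeal-acquired extensions on universal proteins (Ua), A and E.
  uaHosts <- c("uL4", "uL24", setdiff(U, c("uL4", "uL24"))[1:22])
  for (i in seq_along(uaHosts)) {
    p <- uaHosts[i]
    len <- if (p == "uL4") 90L else if (p == "uL24") 86L else cyc(.SHORT_LENS, i + 3L)
    cat <- if (p == "uL4") "loop" else if (p == "uL24") "mix" else
      cyc(.EXT_CAT_CYCLE, i + 1L)
    term <- if (p == "uL4") "internal" else if (p == "uL24") "N" else
      cyc(.EXT_TERM_CYCLE, i + 1L)
    addRow(p, "aext1", "extension", cat, term, len, "Ua", c("A", "E"))
  }

  # Eukaryote-acquired extensions on universal proteins (Ue), E only;
  # 8 of 20 are long and the terminus is biased C-terminal.
  ueHosts <- c(r$U_SSU[1:10], r$U_LSU[1:10])
  for (i in seq_along(ueHosts)) {
    len <- if (i <= 8) .LONG_LENS[i] else cyc(.SHORT_LENS, i)
    addRow(ueHosts[i], "eext1", "extension", cyc(c("mix", "segment", "helix"), i),
           cyc(c("C", "C", "N", "C", "internal"), i), len, "Ue", "E")
  }

  # Inherited extensions of archaeal proteins (status A), A and E;
  # three are long.
  aExtHosts <- A
  for (i in seq_along(aExtHosts)) {
    p <- aExtHosts[i]
    len <- if (p == "eL8") 84L else if (p == "eL13") 92L else
      if (p == "eL15") 101L else cyc(.SHORT_LENS, i + 5L)
    addRow(p, "aext1", "extension", cyc(.EXT_CAT_CYCLE, i + 2L),
           cyc(.EXT_TERM_CYCLE, i + 2L), len, "A", c("A", "E"))
  }

  # Eukaryote-acquired extensions on archaeal proteins (Ae), E only;
  # 4 of 12 long, C-terminal bias.
  aeHosts <- c("eL13", "eL15", "eL18",
               setdiff(A, c("eL13", "eL15", "eL18"))[1:9])
  for (i in seq_along(aeHosts)) {
    p <- aeHosts[i]
    len <- if (p == "eL13") 95L else if (p == "eL15") 102L else
      if (i <= 4) .LONG_LENS[i + 2L] else cyc(.SHORT_LENS, i + 7L)
    addRow(p, "eext1", "extension", cyc(c("mix", "segment"), i),
           cyc(c("C", "C", "internal"), i), len, "Ae", "E")
  }

  # Extensions of eukaryote-specific proteins (status E): 18 over 11
  # proteins, 2 long.
  i <- 0L
  for (p in E) {
    nExt <- if (p %in% c("eL6", "eL22", "eL27", "eL28", "eL29", "eL36", "eS7"))
      2L else 1L
    for (j in seq_len(nExt)) {
      i <- i + 1L
      len <- if (i <= 2) .LONG_LENS[i + 6L] else cyc(.SHORT_LENS, i + 2L)
      addRow(p, paste0("eext", j), "extension", cyc(.EXT_CAT_CYCLE, i + 3L),
             cyc(c("C", "N", "C"), i), len, "E", "E")
    }
  }

  do.call(rbind, rows)
}

# Per-kingdom annotation tables with sequential, non-overlapping residue
# ranges laid out once over the union of components.
.annotationTables <- function(inv) {
  inv$start <- NA_integer_
  inv$end <- NA_integer_
  for (p in unique(inv$protein_id)) {
    idx <- which(inv$protein_id == p)
    cursor <- 1L
    for (i in idx) {
      inv$start[i] <- cursor
      inv$end[i] <- cursor + inv$length_aa[i] - 1L
      cursor <- inv$end[i] + 1L
    }
  }
  inv$ranges <- paste0(inv$start, "-", inv$end)
  out <- list()
  for (k in c("ABE", "B", "A", "E")) {
    sel <- vapply(strsplit(inv$kingdoms, ","), function(ks) k %in% ks,
                  logical(1))
    tab <- inv[sel, c("protein_id", "component_id", "component_kind",
                      "category", "terminus", "ranges", "status")]
    tab$chain <- tab$protein_id
    tab$kingdom <- k
    out[[k]] <- tab[, c("protein_id", "chain", "component_id",
                        "component_kind", "category", "terminus", "ranges",
                        "status", "kingdom")]
  }
  out
}

# Node coordinates: proteins on spherical shells around their subunit
# centre, the shell radius growing with evolutionary recency so that new
# edges get longer at each stage.
.nodeCoordinates <- function() {
  centers <- list(SSU = c(0, 0, 0), LSU = c(180, 0, 0))
  radii <- c(U = 50, B = 70, A = 85, E = 140)
  rows <- list()
  for (grp in names(.ROSTER)) {
    origin <- sub("_.*$", "", grp)
    su <- sub("^.*_", "", grp)
    for (p in .ROSTER[[grp]]) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      pos <- centers[[su]] + radii[[origin]] * u
      rows[[length(rows) + 1L]] <- data.frame(
        node_id = p, x = pos[1], y = pos[2], z = pos[3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------
# Contact-table construction.

.buildContactTables <- function(inv, coords, bCounts) {
  used <- new.env(parent = emptyenv())
  used$pairs <- character(0)
  used$keys <- character(0)

  compOf <- function(protein, status, needExt) {
    rows <- inv[inv$protein_id == protein, , drop = FALSE]
    if (status %in% c("Ub", "Ua", "Ue", "Ae")) {
      hit <- rows[rows$status == status & rows$component_kind == "extension", ]
      .assert(nrow(hit) > 0, "no ", status, " extension on ", protein)
      return(list(id = hit$component_id[1], kind = "ext"))
    }
    if (!needExt) return(list(id = "G", kind = "G"))
    hit <- rows[rows$component_kind == "extension" & rows$status == status, ]
    .assert(nrow(hit) > 0, "no inherited extension on ", protein)
    list(id = hit$component_id[1], kind = "ext")
  }

  mkRow <- function(pa, sa, pb, sb, type, extVariant = 1L) {
    extA <- type == "ext_ext" || (type %in% c("ext_G", "ext_funct") &&
                                    .STATUS_RANK[sa] < .STATUS_RANK[sb]) ||
      sa %in% c("Ub", "Ua", "Ue", "Ae")
    extB <- type == "ext_ext" || sb %in% c("Ub", "Ua", "Ue", "Ae")
    if (type == "ext_G" && !extA && !extB) extA <- TRUE
    if (type == "ext_G" && extA && extB &&
        !(sa %in% c("Ub", "Ua", "Ue", "Ae"))) extA <- FALSE
    if (type %in% c("G_G", "G_funct")) extA <- extB <- FALSE
    if (sb == "funct") {
      ca <- compOf(pa, sa, extA || type == "ext_funct")
      if (extVariant > 1L && ca$kind == "ext") {
        ca$id <- sub("[0-9]+$", as.character(extVariant), ca$id)
      }
      return(data.frame(protein_a = pa, component_a = ca$id,
                        component_kind_a = ca$kind, status_a = sa,
                        protein_b = pb, component_b = "site",
                        component_kind_b = "site", status_b = "funct",
                        stringsAsFactors = FALSE))
    }
    ca <- compOf(pa, sa, extA)
    cb <- compOf(pb, sb, extB)
    if (extVariant > 1L && ca$kind == "ext") {
      ca$id <- sub("[0-9]+$", as.character(extVariant), ca$id)
    }
    data.frame(protein_a = pa, component_a = ca$id,
               component_kind_a = ca$kind, status_a = sa,
               protein_b = pb, component_b = cb$id,
               component_kind_b = cb$kind, status_b = sb,
               stringsAsFactors = FALSE)
  }

  claim <- function(pa, pb, allowPair = FALSE) {
    key <- .pairKey(pa, pb)
    if (!allowPair && key %in% used$pairs) return(FALSE)
    used$pairs <- c(used$pairs, key)
    TRUE
  }

  # Sample n unused same-subunit pairs from poolA x poolB.
  samplePairs <- function(poolA, poolB, n, distances = NULL) {
    cand <- .subunitPairs(poolA, poolB)
    if (is.null(distances)) {
      cand <- cand[sample(nrow(cand)), , drop = FALSE]
    } else {
      d <- .pairDist(cand, distances)
      ord <- order(-d)
      top <- ord[seq_len(max(1L, floor(length(ord) * 0.25)))]
      cand <- cand[c(sample(top), setdiff(ord, top)), , drop = FALSE]
    }
    out <- matrix(character(0), ncol = 2)
    for (i in seq_len(nrow(cand))) {
      if (nrow(out) == n) break
      if (.pairKey(cand[i, 1], cand[i, 2]) %in% used$pairs) next
      out <- rbind(out, cand[i, , drop = FALSE])
      used$pairs <- c(used$pairs, .pairKey(cand[i, 1], cand[i, 2]))
    }
    .assert(nrow(out) == n, "not enough unused candidate pairs")
    out
  }

  r <- .ROSTER
  U <- c(r$U_SSU, r$U_LSU)
  Bp <- c(r$B_SSU, r$B_LSU)
  Ap <- c(r$A_SSU, r$A_LSU)
  Ep <- c(r$E_SSU, r$E_LSU)
  ApS <- setdiff(Ap, c("eL13", "eL15", "eL18"))  # showcase proteins keep
                                                 # only their fixed edges
  ubHosts <- inv$protein_id[inv$status == "Ub"]
  uaHosts <- inv$protein_id[inv$status == "Ua"]
  ueHosts <- inv$protein_id[inv$status == "Ue"]
  aeHosts <- inv$protein_id[inv$status == "Ae"]

  rows <- list()
  add <- function(df, stage) {
    df$stage <- stage
    rows[[length(rows) + 1L]] <<- df
  }

  # Reserve the fixed showcase pairs up front so that no sampled bucket
  # can steal them.
  reserved <- rbind(
    c("uL5", "bL31"), c("uL13", "bL20"), c("uL13", "bL21"),
    c("uL23", "bL34"), c("uL5", "uS13"), c("uL4", "uL24"),
    c("eL13", "uL4"), c("eL15", "uL4"), c("eL13", "uL15"),
    c("eL18", "uL15"), c("eL15", "PTC"), c("eL15", "tunnel"),
    c("eL20", "tunnel"), c("eL21", "PTC"), c("eL15", "tRNA_E"),
    c("eS7", "mRNA"))
  for (i in seq_len(nrow(reserved))) claim(reserved[i, 1], reserved[i, 2])

  # Sample one unused partner pair per incoming protein (coverage rows).
  coverPairs <- function(newProts, ssuPool, lsuPool) {
    t(vapply(newProts, function(np) {
      pool <- if (.subunitOf(np) == "SSU") ssuPool else lsuPool
      pool <- pool[sample(length(pool))]
      for (cand in pool) {
        if (claim(cand, np)) return(c(cand, np))
      }
      stop("no unused partner left for ", np)
    }, character(2)))
  }

  # ---- Universal core --------------------------------------------------
  for (i in seq_len(nrow(.CORE_PP))) {
    claim(.CORE_PP$a[i], .CORE_PP$b[i])
    add(mkRow(.CORE_PP$a[i], "U", .CORE_PP$b[i], "U", .CORE_PP$type[i]),
        "core")
  }
  for (i in seq_len(nrow(.CORE_FUNCT))) {
    claim(.CORE_FUNCT$protein[i], .CORE_FUNCT$site[i])
    add(mkRow(.CORE_FUNCT$protein[i], "U", .CORE_FUNCT$site[i], "funct",
              .CORE_FUNCT$type[i]), "core")
  }
  coreProteins <- unique(c(.CORE_PP$a, .CORE_PP$b, .CORE_FUNCT$protein))
  .assert(setequal(coreProteins, U), "core must touch every universal protein")

  # ---- Bacterial transition -------------------------------------------
  typed <- function(pairs, sa, sb, types, stage, startCol = 1) {
    for (i in seq_len(nrow(pairs))) {
      add(mkRow(pairs[i, 1], sa, pairs[i, 2], sb, types[i]), stage)
    }
  }
  # U-B: the first rows cover every bacterial protein once.
  nUB <- bCounts[["U-B"]]
  ubTypes <- .allocTypes(nUB, c(ext_G = 0.52, G_G = 0.34, ext_ext = 0.14))
  firstB <- coverPairs(Bp, r$U_SSU, r$U_LSU)
  firstB <- firstB[seq_len(min(nrow(firstB), nUB)), , drop = FALSE]
  restB <- samplePairs(U, Bp, nUB - nrow(firstB))
  typed(rbind(firstB, restB), "U", "B", sample(ubTypes), "B")

  bbTypes <- .allocTypes(bCounts[["B-B"]], c(G_G = 0.53, ext_G = 0.31,
                                             ext_ext = 0.16))
  typed(samplePairs(Bp, Bp, bCounts[["B-B"]]), "B", "B", sample(bbTypes), "B")

  ubuTypes <- .allocTypes(bCounts[["Ub-U"]], c(ext_G = 0.67, ext_ext = 0.33))
  ubuPairs <- samplePairs(ubHosts, U, bCounts[["Ub-U"]])
  typed(ubuPairs, "Ub", "U", sample(ubuTypes), "B")

  # Ub-B: the coevolution showcase rows come first (uL5/uL13/uL23
  # extensions acquired together with the bacterial proteins they bind).
  fixedUbB <- rbind(c("uL5", "bL31"), c("uL13", "bL20"), c("uL13", "bL21"),
                    c("uL23", "bL34"))
  nUbB <- bCounts[["Ub-B"]]
  fixedUbB <- fixedUbB[seq_len(min(nrow(fixedUbB), nUbB)), , drop = FALSE]
  for (i in seq_len(nrow(fixedUbB))) claim(fixedUbB[i, 1], fixedUbB[i, 2])
  moreUbB <- samplePairs(ubHosts, Bp, nUbB - nrow(fixedUbB))
  ubbTypes <- c(rep("ext_G", nrow(fixedUbB)),
                sample(.allocTypes(nUbB - nrow(fixedUbB),
                                   c(ext_G = 0.4, ext_ext = 0.6))))
  typed(rbind(fixedUbB, moreUbB), "Ub", "B", ubbTypes, "B")

  # "Other" new universal-universal contacts: one reinforcement of the
  # core uS3-uS5 pair (multiplicity 2) and one new subunit bridge.
  nUU <- bCounts[["U-U"]]
  if (nUU >= 1) add(mkRow("uS3", "U", "uS5", "U", "ext_G", extVariant = 2L), "B")
  if (nUU >= 2) {
    claim("uL5", "uS13")
    add(mkRow("uL5", "U", "uS13", "U", "G_G"), "B")
  }
  if (nUU > 2) {
    typed(samplePairs(U, U, nUU - 2L), "U", "U",
          rep("G_G", nUU - 2L), "B")
  }

  # Functional contacts: 16 (one reinforces uS3-mRNA via a second
  # universal extension, 15 from bacterial proteins).
  add(mkRow("uS3", "U", "mRNA", "funct", "ext_funct", extVariant = 3L), "B")
  bFunct <- .sampleFunctPairs(Bp, r, 15, used)
  bfTypes <- sample(.allocTypes(15, c(G_funct = 0.5, ext_funct = 0.5)))
  for (i in seq_len(nrow(bFunct))) {
    add(mkRow(bFunct[i, 1], "B", bFunct[i, 2], "funct", bfTypes[i]), "B")
  }

  # ---- Archaeal transition --------------------------------------------
  uaTypes <- .allocTypes(47, c(ext_G = 30 / 47, ext_ext = 15 / 47,
                               G_G = 2 / 47))
  firstA <- coverPairs(Ap, r$U_SSU, r$U_LSU)
  restA <- samplePairs(U, ApS, 47 - nrow(firstA))
  typed(rbind(firstA, restA), "U", "A", sample(uaTypes), "A")

  aaTypes <- .allocTypes(19, c(ext_G = 12 / 19, ext_ext = 5 / 19, G_G = 2 / 19))
  typed(samplePairs(ApS, ApS, 19), "A", "A", sample(aaTypes), "A")

  uaaTypes <- .allocTypes(23, c(ext_G = 13 / 23, ext_ext = 10 / 23))
  typed(samplePairs(uaHosts, ApS, 23), "Ua", "A", sample(uaaTypes), "A")

  claim("uL4", "uL24")
  add(mkRow("uL4", "Ua", "uL24", "Ua", "ext_ext"), "A")
  typed(samplePairs(uaHosts, uaHosts, 10), "Ua", "Ua", rep("ext_ext", 10), "A")

  aFunct <- rbind(c("eL15", "PTC"), c("eL15", "tunnel"), c("eL20", "tunnel"),
                  c("eL21", "PTC"))
  for (i in seq_len(nrow(aFunct))) {
    claim(aFunct[i, 1], aFunct[i, 2])
    add(mkRow(aFunct[i, 1], "A", aFunct[i, 2], "funct", "ext_funct"), "A")
  }

  # ---- Eukaryotic transition ------------------------------------------
  dco <- coords
  mixed <- list(
    list(hosts = ueHosts, pool = U, sa = "Ue", sb = "U", n = 10),
    list(hosts = ueHosts, pool = ApS, sa = "Ue", sb = "A", n = 8),
    list(hosts = aeHosts, pool = U, sa = "Ae", sb = "U", n = 6),
    list(hosts = setdiff(aeHosts, c("eL13", "eL15", "eL18")), pool = ApS, sa = "Ae", sb = "A", n = 6)
  )
  # Tripartite coevolution showcase: eL13/eL15 reach uL4, eL13/eL18
  # reach uL15 through their eukaryote-acquired extensions.
  fixedAeU <- rbind(c("eL13", "uL4"), c("eL15", "uL4"), c("eL13", "uL15"),
                    c("eL18", "uL15"))
  for (i in seq_len(nrow(fixedAeU))) claim(fixedAeU[i, 1], fixedAeU[i, 2])
  typed(fixedAeU, "Ae", "U", rep("ext_G", 4), "E")
  mixed[[3]]$n <- 2  # remaining Ae-U rows
  mixedTypes <- c("ext_G", rep("ext_ext", 25))  # 1 more ext_G, rest ext-ext
  ti <- 1L
  for (bk in mixed) {
    prs <- samplePairs(bk$hosts, bk$pool, bk$n, distances = dco)
    for (i in seq_len(nrow(prs))) {
      add(mkRow(prs[i, 1], bk$sa, prs[i, 2], bk$sb, mixedTypes[ti]), "E")
      ti <- ti + 1L
    }
  }
  typed(samplePairs(ueHosts, ueHosts, 13, distances = dco), "Ue", "Ue",
        rep("ext_ext", 13), "E")
  typed(samplePairs(setdiff(aeHosts, c("eL13", "eL15", "eL18")),
        setdiff(aeHosts, c("eL13", "eL15", "eL18")), 8,
        distances = dco), "Ae", "Ae",
        rep("ext_ext", 8), "E")
  typed(samplePairs(ueHosts, setdiff(aeHosts, c("eL13", "eL15", "eL18")),
        6, distances = dco), "Ue", "Ae",
        rep("ext_ext", 6), "E")

  # Plain new contacts; the first rows cover every eukaryote-specific
  # protein once.
  firstE <- coverPairs(Ep, r$U_SSU, r$U_LSU)
  typed(firstE, "U", "E", rep("ext_G", nrow(firstE)), "E")
  typed(samplePairs(U, Ep, 16 - nrow(firstE)), "U", "E",
        rep("ext_G", 16 - nrow(firstE)), "E")
  typed(samplePairs(ApS, Ep, 13), "A", "E", rep("ext_G", 13), "E")
  typed(samplePairs(Ep, Ep, 6), "E", "E", rep("ext_G", 6), "E")
  typed(samplePairs(U, ApS, 5, distances = dco), "U", "A",
        rep("ext_G", 5), "E")
  typed(samplePairs(ApS, ApS, 3, distances = dco), "A", "A",
        rep("ext_G", 3), "E")

  claim("eL15", "tRNA_E")
  add(mkRow("eL15", "Ae", "tRNA_E", "funct", "ext_funct"), "E")
  claim("eS7", "mRNA")
  add(mkRow("eS7", "E", "mRNA", "funct", "ext_funct"), "E")

  # ---- Assemble per-kingdom tables ------------------------------------
  all <- do.call(rbind, rows)
  siteSite <- data.frame(
    protein_a = .SITE_SITE$a, component_a = "site", component_kind_a = "site",
    status_a = "funct", protein_b = .SITE_SITE$b, component_b = "site",
    component_kind_b = "site", status_b = "funct", stage = "sites",
    stringsAsFactors = FALSE)
  all <- rbind(all, siteSite)

  stageSets <- list(ABE = c("core", "sites"),
                    B = c("core", "sites", "B"),
                    A = c("core", "sites", "A"),
                    E = c("core", "sites", "A", "E"))
  out <- lapply(stageSets, function(st) {
    tab <- all[all$stage %in% st, , drop = FALSE]
    tab$stage <- NULL
    rownames(tab) <- NULL
    tab
  })
  out
}

.subunitPairs <- function(poolA, poolB) {
  su <- .subunitOf
  out <- list()
  for (s in c("SSU", "LSU")) {
    a <- poolA[su(poolA) == s]
    b <- poolB[su(poolB) == s]
    if (!length(a) || !length(b)) next
    grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    out[[s]] <- as.matrix(grid)
  }
  m <- do.call(rbind, out)
  m[!duplicated(.pairKey(m[, 1], m[, 2])), , drop = FALSE]
}

.pairDist <- function(pairs, coords) {
  m1 <- match(pairs[, 1], coords$node_id)
  m2 <- match(pairs[, 2], coords$node_id)
  sqrt((coords$x[m1] - coords$x[m2])^2 + (coords$y[m1] - coords$y[m2])^2 +
         (coords$z[m1] - coords$z[m2])^2)
}

# Largest-remainder allocation of n items to named proportions.
.allocTypes <- function(n, props) {
  raw <- props / sum(props) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(base), times = base)
}

.sampleFunctPairs <- function(proteins, roster, n, used) {
  ssuSites <- c("mRNA", "tRNA_A", "tRNA_P", "tRNA_E")
  lsuSites <- c("PTC", "tunnel")
  cand <- rbind(
    expand.grid(p = proteins[.subunitOf(proteins) == "SSU"], s = ssuSites,
                stringsAsFactors = FALSE),
    expand.grid(p = proteins[.subunitOf(proteins) == "LSU"], s = lsuSites,
                stringsAsFactors = FALSE)
  )
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  out <- matrix(character(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    if (nrow(out) == n) break
    key <- .pairKey(cand$p[i], cand$s[i])
    if (key %in% used$pairs) next
    used$pairs <- c(used$pairs, key)
    out <- rbind(out, c(cand$p[i], cand$s[i]))
  }
  .assert(nrow(out) == n, "not enough functional-site pairs")
  out
}

# Planted ground truth, recomputed here by direct counting on the
# generated tables (independent of the archaeology code paths).
.networkTruth <- function(tables, graphs, bCounts, nNewB) {
  pairs <- function(tab) {
    pp <- tab[tab$component_kind_a != "site" | tab$component_kind_b != "site", ]
    unique(.pairKey(pp$protein_a, pp$protein_b))
  }
  corePairs <- pairs(tables$ABE)
  distMean <- function(k, parent) {
    ed <- graphEdges(graphs[[k]], includeExcluded = FALSE)
    key <- .pairKey(ed$node_a, ed$node_b)
    ped <- graphEdges(graphs[[parent]], includeExcluded = FALSE)
    pk <- .pairKey(ped$node_a, ped$node_b)
    mean(ed$com_distance[!(key %in% pk)])
  }
  list(
    core_edges = length(corePairs),
    b_status_counts = bCounts,
    n_new_pp_b = nNewB,
    a_status_counts = c("U-A" = 47, "A-A" = 19, "Ua-A" = 23, "Ua-Ua" = 11),
    e_ext_mediated = 57, n_new_pp_a = 100, n_new_pp_e = 100,
    funct_new = c(B = 16, A = 4, E = 2),
    funct_fraction_core = 22 / 49,
    e_type_counts = c(ext_G = 115, ext_ext = 99, G_G = 13,
                      ext_funct = 12, G_funct = 16),
    n_new_proteins = c(B = 18, A = 26, E = 11),
    multiplicity2_pairs_B = c(.pairKey("uS3", "uS5"), .pairKey("uS3", "mRNA")),
    ext_gt80_fraction = c(ABE = 0.01, B = 0.02, A = 0.04, E = 0.10),
    coevolved_counts = c(B = sum(bCounts[c("B-B", "Ub-B")]), A = 53, E = 33),
    stage_mean_distance = c(
      core = mean(graphEdges(graphs$ABE, includeExcluded = FALSE)$com_distance),
      B = distMean("B", "ABE"), A = distMean("A", "ABE"),
      E = distMean("E", "A")),
    bridge3_E = "eL15"
  )
}
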