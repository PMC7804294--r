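#' Load a component annotation
#'
#' Reads the per-protein anatomy table: for every r-protein chain, its
#' globular domain and extensions with category (segment, mix, helix,
#' loop, beta-hairpin), terminus (N/C/internal), author-numbering residue
#' ranges (`"start-end;start-end"`) and evolutionary status (U/A/B/E for
#' proteins, Ub/Ua/Ue/Ae for transition-acquired extensions). Accepts the
#' TSV schema (columns `protein_id`, `chain`, `component_id`,
#' `component_kind`, `category`, `terminus`, `ranges`, `status`) or a JSON
#' equivalent; non-protein chains (rRNA, tRNA, mRNA) are declared in rows
#' with `component_kind = "non_protein"` and the molecule type in
#' `category`.
#'
#' @param path TSV or JSON annotation file.
#' @param kingdom Kingdom label; defaults to a `kingdom` column/field in
#'   the file if present.
#' @param structure Optional atom table from [readStructure()]; when
#'   given, every annotated chain must exist in the structure and every
#'   residue range must be covered by modelled residues.
#' @return A [ComponentAnnotation-class] object.
#' @export
loadAnnotation <- function(path, kingdom = NULL, structure = NULL) {
  .assert(file.exists(path), "annotation file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    tab <- as.data.frame(raw$components %||% raw, stringsAsFactors = FALSE)
    kingdom <- kingdom %||% raw$kingdom
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  if (is.null(kingdom) && "kingdom" %in% names(tab)) {
    kingdom <- unique(tab$kingdom)
  }
  .assert(length(kingdom %||% character()) == 1, "kingdom must be a single label")

  nonProt <- tab[tab$component_kind == "non_protein", , drop = FALSE]
  tab <- tab[tab$component_kind != "non_protein", , drop = FALSE]
  .assert(nrow(tab) > 0, "no protein components in ", path)

  tab$category[is.na(tab$category)] <- ""
  tab$terminus[is.na(tab$terminus)] <- ""
  tab$length_aa <- vapply(tab$ranges, function(s) {
    r <- .parseRanges(s)
    sum(pmax(0L, r[, 2] - r[, 1] + 1L))
  }, numeric(1))

  chains <- unique(rbind(
    data.frame(chain = tab$chain, protein_id = tab$protein_id,
               molecule_type = "protein", stringsAsFactors = FALSE),
    if (nrow(nonProt)) data.frame(chain = nonProt$chain,
                                  protein_id = NA_character_,
                                  molecule_type = nonProt$category,
                                  stringsAsFactors = FALSE)
  ))

  if (!is.null(structure)) {
    missing <- setdiff(chains$chain, unique(structure$chain))
    .assert(length(missing) == 0,
            "annotated chain(s) absent from the structure: ",
            paste(missing, collapse = ", "))
    for (i in seq_len(nrow(tab))) {
      rng <- .parseRanges(tab$ranges[i])
      present <- unique(structure$resno[structure$chain == tab$chain[i]])
      want <- unlist(apply(rng, 1, function(r) seq(r[1], r[2])))
      if (!any(want %in% present)) {
        warning("component ", tab$component_id[i], " of ", tab$protein_id[i],
                " has no modelled residues", call. = FALSE)
      }
    }
  }

  ann <- new("ComponentAnnotation", kingdom = as.character(kingdom),
             components = tab[, c("protein_id", "chain", "component_id",
                                  "component_kind", "category", "terminus",
                                  "ranges", "length_aa", "status")],
             chainMap = chains, source = path)
  validObject(ann)
  ann
}

#' Write a component annotation to TSV
#' @param annotation A [ComponentAnnotation-class].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeAnnotation <- function(annotation, path) {
  cmp <- componentTable(annotation)
  cmp$kingdom <- kingdom(annotation)
  np <- chainMap(annotation)
  np <- np[np$molecule_type != "protein", , drop = FALSE]
  if (nrow(np)) {
    extra <- data.frame(protein_id = np$chain, chain = np$chain,
                        component_id = "all", component_kind = "non_protein",
                        category = np$molecule_type, terminus = "",
                        ranges = "1-1", length_aa = 1,
                        status = "U", kingdom = kingdom(annotation),
                        stringsAsFactors = FALSE)
    cmp <- rbind(cmp, extra[, names(cmp)])
  }
  utils::write.table(cmp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Centre of mass of an atom selection
#'
#' Geometric (unweighted) mean of atom coordinates by default. The choice
#' is recorded in the attribute `weighting`; pass `weights` (e.g. atomic
#' masses) for a weighted centre.
#'
#' @param atoms Atom table (needs `x`, `y`, `z`) or an `n x 3` matrix.
#' @param weights Optional per-atom weights.
#' @return Numeric length-3 vector with attribute `weighting`.
#' @examples
#' centerOfMass(matrix(c(0, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE))
#' @export
centerOfMass <- function(atoms, weights = NULL) {
  xyz <- if (is.matrix(atoms)) atoms else as.matrix(atoms[, c("x", "y", "z")])
  .assert(nrow(xyz) > 0, "empty atom selection")
  if (is.null(weights)) {
    com <- colMeans(xyz)
    attr(com, "weighting") <- "geometric"
  } else {
    .assert(length(weights) == nrow(xyz), "one weight per atom required")
    com <- colSums(xyz * weights) / sum(weights)
    attr(com, "weighting") <- "weighted"
  }
  stats::setNames(com, c("x", "y", "z"))
}

#' Centre of mass of each protein in a structure
#'
#' Uses the globular-domain residues of each protein; proteins devoid of a
#' globular domain fall back to the entire protein coordinates.
#'
#' @param atoms Atom table.
#' @param annotation A [ComponentAnnotation-class].
#' @return `data.frame` with `protein_id`, `x`, `y`, `z`, `selection`
#'   (`"globular"` or `"whole_protein"`).
#' @export
proteinCOMs <- function(atoms, annotation) {
  cmp <- componentTable(annotation)
  out <- lapply(unique(cmp$protein_id), function(p) {
    rows <- cmp[cmp$protein_id == p, , drop = FALSE]
    glob <- rows[rows$component_kind == "globular", , drop = FALSE]
    use <- if (nrow(glob)) glob else rows
    sel <- atoms$chain %in% use$chain & .inRanges(atoms$resno, use$ranges)
    if (!any(sel)) sel <- atoms$chain %in% rows$chain
    .assert(any(sel), "no atoms found for protein ", p)
    com <- centerOfMass(atoms[sel, , drop = FALSE])
    data.frame(protein_id = p, x = com[1], y = com[2], z = com[3],
               selection = if (nrow(glob)) "globular" else "whole_protein",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.inRanges <- function(resno, rangeStrings) {
  segs <- do.call(rbind, lapply(rangeStrings, .parseRanges))
  hit <- rep(FALSE, length(resno))
  for (i in seq_len(nrow(segs))) {
    hit <- hit | (resno >= segs[i, 1] & resno <= segs[i, 2])
  }
  hit
}

#' Extension size statistics
#'
#' Fraction of extensions longer than a threshold (default 80 amino
#' acids), per kingdom, plus the per-category size distribution. Lengths
#' count modelled residues as given by the annotation ranges.
#'
#' @param annotations A [ComponentAnnotation-class] or a named list of
#'   them (one per kingdom).
#' @param threshold Length threshold in amino acids.
#' @param status Optional status filter (e.g. `"U"` to restrict to the
#'   universal extension set).
#' @return A list with `fraction_gt` (named per kingdom), `threshold`,
#'   and `sizes` (`data.frame` of kingdom, category, status, length_aa).
#' @export
extensionSizeStats <- function(annotations, threshold = 80, status = NULL) {
  if (is(annotations, "ComponentAnnotation")) {
    annotations <- stats::setNames(list(annotations), kingdom(annotations))
  }
  sizes <- do.call(rbind, lapply(names(annotations), function(k) {
    cmp <- componentTable(annotations[[k]])
    ext <- cmp[cmp$component_kind == "extension", , drop = FALSE]
    if (!is.null(status)) ext <- ext[ext$status %in% status, , drop = FALSE]
    if (!nrow(ext)) return(NULL)
    data.frame(kingdom = k, category = ext$category, status = ext$status,
               length_aa = ext$length_aa, stringsAsFactors = FALSE)
  }))
  .assert(!is.null(sizes) && nrow(sizes) > 0, "no extensions found")
  frac <- vapply(split(sizes$length_aa, sizes$kingdom),
                 function(l) mean(l > threshold), numeric(1))
  list(fraction_gt = frac, threshold = threshold, sizes = sizes)
}
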