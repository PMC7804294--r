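#' @include utils.R
NULL

.EXT_CATEGORIES <- c("segment", "mix", "helix", "loop", "beta_hairpin")
.COMPONENT_KINDS <- c("globular", "extension", "extra_domain")
.PROTEIN_STATUSES <- c("U", "A", "B", "E")
.EXT_STATUSES <- c("U", "A", "B", "E", "Ub", "Ua", "Ue", "Ae")

#' ComponentAnnotation: r-protein anatomy for one kingdom
#'
#' Holds, per r-protein chain, the decomposition into a globular domain and
#' categorised extensions (segment, mix, helix, loop, beta-hairpin; N-, C-
#' terminal or internal) with author-numbering residue ranges and
#' evolutionary status labels, plus the chain-to-molecule map for the
#' attached structure.
#'
#' @slot kingdom One of `"A"`, `"B"`, `"E"` (or `"ABE"` for the universal
#'   set).
#' @slot components `data.frame` with columns `protein_id`, `chain`,
#'   `component_id`, `component_kind`, `category`, `terminus`, `ranges`
#'   (string, `"start-end;start-end"`), `length_aa`, `status`.
#' @slot chainMap `data.frame` with columns `chain`, `protein_id` (NA for
#'   non-protein chains), `molecule_type` (`protein`, `rRNA`, `tRNA`,
#'   `mRNA`).
#' @slot source Path the annotation was loaded from (may be `""`).
#' @export
setClass("ComponentAnnotation",
         representation(kingdom = "character",
                        components = "data.frame",
                        chainMap = "data.frame",
                        source = "character"))

setValidity("ComponentAnnotation", function(object) {
  cmp <- object@components
  need <- c("protein_id", "chain", "component_id", "component_kind",
            "category", "terminus", "ranges", "length_aa", "status")
  miss <- setdiff(need, names(cmp))
  if (length(miss)) return(paste("missing component columns:",
                                 paste(miss, collapse = ", ")))
  if (!all(cmp$component_kind %in% .COMPONENT_KINDS))
    return("unknown component_kind")
  isExt <- cmp$component_kind == "extension"
  if (any(isExt & !(cmp$category %in% .EXT_CATEGORIES)))
    return(paste("unknown extension category:",
                 paste(unique(cmp$category[isExt &
                   !(cmp$category %in% .EXT_CATEGORIES)]), collapse = ", ")))
  if (any(!isExt & !is.na(cmp$category) & cmp$category != ""))
    return("category must be empty unless component_kind is 'extension'")
  if (any(isExt & !(cmp$terminus %in% c("N", "C", "internal"))))
    return("extension terminus must be N, C or internal")
  if (!all(cmp$status %in% .EXT_STATUSES))
    return(paste("unknown status:",
                 paste(setdiff(unique(cmp$status), .EXT_STATUSES),
                       collapse = ", ")))
  for (p in unique(cmp$protein_id)) {
    rows <- cmp[cmp$protein_id == p, ]
    rng <- lapply(rows$ranges, .parseRanges)
    for (r in rng) {
      if (any(r[, 1] > r[, 2]))
        return(paste0("inverted residue range in protein ", p))
    }
    segs <- do.call(rbind, rng)
    if (nrow(segs) > 1) {
      segs <- segs[order(segs[, 1]), , drop = FALSE]
      if (any(segs[-1, 1] <= segs[-nrow(segs), 2]))
        return(paste0("overlapping residue ranges in protein ", p))
    }
    lens <- vapply(rng, function(r) sum(r[, 2] - r[, 1] + 1L), numeric(1))
    if (!isTRUE(all.equal(lens, as.numeric(rows$length_aa))))
      return(paste0("length_aa does not match ranges in protein ", p))
    # Extension-status consistency with the protein status.
    pstat <- rows$status[rows$component_kind == "globular"]
    if (length(pstat) == 1) {
      est <- rows$status[rows$component_kind == "extension"]
      bad <- (est %in% c("Ub", "Ua", "Ue") & pstat != "U") |
        (est == "Ae" & pstat != "A")
      if (any(bad))
        return(paste0("extension status inconsistent with protein status in ", p))
    }
  }
  TRUE
})

#' RibosomeGraph: centre-of-mass network of one kingdom's ribosome
#'
#' An undirected simple graph whose nodes are r-proteins (at the centre of
#' mass of their globular domain, or of the whole protein when no globular
#' domain exists) and functional sites (PTC, exit tunnel, mRNA, tRNA A/P/E
#' sites). Component-level contacts between a pair are aggregated into a
#' single edge whose `n_connections` records the multiplicity; the full
#' component-level contact table is retained in the `contacts` slot.
#' tRNA-tRNA and tRNA-mRNA edges are drawn but flagged
#' `excluded_from_stats`.
#'
#' @slot kingdom Kingdom label.
#' @slot nodes `data.frame`: `node_id`, `node_kind` (`protein` or
#'   `functional_site`), `functional_site_kind`, `x`, `y`, `z`,
#'   `functional_module`, `subunit`.
#' @slot edges `data.frame`: `node_a`, `node_b`, `contact_type`,
#'   `status_pair`, `n_connections`, `com_distance`,
#'   `excluded_from_stats`.
#' @slot contacts Component-level contact table (`protein_a`,
#'   `component_a`, `protein_b`, `component_b`, `status_a`, `status_b`,
#'   `status_pair`, `contact_type`, `excluded_from_stats`).
#' @slot metadata List (COM convention, probe, source, ...).
#' @export
setClass("RibosomeGraph",
         representation(kingdom = "character",
                        nodes = "data.frame",
                        edges = "data.frame",
                        contacts = "data.frame",
                        metadata = "list"))

setValidity("RibosomeGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("node_id", "node_kind") %in% names(nd)))
    return("nodes need node_id and node_kind")
  if (anyDuplicated(nd$node_id)) return("duplicate node ids")
  if (!all(nd$node_kind %in% c("protein", "functional_site")))
    return("node_kind must be protein or functional_site")
  fs <- nd$node_kind == "functional_site"
  if (any(fs & !(nd$functional_site_kind %in% .FUNCTIONAL_SITES)))
    return("functional_site_kind must be set (PTC/tunnel/mRNA/tRNA_*) on site nodes")
  if (any(!fs & !is.na(nd$functional_site_kind)))
    return("functional_site_kind must be NA on protein nodes")
  if (nrow(ed)) {
    if (any(ed$node_a == ed$node_b)) return("self-loops are not allowed")
    if (anyDuplicated(.pairKey(ed$node_a, ed$node_b)))
      return("multiple edges for one node pair; use n_connections")
    if (!all(c(ed$node_a, ed$node_b) %in% nd$node_id))
      return("edge endpoint not in node table")
    if (any(ed$n_connections < 1)) return("n_connections must be >= 1")
  }
  TRUE
})

#' ConservationProfile: per-column MSA conservation
#'
#' Per-column consensus and conservation flags under the "more than 80% of
#' the sequences" rule. `strict` requires a single residue above the
#' threshold; `similar` requires one amino-acid class (aromatic FYWH,
#' basic KR, acidic DE, polar STNQC, hydrophobic AVLIMGP) above it. Gaps
#' count in the denominator, so an all-gap or heavily gapped column is
#' never conserved.
#'
#' @slot protein_id Protein the alignment belongs to (may be `""`).
#' @slot nSequences Number of aligned sequences.
#' @slot threshold Conservation threshold (fraction, default 0.80).
#' @slot columns `data.frame`: `column`, `consensus`,
#'   `identity_fraction`, `consensus_class`, `class_fraction`, `strict`,
#'   `similar`, `all_gap`.
#' @export
setClass("ConservationProfile",
         representation(protein_id = "character",
                        nSequences = "integer",
                        threshold = "numeric",
                        columns = "data.frame"))

setValidity("ConservationProfile", function(object) {
  cl <- object@columns
  if (!all(c("column", "consensus", "identity_fraction", "class_fraction",
             "strict", "similar") %in% names(cl)))
    return("missing profile columns")
  if (any(cl$identity_fraction < 0 | cl$identity_fraction > 1, na.rm = TRUE))
    return("identity_fraction outside [0,1]")
  if (any(cl$strict & !cl$similar))
    return("strict conservation must imply similar conservation")
  TRUE
})

.parseRanges <- function(s) {
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  .assert(length(parts) > 0, "empty residue range: '", s, "'")
  m <- regmatches(parts, regexec("^(-?[0-9]+)-(-?[0-9]+)$", parts))
  bad <- vapply(m, length, integer(1)) != 3
  .assert(!any(bad), "malformed residue range: '", s, "'")
  out <- t(vapply(m, function(x) as.integer(x[2:3]), integer(2)))
  colnames(out) <- c("start", "end")
  out
}

.formatRanges <- function(mat) {
  paste(paste0(mat[, 1], "-", mat[, 2]), collapse = ";")
}
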