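#' Build a centre-of-mass network from detected interfaces
#'
#' Turns chain-level interface contacts into the kingdom's r-protein
#' network: one node per protein (placed at the centre of mass of its
#' globular domain, or of the whole protein when no globular domain
#' exists) and one node per functional site (PTC, exit tunnel, mRNA,
#' tRNA A/P/E), with one edge per interacting pair. Each contact is
#' classified at the component level: the side of an interface is
#' attributed to the component (globular domain vs extension) whose
#' interface residues bury the larger summed area, ties going to the
#' extension. Contacts between a protein chain and a non-protein chain
#' are kept only where the buried residues intersect a functional-site
#' selection; site-site edges (e.g. tRNA-mRNA) are drawn but flagged
#' `excluded_from_stats`.
#'
#' @param contacts Result of [detectInterfaces()].
#' @param annotation A [ComponentAnnotation-class] whose `chainMap` covers
#'   every contacted chain.
#' @param sites Named list of functional-site definitions, each
#'   `list(chain =, residues = NULL)`; `residues = NULL` means the whole
#'   chain. Names must be among PTC, tunnel, mRNA, tRNA_A, tRNA_P, tRNA_E.
#' @param atoms Atom table used for centres of mass.
#' @return A [RibosomeGraph-class].
#' @export
buildGraph <- function(contacts, annotation, sites, atoms) {
  .assert(all(names(sites) %in% .FUNCTIONAL_SITES),
          "site names must be among ", paste(.FUNCTIONAL_SITES, collapse = ", "))
  cm <- chainMap(annotation)
  cmp <- componentTable(annotation)

  known <- unique(c(contacts$chain_a, contacts$chain_b))
  unmapped <- setdiff(known, cm$chain)
  .assert(length(unmapped) == 0, "contact touches unannotated chain(s): ",
          paste(unmapped, collapse = ", "))

  rows <- list()
  for (i in seq_len(nrow(contacts))) {
    endsA <- .resolveEndpoint(contacts$chain_a[i], contacts$residues_a[[i]],
                              cm, cmp, sites)
    endsB <- .resolveEndpoint(contacts$chain_b[i], contacts$residues_b[[i]],
                              cm, cmp, sites)
    for (ea in endsA) for (eb in endsB) {
      if (ea$id == eb$id) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein_a = ea$id, component_a = ea$component,
        protein_b = eb$id, component_b = eb$component,
        status_a = ea$status, status_b = eb$status,
        stringsAsFactors = FALSE)
    }
  }
  ct <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(protein_a = character(), component_a = character(),
               protein_b = character(), component_b = character(),
               status_a = character(), status_b = character(),
               stringsAsFactors = FALSE)
  ct <- .finishContactTable(ct, cmp)

  coms <- proteinCOMs(atoms, annotation)
  nodes <- data.frame(node_id = coms$protein_id, node_kind = "protein",
                      functional_site_kind = NA_character_,
                      x = coms$x, y = coms$y, z = coms$z,
                      stringsAsFactors = FALSE)
  for (s in names(sites)) {
    sel <- atoms$chain == sites[[s]]$chain
    if (!is.null(sites[[s]]$residues)) {
      sel <- sel & atoms$resno %in% sites[[s]]$residues
    }
    .assert(any(sel), "no atoms for functional site ", s)
    com <- centerOfMass(atoms[sel, , drop = FALSE])
    nodes <- rbind(nodes, data.frame(node_id = s, node_kind = "functional_site",
                                     functional_site_kind = s,
                                     x = com[1], y = com[2], z = com[3],
                                     stringsAsFactors = FALSE))
  }

  .assembleGraph(kingdom(annotation), nodes, ct,
                 metadata = list(com = "geometric",
                                 probe = attr(contacts, "probe"),
                                 source = "structure",
                                 convention = attr(contacts, "convention")))
}

# Map one side of a chain-level contact onto protein components and/or
# functional sites. Returns a list of endpoints (possibly several sites).
.resolveEndpoint <- function(chain, residues, cm, cmp, sites) {
  row <- cm[cm$chain == chain, , drop = FALSE][1, ]
  if (!is.na(row$protein_id)) {
    comps <- cmp[cmp$chain == chain, , drop = FALSE]
    resno <- as.integer(sub("^.*:", "", sub("[A-Za-z]*$", "", residues$reskey)))
    share <- vapply(seq_len(nrow(comps)), function(j) {
      sum(residues$dsasa[.inRanges(resno, comps$ranges[j])])
    }, numeric(1))
    if (all(share == 0)) share <- comps$length_aa * 0 + 1  # fall back: whole protein
    isExt <- comps$component_kind == "extension"
    best <- which(share == max(share))
    if (length(best) > 1 && any(isExt[best])) best <- best[isExt[best]][1]
    best <- best[1]
    return(list(list(id = row$protein_id,
                     component = comps$component_id[best],
                     kind = if (isExt[best]) "ext" else "G",
                     status = comps$status[best])))
  }
  # Non-protein chain: attribute to overlapping functional sites.
  resno <- as.integer(sub("^.*:", "", sub("[A-Za-z]*$", "", residues$reskey)))
  hits <- list()
  for (s in names(sites)) {
    if (sites[[s]]$chain != chain) next
    ok <- is.null(sites[[s]]$residues) || any(resno %in% sites[[s]]$residues)
    if (ok) hits[[length(hits) + 1L]] <-
        list(id = s, component = "site", kind = "funct", status = "funct")
  }
  hits
}

# Fill status_pair / contact_type / excluded flag on a raw contact table.
.finishContactTable <- function(ct, cmp = NULL) {
  if (!nrow(ct)) {
    ct$status_pair <- character(0)
    ct$contact_type <- character(0)
    ct$excluded_from_stats <- logical(0)
    return(ct)
  }
  kindOf <- function(prot, comp) {
    if (comp == "site") return("funct")
    if (is.null(cmp)) {
      return(if (grepl("^G", comp)) "G" else "ext")
    }
    rows <- cmp[cmp$protein_id == prot & cmp$component_id == comp, , drop = FALSE]
    if (nrow(rows) && rows$component_kind[1] == "extension") "ext" else "G"
  }
  ka <- mapply(kindOf, ct$protein_a, ct$component_a)
  kb <- mapply(kindOf, ct$protein_b, ct$component_b)
  ct$status_pair <- .statusPair(ct$status_a, ct$status_b)
  ct$contact_type <- mapply(.contactType, ka, kb)
  sitePair <- ka == "funct" & kb == "funct"
  ct$excluded_from_stats <- sitePair
  ct
}

.contactType <- function(ka, kb) {
  k <- c(ka, kb)
  .assert(all(k %in% c("G", "ext", "funct", "site")),
          "cannot classify contact type for kinds ", ka, ", ", kb)
  k[k == "site"] <- "funct"
  if (any(k == "funct")) {
    other <- k[k != "funct"]
    if (length(other) == 0) return("funct_funct")
    return(if (other == "ext") "ext_funct" else "G_funct")
  }
  nExt <- sum(k == "ext")
  if (nExt == 2) "ext_ext" else if (nExt == 1) "ext_G" else "G_G"
}

#' Build a network from a supplementary-style contact table
#'
#' The table route: contacts are already enumerated at the component level
#' (the layout of the kingdom interaction tables), with one row per
#' component-level contact. Functional-site endpoints use the site id as
#' `protein_*` and `"site"` as `component_*`.
#'
#' @param contactTable `data.frame` (or TSV path) with columns
#'   `protein_a`, `component_a`, `protein_b`, `component_b`, `status_a`,
#'   `status_b`, and optionally `component_kind_a/b` (`G`/`ext`; inferred
#'   from the component id prefix otherwise).
#' @param nodes `data.frame` (or TSV path) with `node_id`, `x`, `y`, `z`.
#' @param kingdom Kingdom label.
#' @return A [RibosomeGraph-class].
#' @export
graphFromTable <- function(contactTable, nodes, kingdom) {
  if (is.character(contactTable)) {
    contactTable <- utils::read.delim(contactTable, stringsAsFactors = FALSE)
  }
  if (is.character(nodes)) nodes <- utils::read.delim(nodes,
                                                      stringsAsFactors = FALSE)
  ct <- contactTable
  need <- c("protein_a", "component_a", "protein_b", "component_b",
            "status_a", "status_b")
  .assert(all(need %in% names(ct)), "contact table needs columns: ",
          paste(need, collapse = ", "))
  if (all(c("component_kind_a", "component_kind_b") %in% names(ct)) && nrow(ct)) {
    ka <- ifelse(ct$component_a == "site", "funct", ct$component_kind_a)
    kb <- ifelse(ct$component_b == "site", "funct", ct$component_kind_b)
    ct$status_pair <- .statusPair(ct$status_a, ct$status_b)
    ct$contact_type <- mapply(.contactType, ka, kb)
    ct$excluded_from_stats <- ka == "funct" & kb == "funct"
  } else {
    ct <- .finishContactTable(ct)
  }

  ids <- unique(c(ct$protein_a, ct$protein_b, nodes$node_id))
  nd <- data.frame(node_id = ids,
                   node_kind = ifelse(ids %in% .FUNCTIONAL_SITES,
                                      "functional_site", "protein"),
                   functional_site_kind = ifelse(ids %in% .FUNCTIONAL_SITES,
                                                 ids, NA_character_),
                   stringsAsFactors = FALSE)
  m <- match(nd$node_id, nodes$node_id)
  nd$x <- nodes$x[m]; nd$y <- nodes$y[m]; nd$z <- nodes$z[m]
  .assembleGraph(kingdom, nd, ct,
                 metadata = list(com = "as supplied", source = "table"))
}

# Aggregate component-level contacts into simple-graph edges and build the
# validated S4 object.
.assembleGraph <- function(kingdom, nodes, contacts, metadata = list()) {
  nodes$subunit <- .subunitOf(nodes$node_id)
  nodes$functional_module <- "none"
  if (nrow(contacts)) {
    key <- .pairKey(contacts$protein_a, contacts$protein_b)
    agg <- lapply(split(seq_len(nrow(contacts)), key), function(idx) {
      sub <- contacts[idx, , drop = FALSE]
      a <- min(sub$protein_a[1], sub$protein_b[1])
      b <- max(sub$protein_a[1], sub$protein_b[1])
      data.frame(node_a = a, node_b = b,
                 contact_type = .modalType(sub$contact_type),
                 status_pair = sub$status_pair[1],
                 n_connections = nrow(sub),
                 excluded_from_stats = all(sub$excluded_from_stats),
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, agg)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(), node_b = character(),
                        contact_type = character(), status_pair = character(),
                        n_connections = integer(),
                        excluded_from_stats = logical(),
                        stringsAsFactors = FALSE)
  }
  m1 <- match(edges$node_a, nodes$node_id)
  m2 <- match(edges$node_b, nodes$node_id)
  .assert(!anyNA(c(m1, m2)), "edge endpoint missing from node table")
  edges$com_distance <- sqrt((nodes$x[m1] - nodes$x[m2])^2 +
                             (nodes$y[m1] - nodes$y[m2])^2 +
                             (nodes$z[m1] - nodes$z[m2])^2)
  g <- new("RibosomeGraph", kingdom = kingdom, nodes = nodes, edges = edges,
           contacts = contacts, metadata = metadata)
  validObject(g)
  assignFunctionalModules(g)
}

# Majority contact type; ties resolved by the extension-first preference.
.modalType <- function(types) {
  tab <- table(factor(types, levels = .CONTACT_TYPES))
  best <- names(tab)[tab == max(tab)]
  .CONTACT_TYPES[.CONTACT_TYPES %in% best][1]
}

#' Centre-of-mass distances along the network edges
#'
#' @param graph A [RibosomeGraph-class].
#' @param topN How many largest-distance edges to report.
#' @return List with `edges` (edge table with `com_distance`), `mean`,
#'   `max`, and `largest` (the `topN` longest edges).
#' @export
comDistances <- function(graph, topN = 10) {
  ed <- graphEdges(graph)
  .assert(!anyNA(ed$com_distance), "missing COM coordinates on some nodes")
  ord <- order(-ed$com_distance)
  list(edges = ed, mean = mean(ed$com_distance), max = max(ed$com_distance),
       largest = utils::head(ed[ord, ], topN))
}

#' Assign functional modules to network nodes
#'
#' A protein touching sites of exactly one functional category (mRNA,
#' tRNA, PTC, tunnel; the three tRNA sites count as one category) joins
#' that module; two categories make it a 2-way bridge, three a 3-way
#' bridge. A protein with no site contact whose protein neighbourhood
#' spans both subunits is a subunit bridge. Everything else is `none`.
#'
#' @param graph A [RibosomeGraph-class].
#' @return The graph with `functional_module` filled on its node table.
#' @export
assignFunctionalModules <- function(graph) {
  nd <- graph@nodes
  ed <- graph@edges
  catOf <- function(site) {
    ifelse(grepl("^tRNA", site), "tRNA",
           ifelse(site == "mRNA", "mRNA", site))
  }
  mod <- rep("none", nrow(nd))
  for (i in seq_len(nrow(nd))) {
    if (nd$node_kind[i] == "functional_site") {
      mod[i] <- paste0(catOf(nd$functional_site_kind[i]), "_module")
      next
    }
    id <- nd$node_id[i]
    nb <- c(ed$node_b[ed$node_a == id], ed$node_a[ed$node_b == id])
    nbSites <- nb[nb %in% nd$node_id[nd$node_kind == "functional_site"]]
    cats <- unique(catOf(nbSites))
    if (length(cats) == 1) {
      mod[i] <- paste0(cats, "_module")
    } else if (length(cats) == 2) {
      mod[i] <- "bridge_2"
    } else if (length(cats) >= 3) {
      mod[i] <- "bridge_3"
    } else {
      nbProt <- nb[nb %in% nd$node_id[nd$node_kind == "protein"]]
      su <- unique(stats::na.omit(.subunitOf(c(id, nbProt))))
      if (length(su) == 2) mod[i] <- "subunit_bridge"
    }
  }
  nd$functional_module <- mod
  initialize(graph, nodes = nd)
}

#' Export a network
#'
#' @param graph A [RibosomeGraph-class].
#' @param graphml,json,tsv Output paths (any may be `NULL`): GraphML via
#'   \pkg{igraph}, node-link JSON, and the component-level contact table
#'   as TSV in the supplementary layout.
#' @return Invisibly, the graph.
#' @export
writeGraph <- function(graph, graphml = NULL, json = NULL, tsv = NULL) {
  if (!is.null(graphml)) {
    g <- asIgraph(graph)
    igraph::V(g)$functional_site_kind <-
      ifelse(is.na(igraph::V(g)$functional_site_kind), "",
             igraph::V(g)$functional_site_kind)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(kingdom = kingdom(graph), nodes = graphNodes(graph),
           links = graphEdges(graph)),
      json, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  }
  if (!is.null(tsv)) {
    ct <- contactTable(graph, includeExcluded = TRUE)
    ct$kingdom <- kingdom(graph)
    utils::write.table(ct, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(graph)
}
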