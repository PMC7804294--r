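#' Universal (ABE) core network
#'
#' Intersects the three kingdom networks: an edge belongs to the
#' universal core when the same unordered protein/site pair (identified
#' by unified nomenclature name) is connected in all three kingdoms.
#' Reported both as aggregated protein-pair edges and as component-level
#' contact counts; site-site edges flagged as excluded from statistics do
#' not participate.
#'
#' @param graphs Named list of three [RibosomeGraph-class] objects (names
#'   `A`, `B`, `E`).
#' @return List with `edges` (character vector of `"a|b"` pair keys),
#'   `n_edges`, `n_contacts` (component-level contacts of the reference
#'   kingdom restricted to core pairs, per kingdom), and `table` (core
#'   pairs as a `data.frame`).
#' @export
universalCore <- function(graphs) {
  .assert(is.list(graphs) && length(graphs) == 3,
          "need the three kingdom graphs")
  .assert(all(c("A", "B", "E") %in% names(graphs)),
          "graphs must be named A, B and E; missing: ",
          paste(setdiff(c("A", "B", "E"), names(graphs)), collapse = ", "))
  keys <- lapply(graphs, function(g) {
    ed <- graphEdges(g, includeExcluded = FALSE)
    unique(.pairKey(ed$node_a, ed$node_b))
  })
  core <- Reduce(intersect, keys)
  nContacts <- vapply(graphs, function(g) {
    ct <- contactTable(g)
    sum(.pairKey(ct$protein_a, ct$protein_b) %in% core)
  }, numeric(1))
  parts <- do.call(rbind, strsplit(core, "|", fixed = TRUE))
  tab <- if (length(core)) {
    data.frame(node_a = parts[, 1], node_b = parts[, 2],
               stringsAsFactors = FALSE)
  } else {
    data.frame(node_a = character(), node_b = character(),
               stringsAsFactors = FALSE)
  }
  list(edges = core, n_edges = length(core), n_contacts = nContacts,
       table = tab)
}

# Normalise a "parent" argument into component-level contact keys and
# pair keys. Accepts a RibosomeGraph, a universalCore() result, or a
# character vector of pair keys.
.parentKeys <- function(parent) {
  if (is(parent, "RibosomeGraph")) {
    ct <- contactTable(parent)
    list(pairs = unique(.pairKey(ct$protein_a, ct$protein_b)),
         contacts = .contactKey(ct),
         hasContacts = TRUE)
  } else if (is.list(parent) && !is.null(parent$edges)) {
    list(pairs = parent$edges, contacts = character(), hasContacts = FALSE)
  } else {
    list(pairs = as.character(parent), contacts = character(),
         hasContacts = FALSE)
  }
}

.contactKey <- function(ct) {
  a <- paste(ct$protein_a, ct$component_a, sep = ":")
  b <- paste(ct$protein_b, ct$component_b, sep = ":")
  .pairKey(a, b)
}

# Acquisition statuses of each transition: a component carrying one of
# these labels was acquired at that transition.
.TRANSITION_ACQUIRED <- list(
  ABE_to_B = c("B", "Ub"),
  ABE_to_A = c("A", "Ua"),
  A_to_E = c("E", "Ue", "Ae")
)

#' New-contact statistics at one evolutionary transition
#'
#' Compares a child kingdom network against its parent network: new
#' contacts are component-level contacts of the child absent from the
#' parent (when the parent is a core edge set, any contact on a
#' non-core protein pair is new). Each new protein-protein contact is
#' labelled by the status pair of its two contacting components (U-B,
#' B-B, Ub-U, ...); fractions are computed over new protein-protein
#' contacts, while the functional fraction uses all new contacts as its
#' denominator. Contacts whose two components both carry the
#' transition's acquisition status are reported as coevolved.
#'
#' @param parent Parent network: a [RibosomeGraph-class], a
#'   [universalCore()] result, or a vector of `"a|b"` pair keys.
#' @param child Child kingdom [RibosomeGraph-class].
#' @param transition One of `"ABE_to_B"`, `"ABE_to_A"`, `"A_to_E"`.
#' @return List of class `TransitionStats`: `transition`, `n_new_edges`
#'   (aggregated pairs), `n_new_contacts`, `n_new_proteins`,
#'   `status_pair_fractions`, `status_pair_counts`,
#'   `contact_type_fractions`, `functional_fraction`, `coevolved`
#'   (contact table subset), `new_contacts` (full table),
#'   `mean_com_distance` of new edges.
#' @export
transitionStats <- function(parent, child,
                            transition = c("ABE_to_B", "ABE_to_A", "A_to_E")) {
  transition <- match.arg(transition)
  pk <- .parentKeys(parent)
  ct <- contactTable(child)
  .assert(all(c(ct$status_a, ct$status_b) %in% c(.EXT_STATUSES, "funct")),
          "unknown evolutionary status in child contact table")

  pair <- .pairKey(ct$protein_a, ct$protein_b)
  if (pk$hasContacts) {
    isNew <- !(.contactKey(ct) %in% pk$contacts)
  } else {
    isNew <- !(pair %in% pk$pairs)
  }
  new <- ct[isNew, , drop = FALSE]

  pp <- new[new$contact_type %in% c("ext_ext", "ext_G", "G_G"), , drop = FALSE]
  statusCounts <- if (nrow(pp)) table(pp$status_pair) else table(character())
  statusFrac <- if (nrow(pp)) statusCounts / nrow(pp) else statusCounts
  typeFrac <- if (nrow(new)) {
    table(factor(new$contact_type, levels = .CONTACT_TYPES)) / nrow(new)
  } else {
    table(factor(character(), levels = .CONTACT_TYPES))
  }
  funcFrac <- if (nrow(new)) {
    mean(new$contact_type %in% c("ext_funct", "G_funct"))
  } else {
    NA_real_
  }

  acq <- .TRANSITION_ACQUIRED[[transition]]
  coev <- new[new$status_a %in% acq & new$status_b %in% acq, , drop = FALSE]

  childProteins <- unique(c(ct$protein_a, ct$protein_b))
  childProteins <- childProteins[!(childProteins %in% .FUNCTIONAL_SITES)]
  parentProteins <- unique(unlist(strsplit(pk$pairs, "|", fixed = TRUE)))
  newProteins <- setdiff(childProteins, parentProteins)

  newPairs <- setdiff(unique(pair[isNew]), pk$pairs)
  ed <- graphEdges(child, includeExcluded = FALSE)
  newEdge <- .pairKey(ed$node_a, ed$node_b) %in% newPairs
  meanDist <- if (any(newEdge)) mean(ed$com_distance[newEdge]) else NA_real_

  structure(list(
    transition = transition,
    n_new_edges = length(newPairs),
    n_new_contacts = nrow(new),
    n_new_proteins = length(newProteins),
    new_proteins = sort(newProteins),
    status_pair_counts = statusCounts,
    status_pair_fractions = statusFrac,
    contact_type_fractions = typeFrac,
    functional_fraction = funcFrac,
    coevolved = coev,
    new_contacts = new,
    mean_com_distance = meanDist
  ), class = "TransitionStats")
}

#' @export
print.TransitionStats <- function(x, ...) {
  cat(sprintf("Transition %s: %d new contacts on %d new pairs, %d new proteins\n",
              x$transition, x$n_new_contacts, x$n_new_edges, x$n_new_proteins))
  if (length(x$status_pair_fractions)) {
    f <- sort(unclass(x$status_pair_fractions), decreasing = TRUE)
    cat("  status pairs:",
        paste(sprintf("%s %.0f%%", names(f), 100 * f), collapse = ", "), "\n")
  }
  cat(sprintf("  functional-site fraction of new contacts: %.1f%%\n",
              100 * x$functional_fraction))
  invisible(x)
}

#' Fraction of contacts involving a functional site
#'
#' @param graph A [RibosomeGraph-class].
#' @param newOnly Restrict to contacts absent from `parent`.
#' @param parent Parent network or pair-key vector (required when
#'   `newOnly = TRUE`).
#' @return Fraction in `[0, 1]` (0 when the graph has no functional-site
#'   contacts).
#' @export
functionalContactFraction <- function(graph, newOnly = FALSE, parent = NULL) {
  ct <- contactTable(graph)
  if (newOnly) {
    .assert(!is.null(parent), "newOnly = TRUE requires a parent")
    pk <- .parentKeys(parent)
    if (pk$hasContacts) {
      ct <- ct[!(.contactKey(ct) %in% pk$contacts), , drop = FALSE]
    } else {
      ct <- ct[!(.pairKey(ct$protein_a, ct$protein_b) %in% pk$pairs), ,
               drop = FALSE]
    }
  }
  if (!nrow(ct)) return(0)
  mean(ct$contact_type %in% c("ext_funct", "G_funct"))
}

#' COM-distance trend of newly added edges across evolutionary stages
#'
#' For an ordered list of stages (e.g. universal core, B, A, E), computes
#' the mean centre-of-mass distance of the edges each stage added
#' relative to its parent stage. The trend is reported, not asserted.
#'
#' @param graphs Ordered named list of [RibosomeGraph-class] objects.
#' @param parents Integer vector, same length: index of each stage's
#'   parent within `graphs` (0 = no parent, all edges count as new).
#'   Default: first stage is the root and every later stage descends
#'   from the stage before it, except that stages 2 and 3 of a 4-stage
#'   lineage (B and A) both descend from the root core.
#' @return `data.frame` with `stage`, `n_new_edges`, `mean_distance`,
#'   plus attribute `distances` (list of per-stage distance vectors).
#'   Stages with zero new edges get `NA` and a warning.
#' @export
distanceTrend <- function(graphs, parents = NULL) {
  n <- length(graphs)
  .assert(n >= 1, "need at least one stage")
  if (is.null(parents)) {
    parents <- if (n == 4) c(0L, 1L, 1L, 3L) else c(0L, seq_len(n - 1L))
  }
  .assert(length(parents) == n, "one parent index per stage required")
  dists <- vector("list", n)
  out <- data.frame(stage = names(graphs) %||% as.character(seq_len(n)),
                    n_new_edges = integer(n), mean_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ed <- graphEdges(graphs[[i]], includeExcluded = FALSE)
    .assert(!anyNA(ed$com_distance), "missing COM distances in stage ",
            out$stage[i])
    key <- .pairKey(ed$node_a, ed$node_b)
    if (parents[i] > 0) {
      ped <- graphEdges(graphs[[parents[i]]], includeExcluded = FALSE)
      pkey <- .pairKey(ped$node_a, ped$node_b)
      ed <- ed[!(key %in% pkey), , drop = FALSE]
    }
    dists[[i]] <- ed$com_distance
    out$n_new_edges[i] <- nrow(ed)
    if (nrow(ed)) {
      out$mean_distance[i] <- mean(ed$com_distance)
    } else {
      warning("stage ", out$stage[i], " adds no new edges; mean undefined",
              call. = FALSE)
    }
  }
  attr(out, "distances") <- dists
  out
}
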