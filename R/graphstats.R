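#' Node centralities of a network
#'
#' Degree, betweenness (fraction of shortest paths through a node,
#' standard normalisation, unweighted edges), eigenvector (leading
#' adjacency eigenvector, scaled to unit maximum) and closeness
#' centralities, with the argmax node of each index (ties broken
#' lexicographically by node id). Edges drawn but excluded from the
#' connectivity statistics (tRNA-tRNA, tRNA-mRNA) still belong to the
#' graph and participate here.
#'
#' @param graph A [RibosomeGraph-class] or an \pkg{igraph} graph.
#' @param giant Analyse the giant component when the graph is
#'   disconnected? If `FALSE`, a disconnected graph is an error naming
#'   the components.
#' @return List of class `CentralityReport`: `table` (`data.frame` of
#'   `node`, `degree`, `betweenness`, `eigenvector`, `closeness`),
#'   `argmax` (named character vector), `n_nodes`, `n_edges`.
#' @export
centralities <- function(graph, giant = FALSE) {
  g <- if (is(graph, "RibosomeGraph")) asIgraph(graph) else graph
  .assert(igraph::vcount(g) > 0, "empty graph")
  comp <- igraph::components(g)
  if (comp$no > 1) {
    if (!giant) {
      sizes <- split(igraph::V(g)$name, comp$membership)
      stop("graph is disconnected (", comp$no, " components: ",
           paste(vapply(sizes, function(s) paste(s, collapse = ","),
                        character(1)), collapse = " | "),
           "); pass giant = TRUE to analyse the giant component",
           call. = FALSE)
    }
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  nm <- igraph::V(g)$name
  tab <- data.frame(
    node = nm,
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(igraph::betweenness(g, normalized = TRUE)),
    eigenvector = .eigenCentrality(g),
    closeness = as.numeric(suppressWarnings(
      igraph::closeness(g, normalized = TRUE))),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  argmax <- vapply(c("degree", "betweenness", "eigenvector", "closeness"),
                   function(idx) {
                     v <- tab[[idx]]
                     cand <- tab$node[v == max(v)]
                     sort(cand)[1]
                   }, character(1))
  structure(list(table = tab, argmax = argmax,
                 n_nodes = nrow(tab), n_edges = igraph::ecount(g)),
            class = "CentralityReport")
}

#' @export
print.CentralityReport <- function(x, ...) {
  cat(sprintf("Centralities on %d nodes / %d edges\n", x$n_nodes, x$n_edges))
  cat("  argmax:", paste(names(x$argmax), x$argmax, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

# Deterministic eigenvector centrality: leading eigenvector of the dense
# adjacency matrix (symmetric solver), scaled to unit maximum. Avoids the
# randomly started iterative solver so results are bit-reproducible.
.eigenCentrality <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  if (all(A == 0)) return(rep(0, nrow(A)))
  v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
  v / max(v)
}

# The default statistic family for the randomness test. Each statistic is
# an upper-tail summary of how concentrated the graph's centrality mass
# is; a structured (hub-dominated) graph scores high, an Erdos-Renyi
# graph low. ev_conc is the inverse participation ratio of the
# eigenvector-centrality vector (large when the eigenvector mass sits on
# few nodes).
.ER_STATISTICS <- list(
  bc_max = function(g) max(igraph::betweenness(g, normalized = TRUE)),
  bc_var = function(g) stats::var(igraph::betweenness(g, normalized = TRUE)),
  ev_conc = function(g) {
    v <- .eigenCentrality(g)
    sum(v^4) / sum(v^2)^2
  },
  deg_var = function(g) stats::var(as.numeric(igraph::degree(g)))
)

#' Monte Carlo test of non-randomness against Erdos-Renyi graphs
#'
#' Null hypothesis: the observed network is a typical realisation of an
#' Erdos-Renyi random graph. The null is G(n, m) with node and edge
#' counts matched to the observation (conditioning on the observed
#' density). For each sampled null graph a family of centrality
#' concentration statistics is computed (default: maximum betweenness,
#' betweenness variance, eigenvector variance, degree variance); the
#' empirical upper-tail p-value uses the add-one rule
#' p = (1 + #\{null >= observed\}) / (nSamples + 1), so it is never zero.
#' `coherent_reject` is `TRUE` only when every statistic in the family
#' rejects at `alpha` (a conservative, unanimity-based operationalisation
#' of coherence across a statistic family; an approximation).
#'
#' @param graph A [RibosomeGraph-class] or \pkg{igraph} graph.
#' @param statistics Character subset of
#'   `c("bc_max", "bc_var", "ev_var", "deg_var")`.
#' @param nSamples Number of null samples (>= 100; empirical p is
#'   unstable below that).
#' @param seed Integer seed; the test is bit-reproducible for a fixed
#'   seed.
#' @param alpha Rejection level for the coherence flag.
#' @param keepNullSamples Return the sampled null statistics?
#' @return List of class `ERTestResult`: `results` (`data.frame` of
#'   `statistic`, `observed`, `p`, `reject`), `coherent_reject`,
#'   `n_samples`, `seed`, `alpha`, `n`, `m`, and optionally
#'   `null_samples` (named list of numeric vectors).
#' @export
erNullTest <- function(graph, statistics = names(.ER_STATISTICS),
                       nSamples = 999, seed = 1, alpha = 0.05,
                       keepNullSamples = FALSE) {
  .assert(nSamples >= 100, "nSamples must be >= 100 (empirical p unstable)")
  statistics <- match.arg(statistics, names(.ER_STATISTICS),
                          several.ok = TRUE)
  g <- if (is(graph, "RibosomeGraph")) asIgraph(graph) else graph
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  .assert(n >= 2 && m >= 1, "graph too small for a null test")

  observed <- vapply(statistics, function(s) .ER_STATISTICS[[s]](g),
                     numeric(1))
  null <- matrix(NA_real_, nrow = nSamples, ncol = length(statistics),
                 dimnames = list(NULL, statistics))
  .withSeed(seed, {
    for (i in seq_len(nSamples)) {
      gr <- igraph::sample_gnm(n, m)
      for (s in statistics) null[i, s] <- .ER_STATISTICS[[s]](gr)
    }
  })
  p <- vapply(statistics, function(s) {
    (1 + sum(null[, s] >= observed[s])) / (nSamples + 1)
  }, numeric(1))
  res <- data.frame(statistic = statistics, observed = unname(observed),
                    p = unname(p), reject = unname(p <= alpha),
                    stringsAsFactors = FALSE)
  out <- list(results = res, coherent_reject = all(res$reject),
              n_samples = nSamples, seed = seed, alpha = alpha,
              n = n, m = m)
  if (keepNullSamples) {
    out$null_samples <- lapply(stats::setNames(statistics, statistics),
                               function(s) null[, s])
  }
  structure(out, class = "ERTestResult")
}

#' @export
print.ERTestResult <- function(x, ...) {
  cat(sprintf("Erdos-Renyi G(%d, %d) null test, %d samples (seed %d)\n",
              x$n, x$m, x$n_samples, x$seed))
  print(x$results, row.names = FALSE)
  cat(sprintf("coherent rejection at alpha = %.2f: %s\n", x$alpha,
              x$coherent_reject))
  invisible(x)
}

#' Centrality jumps between two evolutionary stages
#'
#' Per-node differences of centrality values between a parent and a child
#' network report, ranked by absolute betweenness change; nodes absent
#' from the parent are flagged new.
#'
#' @param parentReport,childReport Results of [centralities()].
#' @param rankBy Index used for ranking (default betweenness).
#' @return `data.frame` of shared nodes with `d_degree`, `d_betweenness`,
#'   `d_eigenvector`, `d_closeness`, ordered by `|rankBy|` descending;
#'   attribute `new_nodes` lists child-only nodes.
#' @export
centralityJumps <- function(parentReport, childReport,
                            rankBy = c("betweenness", "eigenvector",
                                       "degree", "closeness")) {
  rankBy <- match.arg(rankBy)
  pt <- parentReport$table
  ctb <- childReport$table
  shared <- intersect(pt$node, ctb$node)
  mp <- match(shared, pt$node)
  mc <- match(shared, ctb$node)
  out <- data.frame(node = shared, stringsAsFactors = FALSE)
  for (idx in c("degree", "betweenness", "eigenvector", "closeness")) {
    out[[paste0("d_", idx)]] <- ctb[[idx]][mc] - pt[[idx]][mp]
  }
  out <- out[order(-abs(out[[paste0("d_", rankBy)]])), ]
  rownames(out) <- NULL
  attr(out, "new_nodes") <- setdiff(ctb$node, pt$node)
  out
}

# Evaluate an expression under a fixed RNG state, restoring the caller's
# state afterwards.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}
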