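#' Run the full network-archaeology pipeline
#'
#' Orchestrates the stages over the three kingdoms: load or build the
#' kingdom networks (either from a structure + annotation + functional
#' site definitions, or from a pre-enumerated component-level contact
#' table + node coordinates), intersect the universal core, compute the
#' three transition statistics, centralities and the Erdos-Renyi
#' randomness test per kingdom, the COM distance trend, extension-size
#' statistics, and (when alignments are configured) conservation
#' profiles with aromatic acquisitions. Writes per-stage outputs under
#' `output_dir` and a single JSON summary echoing every headline
#' number; missing optional inputs mark their stage `"skipped"` rather
#' than failing the run.
#'
#' @param config Path to a YAML config file or an equivalent nested
#'   list. Top level: `kingdoms` (named `ABE`/`B`/`A`/`E`, each either
#'   `contacts`+`nodes`+`annotation` paths or `structure`+`annotation`+
#'   `sites`), optional `msa` (`A`, `E`, `map`), `params` (`probe`,
#'   `conservation_threshold`, `extension_threshold`, `n_null`,
#'   `alpha`, `seed`) and `output_dir`.
#' @return Invisibly, a list with `graphs`, `core`, `transitions`,
#'   `centralities`, `er_tests`, `distance_trend`, `extensions`,
#'   `conservation`, and `summary` (the content of `summary.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- utils::modifyList(
    list(probe = 1.4, conservation_threshold = 0.80,
         extension_threshold = 80, n_null = 999, alpha = 0.05, seed = 1),
    config$params %||% list())
  outDir <- config$output_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  stageFail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  graphs <- list()
  annotations <- list()
  for (k in names(config$kingdoms)) {
    cfg <- config$kingdoms[[k]]
    g <- tryCatch({
      if (!is.null(cfg$contacts)) {
        graphFromTable(cfg$contacts, cfg$nodes, kingdom = k)
      } else {
        atoms <- readStructure(cfg$structure)
        ann <- loadAnnotation(cfg$annotation, kingdom = k, structure = atoms)
        sites <- if (is.character(cfg$sites)) jsonlite::fromJSON(cfg$sites,
                   simplifyVector = FALSE) else cfg$sites
        contacts <- detectInterfaces(atoms, probe = p$probe)
        buildGraph(contacts, ann, sites, atoms)
      }
    }, error = function(e) stageFail(paste0("network[", k, "]"), e))
    graphs[[k]] <- g
    writeGraph(g, graphml = file.path(outDir, paste0("graph_", k, ".graphml")),
               tsv = file.path(outDir, paste0("contacts_", k, ".tsv")))
    if (!is.null(cfg$annotation)) {
      annotations[[k]] <- tryCatch(
        loadAnnotation(cfg$annotation, kingdom = k),
        error = function(e) stageFail(paste0("annotation[", k, "]"), e))
    }
  }

  kingdomSet <- intersect(c("B", "A", "E"), names(graphs))
  core <- NULL
  if (length(kingdomSet) == 3) {
    core <- tryCatch(universalCore(graphs[c("A", "B", "E")]),
                     error = function(e) stageFail("universal_core", e))
  }

  transitions <- list()
  if (!is.null(graphs$ABE)) {
    if (!is.null(graphs$B)) {
      transitions$ABE_to_B <- transitionStats(graphs$ABE, graphs$B, "ABE_to_B")
    }
    if (!is.null(graphs$A)) {
      transitions$ABE_to_A <- transitionStats(graphs$ABE, graphs$A, "ABE_to_A")
    }
    if (!is.null(graphs$A) && !is.null(graphs$E)) {
      transitions$A_to_E <- transitionStats(graphs$A, graphs$E, "A_to_E")
    }
  }

  cents <- lapply(graphs, function(g) centralities(g, giant = TRUE))
  erTests <- lapply(graphs, function(g) {
    erNullTest(g, nSamples = p$n_null, seed = p$seed, alpha = p$alpha)
  })

  trend <- NULL
  if (all(c("ABE", "B", "A", "E") %in% names(graphs))) {
    trend <- distanceTrend(graphs[c("ABE", "B", "A", "E")])
  }

  extensions <- if (length(annotations)) {
    tryCatch(extensionSizeStats(annotations, threshold = p$extension_threshold),
             error = function(e) stageFail("extensions", e))
  } else {
    NULL
  }

  conservation <- "skipped"
  if (!is.null(config$msa) &&
      all(file.exists(unlist(config$msa[c("A", "E")])))) {
    profA <- conservationProfile(config$msa$A, p$conservation_threshold)
    profE <- conservationProfile(config$msa$E, p$conservation_threshold)
    crossMap <- utils::read.delim(config$msa$map, stringsAsFactors = FALSE)
    conservation <- list(
      profile_A = profA, profile_E = profE,
      aromatic = aromaticAcquisitions(profA, profE, crossMap))
    utils::write.table(conservation$aromatic,
                       file.path(outDir, "aromatic_acquisitions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  fr <- function(ts, label) {
    f <- ts$status_pair_fractions
    if (label %in% names(f)) as.numeric(f[[label]]) else 0
  }
  summary <- list(
    schema = "riboarch-summary/1",
    seed = p$seed,
    universal_core_edges = if (!is.null(core)) core$n_edges else NA,
    functional_fraction = lapply(graphs, functionalContactFraction),
    transitions = lapply(transitions, function(ts) {
      list(n_new_contacts = ts$n_new_contacts,
           n_new_proteins = ts$n_new_proteins,
           status_pair_pct = as.list(round(
             100 * unclass(ts$status_pair_fractions), 6)),
           functional_pct = 100 * ts$functional_fraction,
           n_coevolved = nrow(ts$coevolved))
    }),
    contact_type_pct = lapply(graphs, function(g) {
      ct <- contactTable(g)
      as.list(round(100 * prop.table(table(
        factor(ct$contact_type, levels = .CONTACT_TYPES))), 6))
    }),
    extensions_gt_threshold = if (!is.null(extensions))
      as.list(extensions$fraction_gt) else "skipped",
    bc_argmax = lapply(cents, function(cc) unname(cc$argmax["betweenness"])),
    er_coherent_reject = lapply(erTests, function(t) t$coherent_reject),
    mean_new_edge_distance = if (!is.null(trend))
      as.list(stats::setNames(trend$mean_distance, trend$stage)) else NULL,
    conservation = if (identical(conservation, "skipped")) "skipped" else
      list(n_new_aromatic = sum(conservation$aromatic$status == "new_in_E"),
           n_ancient = sum(conservation$aromatic$status == "ancient"),
           n_strengthened = sum(conservation$aromatic$status ==
                                  "strengthened_similar_to_strict"))
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  invisible(list(graphs = graphs, core = core, transitions = transitions,
                 centralities = cents, er_tests = erTests,
                 distance_trend = trend, extensions = extensions,
                 conservation = conservation, summary = summary))
}
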