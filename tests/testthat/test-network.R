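# Table-route fixtures.
nodeDf <- function(ids, coords = NULL) {
  if (is.null(coords)) coords <- matrix(seq_len(3 * length(ids)), ncol = 3)
  data.frame(node_id = ids, x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

ctRow <- function(pa, ca, ka, sa, pb, cb, kb, sb) {
  data.frame(protein_a = pa, component_a = ca, component_kind_a = ka,
             status_a = sa, protein_b = pb, component_b = cb,
             component_kind_b = kb, status_b = sb, stringsAsFactors = FALSE)
}

test_that("contacts A-B and B-C build a path graph", {
  ct <- rbind(ctRow("uS3", "G", "G", "U", "uS5", "G", "G", "U"),
              ctRow("uS5", "e1", "ext", "U", "uS7", "G", "G", "U"))
  g <- graphFromTable(ct, nodeDf(c("uS3", "uS5", "uS7")), kingdom = "B")
  expect_equal(nrow(graphNodes(g)), 3L)
  expect_equal(nrow(graphEdges(g)), 2L)
  ig <- asIgraph(g)
  expect_equal(sum(igraph::degree(ig)), 2L * igraph::ecount(ig))
})

test_that("contact types follow the component kinds", {
  ct <- rbind(ctRow("uS3", "e1", "ext", "U", "uS5", "e2", "ext", "U"),
              ctRow("uS3", "G", "G", "U", "uS7", "e1", "ext", "U"),
              ctRow("uS5", "G", "G", "U", "uS7", "G", "G", "U"),
              ctRow("uS7", "e1", "ext", "U", "mRNA", "site", "site", "funct"),
              ctRow("uS5", "G", "G", "U", "mRNA", "site", "site", "funct"))
  g <- graphFromTable(ct, nodeDf(c("uS3", "uS5", "uS7", "mRNA")), "B")
  tab <- contactTable(g)
  expect_equal(tab$contact_type,
               c("ext_ext", "ext_G", "G_G", "ext_funct", "G_funct"))
  # partition: each contact has exactly one type
  expect_equal(sum(table(tab$contact_type)), nrow(tab))
})

test_that("multiplicities aggregate into n_connections", {
  ct <- rbind(ctRow("uS3", "G", "G", "U", "uS5", "G", "G", "U"),
              ctRow("uS3", "e1", "ext", "U", "uS5", "G", "G", "U"),
              ctRow("uS3", "e2", "ext", "U", "uS5", "e1", "ext", "U"),
              ctRow("uS3", "G", "G", "U", "uS7", "G", "G", "U"))
  g <- graphFromTable(ct, nodeDf(c("uS3", "uS5", "uS7")), "B")
  ed <- graphEdges(g)
  expect_equal(sort(ed$n_connections), c(1L, 3L))
  expect_equal(ed$n_connections[ed$node_a == "uS3" & ed$node_b == "uS5"], 3L)
  # simple graph: one edge per pair
  expect_false(anyDuplicated(paste(ed$node_a, ed$node_b)) > 0)
})

test_that("aggregation is idempotent", {
  net <- plantedNet(3)
  g <- net$graphs$B
  rebuilt <- graphFromTable(contactTable(g, includeExcluded = TRUE),
                            graphNodes(g), kingdom(g))
  e1 <- graphEdges(g); e2 <- graphEdges(rebuilt)
  ord <- function(e) e[order(e$node_a, e$node_b),
                       c("node_a", "node_b", "n_connections", "contact_type")]
  expect_equal(ord(e1), ord(e2), ignore_attr = TRUE)
})

test_that("COM distances are Euclidean and rigid-motion invariant", {
  ct <- ctRow("uS3", "G", "G", "U", "uS5", "G", "G", "U")
  nd <- nodeDf(c("uS3", "uS5"), matrix(c(0, 0, 0, 3, 4, 0), ncol = 3,
                                       byrow = TRUE))
  g <- graphFromTable(ct, nd, "B")
  expect_equal(graphEdges(g)$com_distance, 5)
  d0 <- comDistances(g)
  expect_equal(d0$max, 5)
  # rigid motion
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- nd
  xyz <- as.matrix(nd[, c("x", "y", "z")]) %*% t(R)
  moved$x <- xyz[, 1] + 11; moved$y <- xyz[, 2] - 4; moved$z <- xyz[, 3] + 2
  g2 <- graphFromTable(ct, moved, "B")
  expect_equal(graphEdges(g2)$com_distance, 5, tolerance = 1e-10)
  # the max-distance edge agrees with an exhaustive scan on a larger graph
  net <- plantedNet(5)
  ed <- graphEdges(net$graphs$E)
  expect_equal(comDistances(net$graphs$E)$max, max(ed$com_distance))
})

test_that("functional modules follow the site-category rules", {
  sites <- c("PTC", "tunnel", "tRNA_P", "tRNA_A", "mRNA")
  ct <- rbind(
    ctRow("uL2", "G", "G", "U", "PTC", "site", "site", "funct"),
    ctRow("uL4", "G", "G", "U", "PTC", "site", "site", "funct"),
    ctRow("uL4", "e1", "ext", "U", "tunnel", "site", "site", "funct"),
    ctRow("eL15", "e1", "ext", "A", "PTC", "site", "site", "funct"),
    ctRow("eL15", "e1", "ext", "A", "tunnel", "site", "site", "funct"),
    ctRow("eL15", "e2", "ext", "A", "tRNA_P", "site", "site", "funct"),
    ctRow("uS13", "G", "G", "U", "tRNA_A", "site", "site", "funct"),
    ctRow("uS13", "G", "G", "U", "tRNA_P", "site", "site", "funct"),
    ctRow("uL5", "G", "G", "U", "uS11", "G", "G", "U"),
    ctRow("uS4", "G", "G", "U", "uS11", "G", "G", "U"))
  nd <- nodeDf(c("uL2", "uL4", "eL15", "uS13", "uL5", "uS11", "uS4", sites))
  g <- graphFromTable(ct, nd, "E")
  m <- graphNodes(g)
  mod <- setNames(m$functional_module, m$node_id)
  expect_equal(unname(mod["uL2"]), "PTC_module")
  expect_equal(unname(mod["uL4"]), "bridge_2")
  expect_equal(unname(mod["eL15"]), "bridge_3")
  expect_equal(unname(mod["uS13"]), "tRNA_module")  # both tRNAs, one category
  expect_equal(unname(mod["uL5"]), "subunit_bridge")
  expect_equal(unname(mod["uS11"]), "subunit_bridge")
  expect_equal(unname(mod["uS4"]), "none")  # same-subunit protein contact only
  expect_equal(unname(mod["PTC"]), "PTC_module")
})

test_that("site-site edges are drawn but excluded from statistics", {
  net <- plantedNet(3)
  g <- net$graphs$ABE
  edAll <- graphEdges(g, includeExcluded = TRUE)
  edStat <- graphEdges(g, includeExcluded = FALSE)
  expect_gt(nrow(edAll), nrow(edStat))
  excl <- edAll[edAll$excluded_from_stats, ]
  expect_true(all(excl$node_a %in% c("mRNA", "PTC", "tRNA_A", "tRNA_P",
                                     "tRNA_E", "tunnel") &
                  excl$node_b %in% c("mRNA", "PTC", "tRNA_A", "tRNA_P",
                                     "tRNA_E", "tunnel")))
})

test_that("unannotated contact chains are reported", {
  tc <- makeToyComplex(tempfile("toy"), separation = 0)
  atoms <- readStructure(tc$pdb)
  contacts <- detectInterfaces(atoms)
  ann <- data.frame(protein_id = "uL4", chain = "A", component_id = "G",
                    component_kind = "globular", category = "",
                    terminus = "", ranges = "1-12", status = "U",
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write.table(ann, f, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- loadAnnotation(f, kingdom = "B")
  expect_error(buildGraph(contacts, a, sites = list(), atoms = atoms), "B")
})

test_that("graph export produces GraphML and the supplementary TSV", {
  net <- plantedNet(3)
  g <- net$graphs$B
  gm <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  writeGraph(g, graphml = gm, tsv = tsv)
  back <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(graphNodes(g)))
  expect_equal(igraph::ecount(back), nrow(graphEdges(g)))
  tab <- read.delim(tsv)
  expect_true(all(c("protein_a", "component_a", "protein_b", "component_b",
                    "status_pair", "contact_type") %in% names(tab)))
})
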