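test_that("universal core of identical graphs is the graph itself", {
  net <- plantedNet(3)
  g <- net$graphs$B
  core <- universalCore(list(A = g, B = g, E = g))
  ed <- graphEdges(g, includeExcluded = FALSE)
  expect_equal(core$n_edges, nrow(ed))
  expect_setequal(core$edges, paste(pmin(ed$node_a, ed$node_b),
                                    pmax(ed$node_a, ed$node_b), sep = "|"))
})

test_that("disjoint graphs have an empty core and arguments commute", {
  ctRow <- function(pa, pb) data.frame(
    protein_a = pa, component_a = "G", component_kind_a = "G", status_a = "U",
    protein_b = pb, component_b = "G", component_kind_b = "G", status_b = "U",
    stringsAsFactors = FALSE)
  nd <- data.frame(node_id = c("uS2", "uS3", "uS4", "uS5"),
                   x = 1:4, y = 0, z = 0)
  g1 <- graphFromTable(ctRow("uS2", "uS3"), nd, "A")
  g2 <- graphFromTable(ctRow("uS3", "uS4"), nd, "B")
  g3 <- graphFromTable(ctRow("uS4", "uS5"), nd, "E")
  expect_equal(universalCore(list(A = g1, B = g2, E = g3))$n_edges, 0L)

  net <- plantedNet(4)
  c1 <- universalCore(net$graphs[c("A", "B", "E")])
  c2 <- universalCore(net$graphs[c("E", "A", "B")])
  expect_setequal(c1$edges, c2$edges)
  expect_error(universalCore(net$graphs[c("A", "B")]), "three")
  # core is contained in each kingdom's edge set
  for (k in c("A", "B", "E")) {
    ed <- graphEdges(net$graphs[[k]], includeExcluded = FALSE)
    expect_true(all(c1$edges %in% paste(pmin(ed$node_a, ed$node_b),
                                        pmax(ed$node_a, ed$node_b),
                                        sep = "|")))
  }
})

test_that("a child identical to its parent adds nothing", {
  net <- plantedNet(3)
  ts <- transitionStats(net$graphs$B, net$graphs$B, "ABE_to_B")
  expect_equal(ts$n_new_contacts, 0L)
  expect_equal(ts$n_new_edges, 0L)
  expect_equal(length(ts$status_pair_fractions), 0L)
})

test_that("planted status-pair proportions are recovered exactly", {
  net <- plantedNet(8)
  ts <- transitionStats(net$graphs$ABE, net$graphs$B, "ABE_to_B")
  f <- ts$status_pair_fractions
  expect_equal(unname(f[["U-B"]]), 0.58)
  expect_equal(unname(f[["B-B"]]), 0.19)
  expect_equal(unname(f[["Ub-U"]]), 0.12)
  expect_equal(unname(f[["Ub-B"]]), 0.09)
  expect_equal(unname(f[["U-U"]]), 0.02)
  expect_equal(sum(unclass(f)), 1, tolerance = 0.005)
  expect_equal(ts$n_new_proteins, 18L)
  # coevolved pairs: both endpoints acquired at this transition
  expect_equal(nrow(ts$coevolved),
               unname(net$truth$coevolved_counts["B"]))
  expect_true(all(ts$coevolved$status_a %in% c("B", "Ub") &
                  ts$coevolved$status_b %in% c("B", "Ub")))
})

test_that("archaeal and eukaryotic transitions recover their plants", {
  net <- plantedNet(9)
  tsA <- transitionStats(net$graphs$ABE, net$graphs$A, "ABE_to_A")
  f <- tsA$status_pair_fractions
  expect_equal(unname(f[["U-A"]]), 0.47)
  expect_equal(unname(f[["A-A"]]), 0.19)
  expect_equal(unname(f[["Ua-A"]]) + unname(f[["Ua-Ua"]]), 0.34)
  expect_equal(tsA$n_new_proteins, 26L)

  tsE <- transitionStats(net$graphs$A, net$graphs$E, "A_to_E")
  fe <- unclass(tsE$status_pair_fractions)
  extMediated <- sum(fe[grepl("Ue|Ae", names(fe))])
  expect_equal(extMediated, 0.57)
  expect_equal(tsE$n_new_proteins, 11L)
  expect_equal(nrow(tsE$coevolved), unname(net$truth$coevolved_counts["E"]))
})

test_that("functional-contact fractions match the planted design", {
  net <- plantedNet(10)
  g <- net$graphs
  expect_equal(functionalContactFraction(g$ABE), 22 / 49)
  expect_equal(functionalContactFraction(g$B, newOnly = TRUE,
                                         parent = g$ABE), 16 / 116)
  expect_equal(functionalContactFraction(g$A, newOnly = TRUE,
                                         parent = g$ABE), 4 / 104)
  expect_equal(functionalContactFraction(g$E, newOnly = TRUE,
                                         parent = g$A), 2 / 102)
  # a graph without functional sites scores zero
  ct <- data.frame(protein_a = "uS2", component_a = "G",
                   component_kind_a = "G", status_a = "U",
                   protein_b = "uS3", component_b = "G",
                   component_kind_b = "G", status_b = "U",
                   stringsAsFactors = FALSE)
  nd <- data.frame(node_id = c("uS2", "uS3"), x = 0:1, y = 0, z = 0)
  expect_equal(functionalContactFraction(graphFromTable(ct, nd, "B")), 0)
})

test_that("COM distances of new edges grow along the planted stages", {
  net <- plantedNet(12)
  tr <- distanceTrend(net$graphs[c("ABE", "B", "A", "E")])
  expect_equal(tr$mean_distance, unname(net$truth$stage_mean_distance),
               tolerance = 1e-9)
  expect_true(all(diff(tr$mean_distance) > 0))
  # coincident nodes give zero distances
  ct <- data.frame(protein_a = "uS2", component_a = "G",
                   component_kind_a = "G", status_a = "U",
                   protein_b = "uS3", component_b = "G",
                   component_kind_b = "G", status_b = "U",
                   stringsAsFactors = FALSE)
  nd <- data.frame(node_id = c("uS2", "uS3"), x = 0, y = 0, z = 0)
  g0 <- graphFromTable(ct, nd, "B")
  tr0 <- distanceTrend(list(only = g0))
  expect_equal(tr0$mean_distance, 0)
  expect_equal(nrow(tr0), 1L)
  # a stage adding no edges is flagged
  expect_warning(distanceTrend(list(a = g0, b = g0)), "no new edges")
})

test_that("multiplicity plants are recovered in the bacterial network", {
  net <- plantedNet(13)
  ed <- graphEdges(net$graphs$B)
  multi <- ed[ed$n_connections >= 2, ]
  keys <- paste(pmin(multi$node_a, multi$node_b),
                pmax(multi$node_a, multi$node_b), sep = "|")
  expect_setequal(keys, net$truth$multiplicity2_pairs_B)
  expect_true(all(multi$n_connections == 2L))
})
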