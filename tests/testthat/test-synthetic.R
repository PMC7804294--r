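test_that("toy complexes encode their planted contact truth", {
  apart <- makeToyComplex(tempfile("apart"), separation = 50)
  expect_false(apart$groundTruth$contact)
  touching <- makeToyComplex(tempfile("touch"), separation = 0)
  expect_true(touching$groundTruth$contact)
  expect_error(makeToyComplex(tempfile("bad"), separation = -5),
               "interpenetrate")
})

test_that("the same seed reproduces byte-identical structure files", {
  f1 <- makeToyComplex(tempfile("a"), separation = 1, jitter = 0.05, seed = 9)
  f2 <- makeToyComplex(tempfile("b"), separation = 1, jitter = 0.05, seed = 9)
  expect_identical(readLines(f1$pdb), readLines(f2$pdb))
  expect_identical(readLines(f1$cif), readLines(f2$cif))
  f3 <- makeToyComplex(tempfile("c"), separation = 1, jitter = 0.05, seed = 10)
  expect_false(identical(readLines(f1$pdb), readLines(f3$pdb)))
})

test_that("ER generator covers the degenerate and calibrated regimes", {
  n <- 7
  full <- makeErGraph(n, m = n * (n - 1) / 2, seed = 1)
  expect_equal(igraph::ecount(full), n * (n - 1) / 2)
  expect_true(all(igraph::degree(full) == n - 1))
  empty <- makeErGraph(n, m = 0, seed = 1)
  expect_equal(igraph::ecount(empty), 0)
  expect_error(makeErGraph(5, m = 11, seed = 1), "out of range")
  expect_error(makeErGraph(5, seed = 1), "exactly one")
  # G(n, p): mean edge count within a 4-sigma binomial window
  p <- 0.3; N <- 40
  counts <- vapply(1:200, function(i)
    igraph::ecount(makeErGraph(N, p = p, seed = i)), numeric(1))
  mu <- p * N * (N - 1) / 2
  sd4 <- 4 * sqrt(N * (N - 1) / 2 * p * (1 - p)) / sqrt(200)
  expect_lt(abs(mean(counts) - mu), sd4)
})

test_that("the annotated network generator is seed-deterministic", {
  n1 <- makeAnnotatedNetwork(tempfile("d1"), seed = 6)
  n2 <- makeAnnotatedNetwork(tempfile("d2"), seed = 6)
  expect_identical(readLines(n1$files$E$contacts),
                   readLines(n2$files$E$contacts))
  expect_identical(readLines(n1$files$B$nodes), readLines(n2$files$B$nodes))
  expect_identical(n1$truth, n2$truth)
  n3 <- makeAnnotatedNetwork(tempfile("d3"), seed = 60)
  expect_false(identical(readLines(n1$files$E$contacts),
                         readLines(n3$files$E$contacts)))
})

test_that("infeasible fraction/count combinations are rejected", {
  expect_error(makeAnnotatedNetwork(tempfile("x"), nNewB = 90),
               "infeasible")
  expect_error(makeAnnotatedNetwork(tempfile("x"), bFractions = c(
    "U-B" = 0.5, "B-B" = 0.3)), "sum to 1")
})

test_that("generated annotations validate and carry the planted sizes", {
  net <- plantedNet(3)
  for (k in c("ABE", "B", "A", "E")) {
    ann <- loadAnnotation(net$files[[k]]$annotation)
    expect_s4_class(ann, "ComponentAnnotation")
  }
  st <- extensionSizeStats(
    list(E = loadAnnotation(net$files$E$annotation)), threshold = 80)
  expect_equal(unname(st$fraction_gt), 0.10)
  stU <- extensionSizeStats(
    list(ABE = loadAnnotation(net$files$ABE$annotation)), threshold = 80,
    status = "U")
  expect_equal(unname(stU$fraction_gt), 0.01)
})

test_that("MSA generation is deterministic and validates lengths", {
  expect_error(makeMsa(tempfile("m"), length = 10), "cannot hold")
  m1 <- makeMsa(tempfile("m1"), seed = 4)
  m2 <- makeMsa(tempfile("m2"), seed = 4)
  expect_identical(readLines(m1$files$A), readLines(m2$files$A))
  expect_identical(readLines(m1$files$E), readLines(m2$files$E))
  # background columns stay unconserved at the default depth
  pE <- profileTable(conservationProfile(m1$files$E))
  planted <- sort(unlist(m1$truth[c("strict", "ancient_aromatic",
                                    "new_aromatic", "strengthened")]))
  expect_setequal(pE$column[pE$strict], planted)
})
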