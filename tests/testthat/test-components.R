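writeAnnTsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

baseAnn <- function() {
  data.frame(
    protein_id = c("uL4", "uL4", "uS3", "eL15"),
    chain = c("A", "A", "B", "C"),
    component_id = c("G", "loop1", "G", "ext1"),
    component_kind = c("globular", "extension", "globular", "extension"),
    category = c("", "loop", "", "mix"),
    terminus = c("", "internal", "", "C"),
    ranges = c("1-100", "101-140", "1-80", "10-95"),
    status = c("U", "Ua", "U", "Ae"),
    stringsAsFactors = FALSE)
}

test_that("a valid annotation parses with categories preserved", {
  ann <- loadAnnotation(writeAnnTsv(baseAnn()), kingdom = "E")
  expect_s4_class(ann, "ComponentAnnotation")
  cmp <- componentTable(ann)
  expect_equal(length(unique(cmp$protein_id)), 3L)
  expect_setequal(cmp$category[cmp$component_kind == "extension"],
                  c("loop", "mix"))
  expect_equal(cmp$length_aa[cmp$component_id == "loop1"], 40)
  expect_equal(kingdom(ann), "E")
})

test_that("invalid annotations are rejected with informative errors", {
  inv <- baseAnn(); inv$ranges[2] <- "140-101"
  expect_error(loadAnnotation(writeAnnTsv(inv), kingdom = "E"), "inverted")
  ov <- baseAnn(); ov$ranges[2] <- "90-140"
  expect_error(loadAnnotation(writeAnnTsv(ov), kingdom = "E"), "overlapping")
  badCat <- baseAnn(); badCat$category[2] <- "coil"
  expect_error(loadAnnotation(writeAnnTsv(badCat), kingdom = "E"),
               "category")
  badStat <- baseAnn()
  badStat$status[2] <- "Ae"  # an E-acquired archaeal extension on a U protein
  expect_error(loadAnnotation(writeAnnTsv(badStat), kingdom = "E"),
               "inconsistent")
})

test_that("annotated chains must exist in an attached structure", {
  tc <- makeToyComplex(tempfile("toy"), nChains = 2, chainLength = 10)
  atoms <- readStructure(tc$pdb)
  ann <- baseAnn()[3, ]
  ann$ranges <- "1-10"
  ann$chain <- "Q"
  expect_error(loadAnnotation(writeAnnTsv(ann), kingdom = "B",
                              structure = atoms), "Q")
})

test_that("centre of mass matches direct averaging and is equivariant", {
  m <- matrix(c(0, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE)
  expect_equal(unname(centerOfMass(m)), c(1, 0, 0), ignore_attr = TRUE)

  set.seed(7)
  pts <- matrix(rnorm(60), ncol = 3)
  com <- centerOfMass(pts)
  expect_equal(unname(com), colMeans(pts), ignore_attr = TRUE)
  for (k in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0,
                   sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    shift <- runif(3, -50, 50)
    moved <- sweep(pts %*% t(Rz), 2, shift, "+")
    expect_equal(unname(centerOfMass(moved)),
                 as.numeric(Rz %*% unname(com)) + shift,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(centerOfMass(pts[0, , drop = FALSE]), "empty")
})

test_that("proteins without a globular domain use all their atoms", {
  tc <- makeToyComplex(tempfile("toy"), nChains = 2, chainLength = 10)
  atoms <- readStructure(tc$pdb)
  ann <- data.frame(
    protein_id = c("uL4", "uL4", "bL36"),
    chain = c("A", "A", "B"),
    component_id = c("G", "ext1", "seg1"),
    component_kind = c("globular", "extension", "extension"),
    category = c("", "segment", "segment"),
    terminus = c("", "C", "N"),
    ranges = c("1-6", "7-10", "1-10"),
    status = c("U", "U", "B"), stringsAsFactors = FALSE)
  a <- loadAnnotation(writeAnnTsv(ann), kingdom = "B", structure = atoms)
  coms <- proteinCOMs(atoms, a)
  expect_equal(coms$selection[coms$protein_id == "uL4"], "globular")
  expect_equal(coms$selection[coms$protein_id == "bL36"], "whole_protein")
  sel <- atoms$chain == "A" & atoms$resno <= 6
  expect_equal(coms$x[coms$protein_id == "uL4"], mean(atoms$x[sel]))
  expect_equal(coms$x[coms$protein_id == "bL36"],
               mean(atoms$x[atoms$chain == "B"]))
})

test_that("extension size statistics count planted fractions exactly", {
  mk <- function(lengths, kingdom) {
    n <- length(lengths)
    df <- data.frame(
      protein_id = paste0("uL", seq_len(n)),
      chain = paste0("uL", seq_len(n)),
      component_id = "e1",
      component_kind = "extension",
      category = rep(c("segment", "loop", "helix"), length.out = n),
      terminus = "C",
      ranges = paste0("1-", lengths),
      status = "U", stringsAsFactors = FALSE)
    loadAnnotation(writeAnnTsv(df), kingdom = kingdom)
  }
  allShort <- mk(rep(10, 12), "B")
  expect_equal(unname(extensionSizeStats(allShort)$fraction_gt), 0)

  planted <- mk(c(rep(30, 27), 81, 100, 200), "E")  # 3 of 30 above 80
  st <- extensionSizeStats(planted, threshold = 80)
  expect_equal(unname(st$fraction_gt), 0.10)

  # invariance under row reordering
  tab <- componentTable(planted)
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  f <- writeAnnTsv(cbind(shuffled[, c("protein_id", "chain", "component_id",
                                      "component_kind", "category",
                                      "terminus", "ranges", "status")]))
  st2 <- extensionSizeStats(loadAnnotation(f, kingdom = "E"), threshold = 80)
  expect_equal(st2$fraction_gt, st$fraction_gt)
})
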