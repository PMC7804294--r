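test_that("identical sequences give fully strict profiles", {
  p <- conservationProfile(rep("ACDEFGHIKL", 10))
  tab <- profileTable(p)
  expect_true(all(tab$strict))
  expect_true(all(tab$similar))
  expect_equal(tab$identity_fraction, rep(1, 10))
})

test_that("the 80% rule separates strict from class conservation", {
  # column: 7 F, 2 Y, 1 K over 10 sequences
  p <- conservationProfile(c(rep("F", 7), rep("Y", 2), "K"))
  tab <- profileTable(p)
  expect_equal(tab$identity_fraction, 0.7)
  expect_false(tab$strict)
  expect_equal(tab$class_fraction, 0.9)
  expect_equal(tab$consensus_class, "aromatic")
  expect_true(tab$similar)
  # exactly at threshold is NOT conserved ("more than 80%")
  pEq <- conservationProfile(c(rep("A", 8), "C", "D"))
  expect_false(profileTable(pEq)$strict)
})

test_that("gaps count in the denominator and all-gap columns are flagged", {
  p <- conservationProfile(c(rep("F-", 5), rep("FF", 5)))
  tab <- profileTable(p)
  expect_true(tab$strict[1])
  expect_false(tab$strict[2])   # 50% gapped
  expect_false(tab$similar[2])
  pg <- conservationProfile(rep("-A", 4))
  expect_true(profileTable(pg)$all_gap[1])
  expect_false(profileTable(pg)$strict[1])
})

test_that("ragged alignments and singleton inputs are rejected", {
  expect_error(conservationProfile(c("ACD", "AC")), "ragged")
  expect_error(conservationProfile("ACD"), "two")
})

test_that("profiles are invariant to order and duplication of sequences", {
  seqs <- c("FYKA", "FYKC", "FWKA", "LYKA", "FYRA")
  p1 <- profileTable(conservationProfile(seqs))
  p2 <- profileTable(conservationProfile(rev(seqs)))
  expect_equal(p1, p2)
  p3 <- profileTable(conservationProfile(rep(seqs, 3)))
  expect_equal(p1$identity_fraction, p3$identity_fraction)
  expect_equal(p1$class_fraction, p3$class_fraction)
})

test_that("planted MSA columns are recovered exactly", {
  m <- makeMsa(tempfile("msa"), seed = 21)
  pA <- conservationProfile(m$files$A)
  pE <- conservationProfile(m$files$E)
  tA <- profileTable(pA); tE <- profileTable(pE)
  plantedBoth <- sort(c(m$truth$strict, m$truth$ancient_aromatic))
  expect_setequal(tA$column[tA$strict], plantedBoth)
  expect_setequal(tE$column[tE$strict],
                  sort(c(plantedBoth, m$truth$new_aromatic,
                         m$truth$strengthened)))
  # strengthened columns are similar-but-not-strict in archaea
  expect_true(all(tA$similar[m$truth$strengthened]))
  expect_false(any(tA$strict[m$truth$strengthened]))
})

test_that("aromatic acquisitions classify new, ancient and strengthened", {
  m <- makeMsa(tempfile("msa"), seed = 22)
  pA <- conservationProfile(m$files$A)
  pE <- conservationProfile(m$files$E)
  ar <- aromaticAcquisitions(pA, pE, m$truth$map,
                             interfacesE = m$truth$new_aromatic[1:3])
  expect_setequal(ar$column_E[ar$status == "new_in_E"], m$truth$new_aromatic)
  expect_setequal(ar$column_E[ar$status == "ancient"],
                  m$truth$ancient_aromatic)
  expect_setequal(ar$column_E[ar$status == "strengthened_similar_to_strict"],
                  m$truth$strengthened)
  expect_setequal(ar$column_E[ar$at_new_interface],
                  m$truth$new_aromatic[1:3])
  # identical profiles: nothing is new
  none <- aromaticAcquisitions(pE, pE, m$truth$map)
  expect_false(any(none$status == "new_in_E"))
})

test_that("interface conservation maps residues onto profile columns", {
  profiles <- list(
    # columns 1-2 are 90% F (strict); 3-5 cycle five residues (nothing
    # above 20%)
    P1 = conservationProfile(paste0(
      c(rep("FF", 9), "YL"),
      rep(c("ACD", "CDK", "DKL", "KLA", "LAC"), 2))),
    # 60% K / 40% R per column: basic class similar, never strict
    P2 = conservationProfile(c(rep("KKKKK", 6), rep("RRRRR", 4))))
  seqMap <- data.frame(
    reskey = c(paste0("A:", 1:5), paste0("B:", 1:5)),
    protein_id = rep(c("P1", "P2"), each = 5),
    column = rep(1:5, 2), stringsAsFactors = FALSE)
  contact <- list(
    residues_a = data.frame(reskey = paste0("A:", 1:5), dsasa = 1),
    residues_b = data.frame(reskey = paste0("B:", 1:2), dsasa = 1))
  res <- interfaceConservation(contact, profiles, seqMap)
  # P1: columns 1-2 strict, 3-5 not; P2: all columns basic class only
  expect_equal(res$frac_strict[res$side == "a"], 2 / 5)
  expect_equal(res$frac_strict[res$side == "b"], 0)
  expect_equal(res$frac_similar[res$side == "b"], 1)
  expect_equal(res$n_mapped[res$side == "combined"], 7)
  # unmapped residues are excluded with a warning
  contact$residues_b <- data.frame(reskey = c("B:1", "B:99"), dsasa = 1)
  expect_warning(res2 <- interfaceConservation(contact, profiles, seqMap),
                 "unmapped")
  expect_equal(res2$n_mapped[res2$side == "b"], 1)
})

test_that("interface conservation rises as columns flip to conserved", {
  mkProf <- function(nCons) {
    seqs <- vapply(seq_len(10), function(i) {
      row <- c(rep("F", nCons), sample(c("A", "C", "D", "K", "L"),
                                       5 - nCons, replace = TRUE))
      paste(row, collapse = "")
    }, character(1))
    # column j conserved iff j <= nCons (others scrambled per sequence)
    conservationProfile(seqs)
  }
  set.seed(1)
  seqMap <- data.frame(reskey = paste0("A:", 1:5), protein_id = "P",
                       column = 1:5, stringsAsFactors = FALSE)
  contact <- list(residues_a = data.frame(reskey = paste0("A:", 1:5),
                                          dsasa = 1),
                  residues_b = data.frame(reskey = character(0),
                                          dsasa = numeric(0)))
  fr <- vapply(0:5, function(k) {
    res <- interfaceConservation(contact, list(P = mkProf(k)), seqMap)
    res$frac_strict[res$side == "a"]
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[1], 0)
  expect_equal(fr[6], 1)
})

test_that("pi interactions are classified by constructed geometry", {
  phe <- ringAtoms("A", 1, "PHE", cx = 0)
  # second ring 5.0 A away: pi-pi
  phe2 <- ringAtoms("A", 5, "PHE", cx = 5)
  # Arg guanidinium carbon 4.5 A above the first ring: cation-pi
  arg <- atomRow("B", 9, "CZ", 0, 0, 4.5, resid = "ARG", element = "C")
  # Glu carboxylate carbon 5.0 A: anion-pi
  glu <- atomRow("A", 12, "CD", 0, 0, -5.0, resid = "GLU", element = "C")
  pi <- classifyPiInteractions(rbind(phe, phe2, arg, glu))
  cls <- setNames(pi$interaction_class, pi$partner)
  expect_equal(unname(cls[["B:9"]]), "cation_pi")
  expect_equal(pi$distance[pi$partner == "B:9"], 4.5)
  expect_equal(unname(cls[["A:12"]]), "anion_pi")
  pp <- pi[pi$interaction_class == "pi_pi", ]
  expect_equal(nrow(pp), 1L)  # reported once per pair
  expect_equal(pp$distance, 5)
  expect_true(pp$intra_molecular)
  expect_false(pi$intra_molecular[pi$partner == "B:9"])
})

test_that("lonely aromatics and incomplete rings are handled", {
  lone <- ringAtoms("A", 1, "TRP")
  lone$resid <- "TRP"  # incomplete: TRP needs 9 ring atoms
  expect_warning(res <- classifyPiInteractions(lone), "incomplete")
  expect_equal(nrow(res), 0L)
  solo <- ringAtoms("A", 1, "PHE")
  far <- atomRow("B", 2, "NZ", 50, 0, 0, resid = "LYS", element = "N")
  expect_equal(nrow(classifyPiInteractions(rbind(solo, far))), 0L)
})
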