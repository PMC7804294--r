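.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a paired synthetic alignment (archaea / eukarya)
#'
#' Builds two aligned FASTA files for one protein family, with planted
#' conservation signal and an explicit cross-kingdom column map:
#' \itemize{
#'   \item `strict` columns: the same non-aromatic residue strictly
#'     conserved in both kingdoms (planted at > threshold identity);
#'   \item `ancient_aromatic` columns: an aromatic residue strictly
#'     conserved in both kingdoms;
#'   \item `new_aromatic` columns: an aromatic strictly conserved in the
#'     eukaryotic alignment only (background in archaea);
#'   \item `strengthened` columns: aromatic-class (mixed F/Y) conserved
#'     in archaea, a single aromatic strictly conserved in eukarya.
#' }
#' All other columns draw residues uniformly, so with the default depth
#' the probability that a background column exceeds an 80% identity or
#' class threshold is negligible (binomial tail below 1e-15 per column).
#' Gap characters are planted only in background columns.
#'
#' @param prefix Output prefix; writes `<prefix>_A.fasta`,
#'   `<prefix>_E.fasta`, `<prefix>_map.tsv`.
#' @param seed Integer seed (same seed, byte-identical FASTA).
#' @param nSeqs Sequences per kingdom alignment.
#' @param length Alignment length (columns); must hold all planted
#'   columns or an error is raised.
#' @param nStrict,nAncientAromatic,nNewAromatic,nStrengthened Numbers of
#'   planted columns per class.
#' @param conservedFraction Fraction of sequences carrying the planted
#'   consensus in a conserved column (> 0.8 by default).
#' @param gapRate Per-cell gap probability in background columns.
#' @return List with `files`, and `truth` (planted column indices per
#'   class, identical numbering in both kingdoms plus the column map).
#' @export
makeMsa <- function(prefix, seed = 1, nSeqs = 60, length = 120,
                    nStrict = 8, nAncientAromatic = 5, nNewAromatic = 12,
                    nStrengthened = 6, conservedFraction = 0.9,
                    gapRate = 0.02) {
  nPlanted <- nStrict + nAncientAromatic + nNewAromatic + nStrengthened
  .assert(length >= nPlanted,
          "alignment length ", length, " cannot hold ", nPlanted,
          " planted columns")
  .assert(conservedFraction > 0.8 && conservedFraction <= 1,
          "conservedFraction must exceed the 0.8 rule to plant conservation")

  cols <- seq_len(nPlanted)
  idx <- list(
    strict = cols[seq_len(nStrict)],
    ancient_aromatic = cols[nStrict + seq_len(nAncientAromatic)],
    new_aromatic = cols[nStrict + nAncientAromatic + seq_len(nNewAromatic)],
    strengthened = cols[nStrict + nAncientAromatic + nNewAromatic +
                          seq_len(nStrengthened)]
  )
  # Spread planted columns over the alignment deterministically.
  slots <- round(seq(1, length, length.out = nPlanted))
  idx <- lapply(idx, function(i) slots[i])

  nCons <- ceiling(conservedFraction * nSeqs)
  aromatic <- c("F", "Y", "W")
  nonAromatic <- setdiff(.AA20, c(aromatic, "H"))

  A <- E <- NULL
  .withSeed(seed, {
    A <- matrix(sample(.AA20, nSeqs * length, replace = TRUE), nSeqs, length)
    E <- matrix(sample(.AA20, nSeqs * length, replace = TRUE), nSeqs, length)
    planted <- unlist(idx)
    bg <- setdiff(seq_len(length), planted)
    for (M in c("A", "E")) {
      mat <- get(M)
      gaps <- matrix(stats::runif(nSeqs * base::length(bg)) < gapRate,
                     nSeqs, base::length(bg))
      mat[, bg][gaps] <- "-"
      assign(M, mat)
    }
    plantCol <- function(mat, col, residue) {
      rows <- sample(nSeqs, nCons)
      mat[, col] <- sample(setdiff(.AA20, residue), nSeqs, replace = TRUE)
      mat[rows, col] <- residue
      mat
    }
    for (k in seq_along(idx$strict)) {
      res <- nonAromatic[(k - 1) %% base::length(nonAromatic) + 1]
      A <- plantCol(A, idx$strict[k], res)
      E <- plantCol(E, idx$strict[k], res)
    }
    for (k in seq_along(idx$ancient_aromatic)) {
      res <- aromatic[(k - 1) %% 3 + 1]
      A <- plantCol(A, idx$ancient_aromatic[k], res)
      E <- plantCol(E, idx$ancient_aromatic[k], res)
    }
    for (k in seq_along(idx$new_aromatic)) {
      res <- aromatic[(k - 1) %% 3 + 1]
      E <- plantCol(E, idx$new_aromatic[k], res)
    }
    for (k in seq_along(idx$strengthened)) {
      # Archaea: aromatic class above threshold, no single residue above
      # it (half F, half Y among the conserved rows).
      col <- idx$strengthened[k]
      rows <- sample(nSeqs, nCons)
      half <- seq_len(floor(nCons / 2))
      A[, col] <- sample(nonAromatic, nSeqs, replace = TRUE)
      A[rows[half], col] <- "F"
      A[rows[-half], col] <- "Y"
      E <- plantCol(E, col, "F")
    }
  })

  toFasta <- function(mat, kingdom) {
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- sprintf("%s_seq%03d", kingdom, seq_along(seqs))
    Biostrings::AAStringSet(seqs)
  }
  files <- list(A = paste0(prefix, "_A.fasta"), E = paste0(prefix, "_E.fasta"),
                map = paste0(prefix, "_map.tsv"))
  Biostrings::writeXStringSet(toFasta(A, "A"), files$A)
  Biostrings::writeXStringSet(toFasta(E, "E"), files$E)
  map <- data.frame(column_A = seq_len(length), column_E = seq_len(length))
  utils::write.table(map, files$map, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(files = files,
       truth = c(idx, list(map = map, n_sequences = nSeqs,
                           conserved_fraction = conservedFraction)))
}
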