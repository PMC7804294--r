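# Independent oracles and small builders used across the suite.

# Minimal atom-table builder.
atomRow <- function(chain, resno, elety, x, y, z, resid = "ALA",
                    element = substr(elety, 1, 1), radius = NULL) {
  r <- if (is.null(radius)) unname(vdwRadius(element)) else radius
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, element = element, x = x, y = y, z = z,
             radius = r, reskey = paste0(chain, ":", resno),
             stringsAsFactors = FALSE)
}

# Monte Carlo SASA oracle: random (not quadrature) directions, shared
# across atoms, brute-force neighbour exclusion. Independent of the
# package's golden-spiral implementation.
mcSasaOracle <- function(atoms, probe = 1.4, nPoints = 1e5, seed = 42) {
  set.seed(seed)
  u <- matrix(stats::rnorm(nPoints * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- atoms$radius + probe
  total <- 0
  perAtom <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    p <- sweep(u * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in seq_len(nrow(atoms))) {
      if (j == i) next
      d2c <- sum((xyz[i, ] - xyz[j, ])^2)
      if (d2c >= (R[i] + R[j])^2) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > R[j]^2
    }
    perAtom[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  list(perAtom = perAtom, total = sum(perAtom))
}

# Buried-area oracle for a two-chain complex via the MC SASA oracle.
mcBuriedOracle <- function(atoms, chainA, chainB, probe = 1.4,
                           nPoints = 1e5, seed = 42) {
  A <- atoms[atoms$chain == chainA, , drop = FALSE]
  B <- atoms[atoms$chain == chainB, , drop = FALSE]
  sA <- mcSasaOracle(A, probe, nPoints, seed)$total
  sB <- mcSasaOracle(B, probe, nPoints, seed)$total
  sAB <- mcSasaOracle(rbind(A, B), probe, nPoints, seed)$total
  sA + sB - sAB
}

# Exhaustive betweenness oracle: enumerate every shortest path of every
# node pair by depth-first descent over a BFS distance field. Normalised
# like igraph: divide by (n-1)(n-2)/2 for undirected graphs.
bcOracle <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(i)
    as.integer(igraph::neighbors(g, i)))
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
      frontier <- unique(nxt)
    }
    for (t in (s + 1):n) {
      if (is.na(dist[t])) next
      paths <- list()
      descend <- function(v, acc) {
        if (v == s) {
          paths[[length(paths) + 1L]] <<- acc
          return(invisible(NULL))
        }
        for (w in adj[[v]]) {
          if (!is.na(dist[w]) && dist[w] == dist[v] - 1L) descend(w, c(acc, w))
        }
      }
      descend(t, integer(0))
      sigma <- length(paths)
      if (sigma == 0) next
      inner <- unlist(lapply(paths, function(p) setdiff(p, c(s, t))))
      if (length(inner)) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        bc[idx] <- bc[idx] + as.numeric(tab) / sigma
      }
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2) / 2) else bc
}

# Idealised aromatic ring for pi-interaction fixtures.
ringAtoms <- function(chain, resno, resid = "PHE", cx = 0, cy = 0, cz = 0) {
  names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  do.call(rbind, lapply(seq_along(names), function(i)
    atomRow(chain, resno, names[i], cx + 1.4 * cos(th[i]),
            cy + 1.4 * sin(th[i]), cz, resid = resid, element = "C")))
}

# A small planted kingdom-network fixture shared by several files.
plantedNet <- function(seed = 11) {
  makeAnnotatedNetwork(file.path(tempdir(), paste0("net", seed)), seed = seed)
}
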