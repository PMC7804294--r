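#' Deterministic sphere quadrature points
#'
#' Golden-spiral (Fibonacci lattice) points on the unit sphere. The
#' construction is fully deterministic, so SASA values are machine-stable
#' for a fixed number of points.
#'
#' @param n Number of points (>= 1).
#' @return An `n x 3` matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  .assert(n >= 1, "need at least one sphere point")
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a rolling probe: each atom is inflated to radius
#' vdW + probe, test points are placed on the inflated sphere with a
#' deterministic golden-spiral quadrature, and the accessible fraction is
#' the fraction of points outside every neighbouring inflated sphere.
#' Identical overlapping atoms are computed normally (they simply shadow
#' each other, possibly to zero exposed area).
#'
#' @param atoms Atom table from [readStructure()] (needs `x`, `y`, `z`,
#'   `radius`, `chain`, `reskey`).
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param nPoints Quadrature points per atom (>= 100; default 960).
#' @return A list of class `SasaResult`: `perAtom` (numeric vector, A^2),
#'   `perResidue` (`data.frame` with `chain`, `reskey`, `area`), `total`,
#'   `probe`, `nPoints`.
#' @examples
#' a <- data.frame(chain = "A", resno = 1, insert = "", resid = "ALA",
#'                 elety = "C", element = "C", x = 0, y = 0, z = 0,
#'                 radius = 1.7, reskey = "A:1")
#' computeSasa(a, probe = 1.4)$total  # 4*pi*(1.7+1.4)^2
#' @export
computeSasa <- function(atoms, probe = 1.4, nPoints = 960) {
  .assert(probe >= 0, "probe radius must be >= 0")
  .assert(nPoints >= 100, "nPoints must be >= 100 for a stable quadrature")
  .assert(nrow(atoms) > 0, "empty atom set")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  R <- atoms$radius + probe
  .assert(all(R > probe | probe == 0), "all vdW radii must be positive")

  pts <- spherePoints(nPoints)
  n <- nrow(xyz)
  areas <- numeric(n)
  nb <- .neighborLists(xyz, R)
  for (i in seq_len(n)) {
    Ri <- R[i]
    js <- nb[[i]]
    if (length(js) == 0L) {
      areas[i] <- 4 * pi * Ri^2
      next
    }
    p <- pts * Ri
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in js) {
      if (!any(acc)) break
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      # inclusive boundary: a point exactly on a neighbour's surface is
      # buried, so coincident duplicate atoms contribute zero area
      acc <- acc & d2 > R[j]^2 + 1e-8
    }
    areas[i] <- 4 * pi * Ri^2 * sum(acc) / nPoints
  }

  perRes <- stats::aggregate(areas,
                             by = list(chain = atoms$chain, reskey = atoms$reskey),
                             FUN = sum)
  names(perRes)[3] <- "area"
  structure(
    list(perAtom = areas,
         perResidue = perRes[order(perRes$chain, perRes$reskey), ],
         total = sum(areas), probe = probe, nPoints = nPoints),
    class = "SasaResult"
  )
}

#' @export
print.SasaResult <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.2f A, %d points/atom)\n",
              x$total, length(x$perAtom), x$probe, x$nPoints))
  invisible(x)
}

# Neighbour lists: j is a neighbour of i iff their inflated spheres
# intersect. Computed blockwise to bound memory on large structures.
.neighborLists <- function(xyz, R) {
  n <- nrow(xyz)
  out <- vector("list", n)
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    idx <- s:e
    d2 <- outer(xyz[idx, 1], xyz[, 1], "-")^2 +
      outer(xyz[idx, 2], xyz[, 2], "-")^2 +
      outer(xyz[idx, 3], xyz[, 3], "-")^2
    lim <- outer(R[idx], R, "+")^2
    hits <- d2 < lim
    for (k in seq_along(idx)) {
      i <- idx[k]
      js <- which(hits[k, ])
      out[[i]] <- js[js != i]
    }
  }
  out
}
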