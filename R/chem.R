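#' Perceive covalent bonds from geometry
#'
#' Atoms i and j are bonded iff d_ij < tolerance * (r_cov(i) + r_cov(j)),
#' using the bundled covalent-radius table.  Designed for equilibrium-like
#' monomer geometries of small organics.
#'
#' @param mon A `monomer`.
#' @param tolerance Radius-sum scale factor; default 1.2.
#' @return The monomer with a `bonds` two-column index matrix (i < j).
#' @export
perceive_bonds <- function(mon, tolerance = 1.2) {
  stopifnot(inherits(mon, "monomer"))
  n <- length(mon$element)
  d <- as.matrix(stats::dist(mon$xyz))
  if (n > 1L) {
    mind <- min(d[upper.tri(d)])
    if (mind < 0.4) {
      stop(sprintf("degenerate geometry: atoms %.3f Angstrom apart", mind))
    }
  }
  rc <- COVALENT_RADII[mon$element]
  cutoff <- tolerance * outer(rc, rc, `+`)
  bonded <- d < cutoff & upper.tri(d)
  idx <- which(bonded, arr.ind = TRUE)
  mon$bonds <- matrix(as.integer(idx), ncol = 2,
                      dimnames = list(NULL, c("i", "j")))
  mon
}

#' Assign atom-species labels
#'
#' Heavy atoms get element + total bonded-neighbour count (C4/C3/C2,
#' N3/N2/N1, O2/O1, S2/S1); hydrogens get H + attached heavy element
#' (HC/HN/HO/HS); halogens are typed by element alone.  Any
#' (element, neighbour-count) combination outside the 17-label vocabulary
#' is a typing error.
#'
#' @param mon A `monomer` with perceived bonds.
#' @return The monomer with a `species` character vector.
#' @export
assign_atom_types <- function(mon) {
  stopifnot(inherits(mon, "monomer"))
  if (is.null(mon$bonds)) stop("perceive bonds before typing")
  n <- length(mon$element)
  deg <- integer(n)
  nbrs <- vector("list", n)
  if (nrow(mon$bonds) > 0) {
    for (k in seq_len(nrow(mon$bonds))) {
      i <- mon$bonds[k, 1]; j <- mon$bonds[k, 2]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  vocab <- species_vocabulary()
  sp <- character(n)
  for (i in seq_len(n)) {
    el <- mon$element[i]
    if (el %in% c("F", "Cl", "Br")) {
      sp[i] <- el
    } else if (el == "H") {
      if (deg[i] != 1L) {
        stop(sprintf("atom %d (H): %d bonded neighbours, expected exactly 1",
                     i, deg[i]))
      }
      heavy <- mon$element[nbrs[[i]][1]]
      sp[i] <- paste0("H", heavy)
    } else {
      sp[i] <- paste0(el, deg[i])
    }
    if (!(sp[i] %in% vocab)) {
      stop(sprintf("atom %d (%s, %d neighbours): species '%s' outside vocabulary",
                   i, el, deg[i], sp[i]))
    }
  }
  mon$species <- sp
  mon
}

#' Build a dimer from two typed monomers
#'
#' @param monomer_a,monomer_b Typed `monomer` objects.
#' @param id Dimer identifier string.
#' @return Object of class `dimer`.
#' @export
build_dimer <- function(monomer_a, monomer_b, id = "dimer") {
  stopifnot(inherits(monomer_a, "monomer"), inherits(monomer_b, "monomer"))
  if (is.null(monomer_a$species) || is.null(monomer_b$species)) {
    stop("both monomers must be typed (assign_atom_types) before dimer build")
  }
  dmin <- min(intermolecular_distances(monomer_a$xyz, monomer_b$xyz))
  if (dmin < 0.4) {
    stop(sprintf("monomers clash: closest intermolecular contact %.3f Angstrom",
                 dmin))
  }
  structure(list(monomer_a = monomer_a, monomer_b = monomer_b, id = id),
            class = "dimer")
}

#' @export
print.dimer <- function(x, ...) {
  cat(sprintf("dimer '%s': %d + %d atoms\n", x$id,
              length(x$monomer_a$element), length(x$monomer_b$element)))
  invisible(x)
}

# All intermolecular distances (Angstrom), nA x nB matrix.
intermolecular_distances <- function(xyz_a, xyz_b) {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  dx <- outer(xyz_a[, 1], xyz_b[, 1], `-`)
  dy <- outer(xyz_a[, 2], xyz_b[, 2], `-`)
  dz <- outer(xyz_a[, 3], xyz_b[, 3], `-`)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Swap the two monomers of a dimer
#'
#' Utility for symmetry checks; all component energies must be invariant
#' under this relabelling.
#'
#' @param dim A `dimer`.
#' @return The dimer with monomers A and B exchanged.
#' @export
swap_dimer <- function(dim) {
  build_dimer(dim$monomer_b, dim$monomer_a, id = dim$id)
}
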