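#' Construct per-atom property records
#'
#' The atoms-in-molecules quantities the energy model consumes, in atomic
#' units: multipole monopole q (e), dipole mu (e bohr), traceless symmetric
#' quadrupole theta (e bohr^2), effective nuclear charge Z (e) entering the
#' electrostatic nuclear terms, atomic width sigma (bohr), and Hirshfeld
#' ratio h (dimensionless).  The convention is that Z_i + q_i equals the
#' net atomic charge, so the four charge-charge terms of the electrostatic
#' model reduce to net-charge Coulomb interaction at long range.
#'
#' @param element Character vector of element symbols.
#' @param q Numeric vector, multipole monopoles (e).
#' @param mu n x 3 matrix, atomic dipoles (e bohr).
#' @param theta 3 x 3 x n array of traceless symmetric quadrupoles
#'   (e bohr^2).
#' @param Z Numeric vector, effective nuclear charges (e).
#' @param sigma Numeric vector, atomic widths (bohr), > 0.
#' @param h Numeric vector, Hirshfeld ratios, > 0.
#' @return Object of class `atomic_properties`.
#' @export
atomic_properties <- function(element, q, mu, theta, Z, sigma, h) {
  n <- length(element)
  mu <- matrix(as.numeric(mu), ncol = 3)
  if (length(q) != n || nrow(mu) != n || length(Z) != n ||
      length(sigma) != n || length(h) != n ||
      !identical(dim(theta), c(3L, 3L, n))) {
    stop("property record count mismatch")
  }
  if (!all(is.finite(q), is.finite(mu), is.finite(theta),
           is.finite(Z), is.finite(sigma), is.finite(h))) {
    stop("non-finite atomic property")
  }
  if (any(sigma <= 0)) stop("atomic width sigma must be > 0")
  if (any(h <= 0)) stop("Hirshfeld ratio h must be > 0")
  for (i in seq_len(n)) {
    th <- theta[, , i]
    if (max(abs(th - t(th))) > 1e-10) stop("quadrupole not symmetric")
    if (abs(sum(diag(th))) > 1e-10) stop("quadrupole not traceless")
  }
  structure(list(element = as.character(element), q = as.numeric(q), mu = mu,
                 theta = theta, Z = as.numeric(Z), sigma = as.numeric(sigma),
                 h = as.numeric(h)),
            class = "atomic_properties")
}

#' @export
print.atomic_properties <- function(x, ...) {
  cat(sprintf("atomic_properties: %d atoms (%s)\n",
              length(x$element), paste(x$element, collapse = " ")))
  invisible(x)
}

# Concatenate property records (monomer A then monomer B of a dimer).
c_properties <- function(pa, pb) {
  atomic_properties(
    element = c(pa$element, pb$element),
    q = c(pa$q, pb$q),
    mu = rbind(pa$mu, pb$mu),
    theta = array(c(pa$theta, pb$theta),
                  dim = c(3, 3, length(pa$element) + length(pb$element))),
    Z = c(pa$Z, pb$Z),
    sigma = c(pa$sigma, pb$sigma),
    h = c(pa$h, pb$h)
  )
}

# Subset property records by atom index.
subset_properties <- function(p, idx) {
  atomic_properties(
    element = p$element[idx], q = p$q[idx],
    mu = p$mu[idx, , drop = FALSE],
    theta = p$theta[, , idx, drop = FALSE],
    Z = p$Z[idx], sigma = p$sigma[idx], h = p$h[idx]
  )
}

#' Write per-atom properties to a text file
#'
#' Plain-text format: a header line declaring units (`units=au`), then one
#' record per atom:
#' `element q mux muy muz txx txy txz tyy tyz tzz Z sigma h`.
#'
#' @param props An `atomic_properties` object.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_properties <- function(props, file) {
  n <- length(props$element)
  rows <- vapply(seq_len(n), function(i) {
    th <- props$theta[, , i]
    paste(c(props$element[i],
            sprintf("%.12g", c(props$q[i], props$mu[i, ],
                               th[1, 1], th[1, 2], th[1, 3],
                               th[2, 2], th[2, 3], th[3, 3],
                               props$Z[i], props$sigma[i], props$h[i]))),
          collapse = " ")
  }, character(1))
  writeLines(c("units=au", rows), file)
  invisible(file)
}

#' Read per-atom properties from a text file
#'
#' Accepts the format written by [write_properties()].  A header of
#' `units=angstrom` declares dipole/quadrupole length units in Angstrom
#' (and sigma in Angstrom); these are converted to bohr on read.
#'
#' @param file Path.
#' @param n_expected Optional expected record count (e.g. the matching
#'   monomer's atom count); mismatch is an error.
#' @return An `atomic_properties` object (atomic units).
#' @export
read_properties <- function(file, n_expected = NULL) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("property file too short")
  hdr <- trimws(lines[1])
  if (!grepl("^units=", hdr)) stop("property file must start with a units= header")
  units <- sub("^units=", "", hdr)
  if (!units %in% c("au", "angstrom")) stop("unknown units declaration: ", units)
  len <- if (units == "angstrom") sapt_units[["bohr_per_angstrom"]] else 1

  rec <- lines[-1]
  n <- length(rec)
  if (!is.null(n_expected) && n != n_expected) {
    stop(sprintf("property file has %d records, geometry has %d atoms",
                 n, n_expected))
  }
  el <- character(n); num <- matrix(NA_real_, n, 13)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(rec[i]), "\\s+")[[1]]
    if (length(tok) != 14L) {
      stop(sprintf("property record %d: expected 14 fields, got %d", i, length(tok)))
    }
    el[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(v)) stop(sprintf("property record %d: non-numeric field", i))
    num[i, ] <- v
  }
  theta <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) {
    txx <- num[i, 5]; txy <- num[i, 6]; txz <- num[i, 7]
    tyy <- num[i, 8]; tyz <- num[i, 9]; tzz <- num[i, 10]
    theta[, , i] <- matrix(c(txx, txy, txz, txy, tyy, tyz, txz, tyz, tzz), 3, 3) *
      len^2
  }
  atomic_properties(
    element = el,
    q = num[, 1],
    mu = num[, 2:4] * len,
    theta = theta,
    Z = num[, 11],
    sigma = num[, 12] * len,
    h = num[, 13]
  )
}

#' Hirshfeld scaling of free-atom dispersion inputs
#'
#' Scales the free-atom C6 coefficient and polarizability by the
#' atom-in-molecule Hirshfeld ratio: C6 = C6_free h^2, alpha = alpha_free h.
#'
#' @param c6_free Free-atom C6 (hartree bohr^6), > 0.
#' @param alpha_free Free-atom polarizability (bohr^3), > 0.
#' @param h Hirshfeld ratio, > 0 (vectorized).
#' @return List with components `c6` and `alpha`.
#' @export
scale_dispersion_inputs <- function(c6_free, alpha_free, h) {
  if (any(h <= 0)) stop("Hirshfeld ratio h must be > 0")
  if (any(c6_free <= 0) || any(alpha_free <= 0)) {
    stop("free-atom constants must be > 0")
  }
  list(c6 = c6_free * h^2, alpha = alpha_free * h)
}

#' Effective dispersion charge Q
#'
#' Q = sqrt(Z_nuc) <r^4>/<r^2> from free-atom density moments; enters the
#' C8 combination rule.
#'
#' @param z_nuc Nuclear charge, > 0.
#' @param r2 Multipole expectation <r^2> (bohr^2), > 0.
#' @param r4 Multipole expectation <r^4> (bohr^4), > 0.
#' @return Q (bohr^2), > 0; vectorized.
#' @export
effective_q <- function(z_nuc, r2, r4) {
  if (any(z_nuc <= 0) || any(r2 <= 0) || any(r4 <= 0)) {
    stop("free-atom moments and nuclear charge must be > 0")
  }
  sqrt(z_nuc) * r4 / r2
}
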